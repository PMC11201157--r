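#' Tally per-class pixel and presence statistics over a dataset
#'
#' Reads every mask of the manifest and returns exact per-class pixel counts
#' and shares together with image-presence counts (an image "contains" a
#' class if at least one pixel carries its label).
#'
#' @param mf A [manifest()]; use `partition` to restrict (class weights are
#'   conventionally computed on the training partition only, to avoid
#'   leaking statistics from evaluation data).
#' @param table A [class_table()].
#' @param partition Optional partition filter.
#' @return A list with tibbles `pixels` (`id`, `name`, `pixel_count`,
#'   `pixel_share`) and `presence` (`id`, `name`, `image_count`,
#'   `presence_pct`), plus `total_pixels` and `total_images`.
#' @export
tally_dataset <- function(mf, table, partition = NULL) {
  if (!is.null(partition)) mf <- mf[mf$partition %in% partition, ]
  if (nrow(mf) == 0) rlang::abort("manifest has no records to tally")
  cc <- n_classes(table)
  px <- numeric(cc); pres <- integer(cc)
  for (i in seq_len(nrow(mf))) {
    m <- read_mask(mf$mask[i])
    tryCatch(check_mask(m, table),
             error = function(e) rlang::abort(sprintf(
               "invalid mask '%s': %s", mf$mask[i], conditionMessage(e))))
    counts <- tabulate(as.vector(m) + 1L, nbins = cc)
    px <- px + counts
    pres <- pres + (counts > 0L)
  }
  total <- sum(px)
  list(
    pixels = tibble::tibble(id = table$id, name = table$name,
                            pixel_count = px, pixel_share = px / total),
    presence = tibble::tibble(
      id = table$id, name = table$name, image_count = pres,
      presence_pct = vapply(pres, presence_percentage, numeric(1),
                            total = nrow(mf))),
    total_pixels = total, total_images = nrow(mf)
  )
}

#' Percentage of images containing a class
#'
#' `100 * image_count / total`, rounded half-up to two decimals (the
#' convention of published per-class presence tables: 248 of 8080 prints as
#' 3.07).
#'
#' @param image_count Number of images containing the class.
#' @param total Total number of images (> 0).
#' @return Percentage rounded to 2 decimals.
#' @export
presence_percentage <- function(image_count, total) {
  if (total <= 0) rlang::abort("total must be positive")
  stopifnot(image_count >= 0, image_count <= total)
  floor(100 * image_count / total * 100 + 0.5) / 100
}

#' Compute class weights from pixel frequencies
#'
#' Algorithm-level class balancing: each pixel's loss contribution is
#' multiplied by its class weight, raising the effective importance of
#' rare classes. Schemes:
#' \describe{
#'   \item{median_frequency}{`w_c = median(f) / f_c` (default; the class at
#'     the median frequency gets weight 1).}
#'   \item{inverse_frequency}{`w_c = 1 / (C * f_c)`, so `w_c * f_c` is equal
#'     across classes.}
#'   \item{uniform}{all weights 1.}
#' }
#'
#' @param pixels Tibble with columns `id`, `name`, `pixel_share` (as
#'   returned in `tally_dataset()$pixels`).
#' @param scheme One of `"median_frequency"`, `"inverse_frequency"`,
#'   `"uniform"`.
#' @return A tibble (`id`, `name`, `pixel_share`, `weight`) with attribute
#'   `scheme`, of class `"class_weights"`.
#' @export
compute_weights <- function(pixels,
                            scheme = c("median_frequency", "inverse_frequency",
                                       "uniform")) {
  scheme <- match.arg(scheme)
  stopifnot(all(c("id", "pixel_share") %in% names(pixels)))
  f <- pixels$pixel_share
  if (scheme != "uniform" && any(f <= 0)) {
    zero <- pixels$name[f <= 0]
    rlang::abort(paste0(
      "zero pixel share for class(es): ", paste(zero, collapse = ", "),
      ". Weighting is undefined for unseen classes; either drop them from ",
      "the class table or smooth the frequency table before weighting ",
      "(no silent default is applied)."))
  }
  w <- switch(scheme,
    uniform = rep(1, length(f)),
    inverse_frequency = 1 / (length(f) * f),
    median_frequency = stats::median(f) / f)
  out <- tibble::tibble(id = pixels$id,
                        name = if ("name" %in% names(pixels)) pixels$name else NA,
                        pixel_share = f, weight = w)
  attr(out, "scheme") <- scheme
  class(out) <- c("class_weights", class(out))
  out
}

#' Raw versus weighted pixel-share report
#'
#' Multiplies each class's pixel share by its weight and renormalizes,
#' showing how weighting rebalances the effective class distribution:
#' dominant classes' weighted shares fall, minority classes' rise (under
#' inverse-frequency weights all weighted shares are equal).
#'
#' @param pixels Tibble with `id`, `pixel_share` (and optionally `name`).
#' @param weights A [compute_weights()] result over the same classes.
#' @return A tibble of class `"weighted_share_report"` with columns `id`,
#'   `name`, `share_pct`, `weight`, `weighted_share_pct`.
#' @export
weighted_share_report <- function(pixels, weights) {
  if (!identical(as.integer(pixels$id), as.integer(weights$id))) {
    rlang::abort("pixel table and weights cover different class sets")
  }
  wf <- pixels$pixel_share * weights$weight
  out <- tibble::tibble(
    id = pixels$id,
    name = if ("name" %in% names(pixels)) pixels$name else weights$name,
    share_pct = 100 * pixels$pixel_share,
    weight = weights$weight,
    weighted_share_pct = 100 * wf / sum(wf))
  class(out) <- c("weighted_share_report", class(out))
  out
}

#' @rdname weighted_share_report
#' @param object A `weighted_share_report`.
#' @param ... Ignored.
#' @export
autoplot.weighted_share_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("name", "share_pct", "weighted_share_pct")],
    cols = c("share_pct", "weighted_share_pct"),
    names_to = "kind", values_to = "pct")
  long$kind <- ifelse(long$kind == "share_pct", "raw", "weighted")
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$name, levels = object$name),
    y = .data$pct, shape = .data$kind, color = .data$kind)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_shape_manual(values = c(raw = 16, weighted = 4)) +
    ggplot2::labs(x = NULL, y = "pixel share (%)", shape = NULL, color = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
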