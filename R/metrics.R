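#' Confusion accumulator
#'
#' A `C x C` pixel-count matrix (rows = truth class, columns = predicted
#' class) accumulated over a dataset; the source of every non-boundary
#' metric. For class `c`: `TP = counts[c, c]`, `FN = rowsum - TP`,
#' `FP = colsum - TP`, `TN = total - TP - FP - FN`.
#'
#' @param n_classes Number of classes `C`.
#' @return A list of class `"confusion_accumulator"`.
#' @export
confusion_accumulator <- function(n_classes) {
  stopifnot(n_classes >= 1)
  structure(list(counts = matrix(0, n_classes, n_classes),
                 n_images = 0L, n_classes = as.integer(n_classes)),
            class = "confusion_accumulator")
}

#' Accumulate one prediction/truth mask pair
#'
#' Accumulation is additive and commutative: the order of image pairs does
#' not affect the final counts.
#'
#' @param acc A [confusion_accumulator()].
#' @param pred,truth Integer index masks of equal shape, labels `< C`.
#' @return The updated accumulator.
#' @export
accumulate <- function(acc, pred, truth) {
  stopifnot(inherits(acc, "confusion_accumulator"))
  if (!identical(dim(pred), dim(truth))) {
    rlang::abort("pred and truth must have equal dimensions")
  }
  cc <- acc$n_classes
  if (any(pred < 0 | pred >= cc) || any(truth < 0 | truth >= cc)) {
    rlang::abort(sprintf("mask labels must lie in 0..%d", cc - 1L))
  }
  idx <- as.vector(pred) * cc + as.vector(truth) + 1L
  acc$counts <- acc$counts + matrix(tabulate(idx, nbins = cc * cc), cc, cc)
  acc$n_images <- acc$n_images + 1L
  acc
}

#' Per-class metrics from a confusion accumulator
#'
#' Two accuracies are reported because two conventions coexist: `acc_ovr`
#' is the one-vs-rest accuracy `(TP + TN) / (TP + TN + FP + FN)`, which is
#' inflated by the abundant true negatives of rare classes, while
#' `class_acc = TP / (TP + FN)` (recall of the class) is the convention
#' used by segmentation toolboxes when tabulating per-class "Acc" and is
#' what the mean accuracy aggregates. A class with `TP + FP + FN = 0`
#' (absent from truth and prediction) is undefined: all ratio metrics are
#' `NA` and the class is excluded from means, never counted as 0 or 1.
#'
#' @param acc A [confusion_accumulator()].
#' @param class_id Class id in `0..C-1`.
#' @return A one-row tibble: `id`, `support`, `defined`, `acc_ovr`,
#'   `class_acc`, `iou`, `dice`, `precision`, `recall`.
#' @export
class_metrics <- function(acc, class_id) {
  stopifnot(class_id >= 0, class_id < acc$n_classes)
  i <- class_id + 1L
  total <- sum(acc$counts)
  tp <- acc$counts[i, i]
  fn <- sum(acc$counts[i, ]) - tp
  fp <- sum(acc$counts[, i]) - tp
  tn <- total - tp - fn - fp
  defined <- (tp + fp + fn) > 0
  rat <- function(num, den) if (defined && den > 0) num / den else NA_real_
  tibble::tibble(
    id = as.integer(class_id), support = tp + fn, defined = defined,
    acc_ovr = if (defined) (tp + tn) / total else NA_real_,
    class_acc = rat(tp, tp + fn),
    iou = if (defined) tp / (tp + fp + fn) else NA_real_,
    dice = if (defined) 2 * tp / (2 * tp + fp + fn) else NA_real_,
    precision = rat(tp, tp + fp),
    recall = rat(tp, tp + fn))
}

boundary_pixels <- function(mask, class_id) {
  r <- mask == class_id
  h <- nrow(mask); w <- ncol(mask)
  differs <- matrix(FALSE, h, w)
  differs[1, ] <- TRUE; differs[h, ] <- TRUE
  differs[, 1] <- TRUE; differs[, w] <- TRUE
  differs[-1, ] <- differs[-1, ] | (mask[-1, ] != mask[-h, ])
  differs[-h, ] <- differs[-h, ] | (mask[-h, ] != mask[-1, ])
  differs[, -1] <- differs[, -1] | (mask[, -1] != mask[, -w])
  differs[, -w] <- differs[, -w] | (mask[, -w] != mask[, -1])
  which(r & differs, arr.ind = TRUE)
}

#' Boundary F1 score for one class
#'
#' Boundary pixels of class `c` are pixels of the class with a 4-neighbor
#' of a different label (image-edge pixels of the class count as boundary).
#' Boundary precision is the fraction of predicted boundary pixels lying
#' within Euclidean distance `theta` of any true boundary pixel; recall is
#' symmetric; the score is their harmonic mean. Undefined (`NA`) when the
#' class is absent from both masks.
#'
#' @param pred,truth Integer index masks of equal shape.
#' @param class_id Class id.
#' @param theta Match tolerance in pixels; default 0.75% of the image
#'   diagonal.
#' @return A value in `[0, 1]`, or `NA` if undefined.
#' @export
boundary_f1 <- function(pred, truth, class_id, theta = NULL) {
  if (!identical(dim(pred), dim(truth))) {
    rlang::abort("pred and truth must have equal dimensions")
  }
  if (is.null(theta)) theta <- 0.0075 * sqrt(nrow(pred)^2 + ncol(pred)^2)
  if (theta <= 0) rlang::abort("theta must be positive")
  in_pred <- any(pred == class_id); in_truth <- any(truth == class_id)
  if (!in_pred && !in_truth) return(NA_real_)
  pb <- boundary_pixels(pred, class_id)
  tb <- boundary_pixels(truth, class_id)
  frac_matched <- function(a, b) {
    if (nrow(a) == 0) return(0)
    if (nrow(b) == 0) return(0)
    d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
    mean(apply(d2, 1, min) <= theta^2)
  }
  p <- frac_matched(pb, tb)
  r <- frac_matched(tb, pb)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

#' Summarize a confusion accumulator into a metrics report
#'
#' Aggregates: global accuracy `GAcc = trace / total`; `MAcc` and `MIoU`
#' are unweighted means of the defined per-class `class_acc` and `iou`;
#' `Mbfs` is the mean over classes of the per-image-averaged boundary F1
#' (each class averaged over the images where it appears in either mask).
#'
#' @param acc A [confusion_accumulator()].
#' @param per_image_bfs Optional numeric matrix (images x classes) of
#'   per-image boundary F1 values, `NA` where undefined.
#' @param table Optional [class_table()] to attach class names.
#' @return A list of class `"metrics_report"` with `per_class` (tibble) and
#'   `aggregates`.
#' @export
summarize_metrics <- function(acc, per_image_bfs = NULL, table = NULL) {
  stopifnot(inherits(acc, "confusion_accumulator"))
  if (sum(acc$counts) == 0) rlang::abort("empty accumulator")
  cc <- acc$n_classes
  per_class <- dplyr::bind_rows(
    lapply(seq_len(cc) - 1L, function(c) class_metrics(acc, c)))
  if (!is.null(table)) {
    per_class <- dplyr::left_join(per_class, table[, c("id", "name")], by = "id")
    per_class <- per_class[, c("id", "name", setdiff(names(per_class),
                                                     c("id", "name")))]
  }
  bfs <- rep(NA_real_, cc)
  if (!is.null(per_image_bfs)) {
    stopifnot(ncol(per_image_bfs) == cc)
    defined_cols <- colSums(!is.na(per_image_bfs)) > 0
    bfs[defined_cols] <- colMeans(per_image_bfs, na.rm = TRUE)[defined_cols]
  }
  per_class$bfs <- bfs
  aggregates <- list(
    GAcc = sum(diag(acc$counts)) / sum(acc$counts),
    MAcc = mean(per_class$class_acc[per_class$defined], na.rm = TRUE),
    MIoU = mean(per_class$iou[per_class$defined], na.rm = TRUE),
    Mbfs = if (all(is.na(bfs))) NA_real_ else mean(bfs, na.rm = TRUE))
  structure(list(per_class = per_class, aggregates = aggregates,
                 n_images = acc$n_images),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Segmentation metrics over %d image(s)\n", x$n_images))
  cat(sprintf("  GAcc %.4f | MAcc %.4f | MIoU %.4f | Mbfs %s\n",
              x$aggregates$GAcc, x$aggregates$MAcc, x$aggregates$MIoU,
              ifelse(is.na(x$aggregates$Mbfs), "NA",
                     sprintf("%.4f", x$aggregates$Mbfs))))
  print(x$per_class)
  invisible(x)
}

#' @rdname summarize_metrics
#' @param x A `metrics_report`.
#' @param ... Ignored.
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' @rdname summarize_metrics
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(GAcc = x$aggregates$GAcc, MAcc = x$aggregates$MAcc,
                 MIoU = x$aggregates$MIoU, Mbfs = x$aggregates$Mbfs,
                 n_images = x$n_images)
}

#' @rdname summarize_metrics
#' @param object A `metrics_report`.
#' @export
autoplot.metrics_report <- function(object, ...) {
  pc <- object$per_class
  pc$label <- if ("name" %in% names(pc)) pc$name else as.character(pc$id)
  long <- tidyr::pivot_longer(pc[, c("label", "class_acc", "iou", "bfs")],
                              cols = c("class_acc", "iou", "bfs"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$label, levels = pc$label),
    y = .data$value, fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write a metrics report as CSV / JSON
#'
#' CSV mirrors the per-class table layout with an aggregate footer row;
#' JSON carries the same content for machine use.
#'
#' @param report A [summarize_metrics()] report.
#' @param path Output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(per_class = as.data.frame(report$per_class),
                              aggregates = report$aggregates),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- as.data.frame(report$per_class)
    utils::write.csv(df, path, row.names = FALSE)
    footer <- sprintf("# GAcc=%.6f MAcc=%.6f MIoU=%.6f Mbfs=%.6f",
                      report$aggregates$GAcc, report$aggregates$MAcc,
                      report$aggregates$MIoU, report$aggregates$Mbfs)
    cat(footer, "\n", file = path, append = TRUE)
  }
  invisible(path)
}
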