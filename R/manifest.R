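#' Dataset manifests
#'
#' A manifest is a tibble with one row per image/mask pair and columns
#' `image`, `mask`, `partition` (one of `"train"`, `"val"`, `"test"`,
#' `"unassigned"`). Paths must be unique.
#'
#' @param image,mask Character vectors of file paths.
#' @param partition Partition tags; defaults to `"unassigned"`.
#' @return A tibble of class `"dataset_manifest"`.
#' @export
manifest <- function(image, mask, partition = "unassigned") {
  stopifnot(length(image) == length(mask))
  tb <- tibble::tibble(image = as.character(image), mask = as.character(mask),
                       partition = rep_len(as.character(partition), length(image)))
  validate_manifest(tb)
}

validate_manifest <- function(tb) {
  stopifnot(all(c("image", "mask", "partition") %in% names(tb)))
  if (anyDuplicated(tb$image) || anyDuplicated(tb$mask)) {
    rlang::abort("manifest paths must be unique")
  }
  ok <- tb$partition %in% c("train", "val", "test", "unassigned")
  if (!all(ok)) rlang::abort("partition tags must be train/val/test/unassigned")
  class(tb) <- unique(c("dataset_manifest", class(tb)))
  tb
}

#' Split a manifest into train/validation/test partitions
#'
#' Records are sorted canonically by image path, shuffled with a seeded
#' generator, and cut by the requested fractions, so the assignment is
#' reproducible and independent of filesystem ordering. Partition sizes are
#' `floor(f * N)` with the remainder assigned to training; with fractions
#' (0.6, 0.2, 0.2) an 8080-record manifest splits 4848/1616/1616.
#'
#' @param mf A [manifest()].
#' @param fractions Numeric `c(train, val, test)`, nonnegative, summing to 1.
#' @param seed Integer seed for the shuffle.
#' @return The manifest with `partition` filled in; row order is the
#'   canonical (path-sorted) order.
#' @export
split_manifest <- function(mf, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  mf <- validate_manifest(mf)
  stopifnot(length(fractions) == 3)
  if (any(fractions < 0)) rlang::abort("fractions must be nonnegative")
  if (abs(sum(fractions) - 1) > 1e-9) {
    rlang::abort(sprintf("fractions must sum to 1 (got %.12g)", sum(fractions)))
  }
  mf <- mf[order(mf$image), ]
  n <- nrow(mf)
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  n_train <- n - n_val - n_test
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  part <- character(n)
  part[perm[seq_len(n_train)]] <- "train"
  if (n_val > 0) part[perm[n_train + seq_len(n_val)]] <- "val"
  if (n_test > 0) part[perm[n_train + n_val + seq_len(n_test)]] <- "test"
  mf$partition <- part
  validate_manifest(mf)
}

#' Read / write a manifest CSV
#'
#' @param path CSV path with columns `image`, `mask`, `partition`.
#' @return `read_manifest()` returns a [manifest()]; `write_manifest()`
#'   returns `path` invisibly.
#' @export
read_manifest <- function(path) {
  tb <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_manifest(tb)
}

#' @rdname read_manifest
#' @param mf A [manifest()].
#' @export
write_manifest <- function(mf, path) {
  utils::write.csv(as.data.frame(mf)[, c("image", "mask", "partition")],
                   path, row.names = FALSE)
  invisible(path)
}
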