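# Images are numeric H x W x 3 arrays in [0, 1] (png::readPNG convention);
# index masks are integer H x W matrices of class ids.

as_index_mask <- function(m) {
  storage.mode(m) <- "integer"
  m
}

check_mask <- function(mask, table, what = "mask") {
  if (!is.matrix(mask)) rlang::abort(sprintf("%s must be an H x W matrix", what))
  bad <- mask < 0L | mask >= n_classes(table)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    rlang::abort(sprintf(
      "%s contains label %d at (row %d, col %d) outside class table range 0..%d",
      what, mask[idx[1], idx[2]], idx[1], idx[2], n_classes(table) - 1L))
  }
  invisible(mask)
}

#' Convert a color-coded mask to an index mask
#'
#' Each pixel's RGB triple is looked up in the class table by exact byte
#' equality (colors are annotation artifacts, not photographs, so no
#' tolerance is applied). Unknown colors are an error that names the
#' offending color and its first coordinate.
#'
#' @param color_mask `H x W x 3` numeric array in `[0, 1]`.
#' @param table A [class_table()].
#' @return An integer `H x W` index mask.
#' @export
color_to_index <- function(color_mask, table) {
  stopifnot(length(dim(color_mask)) == 3, dim(color_mask)[3] >= 3)
  h <- dim(color_mask)[1]; w <- dim(color_mask)[2]
  bytes <- round(color_mask[, , 1:3] * 255)
  key <- bytes[, , 1] * 65536 + bytes[, , 2] * 256 + bytes[, , 3]
  tab_key <- table$r * 65536 + table$g * 256 + table$b
  pos <- match(as.vector(key), tab_key)
  if (anyNA(pos)) {
    i <- which(is.na(pos))[1]
    rc <- arrayInd(i, c(h, w))
    rlang::abort(sprintf(
      "unknown mask color rgb(%d, %d, %d) at (row %d, col %d)",
      bytes[rc[1], rc[2], 1], bytes[rc[1], rc[2], 2], bytes[rc[1], rc[2], 3],
      rc[1], rc[2]))
  }
  as_index_mask(matrix(table$id[pos], h, w))
}

#' Render an index mask as a color image
#'
#' @param mask Integer `H x W` index mask.
#' @param table A [class_table()].
#' @return `H x W x 3` numeric array in `[0, 1]`.
#' @export
index_to_color <- function(mask, table) {
  check_mask(mask, table)
  h <- nrow(mask); w <- ncol(mask)
  pos <- as.vector(mask) + 1L
  array(c(table$r[pos], table$g[pos], table$b[pos]) / 255, dim = c(h, w, 3))
}

#' Read / write images and index masks as PNG
#'
#' Index masks are stored as 8-bit single-channel PNGs (class id = gray
#' level); images as 8-bit RGB.
#'
#' @param path PNG file path.
#' @return `read_image()` an `H x W x 3` array in `[0,1]`; `read_mask()` an
#'   integer matrix. Writers return `path` invisibly.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' @rdname read_image
#' @param image `H x W x 3` array in `[0,1]`.
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' @rdname read_image
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  as_index_mask(round(m * 255))
}

#' @rdname read_image
#' @param mask Integer `H x W` index mask with values below 256.
#' @export
write_mask <- function(mask, path) {
  stopifnot(all(mask >= 0), all(mask <= 255))
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Resize an image / mask pair
#'
#' The image is resized by bicubic interpolation (output pixels are weighted
#' averages over the nearest 4-by-4 neighborhood, with kernel widening when
#' downsizing so the average covers the footprint of the output pixel). The
#' mask is resized by nearest-neighbor sampling: interpolating class labels
#' would manufacture invalid classes, so label validity takes precedence and
#' the output label set is always a subset of the input's.
#'
#' @param image `H x W x 3` array in `[0,1]`.
#' @param mask Integer `H x W` index mask.
#' @param target Integer vector `c(H', W')`, both positive.
#' @return A list with elements `image` and `mask` at the target size.
#' @export
resize_pair <- function(image, mask, target) {
  stopifnot(length(target) == 2)
  if (any(target < 1)) rlang::abort("target dimensions must be positive")
  stopifnot(dim(image)[1] == nrow(mask), dim(image)[2] == ncol(mask))
  list(image = resize_bicubic(image, target[1], target[2]),
       mask = resize_nearest(mask, target[1], target[2]))
}

# Keys cubic convolution kernel (a = -1/2), the classical bicubic kernel.
cubic_kernel <- function(x) {
  ax <- abs(x)
  ifelse(ax <= 1, 1.5 * ax^3 - 2.5 * ax^2 + 1,
         ifelse(ax < 2, -0.5 * ax^3 + 2.5 * ax^2 - 4 * ax + 2, 0))
}

# Interpolation weights along one axis: rows = output index, cols = input
# index. When downsizing (scale < 1) the kernel is dilated by 1/scale so the
# output value averages over the whole source footprint (antialiasing).
resample_matrix <- function(n_in, n_out) {
  scale <- n_out / n_in
  ksc <- min(scale, 1)
  # center of output pixel i in input coordinates
  u <- (seq_len(n_out) - 0.5) / scale + 0.5
  half <- ceiling(2 / ksc)
  offs <- seq(-half, half)
  w <- matrix(0, n_out, n_in)
  for (k in offs) {
    j <- floor(u) + k
    wt <- cubic_kernel(ksc * (u - j)) * ksc
    jc <- pmin(pmax(j, 1), n_in)          # replicate borders
    w[cbind(seq_len(n_out), jc)] <- w[cbind(seq_len(n_out), jc)] + wt
  }
  w / rowSums(w)
}

#' @rdname resize_pair
#' @param out_h,out_w Target height and width.
#' @export
resize_bicubic <- function(image, out_h, out_w) {
  d <- dim(image)
  if (d[1] == out_h && d[2] == out_w) return(image)
  wr <- resample_matrix(d[1], out_h)
  wc <- resample_matrix(d[2], out_w)
  if (length(d) == 2) return(wr %*% image %*% t(wc))
  out <- array(0, dim = c(out_h, out_w, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- wr %*% image[, , ch] %*% t(wc)
  out
}

#' @rdname resize_pair
#' @export
resize_nearest <- function(mask, out_h, out_w) {
  h <- nrow(mask); w <- ncol(mask)
  if (h == out_h && w == out_w) return(mask)
  ri <- pmin(pmax(ceiling((seq_len(out_h) - 0.5) * h / out_h), 1L), h)
  ci <- pmin(pmax(ceiling((seq_len(out_w) - 0.5) * w / out_w), 1L), w)
  as_index_mask(mask[ri, ci, drop = FALSE])
}

#' Prediction/ground-truth disagreement overlay
#'
#' Renders the two masks in the channel-split style of MATLAB's
#' `imshowpair`: each mask is mapped to a gray level (class id scaled by
#' `255 / (C - 1)`), the prediction drives the red channel and the ground
#' truth the green and blue channels. Where the masks agree all channels are
#' equal (gray); disagreements show as magenta (prediction-only intensity)
#' or green (truth-only).
#'
#' @param pred,truth Integer index masks of equal size.
#' @param table A [class_table()].
#' @return `H x W x 3` numeric array in `[0,1]`.
#' @export
diff_overlay <- function(pred, truth, table) {
  if (!identical(dim(pred), dim(truth))) {
    rlang::abort("prediction and ground-truth masks must have equal dimensions")
  }
  check_mask(pred, table, "pred"); check_mask(truth, table, "truth")
  cc <- n_classes(table)
  sc <- if (cc > 1) 1 / (cc - 1) else 0
  out <- array(0, dim = c(nrow(pred), ncol(pred), 3))
  out[, , 1] <- pred * sc
  out[, , 2] <- truth * sc
  out[, , 3] <- truth * sc
  out
}
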