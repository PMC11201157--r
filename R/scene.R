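#' Configure a synthetic imbalanced scene dataset
#'
#' A scene config fully specifies a synthetic "surgical scene" dataset:
#' per-class image-presence probabilities, target pixel shares, shape
#' families, colors, texture noise, blur and a master seed. Exactly one
#' class must use the `background` family; its presence probability is 1 and
#' it absorbs whatever pixel share the foreground classes do not claim.
#'
#' @param classes A tibble with columns `name`, `presence_prob`,
#'   `target_share`, `family` (one of background, large_blob, medium_blob,
#'   thin_curve, elongated_tool, scattered_specks) and colors `r`, `g`, `b`.
#' @param image_size Integer `c(H, W)`.
#' @param noise_sd Gaussian texture noise standard deviation (intensity
#'   units on the `[0,1]` scale).
#' @param blur_sigma Gaussian blur standard deviation in pixels.
#' @param seed Master seed; each sample derives a counter-based sub-seed
#'   from `(seed, index)` so samples are independent and order-insensitive.
#' @return A list of class `"scene_config"`.
#' @export
scene_config <- function(classes, image_size = c(96L, 96L),
                         noise_sd = 0.05, blur_sigma = 1.0, seed = 1L) {
  stopifnot(is.data.frame(classes), nrow(classes) >= 1)
  need <- c("name", "presence_prob", "target_share", "family", "r", "g", "b")
  stopifnot(all(need %in% names(classes)))
  fams <- c("background", "large_blob", "medium_blob", "thin_curve",
            "elongated_tool", "scattered_specks")
  if (!all(classes$family %in% fams)) rlang::abort("unknown shape family")
  if (sum(classes$family == "background") != 1) {
    rlang::abort("exactly one class must have the background family")
  }
  if (classes$presence_prob[classes$family == "background"] != 1) {
    rlang::abort("background presence probability must be 1")
  }
  fg <- classes$family != "background"
  if (sum(classes$target_share[fg]) > 1 + 1e-9) {
    rlang::abort("foreground target shares must sum to at most 1")
  }
  stopifnot(all(classes$presence_prob >= 0 & classes$presence_prob <= 1),
            all(classes$target_share >= 0 & classes$target_share <= 1))
  classes$id <- seq_len(nrow(classes)) - 1L
  structure(list(
    n_classes = nrow(classes),
    classes = tibble::as_tibble(classes),
    image_size = as.integer(image_size),
    noise_sd = noise_sd, blur_sigma = blur_sigma, seed = as.integer(seed)
  ), class = "scene_config")
}

#' The 13-class cholecystectomy scene profile
#'
#' Preset reproducing the statistical structure of a 13-class laparoscopic
#' cholecystectomy dataset: four dominant classes with pixel-share targets
#' 0.27 / 0.22 / 0.21 / 0.15 (background, abdominal wall, liver, fat), four
#' minority structures each below 1% of pixels (blood, cystic duct, hepatic
#' vein, liver ligament), per-class image-presence probabilities matching
#' the published per-image frequencies (e.g. liver 1.00, cystic duct
#' 0.0307), thin curves for the small tubular structures and elongated tools
#' for the two instruments.
#'
#' @param n_classes Must be 13 for this preset.
#' @inheritParams scene_config
#' @return A [scene_config()].
#' @export
cholecseg_profile <- function(n_classes = 13L, image_size = c(96L, 96L),
                              noise_sd = 0.05, blur_sigma = 1.0, seed = 1L) {
  if (n_classes != 13L) {
    rlang::abort("the cholecystectomy profile is defined for exactly 13 classes")
  }
  tb <- cholecseg8k_classes()
  # background is the canvas: presence 1 by construction (the published
  # 99.69% counts images where other classes cover it entirely)
  presence <- c(1.0000, 0.8979, 1.00, 0.5641, 0.9295, 0.7450, 0.1980,
                0.0856, 0.0307, 0.2790, 0.8491, 0.0392, 0.0297)
  share <- c(0.27, 0.22, 0.21, 0.03, 0.15, 0.020, 0.012, 0.004, 0.003,
             0.014, 0.055, 0.003, 0.003)
  family <- c("background", "large_blob", "large_blob", "large_blob",
              "large_blob", "elongated_tool", "medium_blob",
              "scattered_specks", "thin_curve", "elongated_tool",
              "medium_blob", "thin_curve", "thin_curve")
  classes <- tibble::tibble(
    name = tb$name, presence_prob = presence, target_share = share,
    family = family, r = tb$r, g = tb$g, b = tb$b)
  scene_config(classes, image_size = image_size, noise_sd = noise_sd,
               blur_sigma = blur_sigma, seed = seed)
}

#' Class table of a scene config
#' @param config A [scene_config()].
#' @return A [class_table()].
#' @export
scene_class_table <- function(config) {
  with(config$classes, class_table(name, r, g, b))
}

# Painting order: background first, then progressively foreground layers so
# instruments occlude tissue, as in laparoscopy.
paint_rank <- function(family) {
  match(family, c("background", "large_blob", "medium_blob", "thin_curve",
                  "scattered_specks", "elongated_tool"))
}

scene_sub_seed <- function(seed, index) {
  as.integer((abs(seed) %% 65521) * 31687 + (index %% 65521) * 7919 + 13) %% 2147483647L
}

# ---- shape rasterizers (all return a logical H x W matrix) ----

scene_grids <- function(h, w) {
  list(y = matrix(rep(seq_len(h), w), h), x = matrix(rep(seq_len(w), each = h), h))
}

raster_ellipse <- function(g, cx, cy, a, b, th) {
  dx <- g$x - cx; dy <- g$y - cy
  u <- (dx * cos(th) + dy * sin(th)) / a
  v <- (-dx * sin(th) + dy * cos(th)) / b
  u * u + v * v <= 1
}

raster_blobs <- function(g, h, w, area, k_range, inflate) {
  k <- sample(k_range, 1)
  m <- matrix(FALSE, h, w)
  for (i in seq_len(k)) {
    ai <- inflate * area / k
    rho <- runif(1, 0.45, 1)
    a <- sqrt(ai / (pi * rho)); b <- rho * a
    cx <- runif(1, 0.08 * w, 0.92 * w); cy <- runif(1, 0.08 * h, 0.92 * h)
    m <- m | raster_ellipse(g, cx, cy, a, b, runif(1, 0, pi))
  }
  m
}

raster_curve <- function(g, h, w, area) {
  p <- matrix(runif(6, c(0.1 * w, 0.1 * h), c(0.9 * w, 0.9 * h)), 2)
  t <- seq(0, 1, length.out = 160)
  bx <- (1 - t)^2 * p[1, 1] + 2 * t * (1 - t) * p[1, 2] + t^2 * p[1, 3]
  by <- (1 - t)^2 * p[2, 1] + 2 * t * (1 - t) * p[2, 2] + t^2 * p[2, 3]
  len <- sum(sqrt(diff(bx)^2 + diff(by)^2))
  width <- min(max(area / max(len, 1), 1), 8)
  d2 <- matrix(Inf, h, w)
  for (i in seq_along(t)) {
    d2 <- pmin(d2, (g$x - bx[i])^2 + (g$y - by[i])^2)
  }
  d2 <= (width / 2)^2
}

raster_tool <- function(g, h, w, area) {
  side <- sample(4, 1)
  entry <- switch(side,
    c(runif(1, 1, w), 1), c(runif(1, 1, w), h),
    c(1, runif(1, 1, h)), c(w, runif(1, 1, h)))
  inward <- switch(side, pi / 2, -pi / 2, 0, pi)
  th <- inward + runif(1, -0.6, 0.6)
  len <- runif(1, 0.45, 0.8) * min(h, w)
  width <- min(max(area / len, 2), w / 3)
  dx <- g$x - entry[1]; dy <- g$y - entry[2]
  tproj <- dx * cos(th) + dy * sin(th)
  dperp <- abs(-dx * sin(th) + dy * cos(th))
  taper <- ifelse(tproj > 0.8 * len,
                  pmax(0.15, 1 - 0.85 * (tproj - 0.8 * len) / (0.2 * len)), 1)
  tproj >= 0 & tproj <= len & dperp <= taper * width / 2
}

raster_specks <- function(g, h, w, area) {
  k <- sample(3:10, 1)
  r0 <- sqrt(area / (k * pi))
  m <- matrix(FALSE, h, w)
  for (i in seq_len(k)) {
    r <- max(1, r0 * runif(1, 0.7, 1.3))
    cx <- runif(1, 0.1 * w, 0.9 * w); cy <- runif(1, 0.1 * h, 0.9 * h)
    m <- m | ((g$x - cx)^2 + (g$y - cy)^2 <= r^2)
  }
  m
}

raster_family <- function(family, g, h, w, area) {
  switch(family,
    large_blob = raster_blobs(g, h, w, area, 2:4, 1.3),
    medium_blob = raster_blobs(g, h, w, area, 1:2, 1.15),
    thin_curve = raster_curve(g, h, w, area),
    elongated_tool = raster_tool(g, h, w, area),
    scattered_specks = raster_specks(g, h, w, area),
    rlang::abort(sprintf("no rasterizer for family '%s'", family)))
}

# Rasterize a shape and top up its pixel count toward the requested area:
# edge clipping and within-class overlap otherwise leave realized pixel
# shares well short of their targets.
raster_with_area <- function(family, g, h, w, area) {
  m <- raster_family(family, g, h, w, area)
  tries <- 0
  while (sum(m) < 0.85 * area && tries < 4) {
    tries <- tries + 1
    m <- m | raster_family(family, g, h, w, max(area - sum(m), 0.1 * area))
  }
  m
}

gaussian_band <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  half <- ceiling(3 * sigma)
  b <- matrix(0, n, n)
  for (k in -half:half) {
    j <- pmin(pmax(seq_len(n) + k, 1), n)
    wt <- dnorm(k, sd = sigma)
    b[cbind(seq_len(n), j)] <- b[cbind(seq_len(n), j)] + wt
  }
  b / rowSums(b)
}

#' Generate one synthetic scene sample
#'
#' The mask is painted back-to-front (background, blobs, curves, specks,
#' tools) for each class whose Bernoulli presence draw succeeds; when a
#' class is present its shape area targets
#' `target_share / presence_prob / (1 - later_cover)`, the first-order
#' correction for occlusion by classes painted on top, so the dataset-level
#' mean pixel share approaches `target_share`. The image is the per-class
#' base color plus a smooth illumination gradient, Gaussian texture noise
#' and Gaussian blur. Deterministic given `(config$seed, index)`.
#'
#' @param config A [scene_config()].
#' @param index Sample index (counter for the per-sample sub-seed).
#' @return A list with `image` (`H x W x 3` in `[0,1]`) and `mask`
#'   (integer `H x W`).
#' @export
generate_scene <- function(config, index = 1L) {
  stopifnot(inherits(config, "scene_config"))
  h <- config$image_size[1]; w <- config$image_size[2]
  cls <- config$classes
  ord <- order(paint_rank(cls$family), cls$id)
  withr::with_seed(scene_sub_seed(config$seed, index), {
    present <- runif(nrow(cls)) < cls$presence_prob
    present[cls$family == "background"] <- TRUE
    bg_id <- cls$id[cls$family == "background"]
    mask <- matrix(bg_id, h, w)
    g <- scene_grids(h, w)
    npx <- h * w
    for (pos in seq_along(ord)) {
      i <- ord[pos]
      if (cls$family[i] == "background" || !present[i]) next
      later <- ord[-seq_len(pos)]
      later_cover <- min(sum(cls$target_share[later]), 0.8)
      area <- min(cls$target_share[i] / max(cls$presence_prob[i], 1e-6) /
                    (1 - later_cover), 0.8) * npx
      shp <- raster_with_area(cls$family[i], g, h, w, area)
      if (!any(shp)) shp[ceiling(h / 2), ceiling(w / 2)] <- TRUE
      mask[shp] <- cls$id[i]
    }
    base <- cbind(cls$r, cls$g, cls$b)[as.vector(mask) + 1L, ] / 255
    img <- array(base, dim = c(h, w, 3))
    gx <- runif(1, -0.15, 0.15); gy <- runif(1, -0.15, 0.15)
    grad <- gx * (g$x / w - 0.5) + gy * (g$y / h - 0.5)
    img <- img + as.vector(grad) + array(rnorm(npx * 3, sd = config$noise_sd),
                                         dim = c(h, w, 3))
    if (config$blur_sigma > 0) {
      br <- gaussian_band(h, config$blur_sigma)
      bc <- gaussian_band(w, config$blur_sigma)
      for (ch in 1:3) img[, , ch] <- br %*% img[, , ch] %*% t(bc)
    }
    list(image = pmin(pmax(img, 0), 1), mask = as_index_mask(mask))
  })
}

#' Generate and write a synthetic dataset
#'
#' Writes `n` PNG image/mask pairs, a manifest CSV and the generating
#' config as a JSON sidecar for provenance. Regeneration from the same
#' config and `n` is bit-identical.
#'
#' @inheritParams generate_scene
#' @param n Number of samples (>= 1).
#' @param out_dir Output directory, created if needed.
#' @return The [manifest()] of written pairs (partition `"unassigned"`).
#' @export
generate_dataset <- function(config, n, out_dir) {
  stopifnot(n >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) rlang::abort(sprintf("cannot create '%s'", out_dir))
  img_paths <- file.path(out_dir, sprintf("img_%04d.png", seq_len(n)))
  mask_paths <- file.path(out_dir, sprintf("mask_%04d.png", seq_len(n)))
  for (i in seq_len(n)) {
    s <- generate_scene(config, i)
    write_image(s$image, img_paths[i])
    write_mask(s$mask, mask_paths[i])
  }
  mf <- manifest(img_paths, mask_paths)
  write_manifest(mf, file.path(out_dir, "manifest.csv"))
  sidecar <- list(classes = as.data.frame(config$classes),
                  image_size = config$image_size, noise_sd = config$noise_sd,
                  blur_sigma = config$blur_sigma, seed = config$seed)
  jsonlite::write_json(sidecar, file.path(out_dir, "scene_config.json"),
                       auto_unbox = TRUE, digits = NA)
  mf
}

#' Load a scene dataset into memory
#'
#' Reads every image/mask pair of a manifest (optionally one partition)
#' into a list of samples, the in-memory form the training loop consumes.
#'
#' @param mf A [manifest()].
#' @param partition Optional partition filter.
#' @return A list of `list(image, mask)` samples.
#' @export
load_samples <- function(mf, partition = NULL) {
  if (!is.null(partition)) mf <- mf[mf$partition %in% partition, ]
  if (nrow(mf) == 0) rlang::abort("no records to load")
  purrr::map(seq_len(nrow(mf)), function(i) {
    list(image = read_image(mf$image[i]), mask = read_mask(mf$mask[i]))
  })
}
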