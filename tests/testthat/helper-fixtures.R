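# Small in-code fixtures shared across tests.

toy_table <- function(n = 3) {
  class_table(paste0("class", seq_len(n) - 1),
              r = seq(0, 250, length.out = n),
              g = rev(seq(0, 250, length.out = n)),
              b = seq(10, 200, length.out = n))
}

# deterministic random mask
random_mask <- function(h, w, n_classes, seed) {
  withr::with_seed(seed, matrix(sample(0:(n_classes - 1), h * w, TRUE), h, w))
}

# one-hot probability map from a mask
one_hot_probs <- function(mask, n_classes) {
  h <- nrow(mask); w <- ncol(mask)
  p <- array(0, c(h, w, n_classes))
  for (c in seq_len(n_classes) - 1) p[, , c + 1][mask == c] <- 1
  p
}

# tiny scene config: few classes, small canvas, cheap to generate
tiny_scene <- function(seed = 1, size = c(32L, 32L)) {
  scene_config(
    tibble::tibble(
      name = c("bg", "blob", "curve", "tool"),
      presence_prob = c(1, 0.9, 0.5, 0.8),
      target_share = c(0.55, 0.25, 0.02, 0.08),
      family = c("background", "large_blob", "thin_curve", "elongated_tool"),
      r = c(10, 200, 240, 90), g = c(10, 60, 240, 90), b = c(10, 40, 60, 110)),
    image_size = size, seed = seed)
}

# brute-force per-class metrics from pixel sets (independent oracle)
brute_class_metrics <- function(pred, truth, class_id) {
  p_set <- which(pred == class_id)
  t_set <- which(truth == class_id)
  tp <- length(intersect(p_set, t_set))
  fp <- length(setdiff(p_set, t_set))
  fn <- length(setdiff(t_set, p_set))
  tn <- length(pred) - tp - fp - fn
  if (tp + fp + fn == 0) return(NULL)
  list(acc_ovr = (tp + tn) / length(pred),
       class_acc = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       iou = tp / (tp + fp + fn),
       dice = 2 * tp / (2 * tp + fp + fn),
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

# brute-force boundary F1: boundary sets by explicit neighbor scan,
# distances by full pairwise enumeration
brute_boundary_f1 <- function(pred, truth, class_id, theta) {
  bset <- function(mask) {
    out <- NULL
    h <- nrow(mask); w <- ncol(mask)
    for (i in seq_len(h)) for (j in seq_len(w)) {
      if (mask[i, j] != class_id) next
      edge <- i == 1 || i == h || j == 1 || j == w
      nb <- c(if (i > 1) mask[i - 1, j], if (i < h) mask[i + 1, j],
              if (j > 1) mask[i, j - 1], if (j < w) mask[i, j + 1])
      if (edge || any(nb != mask[i, j])) out <- rbind(out, c(i, j))
    }
    out
  }
  if (!any(pred == class_id) && !any(truth == class_id)) return(NA_real_)
  pb <- bset(pred); tb <- bset(truth)
  match_frac <- function(a, b) {
    if (is.null(a) || is.null(b)) return(0)
    hits <- 0
    for (i in seq_len(nrow(a))) {
      d <- sqrt((a[i, 1] - b[, 1])^2 + (a[i, 2] - b[, 2])^2)
      if (min(d) <= theta) hits <- hits + 1
    }
    hits / nrow(a)
  }
  p <- match_frac(pb, tb)
  r <- match_frac(tb, pb)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}
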