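#' Loss configuration
#'
#' Bundles every tunable of the loss zoo. Defaults are the combined
#' cross-entropy/Tversky loss with the parameterization that favours
#' minority structures: mixing priority `delta = 0.7` (cross-entropy
#' dominant), false-negative weight `beta = 0.7` above the false-positive
#' weight `sigma = 0.3`, focal focusing `gamma = 2` with `alpha_t = 0.25`,
#' and smoothing `epsilon = 1e-6`.
#'
#' @param kind One of `"CE"`, `"FL"`, `"DiL"`, `"TL"`, `"CEDL"`, `"CETL"`.
#' @param alpha_t Focal weighting factor in `[0, 1]` (scalar, or one value
#'   per class applied by true class).
#' @param gamma Focal focusing exponent, `>= 0`.
#' @param sigma,beta Tversky false-positive / false-negative weights, `>= 0`.
#' @param delta Mixing priority of the cross-entropy term in the combined
#'   losses, in `[0, 1]`.
#' @param epsilon Tversky/Dice smoothing added to numerator and denominator.
#' @param ce_eps Clamp applied inside `log()` so a zero predicted
#'   probability yields a large finite loss, never `Inf`.
#' @param class_weights Optional [compute_weights()] table or numeric vector
#'   of per-class weights for the cross-entropy term.
#' @param weight_tversky Also weight the per-class Tversky/Dice terms
#'   (default `FALSE`: weights enter the cross-entropy term only).
#' @param per_image Aggregate the Tversky sums per image and average,
#'   instead of summing pixels across the whole batch (default `FALSE`).
#' @return A list of class `"loss_config"`.
#' @export
loss_config <- function(kind = c("CETL", "CEDL", "CE", "FL", "DiL", "TL"),
                        alpha_t = 0.25, gamma = 2, sigma = 0.3, beta = 0.7,
                        delta = 0.7, epsilon = 1e-6, ce_eps = 1e-12,
                        class_weights = NULL, weight_tversky = FALSE,
                        per_image = FALSE) {
  kind <- match.arg(kind)
  stopifnot(gamma >= 0, sigma >= 0, beta >= 0, delta >= 0, delta <= 1,
            epsilon > 0, all(alpha_t >= 0), all(alpha_t <= 1))
  structure(list(kind = kind, alpha_t = alpha_t, gamma = gamma, sigma = sigma,
                 beta = beta, delta = delta, epsilon = epsilon, ce_eps = ce_eps,
                 class_weights = class_weights, weight_tversky = weight_tversky,
                 per_image = per_image),
            class = "loss_config")
}

# ---- internal representation: probabilities as an M x C matrix ----

prob_matrix <- function(probs) {
  if (is.matrix(probs)) return(probs)
  d <- dim(probs)
  stopifnot(length(d) == 3)
  matrix(as.vector(probs), d[1] * d[2], d[3])
}

target_vector <- function(target) as.integer(as.vector(target))

weights_vector <- function(class_weights, cc) {
  if (is.null(class_weights)) return(rep(1, cc))
  w <- if (is.data.frame(class_weights)) class_weights$weight else class_weights
  stopifnot(length(w) == cc, all(is.finite(w)), all(w > 0))
  as.numeric(w)
}

#' Per-pixel softmax over class logits
#'
#' Numerically stabilized by per-pixel max subtraction; adding a constant to
#' every channel leaves the output unchanged and the argmax is preserved.
#'
#' @param logits `H x W x C` array (or `M x C` matrix) of finite reals.
#' @return Probabilities of the same shape; each pixel's class vector lies
#'   on the simplex.
#' @export
softmax_probabilities <- function(logits) {
  if (any(!is.finite(logits))) rlang::abort("logits must be finite")
  z <- prob_matrix(logits)
  z <- z - row_max(z)$max
  e <- exp(z)
  p <- e / rowSums(e)
  if (is.matrix(logits)) p else array(p, dim = dim(logits))
}

# chain rule through softmax: given dL/dp, return dL/dlogits (both M x C)
softmax_backward <- function(p, dp) {
  p * (dp - rowSums(dp * p))
}

# ---- cross-entropy ----

ce_loss_grad <- function(p, t, w, ce_eps, want_grad = TRUE) {
  m <- nrow(p)
  idx <- cbind(seq_len(m), t + 1L)
  pt <- pmin(pmax(p[idx], ce_eps), 1)
  wm <- w[t + 1L]
  sw <- sum(wm)
  value <- sum(wm * (-log(pt))) / sw
  grad <- NULL
  if (want_grad) {
    grad <- matrix(0, m, ncol(p))
    grad[idx] <- -wm / pt / sw
  }
  list(value = value, grad = grad)
}

#' Weighted multiclass cross-entropy
#'
#' Mean over pixels of `w[y] * (-log p_t)`, normalized by the sum of the
#' applied weights so uniform weights reduce exactly to the unweighted
#' mean. `p_t`, the probability the model assigns to a pixel's true class,
#' is clamped below by `ce_eps` so the loss is always finite.
#'
#' @param probs `H x W x C` probability array (see
#'   [softmax_probabilities()]) or `M x C` matrix.
#' @param target Integer index mask (`H x W` or vector), values in
#'   `0..C-1`.
#' @param class_weights Optional per-class weights (tibble or vector).
#' @param ce_eps Lower clamp on `p_t`.
#' @return Nonnegative scalar; 0 iff every pixel assigns probability 1 to
#'   its true class.
#' @export
cross_entropy <- function(probs, target, class_weights = NULL,
                          ce_eps = 1e-12) {
  p <- prob_matrix(probs); t <- target_vector(target)
  stopifnot(length(t) == nrow(p), all(t >= 0), all(t < ncol(p)))
  w <- weights_vector(class_weights, ncol(p))
  ce_loss_grad(p, t, w, ce_eps, want_grad = FALSE)$value
}

# ---- focal ----

fl_loss_grad <- function(p, t, alpha_t, gamma, ce_eps, want_grad = TRUE) {
  m <- nrow(p)
  idx <- cbind(seq_len(m), t + 1L)
  pt <- pmin(pmax(p[idx], ce_eps), 1)
  am <- if (length(alpha_t) > 1) alpha_t[t + 1L] else rep(alpha_t, m)
  q <- 1 - pt
  value <- mean(am * q^gamma * (-log(pt)))
  grad <- NULL
  if (want_grad) {
    dpt <- if (gamma == 0) -am / pt else
      am * gamma * q^(gamma - 1) * log(pt) - am * q^gamma / pt
    grad <- matrix(0, m, ncol(p))
    grad[idx] <- dpt / m
  }
  list(value = value, grad = grad)
}

#' Focal loss
#'
#' Cross-entropy modulated by `(1 - p_t)^gamma`, which down-weights easy
#' (confidently correct) pixels and focuses training on hard ones, scaled
#' by the weighting factor `alpha_t`. At `gamma = 0`, `alpha_t = 1` it
#' equals the unweighted cross-entropy.
#'
#' @inheritParams cross_entropy
#' @param alpha_t Weighting factor in `[0,1]`, scalar or per-class vector
#'   indexed by the true class.
#' @param gamma Focusing exponent `>= 0`.
#' @return Nonnegative scalar.
#' @export
focal_loss <- function(probs, target, alpha_t = 0.25, gamma = 2,
                       ce_eps = 1e-12) {
  stopifnot(gamma >= 0, all(alpha_t >= 0), all(alpha_t <= 1))
  p <- prob_matrix(probs); t <- target_vector(target)
  stopifnot(length(t) == nrow(p))
  fl_loss_grad(p, t, alpha_t, gamma, ce_eps, want_grad = FALSE)$value
}

# ---- Tversky family ----

ti_class <- function(p, t, class_id, sigma, beta, epsilon) {
  j <- p[, class_id + 1L]
  g <- as.numeric(t == class_id)
  tp <- sum(j * g); fp <- sum(j * (1 - g)); fn <- sum((1 - j) * g)
  (tp + epsilon) / (tp + sigma * fp + beta * fn + epsilon)
}

#' Soft Tversky index for one class
#'
#' `TI_c = sum(J_c G_c) / (sum(J_c G_c) + sigma * sum(J_c G_notc) +
#' beta * sum(J_notc G_c))` over all pixels, with `J` the predicted
#' probability channel of class `c` and `G` the one-hot ground truth;
#' `epsilon` is added to numerator and denominator. `sigma` and `beta`
#' weigh the contribution of false positives and false negatives. On
#' one-hot probabilities this equals the hard Tversky index, and at
#' `sigma = beta = 0.5` it is the Dice index.
#'
#' @inheritParams cross_entropy
#' @param class_id Class id in `0..C-1`.
#' @param sigma,beta False-positive / false-negative weights, `>= 0`.
#' @param epsilon Smoothing constant.
#' @return A value in `[0, 1]`.
#' @export
tversky_index <- function(probs, target, class_id, sigma = 0.3, beta = 0.7,
                          epsilon = 1e-6) {
  stopifnot(sigma >= 0, beta >= 0)
  p <- prob_matrix(probs); t <- target_vector(target)
  stopifnot(length(t) == nrow(p), class_id >= 0, class_id < ncol(p))
  ti_class(p, t, class_id, sigma, beta, epsilon)
}

tl_loss_grad <- function(p, t, sigma, beta, epsilon, class_w = NULL,
                         want_grad = TRUE) {
  cc <- ncol(p)
  if (is.null(class_w)) class_w <- rep(1, cc)
  value <- 0
  grad <- if (want_grad) matrix(0, nrow(p), cc) else NULL
  for (c in seq_len(cc) - 1L) {
    j <- p[, c + 1L]
    g <- as.numeric(t == c)
    tp <- sum(j * g); fp <- sum(j * (1 - g)); fn <- sum((1 - j) * g)
    num <- tp + epsilon
    den <- tp + sigma * fp + beta * fn + epsilon
    value <- value + class_w[c + 1L] * (1 - num / den)
    if (want_grad) {
      # d(num)/dj = g ; d(den)/dj = g + sigma*(1-g) - beta*g
      dti <- (g * den - num * (g + sigma * (1 - g) - beta * g)) / den^2
      grad[, c + 1L] <- grad[, c + 1L] - class_w[c + 1L] * dti
    }
  }
  list(value = value, grad = grad)
}

#' Tversky, Dice and combined losses
#'
#' `tversky_loss()` sums `1 - TI_c` over all classes (soft, differentiable;
#' value in `[0, C]`). `dice_loss()` is the special case
#' `sigma = beta = 0.5`. `combined_loss()` mixes the class-weighted
#' cross-entropy with the Dice (`"CEDL"`) or Tversky (`"CETL"`) loss:
#' `delta * CE + (1 - delta) * X`; by default class weights enter only the
#' cross-entropy term.
#'
#' Classes absent from both the prediction and the truth contribute about
#' zero to `tversky_loss()` through the epsilon-smoothed index.
#'
#' @inheritParams tversky_index
#' @return Nonnegative scalar.
#' @export
tversky_loss <- function(probs, target, sigma = 0.3, beta = 0.7,
                         epsilon = 1e-6) {
  stopifnot(sigma >= 0, beta >= 0)
  p <- prob_matrix(probs); t <- target_vector(target)
  stopifnot(length(t) == nrow(p))
  tl_loss_grad(p, t, sigma, beta, epsilon, want_grad = FALSE)$value
}

#' @rdname tversky_loss
#' @export
dice_loss <- function(probs, target, epsilon = 1e-6) {
  tversky_loss(probs, target, sigma = 0.5, beta = 0.5, epsilon = epsilon)
}

#' @rdname tversky_loss
#' @param kind `"CEDL"` or `"CETL"`.
#' @param config A [loss_config()] supplying `delta`, `sigma`, `beta`,
#'   `epsilon`, `ce_eps` and `class_weights`.
#' @export
combined_loss <- function(kind = c("CETL", "CEDL"), probs, target,
                          config = loss_config(kind)) {
  kind <- match.arg(kind)
  ce <- cross_entropy(probs, target, config$class_weights, config$ce_eps)
  x <- if (kind == "CEDL") {
    dice_loss(probs, target, config$epsilon)
  } else {
    tversky_loss(probs, target, config$sigma, config$beta, config$epsilon)
  }
  config$delta * ce + (1 - config$delta) * x
}

#' Evaluate a configured loss, optionally with its gradient
#'
#' Computes the loss selected by `config$kind` on a probability map and, if
#' `logits` are supplied instead of probabilities, also the analytic
#' gradient with respect to the logits (softmax chain rule) — the form the
#' training loop consumes.
#'
#' @param logits `H x W x C` array or `M x C` matrix of class scores.
#' @param target Integer mask/vector of true class ids.
#' @param config A [loss_config()].
#' @param n_images Number of images the rows of `logits` span (used by the
#'   `per_image` Tversky aggregation; rows must be grouped by image).
#' @return A list with `value` and `grad` (same shape as `logits`).
#' @export
loss_with_gradient <- function(logits, target, config, n_images = 1L) {
  p <- softmax_probabilities(prob_matrix(logits))
  t <- target_vector(target)
  cc <- ncol(p)
  w <- weights_vector(config$class_weights, cc)
  tv_w <- if (isTRUE(config$weight_tversky)) w else NULL
  tv_part <- function(pp, tt) {
    sb <- if (config$kind == "CEDL" || config$kind == "DiL") c(0.5, 0.5)
          else c(config$sigma, config$beta)
    tl_loss_grad(pp, tt, sb[1], sb[2], config$epsilon, tv_w)
  }
  tv_batched <- function() {
    if (!config$per_image || n_images <= 1) return(tv_part(p, t))
    m <- nrow(p) / n_images
    value <- 0; grad <- matrix(0, nrow(p), cc)
    for (i in seq_len(n_images)) {
      rows <- ((i - 1) * m + 1):(i * m)
      part <- tv_part(p[rows, , drop = FALSE], t[rows])
      value <- value + part$value / n_images
      grad[rows, ] <- part$grad / n_images
    }
    list(value = value, grad = grad)
  }
  res <- switch(config$kind,
    CE = ce_loss_grad(p, t, w, config$ce_eps),
    FL = fl_loss_grad(p, t, config$alpha_t, config$gamma, config$ce_eps),
    DiL = tv_batched(),
    TL = tv_batched(),
    CEDL = ,
    CETL = {
      ce <- ce_loss_grad(p, t, w, config$ce_eps)
      tv <- tv_batched()
      list(value = config$delta * ce$value + (1 - config$delta) * tv$value,
           grad = config$delta * ce$grad + (1 - config$delta) * tv$grad)
    })
  gl <- softmax_backward(p, res$grad)
  if (!is.matrix(logits)) gl <- array(gl, dim = dim(logits))
  list(value = res$value, grad = gl)
}
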