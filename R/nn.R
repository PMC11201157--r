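# Internal dense-prediction layer primitives. Activations live in
# H x W x N x C arrays (channels last, so the (H*W*N) x C matrix view is a
# free reshape); convolutions are C-level im2col plus BLAS matrix products.

to_cmat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2] * d[3], d[4])
  x
}

from_cmat <- function(m, h, w, n) {
  array(m, c(h, w, n, ncol(m)))
}

# ---- 3x3 same-padding convolution ----

# Patch-matrix buffer pool: the im2col matrices are by far the largest
# allocations of a training step; reusing them across iterations keeps the
# allocator and garbage collector out of the hot loop. Buffers are keyed by
# layer and reallocated only when the batch shape changes.
nn_buffers <- new.env(parent = emptyenv())

get_patch_buffer <- function(key, rows, cols) {
  buf <- get0(key, envir = nn_buffers, inherits = FALSE)
  if (is.null(buf) || nrow(buf) != rows || ncol(buf) != cols) {
    buf <- matrix(0, rows, cols)
    assign(key, buf, envir = nn_buffers)
  }
  buf
}

conv3_init <- function(c_in, c_out) {
  list(w = matrix(rnorm(9 * c_in * c_out, sd = sqrt(2 / (9 * c_in))),
                  9 * c_in, c_out),
       b = numeric(c_out))
}

conv3_fwd <- function(x, par, key = NULL) {
  d <- dim(x)
  if (is.null(key)) {
    p <- im2col3(x, d[1], d[2], d[3], d[4])
  } else {
    p <- get_patch_buffer(key, d[1] * d[2] * d[3], 9 * d[4])
    im2col3_into(x, d[1], d[2], d[3], d[4], p)
  }
  y <- p %*% par$w
  y <- y + rep(par$b, each = nrow(y))
  list(out = from_cmat(y, d[1], d[2], d[3]), cache = list(p = p, d = d))
}

conv3_bwd <- function(dy, par, cache) {
  d <- cache$d
  dym <- to_cmat(dy)
  dw <- crossprod(cache$p, dym)
  db <- colSums(dym)
  dp <- tcrossprod(dym, par$w)
  list(dx = col2im3(dp, d[1], d[2], d[3], d[4]),
       grads = list(w = dw, b = db))
}

# ---- 1x1 convolution (logit head) ----

conv1_init <- function(c_in, c_out) {
  list(w = matrix(rnorm(c_in * c_out, sd = sqrt(2 / c_in)), c_in, c_out),
       b = numeric(c_out))
}

conv1_fwd <- function(x, par) {
  d <- dim(x)
  xm <- to_cmat(x)
  y <- xm %*% par$w
  y <- y + rep(par$b, each = nrow(y))
  list(out = from_cmat(y, d[1], d[2], d[3]), cache = list(xm = xm, d = d))
}

conv1_bwd <- function(dy, par, cache) {
  dym <- to_cmat(dy)
  list(dx = from_cmat(tcrossprod(dym, par$w), cache$d[1], cache$d[2], cache$d[3]),
       grads = list(w = crossprod(cache$xm, dym), b = colSums(dym)))
}

# ---- batch normalization (per channel over batch and space) ----

bn_init <- function(cc) list(gamma = rep(1, cc), beta = numeric(cc))

bn_state_init <- function(cc) list(rmean = numeric(cc), rvar = rep(1, cc))

bn_fwd <- function(x, par, st, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  xm <- to_cmat(x)
  if (training) {
    mu <- colMeans(xm)
    v <- pmax(colMeans(xm * xm) - mu * mu, 0)
    st$rmean <- (1 - momentum) * st$rmean + momentum * mu
    st$rvar <- (1 - momentum) * st$rvar + momentum * v
  } else {
    mu <- st$rmean; v <- st$rvar
  }
  istd <- 1 / sqrt(v + eps)
  r <- bn_apply(xm, mu, istd, par$gamma, par$beta)
  list(out = from_cmat(r$y, d[1], d[2], d[3]), st = st,
       cache = list(xhat = r$xhat, istd = istd, d = d))
}

bn_bwd <- function(dy, par, cache) {
  d <- cache$d
  dym <- to_cmat(dy)
  cs1 <- colSums(dym)
  cs2 <- colSums(dym * cache$xhat)
  dxm <- bn_input_grad(dym, cache$xhat, par$gamma, cache$istd,
                       par$gamma * cs1, par$gamma * cs2)
  list(dx = from_cmat(dxm, d[1], d[2], d[3]),
       grads = list(gamma = cs2, beta = cs1))
}

# ---- 2x2 max pooling ----

pool_fwd <- function(x) {
  d <- dim(x)
  r <- pool2_fwd(x, d[1], d[2], d[3], d[4])
  list(out = r$out, cache = list(arg = r$arg, d = d))
}

pool_bwd <- function(dy, cache) {
  d <- cache$d
  pool2_bwd(dy, cache$arg, d[1], d[2], d[3], d[4])
}

# ---- 2x2 stride-2 transposed convolution (upsampling) ----

upconv_init <- function(c_in, c_out) {
  list(k = array(rnorm(c_in * c_out * 4, sd = sqrt(2 / c_in)),
                 c(c_in, c_out, 4)),
       b = numeric(c_out))
}

upconv_fwd <- function(x, par) {
  d <- dim(x); h <- d[1]; w <- d[2]; n <- d[3]
  xm <- to_cmat(x)
  c_out <- dim(par$k)[2]
  y <- array(0, c(2 * h, 2 * w, n, c_out))
  offs <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  s1 <- seq(1, 2 * h, 2); s2 <- seq(1, 2 * w, 2)
  for (k in 1:4) {
    yk <- xm %*% par$k[, , k]
    yk <- yk + rep(par$b, each = nrow(yk))
    y[s1 + offs[[k]][1], s2 + offs[[k]][2], , ] <- from_cmat(yk, h, w, n)
  }
  list(out = y, cache = list(xm = xm, d = d))
}

upconv_bwd <- function(dy, par, cache) {
  d <- cache$d; h <- d[1]; w <- d[2]; n <- d[3]
  offs <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  s1 <- seq(1, 2 * h, 2); s2 <- seq(1, 2 * w, 2)
  dk <- 0 * par$k; db <- 0 * par$b
  dxm <- matrix(0, nrow(cache$xm), ncol(cache$xm))
  for (k in 1:4) {
    dyk <- to_cmat(dy[s1 + offs[[k]][1], s2 + offs[[k]][2], , , drop = FALSE])
    dk[, , k] <- crossprod(cache$xm, dyk)
    db <- db + colSums(dyk)
    dxm <- dxm + tcrossprod(dyk, par$k[, , k])
  }
  list(dx = from_cmat(dxm, h, w, n), grads = list(k = dk, b = db))
}

# ---- channel concatenation (skip connections; channels are dim 4) ----

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

# ---- parameter-tree utilities ----

tree_map <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1]])) {
    out <- lapply(seq_along(trees[[1]]), function(i) {
      do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    })
    names(out) <- names(trees[[1]])
    out
  } else {
    do.call(f, trees)
  }
}

tree_zeros <- function(tree) tree_map(function(p) p * 0, tree)
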