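#' Activation functions
#'
#' The three nonlinearities selectable throughout the segmentation network:
#' `relu(x) = max(x, 0)`; `gelu(x) = (x/2) * (1 + erf(x / sqrt(2)))`, which
#' weighs the input by its probability under a standard Gaussian; and
#' `swish(x) = x * sigmoid(x)` (the SiLU form). All are vectorized and
#' continuous.
#'
#' @param x Numeric vector/array of finite values.
#' @return Numeric of the same shape.
#' @export
relu <- function(x) pmax(x, 0)

#' @rdname relu
#' @export
gelu <- function(x) x * pnorm(x)

#' @rdname relu
#' @export
swish <- function(x) x / (1 + exp(-x))

# C-kernel forward/derivative pair used by the network hot path
activation_fns <- function(kind) {
  code <- match(kind, c("ReLU", "GELU", "Swish")) - 1L
  if (is.na(code)) {
    rlang::abort(sprintf("unknown activation '%s' (use ReLU, GELU or Swish)", kind))
  }
  list(f = function(x) act_eval(x, code, FALSE),
       grad = function(x, y) act_eval(x, code, TRUE))
}
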