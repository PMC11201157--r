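#' Configure the encoder-decoder segmentation network
#'
#' A depth-configurable U-Net: `depth` encoder stages of two conv(3x3) +
#' batch-norm + activation blocks each followed by 2x max pooling, with
#' channels doubling from `base_channels`; a bottleneck double-conv; a
#' mirrored decoder that upsamples by 2x transposed convolution and
#' concatenates the encoder's skip tensors at every stage; and a final 1x1
#' convolution to per-class logits (no activation on the logit layer).
#' Depth 5 with 224x224 inputs is the reference ("U-Net5ed") scale; depth 3
#' at 96x96 is the desk scale used throughout the examples.
#'
#' @param depth Number of encoder-decoder stages, `>= 1`.
#' @param base_channels Channel width of the first stage (64 at reference
#'   scale, 8 at desk scale).
#' @param n_classes Number of output classes.
#' @param activation `"ReLU"`, `"GELU"` or `"Swish"` (applied everywhere
#'   except the logit layer).
#' @param input_size `c(H, W)`; both must be divisible by `2^depth`.
#' @return A list of class `"unet_config"`.
#' @export
unet_config <- function(depth = 3L, base_channels = 8L, n_classes = 13L,
                        activation = c("ReLU", "GELU", "Swish"),
                        input_size = c(96L, 96L)) {
  activation <- match.arg(activation)
  stopifnot(depth >= 1, base_channels >= 1, n_classes >= 2)
  if (any(input_size %% 2^depth != 0)) {
    rlang::abort(sprintf(
      "input size (%d x %d) must be divisible by 2^depth = %d",
      input_size[1], input_size[2], 2^depth))
  }
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 n_classes = as.integer(n_classes), activation = activation,
                 input_size = as.integer(input_size)),
            class = "unet_config")
}

#' Build a segmentation network
#'
#' Initializes all parameters (He-scaled Gaussian weights, unit batch-norm
#' scale) deterministically from `seed`.
#'
#' @param config A [unet_config()].
#' @param seed Integer seed for weight initialization.
#' @return A list of class `"unet_model"` with elements `config`, `params`
#'   (trainable tensors) and `state` (batch-norm running statistics).
#' @export
build_unet <- function(config, seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  d <- config$depth; b <- config$base_channels
  ch <- b * 2^(seq_len(d + 1) - 1)          # ch[s] for stages, ch[d+1] bottleneck
  withr::with_seed(as.integer(seed), {
    params <- list(enc = list(), bottleneck = NULL, dec = list(), head = NULL)
    state <- list(enc = list(), bottleneck = NULL, dec = list())
    in_ch <- 3L
    for (s in seq_len(d)) {
      params$enc[[s]] <- list(conv1 = conv3_init(in_ch, ch[s]), bn1 = bn_init(ch[s]),
                              conv2 = conv3_init(ch[s], ch[s]), bn2 = bn_init(ch[s]))
      state$enc[[s]] <- list(bn1 = bn_state_init(ch[s]), bn2 = bn_state_init(ch[s]))
      in_ch <- ch[s]
    }
    cb <- ch[d + 1]
    params$bottleneck <- list(conv1 = conv3_init(ch[d], cb), bn1 = bn_init(cb),
                              conv2 = conv3_init(cb, cb), bn2 = bn_init(cb))
    state$bottleneck <- list(bn1 = bn_state_init(cb), bn2 = bn_state_init(cb))
    up_in <- cb
    for (s in rev(seq_len(d))) {
      params$dec[[s]] <- list(up = upconv_init(up_in, ch[s]),
                              conv1 = conv3_init(2 * ch[s], ch[s]), bn1 = bn_init(ch[s]),
                              conv2 = conv3_init(ch[s], ch[s]), bn2 = bn_init(ch[s]))
      state$dec[[s]] <- list(bn1 = bn_state_init(ch[s]), bn2 = bn_state_init(ch[s]))
      up_in <- ch[s]
    }
    params$head <- conv1_init(ch[1], config$n_classes)
    structure(list(config = config, params = params, state = state),
              class = "unet_model")
  })
}

# conv -> bn -> act -> conv -> bn -> act
double_conv_fwd <- function(x, par, st, act, training, key = NULL) {
  c1 <- conv3_fwd(x, par$conv1, if (is.null(key)) NULL else paste0(key, ".c1"))
  b1 <- bn_fwd(c1$out, par$bn1, st$bn1, training)
  a1 <- act$f(b1$out)
  c2 <- conv3_fwd(a1, par$conv2, if (is.null(key)) NULL else paste0(key, ".c2"))
  b2 <- bn_fwd(c2$out, par$bn2, st$bn2, training)
  a2 <- act$f(b2$out)
  list(out = a2, st = list(bn1 = b1$st, bn2 = b2$st),
       cache = list(c1 = c1$cache, b1 = b1$cache, z1 = b1$out, a1 = a1,
                    c2 = c2$cache, b2 = b2$cache, z2 = b2$out))
}

double_conv_bwd <- function(dy, par, cache, act) {
  dy <- dy * act$grad(cache$z2, NULL)
  b2 <- bn_bwd(dy, par$bn2, cache$b2)
  c2 <- conv3_bwd(b2$dx, par$conv2, cache$c2)
  da1 <- c2$dx * act$grad(cache$z1, NULL)
  b1 <- bn_bwd(da1, par$bn1, cache$b1)
  c1 <- conv3_bwd(b1$dx, par$conv1, cache$c1)
  list(dx = c1$dx,
       grads = list(conv1 = c1$grads, bn1 = b1$grads,
                    conv2 = c2$grads, bn2 = b2$grads))
}

unet_forward <- function(model, x, training = FALSE) {
  cfg <- model$config; par <- model$params; st <- model$state
  act <- activation_fns(cfg$activation)
  d <- cfg$depth
  skips <- vector("list", d)
  caches <- list(enc = vector("list", d), pool = vector("list", d),
                 dec = vector("list", d))
  for (s in seq_len(d)) {
    blk <- double_conv_fwd(x, par$enc[[s]], st$enc[[s]], act, training,
                           key = paste0("enc", s))
    st$enc[[s]] <- blk$st
    skips[[s]] <- blk$out
    caches$enc[[s]] <- blk$cache
    pl <- pool_fwd(blk$out)
    caches$pool[[s]] <- pl$cache
    x <- pl$out
  }
  bt <- double_conv_fwd(x, par$bottleneck, st$bottleneck, act, training,
                        key = "bottleneck")
  st$bottleneck <- bt$st
  caches$bottleneck <- bt$cache
  x <- bt$out
  for (s in rev(seq_len(d))) {
    up <- upconv_fwd(x, par$dec[[s]]$up)
    cat_in <- concat_ch(up$out, skips[[s]])
    blk <- double_conv_fwd(cat_in, par$dec[[s]], st$dec[[s]], act, training,
                           key = paste0("dec", s))
    st$dec[[s]] <- blk$st
    caches$dec[[s]] <- list(up = up$cache, blk = blk$cache,
                            up_ch = dim(up$out)[4])
    x <- blk$out
  }
  hd <- conv1_fwd(x, par$head)
  caches$head <- hd$cache
  model$state <- st
  list(logits = hd$out, cache = caches, model = model)
}

unet_backward <- function(model, cache, dlogits) {
  cfg <- model$config; par <- model$params
  act <- activation_fns(cfg$activation)
  d <- cfg$depth
  grads <- list(enc = vector("list", d), bottleneck = NULL,
                dec = vector("list", d), head = NULL)
  hd <- conv1_bwd(dlogits, par$head, cache$head)
  grads$head <- hd$grads
  dx <- hd$dx
  dskips <- vector("list", d)
  for (s in seq_len(d)) {
    cs <- cache$dec[[s]]
    blk <- double_conv_bwd(dx, par$dec[[s]], cs$blk, act)
    up_ch <- cs$up_ch
    dup <- blk$dx[, , , seq_len(up_ch), drop = FALSE]
    dskips[[s]] <- blk$dx[, , , up_ch + seq_len(dim(blk$dx)[4] - up_ch),
                          drop = FALSE]
    up <- upconv_bwd(dup, par$dec[[s]]$up, cs$up)
    grads$dec[[s]] <- c(list(up = up$grads), blk$grads)
    dx <- up$dx
  }
  bt <- double_conv_bwd(dx, par$bottleneck, cache$bottleneck, act)
  grads$bottleneck <- bt$grads
  dx <- bt$dx
  for (s in rev(seq_len(d))) {
    dpooled <- pool_bwd(dx, cache$pool[[s]])
    blk <- double_conv_bwd(dpooled + dskips[[s]], par$enc[[s]],
                           cache$enc[[s]], act)
    grads$enc[[s]] <- blk$grads
    dx <- blk$dx
  }
  grads
}

#' Count trainable parameters
#' @param model A [build_unet()] model.
#' @return Integer count of trainable scalars.
#' @export
n_parameters <- function(model) {
  total <- 0
  tree_map(function(p) total <<- total + length(p), model$params)
  total
}

#' Predicted class probabilities and hard mask
#'
#' `predict_probs()` runs the network (batch-norm in inference mode) and
#' returns the per-pixel softmax probability map; `predict_mask()` takes the
#' per-pixel argmax, breaking exact ties toward the lowest class id.
#'
#' @param model A [build_unet()] model.
#' @param image `H x W x 3` array matching the model's input size.
#' @return `predict_probs()`: `H x W x C` array; `predict_mask()`: integer
#'   `H x W` index mask.
#' @export
predict_probs <- function(model, image) {
  sz <- model$config$input_size
  if (!all(dim(image)[1:2] == sz)) {
    rlang::abort(sprintf("image is %d x %d but the model expects %d x %d",
                         dim(image)[1], dim(image)[2], sz[1], sz[2]))
  }
  x <- array(image, c(dim(image)[1:2], 1, 3))
  logits <- unet_forward(model, x, training = FALSE)$logits
  d <- dim(logits)
  array(softmax_probabilities(matrix(logits, d[1] * d[2], d[4])),
        dim = c(d[1], d[2], d[4]))
}

#' @rdname predict_probs
#' @export
predict_mask <- function(model, image) {
  p <- predict_probs(model, image)
  m <- matrix(p, prod(dim(p)[1:2]), dim(p)[3])
  as_index_mask(matrix(max.col(m, ties.method = "first") - 1L,
                       dim(p)[1], dim(p)[2]))
}

#' Save / load a model checkpoint
#'
#' Weights and batch-norm state are serialized to `weights.rds`; the
#' network configuration is written alongside as a JSON sidecar so
#' evaluation can reconstruct the architecture without the training
#' session.
#'
#' @param model A `unet_model`.
#' @param dir Checkpoint directory.
#' @return `save_model()` the directory invisibly; `load_model()` the model.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- unclass(model$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(list(params = model$params, state = model$state),
          file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  cfg <- jsonlite::fromJSON(file.path(dir, "config.json"))
  config <- unet_config(cfg$depth, cfg$base_channels, cfg$n_classes,
                        cfg$activation, as.integer(cfg$input_size))
  wt <- readRDS(file.path(dir, "weights.rds"))
  structure(list(config = config, params = wt$params, state = wt$state),
            class = "unet_model")
}
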