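#' Train a segmentation network
#'
#' Mini-batch training with seeded per-epoch shuffling, the configured loss
#' and optimizer, and the piecewise learning-rate schedule. Per-iteration
#' loss/accuracy and per-epoch validation loss/accuracy are logged.
#' Deterministic given `config$seed` under single-threaded numerics.
#'
#' @param model A [build_unet()] model.
#' @param data Either a [manifest()] with train/val partitions (masks are
#'   read from disk once, up front) or a list with elements `train` and
#'   optionally `val`, each a list of `list(image, mask)` samples.
#' @param loss A [loss_config()].
#' @param config A [train_config()].
#' @return A list with the trained `model` and `log`, a tibble of class
#'   `"training_log"` with one row per iteration and per epoch.
#' @export
train_model <- function(model, data, loss = loss_config(),
                        config = train_config()) {
  if (inherits(data, "dataset_manifest")) {
    has_val <- any(data$partition == "val")
    data <- list(train = load_samples(data, "train"),
                 val = if (has_val) load_samples(data, "val"))
  }
  train_set <- data$train
  val_set <- data$val
  if (length(train_set) == 0) rlang::abort("empty training partition")
  sz <- model$config$input_size
  log <- list()
  opt <- optimizer_init(config, model$params)
  it <- 0L
  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr <- learning_rate_at(config, epoch)
      ord <- sample.int(length(train_set))
      starts <- seq(1, length(ord), by = config$mini_batch)
      for (s in starts) {
        batch <- train_set[ord[s:min(s + config$mini_batch - 1, length(ord))]]
        n <- length(batch)
        x <- array(0, c(sz[1], sz[2], n, 3))
        masks <- array(0L, c(sz[1], sz[2], n))
        for (i in seq_len(n)) {
          x[, , i, ] <- batch[[i]]$image
          masks[, , i] <- batch[[i]]$mask
        }
        fw <- unet_forward(model, x, training = TRUE)
        model <- fw$model
        lmat <- to_cmat(fw$logits)                 # rows (h, w, n)
        tvec <- as.integer(as.vector(masks))
        lg <- loss_with_gradient(lmat, tvec, loss, n_images = n)
        pred <- max.col(lmat, ties.method = "first") - 1L
        acc_b <- mean(pred == tvec)
        dlogits <- from_cmat(lg$grad, sz[1], sz[2], n)
        grads <- unet_backward(model, fw$cache, dlogits)
        step <- optimizer_apply(config, model$params, grads, opt, lr)
        model$params <- step$params
        opt <- step$opt
        it <- it + 1L
        log[[length(log) + 1L]] <- tibble::tibble(
          phase = "iteration", epoch = epoch, iteration = it, lr = lr,
          loss = lg$value, acc = acc_b,
          val_loss = NA_real_, val_acc = NA_real_)
      }
      val <- if (!is.null(val_set) && length(val_set) > 0) {
        validate_pass(model, val_set, loss)
      } else {
        list(loss = NA_real_, acc = NA_real_)
      }
      log[[length(log) + 1L]] <- tibble::tibble(
        phase = "epoch", epoch = epoch, iteration = it, lr = lr,
        loss = NA_real_, acc = NA_real_,
        val_loss = val$loss, val_acc = val$acc)
    }
  })
  log <- dplyr::bind_rows(log)
  class(log) <- c("training_log", class(log))
  list(model = model, log = log)
}

validate_pass <- function(model, samples, loss, batch = 8L) {
  sz <- model$config$input_size
  tot_loss <- 0; tot_acc <- 0; nb <- 0
  starts <- seq(1, length(samples), by = batch)
  for (s in starts) {
    bs <- samples[s:min(s + batch - 1, length(samples))]
    n <- length(bs)
    x <- array(0, c(sz[1], sz[2], n, 3))
    masks <- array(0L, c(sz[1], sz[2], n))
    for (i in seq_len(n)) {
      x[, , i, ] <- bs[[i]]$image
      masks[, , i] <- bs[[i]]$mask
    }
    fw <- unet_forward(model, x, training = FALSE)
    lmat <- to_cmat(fw$logits)
    tvec <- as.integer(as.vector(masks))
    p <- softmax_probabilities(lmat)
    v <- switch(loss$kind,
      CE = cross_entropy(p, tvec, loss$class_weights, loss$ce_eps),
      FL = focal_loss(p, tvec, loss$alpha_t, loss$gamma, loss$ce_eps),
      DiL = dice_loss(p, tvec, loss$epsilon),
      TL = tversky_loss(p, tvec, loss$sigma, loss$beta, loss$epsilon),
      combined_loss(loss$kind, p, tvec, loss))
    tot_loss <- tot_loss + v * n
    tot_acc <- tot_acc + mean(max.col(lmat, ties.method = "first") - 1L == tvec) * n
    nb <- nb + n
  }
  list(loss = tot_loss / nb, acc = tot_acc / nb)
}

#' @rdname train_model
#' @param object A `training_log`.
#' @param ... Ignored.
#' @export
autoplot.training_log <- function(object, ...) {
  iters <- object[object$phase == "iteration", ]
  epochs <- object[object$phase == "epoch", ]
  ggplot2::ggplot(iters, ggplot2::aes(x = .data$iteration, y = .data$loss)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(data = epochs,
                        ggplot2::aes(y = .data$val_loss), color = "firebrick") +
    ggplot2::labs(x = "iteration", y = "loss",
                  title = "training loss (line) and validation loss (points)") +
    ggplot2::theme_minimal()
}

#' Evaluate a model over a dataset
#'
#' Runs the network on every sample, accumulates the confusion matrix and
#' the per-image per-class boundary F1, and summarizes per-class and
#' aggregate metrics.
#'
#' @param model A [build_unet()] model.
#' @param samples A list of `list(image, mask)` samples, or a [manifest()]
#'   (use `partition` to select, default `"test"`).
#' @param table Optional [class_table()] for class names.
#' @param theta Boundary match tolerance in pixels (default 0.75% of the
#'   image diagonal).
#' @param partition Partition to evaluate when `samples` is a manifest.
#' @param boundary Also compute per-image boundary F1 (set `FALSE` to skip
#'   the boundary machinery when only confusion-based metrics are needed).
#' @return A [summarize_metrics()] report.
#' @export
evaluate_model <- function(model, samples, table = NULL, theta = NULL,
                           partition = "test", boundary = TRUE) {
  if (inherits(samples, "dataset_manifest")) {
    samples <- load_samples(samples, partition)
  }
  cc <- model$config$n_classes
  acc <- confusion_accumulator(cc)
  bfs <- if (boundary) matrix(NA_real_, length(samples), cc)
  for (i in seq_along(samples)) {
    pred <- predict_mask(model, samples[[i]]$image)
    truth <- samples[[i]]$mask
    acc <- accumulate(acc, pred, truth)
    if (boundary) {
      for (c in seq_len(cc) - 1L) {
        bfs[i, c + 1L] <- boundary_f1(pred, truth, c, theta)
      }
    }
  }
  summarize_metrics(acc, per_image_bfs = bfs, table = table)
}
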