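#' Define an experiment grid
#'
#' A named set of configurations (activation x loss x optimizer) evaluated
#' on one shared synthetic dataset with shared seeds, so rows are directly
#' comparable.
#'
#' @param configs A named list; each element is a list with fields
#'   `activation`, `loss` (a [loss_config()] or the string
#'   `"weighted"`/`"unweighted"` shortcut handled by the caller) and
#'   `optimizer` (`"SGDM"`/`"Adam"`).
#' @param scene A [scene_config()] for the shared dataset.
#' @param n_images Dataset size (split 60/20/20).
#' @param depth,base_channels Network size.
#' @param epochs,mini_batch,ilr Training schedule of every run.
#' @param seed Shared seed for data generation, weight init and shuffling.
#' @return A list of class `"experiment_grid"`.
#' @export
experiment_grid <- function(configs, scene = cholecseg_profile(),
                            n_images = 60L, depth = 3L, base_channels = 8L,
                            epochs = 15L, mini_batch = 8L, ilr = NULL,
                            seed = 1L) {
  if (is.null(names(configs)) || anyDuplicated(names(configs))) {
    rlang::abort("configurations must have unique names")
  }
  for (cf in configs) {
    stopifnot(cf$activation %in% c("ReLU", "GELU", "Swish"),
              inherits(cf$loss, "loss_config"),
              cf$optimizer %in% c("SGDM", "Adam"))
  }
  structure(list(configs = configs, scene = scene,
                 n_images = as.integer(n_images), depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 epochs = as.integer(epochs), mini_batch = as.integer(mini_batch),
                 ilr = ilr, seed = as.integer(seed)),
            class = "experiment_grid")
}

generate_split_samples <- function(scene, n_images, seed) {
  samples <- purrr::map(seq_len(n_images), function(i) generate_scene(scene, i))
  idx <- tibble::tibble(image = sprintf("s%04d", seq_len(n_images)),
                        mask = sprintf("m%04d", seq_len(n_images)))
  mf <- split_manifest(manifest(idx$image, idx$mask), c(0.6, 0.2, 0.2), seed)
  pick <- function(part) samples[match(mf$image[mf$partition == part], idx$image)]
  list(train = pick("train"), val = pick("val"), test = pick("test"))
}

run_one_config <- function(cf, sets, scene, grid) {
  tc <- train_config(optimizer = cf$optimizer, epochs = grid$epochs,
                     mini_batch = grid$mini_batch, ilr = grid$ilr,
                     seed = grid$seed)
  uc <- unet_config(depth = grid$depth, base_channels = grid$base_channels,
                    n_classes = scene$n_classes, activation = cf$activation,
                    input_size = scene$image_size)
  model <- build_unet(uc, seed = grid$seed)
  fit <- train_model(model, sets, loss = cf$loss, config = tc)
  table <- scene_class_table(scene)
  report <- evaluate_model(fit$model, sets$test, table = table)
  # qualitative disagreement overlay for the first test scene
  first <- sets$test[[1]]
  overlay <- diff_overlay(predict_mask(fit$model, first$image), first$mask,
                          table)
  list(model = fit$model, log = fit$log, report = report, overlay = overlay)
}

#' Run an experiment grid
#'
#' Trains and evaluates every configuration on the same generated dataset
#' (60/20/20 split). Each run is independently seeded from the grid's
#' shared seed, so permuting the configuration order changes no numeric
#' output. A failed run is recorded in the `error` column and does not
#' interrupt the remaining runs.
#'
#' @param grid An [experiment_grid()].
#' @param keep_models Keep trained models in the result (default `TRUE`).
#' @return A list of class `"grid_result"` with `summary` (one row per
#'   configuration: GAcc/MAcc/MIoU/Mbfs) and `runs` (per-config reports,
#'   logs and models).
#' @export
run_grid <- function(grid, keep_models = TRUE) {
  stopifnot(inherits(grid, "experiment_grid"))
  sets <- generate_split_samples(grid$scene, grid$n_images, grid$seed)
  runs <- list()
  rows <- list()
  for (nm in names(grid$configs)) {
    cf <- grid$configs[[nm]]
    res <- tryCatch(run_one_config(cf, sets, grid$scene, grid),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[nm]] <- tibble::tibble(config = nm, activation = cf$activation,
                                   loss = cf$loss$kind, optimizer = cf$optimizer,
                                   GAcc = NA_real_, MAcc = NA_real_,
                                   MIoU = NA_real_, Mbfs = NA_real_,
                                   error = conditionMessage(res))
      runs[[nm]] <- list(error = conditionMessage(res))
    } else {
      ag <- res$report$aggregates
      rows[[nm]] <- tibble::tibble(config = nm, activation = cf$activation,
                                   loss = cf$loss$kind, optimizer = cf$optimizer,
                                   GAcc = ag$GAcc, MAcc = ag$MAcc,
                                   MIoU = ag$MIoU, Mbfs = ag$Mbfs,
                                   error = NA_character_)
      if (!keep_models) res$model <- NULL
      runs[[nm]] <- res
    }
  }
  structure(list(summary = dplyr::bind_rows(rows), runs = runs, grid = grid),
            class = "grid_result")
}

#' Per-class comparison table for designated minority classes
#'
#' Extracts the class accuracy, IoU and boundary F1 of the requested
#' classes from every configuration of a grid result and flags the best
#' value per class/metric row (ties all flagged).
#'
#' @param result A [run_grid()] result (or a named list of
#'   `metrics_report`s).
#' @param classes Character vector of class names to report.
#' @return A tibble with one row per class x metric x configuration and a
#'   logical `best` column.
#' @export
minority_report <- function(result, classes) {
  reports <- if (inherits(result, "grid_result")) {
    purrr::keep(purrr::map(result$runs, "report"), Negate(is.null))
  } else {
    result
  }
  if (length(reports) == 0) rlang::abort("no successful runs to report")
  long <- purrr::imap_dfr(reports, function(rep, nm) {
    pc <- rep$per_class
    if (!"name" %in% names(pc)) pc$name <- as.character(pc$id)
    missing <- setdiff(classes, pc$name)
    if (length(missing) > 0) {
      rlang::abort(paste0("unknown class(es): ", paste(missing, collapse = ", ")))
    }
    pc <- pc[pc$name %in% classes, c("name", "class_acc", "iou", "bfs")]
    pc <- tidyr::pivot_longer(pc, cols = c("class_acc", "iou", "bfs"),
                              names_to = "metric", values_to = "value")
    pc$config <- nm
    pc
  })
  dplyr::mutate(
    dplyr::group_by(long, .data$name, .data$metric),
    best = !is.na(.data$value) & .data$value == max(.data$value, na.rm = TRUE)) |>
    dplyr::ungroup()
}

#' Minority-class mean IoU of a metrics report
#'
#' Mean IoU restricted to the named classes, over those defined in the
#' report (present in truth or prediction).
#'
#' @param report A [summarize_metrics()] report with class names.
#' @param classes Character vector of class names.
#' @return Mean IoU, or `NA` if none of the classes is defined.
#' @export
minority_miou <- function(report, classes) {
  pc <- report$per_class
  pc <- pc[pc$name %in% classes & pc$defined, ]
  if (nrow(pc) == 0) return(NA_real_)
  mean(pc$iou, na.rm = TRUE)
}

#' Minority classes of a scene config
#'
#' The classes whose target pixel share is below a threshold (default 1%),
#' mirroring the small-structure grouping of imbalanced surgical datasets.
#'
#' @param scene A [scene_config()].
#' @param threshold Pixel-share threshold.
#' @return Character vector of class names.
#' @export
minority_classes <- function(scene, threshold = 0.01) {
  cl <- scene$classes
  cl$name[cl$family != "background" & cl$target_share < threshold]
}

#' Paired comparison: imbalance-aware configuration vs plain baseline
#'
#' Trains, for each seed, the imbalance-aware configuration (class-weighted
#' combined cross-entropy/Tversky loss with delta = 0.7, sigma = 0.3,
#' beta = 0.7, Swish activation, Adam) and a plain baseline (unweighted
#' cross-entropy, ReLU, Adam) on the same synthetic imbalanced dataset,
#' and evaluates the minority-class mean IoU of both on the shared test
#' partition. Class weights (median-frequency) are computed on the
#' training partition only.
#'
#' @param scene A [scene_config()]; default the 13-class imbalanced preset.
#' @param n_images Images per dataset (60/20/20 split).
#' @param depth,base_channels,epochs,mini_batch,ilr Desk-scale training
#'   setup shared by both arms.
#' @param seeds Integer vector; one paired run per seed.
#' @param eval_extra Additional held-out samples (generated from the same
#'   distribution at indices beyond `n_images`, so disjoint from all
#'   partitions) appended to the test partition for evaluation. The
#'   minority classes appear in only a few percent of images, so a
#'   desk-scale test split alone often contains none of them; widening the
#'   held-out sample makes the minority-class estimates measurable without
#'   touching the training conditions.
#' @return A tibble of class `"imbalance_comparison"`: one row per seed
#'   with minority mean IoU (and MIoU/GAcc) for both arms.
#' @export
compare_imbalance_handling <- function(scene = cholecseg_profile(),
                                       n_images = 60L, depth = 3L,
                                       base_channels = 8L, epochs = 15L,
                                       mini_batch = 8L, ilr = 1e-3,
                                       seeds = c(1L, 2L, 3L),
                                       eval_extra = 60L) {
  minors <- minority_classes(scene)
  table <- scene_class_table(scene)
  rows <- list()
  for (sd in seeds) {
    sc <- scene
    sc$seed <- as.integer(sd)
    sets <- generate_split_samples(sc, n_images, sd)
    if (eval_extra > 0) {
      extra <- purrr::map(n_images + seq_len(eval_extra),
                          function(i) generate_scene(sc, i))
      sets$test <- c(sets$test, extra)
    }
    freq <- tally_samples(sets$train, table)
    w <- compute_weights(smooth_shares(freq$pixels), "median_frequency")
    arms <- list(
      weighted_cetl = list(
        activation = "Swish",
        loss = loss_config("CETL", delta = 0.7, sigma = 0.3, beta = 0.7,
                           class_weights = w)),
      unweighted_ce = list(activation = "ReLU", loss = loss_config("CE")))
    res <- purrr::map(arms, function(arm) {
      uc <- unet_config(depth = depth, base_channels = base_channels,
                        n_classes = sc$n_classes, activation = arm$activation,
                        input_size = sc$image_size)
      tc <- train_config("Adam", epochs = epochs, mini_batch = mini_batch,
                         ilr = ilr, seed = sd)
      fit <- train_model(build_unet(uc, seed = sd), sets, loss = arm$loss,
                         config = tc)
      evaluate_model(fit$model, sets$test, table = table, boundary = FALSE)
    })
    rows[[length(rows) + 1L]] <- tibble::tibble(
      seed = sd,
      minority_iou_weighted = minority_miou(res$weighted_cetl, minors),
      minority_iou_baseline = minority_miou(res$unweighted_ce, minors),
      miou_weighted = res$weighted_cetl$aggregates$MIoU,
      miou_baseline = res$unweighted_ce$aggregates$MIoU,
      gacc_weighted = res$weighted_cetl$aggregates$GAcc,
      gacc_baseline = res$unweighted_ce$aggregates$GAcc)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("imbalance_comparison", class(out))
  out
}

#' Smooth zero pixel shares before weighting
#'
#' Replaces zero shares by half the smallest positive share and
#' renormalizes — the explicit smoothing choice [compute_weights()] asks
#' for when a class drew no pixels in the tallied partition. Classes absent
#' from the data then receive the largest weight rather than an undefined
#' one.
#'
#' @param pixels Tibble with a `pixel_share` column (as in
#'   `tally_dataset()$pixels`).
#' @return The tibble with strictly positive, renormalized shares.
#' @export
smooth_pixel_shares <- function(pixels) smooth_shares(pixels)

# tally over in-memory samples (no file round-trip)
tally_samples <- function(samples, table) {
  cc <- n_classes(table)
  px <- numeric(cc); pres <- integer(cc)
  for (s in samples) {
    counts <- tabulate(as.vector(s$mask) + 1L, nbins = cc)
    px <- px + counts
    pres <- pres + (counts > 0L)
  }
  list(pixels = tibble::tibble(id = table$id, name = table$name,
                               pixel_count = px, pixel_share = px / sum(px)),
       presence = tibble::tibble(id = table$id, name = table$name,
                                 image_count = pres),
       total_pixels = sum(px), total_images = length(samples))
}

# replace zero shares by half the smallest positive share (explicit
# smoothing so weighting stays defined when a rare class drew no pixels)
smooth_shares <- function(pixels) {
  f <- pixels$pixel_share
  if (any(f == 0)) {
    f[f == 0] <- min(f[f > 0]) / 2
    pixels$pixel_share <- f / sum(f)
  }
  pixels
}
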