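test_that("softmax is a stabilized, shift-invariant simplex map", {
  z <- array(0, c(2, 2, 4))
  p <- softmax_probabilities(z)
  expect_equal(as.vector(p), rep(0.25, 16))

  z1 <- array(c(log(1), log(3)), c(1, 1, 2))
  expect_equal(as.vector(softmax_probabilities(z1)), c(0.25, 0.75))

  withr::with_seed(2, zr <- array(rnorm(4 * 4 * 3, sd = 5), c(4, 4, 3)))
  expect_equal(softmax_probabilities(zr + 100), softmax_probabilities(zr),
               tolerance = 1e-12)
  ps <- matrix(softmax_probabilities(zr), 16, 3)
  expect_equal(rowSums(ps), rep(1, 16), tolerance = 1e-12)
  expect_equal(apply(matrix(zr, 16, 3), 1, which.max), apply(ps, 1, which.max))
  expect_error(softmax_probabilities(array(c(1, Inf), c(1, 1, 2))), "finite")
})

test_that("cross-entropy matches hand evaluation and weighting contract", {
  p1 <- array(c(1, 0), c(1, 1, 2))
  expect_equal(cross_entropy(p1, matrix(0L, 1, 1)), 0)

  p2 <- array(c(0.5, 0.5), c(1, 1, 2))
  expect_equal(cross_entropy(p2, matrix(0L, 1, 1)), log(2), tolerance = 1e-12)

  # two pixels with p_t = 0.5 and 0.25 -> (ln2 + ln4)/2
  p3 <- array(c(0.5, 0.25, 0.5, 0.75), c(2, 1, 2))
  t3 <- matrix(0L, 2, 1)
  expect_equal(cross_entropy(p3, t3), (log(2) + log(4)) / 2, tolerance = 1e-12)

  # weights: w = (2, 1), both pixels class 0 and class 1 resp.
  p4 <- array(c(0.5, 0.75, 0.5, 0.25), c(2, 1, 2))
  t4 <- matrix(c(0L, 1L), 2, 1)
  manual <- (2 * log(2) + 1 * log(4)) / 3
  expect_equal(cross_entropy(p4, t4, class_weights = c(2, 1)), manual,
               tolerance = 1e-12)

  # p_t = 0 is clamped, never infinite
  p5 <- array(c(0, 1), c(1, 1, 2))
  expect_true(is.finite(cross_entropy(p5, matrix(0L, 1, 1))))
})

test_that("focal loss reduces to CE at gamma = 0 and follows its closed form", {
  p <- array(c(0.5, 0.5), c(1, 1, 2))
  t <- matrix(0L, 1, 1)
  expect_equal(focal_loss(p, t, alpha_t = 1, gamma = 0), log(2),
               tolerance = 1e-12)

  # gamma = 2, alpha = 0.25, p_t = 0.9
  p9 <- array(c(0.9, 0.1), c(1, 1, 2))
  expect_equal(focal_loss(p9, t, 0.25, 2), 0.25 * 0.1^2 * (-log(0.9)),
               tolerance = 1e-12)

  expect_equal(focal_loss(array(c(1, 0), c(1, 1, 2)), t, 0.25, 4), 0)

  # equivalence on random inputs to 1e-10
  withr::with_seed(31, {
    for (i in 1:5) {
      z <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
      tm <- matrix(sample(0:3, 30, TRUE), 6, 5)
      pp <- softmax_probabilities(z)
      expect_equal(focal_loss(pp, tm, 1, 0), cross_entropy(pp, tm),
                   tolerance = 1e-10)
    }
  })
})

test_that("focal loss is monotone in p_t and in gamma", {
  t <- matrix(0L, 1, 1)
  pts <- seq(0.05, 0.95, by = 0.05)
  for (gamma in c(0.5, 2, 4)) {
    vals <- vapply(pts, function(q) {
      focal_loss(array(c(q, 1 - q), c(1, 1, 2)), t, 0.25, gamma)
    }, numeric(1))
    expect_true(all(diff(vals) < 0))       # nonincreasing in p_t
  }
  for (q in c(0.2, 0.5, 0.8)) {
    p <- array(c(q, 1 - q), c(1, 1, 2))
    vals <- vapply(c(0, 1, 2, 4), function(g) focal_loss(p, t, 0.25, g),
                   numeric(1))
    expect_true(all(diff(vals) <= 1e-14))  # larger gamma never increases loss
  }
})

test_that("Tversky index matches hard counts and the Dice special case", {
  # 5-pixel toy: TP=3, FP=1, FN=1 for class 0
  truth <- matrix(c(0L, 0L, 0L, 0L, 1L), 1, 5)
  pred <- matrix(c(0L, 0L, 0L, 1L, 0L), 1, 5)
  probs <- one_hot_probs(pred, 2)
  ti <- tversky_index(probs, truth, 0, sigma = 0.3, beta = 0.7)
  expect_equal(ti, 3 / (3 + 0.3 + 0.7), tolerance = 1e-5)

  # sigma = beta = 0.5 reduces to Dice = 2TP/(2TP+FP+FN)
  expect_equal(tversky_index(probs, truth, 0, 0.5, 0.5), 6 / 8,
               tolerance = 1e-5)

  perfect <- one_hot_probs(truth, 2)
  expect_equal(tversky_index(perfect, truth, 0, 0.3, 0.7), 1, tolerance = 1e-5)
  expect_equal(tversky_index(perfect, truth, 1, 0.3, 0.7), 1, tolerance = 1e-4)
})

test_that("Tversky index degrades strictly with extra FPs and FNs", {
  truth <- matrix(c(rep(0L, 6), rep(1L, 6)), 2, 6)
  base <- truth
  ti0 <- tversky_index(one_hot_probs(base, 2), truth, 0, 0.3, 0.7)
  fp <- base; fp[2, 4] <- 0L               # extra predicted class-0 pixel
  expect_lt(tversky_index(one_hot_probs(fp, 2), truth, 0, 0.3, 0.7), ti0)
  fn <- base; fn[1, 2] <- 1L               # missed class-0 pixel
  expect_lt(tversky_index(one_hot_probs(fn, 2), truth, 0, 0.3, 0.7), ti0)
})

test_that("Tversky/Dice losses follow their definitions and bounds", {
  truth <- matrix(c(0L, 0L, 0L, 0L, 1L), 1, 5)
  pred <- matrix(c(0L, 0L, 0L, 1L, 0L), 1, 5)
  probs <- one_hot_probs(pred, 2)

  perfect13 <- random_mask(6, 6, 13, seed = 3)
  expect_lt(tversky_loss(one_hot_probs(perfect13, 13), perfect13), 1e-4)

  # C = 1: loss = 1 - TI
  p1 <- array(one_hot_probs(pred, 2)[, , 1], c(1, 5, 1))
  expect_equal(tversky_loss(p1, matrix(0L, 1, 5), 0.3, 0.7),
               1 - tversky_index(p1, matrix(0L, 1, 5), 0, 0.3, 0.7),
               tolerance = 1e-12)

  withr::with_seed(5, {
    z <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
    tm <- matrix(sample(0:2, 16, TRUE), 4)
    pp <- softmax_probabilities(z)
    expect_equal(dice_loss(pp, tm), tversky_loss(pp, tm, 0.5, 0.5))
    expect_lte(tversky_loss(pp, tm), 3)    # bounded by C
    expect_gte(tversky_loss(pp, tm), 0)
  })

  # C=1 hard counts TP=3 FP=1 FN=1 -> Dice loss 1 - 6/8
  j <- array(c(1, 1, 1, 0, 1), c(1, 5, 1))
  expect_equal(dice_loss(j, matrix(c(0L, 0L, 0L, 0L, 1L), 1, 5)), 0.25,
               tolerance = 1e-5)
})

test_that("combined losses interpolate CE and Dice/Tversky by delta", {
  withr::with_seed(11, {
    z <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
    tm <- matrix(sample(0:2, 20, TRUE), 5)
  })
  pp <- softmax_probabilities(z)
  c1 <- loss_config("CETL", delta = 1)
  expect_equal(combined_loss("CETL", pp, tm, c1), cross_entropy(pp, tm),
               tolerance = 1e-12)
  c0 <- loss_config("CETL", delta = 0)
  expect_equal(combined_loss("CETL", pp, tm, c0),
               tversky_loss(pp, tm, 0.3, 0.7), tolerance = 1e-12)
  c0d <- loss_config("CEDL", delta = 0)
  expect_equal(combined_loss("CEDL", pp, tm, c0d), dice_loss(pp, tm),
               tolerance = 1e-12)

  # delta = 0.7, CE = ln 2, TL = 0.25 -> 0.7 ln2 + 0.3 * 0.25
  cfg <- loss_config("CETL", delta = 0.7)
  ce <- cross_entropy(pp, tm)
  tl <- tversky_loss(pp, tm, 0.3, 0.7)
  expect_equal(combined_loss("CETL", pp, tm, cfg), 0.7 * ce + 0.3 * tl,
               tolerance = 1e-12)
  expect_equal(0.7 * log(2) + 0.3 * 0.25, 0.5602, tolerance = 1e-4)
})

test_that("all losses are zero exactly at one-hot perfection, else positive", {
  m <- random_mask(5, 5, 3, seed = 17)
  hot <- one_hot_probs(m, 3)
  expect_equal(cross_entropy(hot, m), 0)
  expect_equal(focal_loss(hot, m), 0)
  expect_lt(tversky_loss(hot, m), 1e-4)
  withr::with_seed(23, {
    z <- array(rnorm(5 * 5 * 3), c(5, 5, 3))
  })
  pp <- softmax_probabilities(z)
  expect_gt(cross_entropy(pp, m), 0)
  expect_gt(focal_loss(pp, m), 0)
  expect_gt(tversky_loss(pp, m), 0)
  expect_gt(dice_loss(pp, m), 0)
})

test_that("analytic loss gradients match numerical differentiation", {
  withr::with_seed(41, {
    z <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
    tm <- matrix(sample(0:2, 16, TRUE), 4)
  })
  h <- 1e-6
  for (kind in c("CE", "FL", "DiL", "TL", "CEDL", "CETL")) {
    cfg <- loss_config(kind, class_weights = c(1.5, 0.7, 2.1))
    g <- loss_with_gradient(z, tm, cfg)
    value_at <- function(zz) loss_with_gradient(zz, tm, cfg)$value
    num <- array(0, dim(z))
    for (i in seq_along(z)) {
      zp <- z; zp[i] <- zp[i] + h
      zm <- z; zm[i] <- zm[i] - h
      num[i] <- (value_at(zp) - value_at(zm)) / (2 * h)
    }
    expect_lt(max(abs(num - g$grad)) / max(abs(num)), 1e-4)
  }
})

test_that("per-image Tversky aggregation averages image-level losses", {
  withr::with_seed(13, {
    z <- matrix(rnorm(2 * 12 * 3), 24, 3)   # two 12-pixel images stacked
    tm <- sample(0:2, 24, TRUE)
  })
  cfg_b <- loss_config("TL", per_image = FALSE)
  cfg_i <- loss_config("TL", per_image = TRUE)
  batch <- loss_with_gradient(z, tm, cfg_b, n_images = 2)$value
  per_img <- loss_with_gradient(z, tm, cfg_i, n_images = 2)$value
  p <- softmax_probabilities(z)
  manual <- (tversky_loss(array(p[1:12, ], c(12, 1, 3)), tm[1:12]) +
             tversky_loss(array(p[13:24, ], c(12, 1, 3)), tm[13:24])) / 2
  expect_equal(per_img, manual, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(batch, per_img)))
})
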