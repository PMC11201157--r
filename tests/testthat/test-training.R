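test_that("the piecewise schedule hits the published endpoints", {
  sgdm <- train_config("SGDM")
  expect_equal(sgdm$ilr, 1e-3)
  expect_equal(learning_rate_at(sgdm, 1), 1e-3)
  expect_equal(learning_rate_at(sgdm, 15), 3e-4)
  expect_equal(learning_rate_at(sgdm, 30), 9e-5)

  adam <- train_config("Adam")
  expect_equal(learning_rate_at(adam, 1), 1e-4)
  expect_equal(learning_rate_at(adam, 30), 9e-6, tolerance = 1e-12)

  rates <- vapply(1:30, function(e) learning_rate_at(sgdm, e), numeric(1))
  expect_true(all(diff(rates) <= 0))
  expect_equal(length(unique(rates)), 3)

  expect_error(learning_rate_at(sgdm, 0), "outside")
  expect_error(learning_rate_at(sgdm, 31), "outside")
})

test_that("optimizer steps match hand-computed updates", {
  # SGDM single step: v=0, g=1, lr=0.1 -> delta = -0.1
  s1 <- sgdm_step(0, 1, 0, lr = 0.1, momentum = 0.9, weight_decay = 0)
  expect_equal(s1$param, -0.1)
  # second step with same gradient: v2 = 0.9*(-0.1) - 0.1 = -0.19
  s2 <- sgdm_step(s1$param, 1, s1$velocity, 0.1, 0.9, 0)
  expect_equal(s2$param, -0.29, tolerance = 1e-12)

  # zero gradient, zero decay: identity
  s0 <- sgdm_step(c(1, 2), c(0, 0), c(0, 0), 0.1, 0.9, 0)
  expect_equal(s0$param, c(1, 2))

  # coupled L2: g' = g + wd * theta
  sw <- sgdm_step(2, 0, 0, lr = 0.1, momentum = 0, weight_decay = 0.5)
  expect_equal(sw$param, 2 - 0.1 * 1)

  # Adam first step: bias-corrected mhat = vhat = g-dependent -> ~ -lr
  a1 <- adam_step(0, 1, 0, 0, lr = 0.1, t = 1)
  expect_equal(a1$param, -0.1 * 1 / (1 + 1e-8), tolerance = 1e-12)
  a0 <- adam_step(c(3, -2), c(0, 0), c(0, 0), c(0, 0), 0.1, t = 1)
  expect_equal(a0$param, c(3, -2))

  # Adam step magnitude bound on bounded gradients
  p <- 0; m <- 0; v <- 0
  withr::with_seed(3, g <- rnorm(50))
  for (t in 1:50) {
    st <- adam_step(p, g[t], m, v, lr = 0.05, t = t)
    expect_lte(abs(st$param - p), 0.05 * (1 + 1e-6) / (1 - 1e-6))
    p <- st$param; m <- st$m; v <- st$v
  }

  expect_error(sgdm_step(0, Inf, 0, 0.1), "diverged")
})

test_that("both optimizers solve a convex quadratic to 1e-3", {
  # f(theta) = 0.5 * (theta - c)' A (theta - c), A diagonal
  a <- c(1, 4); ctr <- c(2, -1)
  grad <- function(th) a * (th - ctr)

  th <- c(0, 0); vel <- c(0, 0)
  for (i in 1:500) {
    st <- sgdm_step(th, grad(th), vel, lr = 0.05, momentum = 0.9)
    th <- st$param; vel <- st$velocity
  }
  expect_lt(max(abs(th - ctr)), 1e-3)

  th <- c(0, 0); m <- c(0, 0); v <- c(0, 0)
  for (t in 1:500) {
    st <- adam_step(th, grad(th), m, v, lr = 0.05, t = t)
    th <- st$param; m <- st$m; v <- st$v
  }
  expect_lt(max(abs(th - ctr)), 1e-3)
})

make_learnable_set <- function(n, seed, size = 32L) {
  # two-class task: bright disc on dark background, learnable at depth 2
  withr::with_seed(seed, {
    purrr::map(seq_len(n), function(i) {
      mask <- matrix(0L, size, size)
      cx <- runif(1, 10, size - 10); cy <- runif(1, 10, size - 10)
      r <- runif(1, 4, 8)
      xx <- matrix(rep(1:size, each = size), size, byrow = TRUE)
      yy <- matrix(rep(1:size, size), size)
      mask[(xx - cx)^2 + (yy - cy)^2 <= r^2] <- 1L
      img <- array(0.2, c(size, size, 3))
      for (ch in 1:3) img[, , ch][mask == 1L] <- 0.8
      img <- img + array(rnorm(size * size * 3, sd = 0.05), c(size, size, 3))
      list(image = pmin(pmax(img, 0), 1), mask = mask)
    })
  })
}

test_that("training logs the expected records and is reproducible", {
  sets <- list(train = make_learnable_set(16, seed = 1),
               val = make_learnable_set(4, seed = 2))
  uc <- unet_config(2, 4, 2, "ReLU", c(32, 32))
  tc <- train_config("Adam", epochs = 2, mini_batch = 8, ilr = 1e-3, seed = 7)
  fit <- train_model(build_unet(uc, 7), sets, loss_config("CE"), tc)
  log <- fit$log
  expect_equal(sum(log$phase == "epoch"), 2)
  expect_equal(sum(log$phase == "iteration"), ceiling(16 / 8) * 2)
  expect_true(all(diff(log$iteration[log$phase == "iteration"]) == 1))
  expect_true(all(!is.na(log$val_loss[log$phase == "epoch"])))
  expect_s3_class(autoplot(log), "ggplot")

  fit2 <- train_model(build_unet(uc, 7), sets, loss_config("CE"), tc)
  expect_equal(utils::tail(fit$log$loss[fit$log$phase == "iteration"], 1),
               utils::tail(fit2$log$loss[fit2$log$phase == "iteration"], 1))
  expect_equal(fit$model$params, fit2$model$params)

  expect_error(train_model(build_unet(uc, 7), list(train = list()),
                           loss_config("CE"), tc), "empty")
})

test_that("training loss falls on a learnable two-class task", {
  uc <- unet_config(2, 4, 2, "ReLU", c(32, 32))
  drops <- vapply(1:3, function(sd) {
    sets <- list(train = make_learnable_set(16, seed = sd + 10))
    tc <- train_config("Adam", epochs = 10, mini_batch = 8, ilr = 1e-3,
                       seed = sd)
    log <- train_model(build_unet(uc, sd), sets, loss_config("CE"), tc)$log
    it <- log[log$phase == "iteration", ]
    mean(it$loss[it$epoch == 1]) - mean(it$loss[it$epoch == 10])
  }, numeric(1))
  expect_gt(median(drops), 0)
})
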