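test_that("color/index conversion is a bijection on table colors", {
  tb <- toy_table(3)
  m <- random_mask(5, 7, 3, seed = 11)
  img <- index_to_color(m, tb)
  expect_identical(color_to_index(img, tb), m)

  uni <- matrix(0L, 2, 2)
  expect_identical(color_to_index(index_to_color(uni, tb), tb), uni)

  full <- cholecseg8k_classes()
  m13 <- matrix(0:12, 13, 4)
  img13 <- index_to_color(m13, full)
  cols <- unique(matrix(round(img13 * 255), ncol = 3)[, 1])
  expect_identical(color_to_index(img13, full), m13)
})

test_that("unknown colors and out-of-range labels are rejected with location", {
  tb <- toy_table(2)
  img <- index_to_color(matrix(0L, 2, 2), tb)
  img[2, 1, ] <- c(0.123, 0.9, 0.5)
  expect_error(color_to_index(img, tb), "row 2, col 1")
  expect_error(index_to_color(matrix(2L, 1, 1), tb), "outside")
  expect_error(index_to_color(matrix(13L, 2, 2), cholecseg8k_classes()),
               "outside")
})

test_that("mask PNG round-trips exactly", {
  tmp <- withr::local_tempfile(fileext = ".png")
  m <- random_mask(9, 6, 13, seed = 4)
  write_mask(m, tmp)
  expect_identical(read_mask(tmp), m)
})

test_that("resize_pair: identity, label closure, positivity check", {
  tb <- toy_table(3)
  m <- random_mask(8, 8, 3, seed = 2)
  img <- index_to_color(m, tb)
  same <- resize_pair(img, m, c(8, 8))
  expect_identical(same$image, img)
  expect_identical(same$mask, m)

  small <- resize_pair(img, m, c(3, 5))
  expect_true(all(small$mask %in% unique(as.vector(m))))
  expect_equal(dim(small$image), c(3, 5, 3))

  # downsizing from a realistic aspect ratio never invents labels
  m2 <- random_mask(48, 85, 3, seed = 9)
  out <- resize_nearest(m2, 22, 22)
  expect_true(all(out %in% unique(as.vector(m2))))

  expect_error(resize_pair(img, m, c(0, 4)), "positive")
})

test_that("bicubic downsizing averages the 4x4 source neighborhood", {
  # half-black / half-white 8x8 image to 4x4: boundary columns blend
  img <- matrix(rep(c(0, 1), each = 32), 8, 8)   # columns 1:4 black, 5:8 white
  out <- resize_bicubic(img, 4, 4)
  expect_true(all(out[, 1] < 0.05))
  expect_true(all(out[, 4] > 0.95))
  expect_true(all(out[, 2] > 0 & out[, 2] < 1))
  expect_true(all(out[, 3] > 0 & out[, 3] < 1))

  # independent direct evaluation of the separable weighted average at one
  # output pixel, using the same scaled cubic kernel definition
  ker <- function(x) {
    ax <- abs(x)
    ifelse(ax <= 1, 1.5 * ax^3 - 2.5 * ax^2 + 1,
           ifelse(ax < 2, -0.5 * ax^3 + 2.5 * ax^2 - 4 * ax + 2, 0))
  }
  direct <- function(img, i, j, scale) {
    u <- (i - 0.5) / scale + 0.5
    v <- (j - 0.5) / scale + 0.5
    acc <- 0; wsum <- 0
    for (si in -4:12) for (sj in -4:12) {   # border pixels replicate outward
      w <- ker(scale * (u - si)) * ker(scale * (v - sj))
      acc <- acc + w * img[min(max(si, 1), 8), min(max(sj, 1), 8)]
      wsum <- wsum + w
    }
    acc / wsum
  }
  expect_equal(out[2, 2], direct(img, 2, 2, 0.5), tolerance = 1e-10)
  expect_equal(out[3, 3], direct(img, 3, 3, 0.5), tolerance = 1e-10)
})

test_that("split_manifest honours floor sizes with remainder to train", {
  paths <- sprintf("img%05d.png", 1:8080)
  mf <- manifest(paths, sub("img", "msk", paths))
  sp <- split_manifest(mf, c(0.6, 0.2, 0.2), seed = 123)
  expect_equal(as.integer(table(sp$partition)[c("train", "val", "test")]),
               c(4848L, 1616L, 1616L))

  mf10 <- manifest(sprintf("a%d", 1:10), sprintf("b%d", 1:10))
  expect_true(all(split_manifest(mf10, c(1, 0, 0), 1)$partition == "train"))

  expect_error(split_manifest(mf10, c(0.5, 0.2, 0.2), 1), "sum to 1")
})

test_that("split_manifest is deterministic and order-insensitive", {
  paths <- sprintf("x%03d.png", 1:37)
  mf <- manifest(paths, sub("x", "y", paths))
  a <- split_manifest(mf, c(0.6, 0.2, 0.2), seed = 5)
  b <- split_manifest(mf, c(0.6, 0.2, 0.2), seed = 5)
  expect_identical(a, b)
  shuffled <- mf[rev(seq_len(nrow(mf))), ]
  c <- split_manifest(shuffled, c(0.6, 0.2, 0.2), seed = 5)
  expect_identical(a, c)
})

test_that("manifest CSV round-trips", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  mf <- split_manifest(manifest(sprintf("i%d.png", 1:9), sprintf("m%d.png", 1:9)),
                       c(0.6, 0.2, 0.2), 3)
  write_manifest(mf, tmp)
  back <- read_manifest(tmp)
  expect_equal(as.data.frame(back), as.data.frame(mf))
})

test_that("diff_overlay renders agreement as gray and disagreement as color", {
  tb <- toy_table(3)
  truth <- random_mask(6, 6, 3, seed = 21)
  ov <- diff_overlay(truth, truth, tb)
  expect_true(all(ov[, , 1] == ov[, , 2] & ov[, , 2] == ov[, , 3]))

  # disagree everywhere: shift labels cyclically
  pred <- (truth + 1L) %% 3L
  ov2 <- diff_overlay(pred, truth, tb)
  expect_true(all(ov2[, , 1] != ov2[, , 2]))

  # single-pixel disagreement -> exactly one non-gray pixel
  pred3 <- truth
  pred3[4, 2] <- (pred3[4, 2] + 1L) %% 3L
  ov3 <- diff_overlay(pred3, truth, tb)
  nongray <- sum(ov3[, , 1] != ov3[, , 2] | ov3[, , 2] != ov3[, , 3])
  expect_equal(nongray, 1L)

  expect_error(diff_overlay(truth[1:3, ], truth, tb), "equal dimensions")
})

test_that("class tables validate and serialize", {
  expect_error(class_table(c("a", "a"), c(0, 1), c(0, 1), c(0, 1)), "unique")
  expect_error(class_table(c("a", "b"), c(0, 0), c(0, 0), c(0, 0)), "unique")
  tb <- cholecseg8k_classes()
  expect_equal(nrow(tb), 13)
  expect_equal(tb$name[tb$id == 2], "Liver")
  for (ext in c(".csv", ".json")) {
    tmp <- withr::local_tempfile(fileext = ext)
    write_class_table(tb, tmp)
    expect_equal(as.data.frame(read_class_table(tmp)), as.data.frame(tb))
  }
})
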