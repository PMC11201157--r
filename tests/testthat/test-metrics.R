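test_that("accumulate keeps exact confusion bookkeeping", {
  acc <- confusion_accumulator(3)
  m <- random_mask(3, 3, 3, seed = 1)
  acc <- accumulate(acc, m, m)
  expect_equal(sum(diag(acc$counts)), 9)
  expect_equal(sum(acc$counts) - sum(diag(acc$counts)), 0)

  # hand bookkeeping: truth (0,1), pred (1,1)
  acc2 <- confusion_accumulator(2)
  acc2 <- accumulate(acc2, matrix(c(1L, 1L), 2, 1), matrix(c(0L, 1L), 2, 1))
  expect_equal(acc2$counts[1, 2], 1)
  expect_equal(acc2$counts[2, 2], 1)
  expect_equal(acc2$counts[1, 1], 0)

  # commutativity
  a <- random_mask(4, 4, 3, seed = 2); b <- random_mask(4, 4, 3, seed = 3)
  p1 <- accumulate(accumulate(confusion_accumulator(3), a, b), b, a)
  p2 <- accumulate(accumulate(confusion_accumulator(3), b, a), a, b)
  expect_equal(p1$counts, p2$counts)

  expect_error(accumulate(acc, m[1:2, ], m), "equal dimensions")
  expect_error(accumulate(confusion_accumulator(2), m, m), "labels")
})

test_that("per-class metrics match the closed forms on a 10-pixel toy", {
  # TP=3, FP=1, FN=1, TN=5 for class 0
  truth <- matrix(c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L, 1L), 2, 5)
  pred <- truth
  pred[which(truth == 0L)[4]] <- 1L        # one FN for class 0
  pred[which(truth == 1L)[1]] <- 0L        # one FP for class 0
  acc <- accumulate(confusion_accumulator(2), pred, truth)
  cm <- class_metrics(acc, 0)
  expect_equal(cm$acc_ovr, 0.8)
  expect_equal(cm$iou, 0.6)
  expect_equal(cm$dice, 0.75)
  expect_equal(cm$precision, 0.75)
  expect_equal(cm$recall, 0.75)
  expect_equal(cm$class_acc, 0.75)

  perfect <- accumulate(confusion_accumulator(2), truth, truth)
  pm <- class_metrics(perfect, 1)
  expect_equal(unlist(pm[c("acc_ovr", "class_acc", "iou", "dice",
                           "precision", "recall")]),
               setNames(rep(1, 6), c("acc_ovr", "class_acc", "iou", "dice",
                                     "precision", "recall")))
})

test_that("metrics equal a brute-force pixel-set oracle on random pairs", {
  withr::with_seed(99, {
    for (rep in 1:60) {
      cc <- sample(2:4, 1)
      h <- sample(2:8, 1); w <- sample(2:8, 1)
      pred <- matrix(sample(0:(cc - 1), h * w, TRUE), h, w)
      truth <- matrix(sample(0:(cc - 1), h * w, TRUE), h, w)
      acc <- accumulate(confusion_accumulator(cc), pred, truth)
      for (c in 0:(cc - 1)) {
        oracle <- brute_class_metrics(pred, truth, c)
        got <- class_metrics(acc, c)
        if (is.null(oracle)) {
          expect_false(got$defined)
        } else {
          for (nm in names(oracle)) {
            expect_equal(got[[nm]], oracle[[nm]], tolerance = 1e-12)
          }
          expect_equal(got$dice, 2 * got$iou / (1 + got$iou), tolerance = 1e-12)
        }
      }
    }
  })
})

test_that("boundary F1 matches brute force and its edge conventions", {
  # identical masks with the class present -> 1
  m <- matrix(0L, 8, 8); m[3:6, 3:6] <- 1L
  expect_equal(boundary_f1(m, m, 1, theta = 2), 1)

  # 4x4 square shifted by one pixel, theta = 2 -> all boundary distances <= 1
  shifted <- matrix(0L, 8, 8); shifted[4:7, 3:6] <- 1L
  expect_equal(boundary_f1(shifted, m, 1, theta = 2), 1)

  # two single-pixel regions 10 px apart, theta = 2 -> 0
  a <- matrix(0L, 3, 12); a[2, 1] <- 1L
  b <- matrix(0L, 3, 12); b[2, 11] <- 1L
  expect_equal(boundary_f1(a, b, 1, theta = 2), 0)

  # absent from both -> undefined
  expect_true(is.na(boundary_f1(a, b, 2, theta = 2)))

  # brute-force agreement on random masks
  withr::with_seed(55, {
    for (rep in 1:20) {
      p <- matrix(sample(0:2, 49, TRUE), 7, 7)
      t <- matrix(sample(0:2, 49, TRUE), 7, 7)
      for (c in 0:2) {
        expect_equal(boundary_f1(p, t, c, theta = 1.5),
                     brute_boundary_f1(p, t, c, theta = 1.5),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("boundary F1 is symmetric under swapping prediction and truth", {
  withr::with_seed(77, {
    for (rep in 1:10) {
      p <- matrix(sample(0:1, 36, TRUE), 6, 6)
      t <- matrix(sample(0:1, 36, TRUE), 6, 6)
      expect_equal(boundary_f1(p, t, 1, theta = 2), boundary_f1(t, p, 1, theta = 2))
    }
  })
})

test_that("summaries aggregate and exclude undefined classes", {
  truth <- random_mask(6, 6, 2, seed = 5)
  acc <- accumulate(confusion_accumulator(3), truth, truth)  # class 2 absent
  rep <- summarize_metrics(acc)
  expect_equal(rep$aggregates$GAcc, 1)
  expect_equal(rep$aggregates$MAcc, 1)
  expect_equal(rep$aggregates$MIoU, 1)
  expect_false(rep$per_class$defined[3])
  expect_true(is.na(rep$per_class$iou[3]))

  # MIoU is the arithmetic mean over defined classes
  t2 <- matrix(c(rep(0L, 6), rep(1L, 4)), 1, 10)
  p2 <- t2; p2[1, 5:6] <- 1L               # class 0: TP=4 FP=0 FN=2; class 1: TP=4 FP=2 FN=0
  acc2 <- accumulate(confusion_accumulator(2), p2, t2)
  r2 <- summarize_metrics(acc2)
  expect_equal(r2$aggregates$MIoU, mean(c(4 / 6, 4 / 6)))

  # GAcc = support-weighted mean of class recalls
  withr::with_seed(8, {
    pred <- matrix(sample(0:2, 64, TRUE), 8, 8)
    tr <- matrix(sample(0:2, 64, TRUE), 8, 8)
  })
  acc3 <- accumulate(confusion_accumulator(3), pred, tr)
  r3 <- summarize_metrics(acc3)
  pc <- r3$per_class
  expect_equal(r3$aggregates$GAcc,
               sum(pc$support * pc$class_acc) / sum(pc$support))

  expect_error(summarize_metrics(confusion_accumulator(2)), "empty")
})

test_that("flipping one correct pixel to wrong never increases GAcc", {
  withr::with_seed(12, {
    truth <- matrix(sample(0:2, 25, TRUE), 5, 5)
    pred <- truth
    for (i in 1:10) {
      idx <- sample(25, 1)
      before <- summarize_metrics(
        accumulate(confusion_accumulator(3), pred, truth))$aggregates$GAcc
      pred2 <- pred
      pred2[idx] <- (pred2[idx] + 1L) %% 3L
      after <- summarize_metrics(
        accumulate(confusion_accumulator(3), pred2, truth))$aggregates$GAcc
      expect_lte(after, before)
      pred <- pred2
    }
  })
})

test_that("report accessors and writers expose the standard layout", {
  truth <- random_mask(5, 5, 3, seed = 31)
  pred <- random_mask(5, 5, 3, seed = 32)
  acc <- accumulate(confusion_accumulator(3), pred, truth)
  bfs <- matrix(runif(3), 1, 3)
  rep <- summarize_metrics(acc, per_image_bfs = bfs, table = toy_table(3))
  expect_equal(rep$per_class$name, toy_table(3)$name)
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  gl <- glance(rep)
  expect_equal(names(gl), c("GAcc", "MAcc", "MIoU", "Mbfs", "n_images"))
  expect_s3_class(autoplot(rep), "ggplot")

  for (ext in c(".csv", ".json")) {
    tmp <- withr::local_tempfile(fileext = ext)
    write_metrics_report(rep, tmp)
    expect_true(file.exists(tmp))
  }
  csv <- withr::local_tempfile(fileext = ".csv")
  write_metrics_report(rep, csv)
  expect_match(readLines(csv)[1], "iou")
  expect_match(utils::tail(readLines(csv), 1), "GAcc")
})
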