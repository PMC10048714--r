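test_that("confusion counting matches direct enumeration", {
  cm <- confusion_from_predictions(
    truth = c("diseased", "diseased", "healthy", "healthy"),
    predicted = c("diseased", "healthy", "diseased", "healthy")
  )
  expect_equal(c(cm$tp, cm$fn, cm$fp, cm$tn), c(1, 1, 1, 1))

  all_right <- confusion_from_predictions(
    c("diseased", "healthy"), c("diseased", "healthy"))
  expect_equal(c(all_right$fp, all_right$fn), c(0, 0))

  flipped <- confusion_from_predictions(
    c("diseased", "healthy"), c("healthy", "diseased"))
  expect_equal(c(flipped$tp, flipped$tn), c(0, 0))

  expect_error(confusion_from_predictions("diseased", c("healthy", "healthy")),
               "same length")
  expect_error(confusion_from_predictions("diseased", "rotten"),
               "Unknown class label")
  expect_error(confusion_2x2(-1, 1, 0, 0), "non-negative")
  expect_error(confusion_2x2(0, 0, 0, 0), "at least one")
})

test_that("metrics agree with a brute-force per-sample oracle", {
  withr::with_seed(123, {
    for (i in 1:1000) {
      n <- sample(2:30, 1)
      truth <- sample(c("healthy", "diseased"), n, replace = TRUE)
      # ensure both metric paths get exercised, including degenerate ones
      predicted <- sample(c("healthy", "diseased"), n, replace = TRUE)
      m <- compute_metrics(confusion_from_predictions(truth, predicted))
      o <- oracle_macro_metrics(truth, predicted)
      expect_equal(m$accuracy, o$accuracy)
      expect_equal(m$precision, o$precision)
      expect_equal(m$recall, o$recall)
      expect_equal(m$f1, o$f1)
    }
  })
})

test_that("accuracy equals macro recall exactly on balanced sets", {
  withr::with_seed(77, {
    for (i in 1:1000) {
      half <- sample(1:120, 1)
      fn <- sample(0:half, 1)
      fp <- sample(0:half, 1)
      m <- compute_metrics(confusion_2x2(tp = half - fn, tn = half - fp,
                                         fp = fp, fn = fn))
      expect_equal(m$accuracy, m$recall, tolerance = 1e-12)
    }
  })
})

test_that("macro metrics are invariant to which class is called positive", {
  m1 <- compute_metrics(confusion_2x2(50, 38, 34, 22,
                                      positive_label = "diseased"))
  m2 <- compute_metrics(confusion_2x2(38, 50, 22, 34,
                                      positive_label = "healthy"))
  expect_equal(m1$accuracy, m2$accuracy)
  expect_equal(m1$precision, m2$precision)
  expect_equal(m1$recall, m2$recall)
  expect_equal(m1$f1, m2$f1)
})

test_that("metric bounds, perfection, and averaging modes behave", {
  perf <- compute_metrics(confusion_2x2(72, 72, 0, 0))
  expect_equal(c(perf$accuracy, perf$precision, perf$recall, perf$f1),
               rep(1, 4))
  m <- compute_metrics(confusion_2x2(5, 3, 2, 4))
  expect_true(all(unlist(m[c("accuracy", "precision", "recall", "f1")]) >= 0))
  expect_true(all(unlist(m[c("accuracy", "precision", "recall", "f1")]) <= 1))
  # weighted coincides with macro exactly when classes are balanced
  mw <- compute_metrics(confusion_2x2(50, 38, 34, 22), averaging = "weighted")
  mm <- compute_metrics(confusion_2x2(50, 38, 34, 22))
  expect_equal(mw$precision, mm$precision)
  pc <- compute_metrics(confusion_2x2(5, 3, 2, 4), averaging = "per_class")
  expect_true(is.na(pc$precision))
  expect_equal(nrow(pc$per_class), 2L)
  # degenerate denominator conventions
  none_pred <- compute_metrics(confusion_from_predictions(
    c("diseased", "healthy"), c("healthy", "healthy")))
  expect_equal(none_pred$per_class$precision[1], 0)
  # tidy/glance
  expect_equal(nrow(tidy(mm)), 2L)
  expect_equal(glance(mm)$total, 144)
})

test_that("the worked-example reconstruction matches the published metrics", {
  we <- reconstruct_worked_examples()
  expect_equal(nrow(we), 4L)
  expect_true(all(we$tp + we$fn == 72 & we$tn + we$fp == 72))
  expect_true(all(we$dev_accuracy == 0))
  expect_true(all(we$dev_precision == 0))
  # the one published recall that breaks the balanced-set identity is
  # reported at its reconstructed (identity-consistent) value
  r5 <- we[we$model == "MLP_30_ResNet101_layer5", ]
  expect_equal(r5$recall, r5$accuracy)
  expect_equal(r5$dev_recall, 0.034)
  expect_equal(sum(we$dev_recall > 0), 1L)
})

test_that("report rendering is deterministic and names the best model", {
  tbl <- tibble::tibble(model = c("a", "b"), accuracy = c(0.7, 0.9),
                        tp = c(7, 9), tn = c(7, 9), fp = c(3, 1),
                        fn = c(3, 1))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  render_report(list(exp = tbl), d1)
  render_report(list(exp = tbl), d2)
  expect_true(file.exists(file.path(d1, "exp.csv")))
  expect_identical(readLines(file.path(d1, "exp.csv")),
                   readLines(file.path(d2, "exp.csv")))
  expect_equal(length(readLines(file.path(d1, "exp.csv"))), 3L)
  summary <- readLines(file.path(d1, "summary.txt"))
  expect_match(summary, "best model b", all = FALSE)
  expect_true(file.exists(file.path(d1, "exp_best_confusion.png")))
  one <- render_report(list(single = tbl[1, ]), withr::local_tempdir())
  expect_error(render_report(list(), d1), "non-empty")
})
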