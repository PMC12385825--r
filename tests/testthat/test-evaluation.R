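test_that("confusion counts follow the standard positive-class convention", {
  truth <- setNames(rep(c("class1", "class2"), each = 10), paste0("s", 1:20))
  cm <- confusion(truth, truth)
  expect_equal(unlist(cm[c("tp", "tn", "fp", "fn")]),
               c(tp = 10, tn = 10, fp = 0, fn = 0))

  flipped <- setNames(ifelse(truth == "class1", "class2", "class1"),
                      names(truth))
  cm2 <- confusion(truth, flipped)
  expect_equal(unlist(cm2[c("tp", "tn", "fp", "fn")]),
               c(tp = 0, tn = 0, fp = 10, fn = 10))
  expect_equal(cm2$total, 20)

  # ids are matched by name, not position
  cm3 <- confusion(truth, rev(truth))
  expect_equal(cm3$tp + cm3$tn, 20)

  expect_error(confusion(character(0), character(0)), "empty")
  expect_error(confusion(truth, setNames(truth, paste0("x", 1:20))),
               "different sample ids")
})

test_that("metric formulas agree with direct arithmetic", {
  r <- metrics(list(tp = 3, tn = 2, fp = 1, fn = 2))
  expect_equal(r$accuracy, 5 / 8)
  expect_equal(r$precision_1, 3 / 4)
  expect_equal(r$recall_1, 3 / 5)
  expect_equal(r$precision_2, 2 / 4)
  expect_equal(r$recall_2, 2 / 3)
  expect_equal(r$f1_1, 2 * (3 / 4) * (3 / 5) / (3 / 4 + 3 / 5))

  perfect <- metrics(list(tp = 7, tn = 5, fp = 0, fn = 0))
  expect_equal(unlist(perfect[c("precision_1", "precision_2", "recall_1",
                                "recall_2", "f1_1", "f1_2")]),
               rep(1, 6), ignore_attr = TRUE)
  expect_error(metrics(list(tp = -1, tn = 1, fp = 0, fn = 0)), "negative")
  warns <- capture_warnings(r0 <- metrics(list(tp = 0, tn = 5, fp = 0, fn = 0)))
  expect_true(any(grepl("undefined", warns)))   # precision_1 and its F1
  expect_true(is.nan(r0$precision_1))
  expect_true(is.nan(r0$f1_1))
})

test_that("metrics are symmetric under a joint class swap and F1 is bounded", {
  set.seed(13)
  for (i in 1:20) {
    cm <- as.list(setNames(sample(0:30, 4, replace = TRUE),
                           c("tp", "tn", "fp", "fn")))
    if (sum(unlist(cm)) == 0) next
    r <- suppressWarnings(metrics(cm))
    swapped <- suppressWarnings(metrics(list(tp = cm$tn, tn = cm$tp,
                                             fp = cm$fn, fn = cm$fp)))
    expect_equal(r$accuracy, swapped$accuracy)
    expect_equal(r$precision_1, swapped$precision_2)
    expect_equal(r$recall_1, swapped$recall_2)
    expect_equal(r$f1_1, swapped$f1_2)
    if (!is.nan(r$f1_1)) {
      expect_lte(r$f1_1, max(r$precision_1, r$recall_1) + 1e-12)
      expect_gte(r$f1_1, min(r$precision_1, r$recall_1) - 1e-12)
    }
  }
})
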