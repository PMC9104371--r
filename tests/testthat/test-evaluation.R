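test_that("confusion matrix counts pairs in the predicted-by-real layout", {
  empty <- confusion_matrix(character(0), character(0))
  expect_true(all(empty == 0))
  expect_equal(dim(empty), c(3, 3))

  all_neg <- confusion_matrix(rep("negative", 10), rep("negative", 10))
  expect_equal(all_neg["negative", "negative"], 10L)
  expect_equal(sum(all_neg), 10L)

  set.seed(13)
  pred <- sample(c("negative", "neutral", "positive"), 100, replace = TRUE)
  real <- sample(c("negative", "neutral", "positive"), 100, replace = TRUE)
  cm <- confusion_matrix(pred, real)
  expect_equal(sum(cm), 100L)
  expect_equal(as.integer(rowSums(cm)),
               as.integer(table(factor(pred, rownames(cm)))))
  expect_equal(as.integer(colSums(cm)),
               as.integer(table(factor(real, colnames(cm)))))
  expect_error(confusion_matrix("meh", "negative"), "unknown")
})

test_that("accuracy is 100 * trace / total", {
  ident <- confusion_matrix(rep(c("negative", "neutral", "positive"), 4),
                            rep(c("negative", "neutral", "positive"), 4))
  expect_equal(accuracy(ident), 100)
  expect_error(accuracy(confusion_matrix(character(0), character(0))),
               "empty")
})

test_that("support-weighted recall equals accuracy on random matrices", {
  set.seed(29)
  for (i in 1:200) {
    cm <- random_cm3()
    rep <- suppressWarnings(weighted_one_vs_all(cm))
    expect_equal(rep$weighted_recall, 100 * sum(diag(cm)) / sum(cm),
                 tolerance = 1e-12)
    expect_equal(rep$weighted_recall, rep$accuracy, tolerance = 1e-12)
    # transposition leaves every class's one-vs-all collapse unchanged
    # (TP and TN per class are symmetric), so the per-class accuracies and
    # any fixed-weight aggregate of them are transpose-invariant
    rep_t <- suppressWarnings(weighted_one_vs_all(t(cm)))
    expect_equal(rep_t$per_class$accuracy, rep$per_class$accuracy,
                 tolerance = 1e-9)
    w <- rep$per_class$support / sum(cm)
    expect_equal(sum(w * rep_t$per_class$accuracy), rep$weighted_accuracy,
                 tolerance = 1e-9)
    # every per-class 2x2 collapse accounts for all N items
    with(rep$per_class, expect_true(all(tp + fp + fn + tn == sum(cm))))
    expect_true(all(unlist(rep[c("accuracy", "weighted_accuracy",
                                 "weighted_precision", "weighted_recall",
                                 "weighted_f1")]) >= 0))
    expect_true(all(unlist(rep[c("accuracy", "weighted_accuracy",
                                 "weighted_precision", "weighted_recall",
                                 "weighted_f1")]) <= 100))
  }
})

test_that("a never-predicted class yields precision 0 with a warning", {
  cm <- confusion_matrix(c("negative", "negative", "positive",
                           "positive", "negative", "positive"),
                         rep(c("negative", "neutral", "positive"), 2))
  expect_warning(rep <- weighted_one_vs_all(cm), "never predicted")
  expect_equal(rep$per_class$precision[rep$per_class$class == "neutral"], 0)
})

test_that("misclassification report lists exactly the off-diagonal items", {
  corpus <- tibble::tibble(id = sprintf("t%02d", 1:6),
                           text = letters[1:6],
                           gold = c("negative", "negative", "neutral",
                                    "neutral", "positive", "positive"))
  correct <- corpus$gold
  expect_equal(nrow(misclassification_report(corpus, correct)), 0)

  planted <- correct
  planted[5] <- "negative"  # one positive classified as negative
  mis <- misclassification_report(corpus, planted)
  expect_equal(nrow(mis), 1)
  expect_equal(mis$id, "t05")
  expect_equal(mis$gold, "positive")
  expect_equal(mis$predicted, "negative")

  cm <- confusion_matrix(planted, corpus$gold)
  expect_equal(nrow(mis), sum(cm) - sum(diag(cm)))
  expect_error(misclassification_report(corpus, planted[-1]),
               "one prediction per testimony")
})

test_that("percent display rounds half away from zero", {
  expect_equal(round_half_up(82.545, 2), 82.55)
  expect_equal(round_half_up(88.889, 2), 88.89)
  expect_equal(round_half_up(c(1.005, 2.675), 2), c(1.01, 2.68))
})

test_that("matrices and reports serialize to TSV and JSON", {
  cm <- reference_matrices()[["mlp-staff"]]
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_confusion_tsv(cm, tsv)
  back <- utils::read.delim(tsv, row.names = 1)
  expect_equal(as.integer(as.matrix(back)), as.integer(cm))

  js <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(weighted_one_vs_all(cm), js)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$n, 140)
  expect_true(abs(parsed$accuracy - 100 * 124 / 140) < 1e-9)
})
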