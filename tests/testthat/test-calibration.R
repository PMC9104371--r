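test_that("decision intervals match the published student MLP thresholds", {
  presets <- threshold_presets()
  th <- presets[["mlp-students"]]
  expect_equal(th$t_neu_neg, 0.22)
  expect_equal(th$t_pos_neu, 0.49)
  expect_equal(decide(0.50, th), "positive")
  expect_equal(decide(0.30, th), "neutral")
  expect_equal(decide(0.10, th), "negative")
  expect_named(presets, c("mlp-students", "mlp-staff", "svm-students",
                          "svm-staff"))
  for (p in presets) expect_lte(p$t_neu_neg, p$t_pos_neu)
})

test_that("the three decision intervals partition [-1, 1]", {
  sweep <- seq(-1, 1, by = 0.001)
  for (th in list(threshold_pair(-0.3, 0.4), threshold_pair(0, 0),
                  threshold_pair(-1, 1))) {
    cls <- decide(sweep, th)
    expect_true(all(cls %in% c("negative", "neutral", "positive")))
    expect_length(cls, length(sweep))
  }
  # boundary membership: neutral is lower-inclusive, positive claims t_pos_neu
  th <- threshold_pair(-0.25, 0.5)
  expect_equal(decide(-0.25, th), "neutral")
  expect_equal(decide(0.5, th), "positive")
  # equal thresholds leave no room for neutral
  expect_false("neutral" %in% decide(sweep, threshold_pair(0, 0)))
  expect_error(decide(1.5, th), "\\[-1, 1\\]")
  expect_error(threshold_pair(0.5, 0.2), "t_neu_neg <= t_pos_neu")
})

test_that("calibrate recovers planted band boundaries within one grid step", {
  planted <- planted_band_scores(100)
  th <- calibrate(planted$score, planted$gold,
                  calibration_config(seed = 5))
  expect_lte(abs(th$t_neu_neg - 0.0), 0.01 + 1e-9)
  expect_lte(abs(th$t_pos_neu - 0.7), 0.01 + 1e-9)
  pairs <- attr(th, "fold_pairs")
  expect_equal(dim(pairs), c(5, 2))
  expect_true(all(pairs[, 1] <= pairs[, 2]))
  expect_true(all(attr(th, "fold_accuracy") > 0.95))
})

test_that("grid search agrees with an exhaustive brute-force oracle", {
  set.seed(31)
  grid <- seq(-1, 1, by = 0.05)
  for (i in 1:12) {
    n <- sample(9:50, 1)
    gold <- sample(c("negative", "neutral", "positive"), n, replace = TRUE)
    centers <- c(negative = -0.6, neutral = 0.2, positive = 0.8)
    score <- pmin(1, pmax(-1, centers[gold] + rnorm(n, sd = 0.3)))
    got <- sentitri:::best_grid_pair(score, gold, grid)
    want <- brute_force_pair(score, gold, step = 0.05)
    expect_equal(got$correct, want$correct)
    expect_equal(got$pair, want$pair, tolerance = 1e-9)
  }
})

test_that("perfectly separated items reach fold accuracy 1 with k = 2", {
  score <- c(-0.9, -0.8, 0.2, 0.9)
  gold <- c("negative", "negative", "neutral", "positive")
  th <- calibrate(score, gold, calibration_config(k_folds = 2, seed = 1))
  # every fold's training half may miss a class, but the averaged pair must
  # still classify the full separated set correctly when possible
  expect_true(all(attr(th, "fold_pairs")[, 1] <=
                    attr(th, "fold_pairs")[, 2]))
  full <- sentitri:::best_grid_pair(score, gold, seq(-1, 1, 0.01))
  expect_equal(full$correct, 4)
})

test_that("calibrate validates its inputs", {
  expect_error(calibrate(c(0.1, 0.2), c("negative", "neutral"),
                         calibration_config(k_folds = 5)), "k_folds")
  expect_error(calibrate(rep(0.1, 10), rep("positive", 10)),
               "three classes")
  expect_error(calibrate(c(2, 0, -0.5),
                         c("negative", "neutral", "positive"),
                         calibration_config(k_folds = 2)), "\\[-1, 1\\]")
  expect_error(calibration_config(k_folds = 1), "k_folds")
  expect_error(calibration_config(grid_step = 0.7), "grid_step")
})

test_that("averaged thresholds always satisfy the ordering invariant", {
  set.seed(77)
  for (i in 1:10) {
    n <- sample(30:120, 1)
    gold <- sample(c("negative", "neutral", "positive"), n, replace = TRUE,
                   prob = c(0.5, 0.2, 0.3))
    score <- pmin(1, pmax(-1, rnorm(n, sd = 0.6)))
    th <- calibrate(score, gold, calibration_config(seed = i,
                                                    stratified = i %% 2 == 0))
    expect_true(-1 <= th$t_neu_neg && th$t_neu_neg <= th$t_pos_neu &&
                  th$t_pos_neu <= 1)
  }
})

test_that("thresholds round-trip through YAML", {
  th <- threshold_pair(-0.12, 0.55)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_thresholds_yaml(th, path, model = "mlp", dataset = "synthetic",
                        config = calibration_config())
  back <- read_thresholds_yaml(path)
  expect_equal(back$t_neu_neg, th$t_neu_neg)
  expect_equal(back$t_pos_neu, th$t_pos_neu)
})
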