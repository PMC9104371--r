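test_that("survey generator returns exactly the requested cell counts", {
  strata <- list(stratum_spec("A", "student", 5, 2, 3),
                 stratum_spec("B", "staff", 1, 0, 4))
  corpus <- generate_survey_corpus(strata, tiny_lexicon(seed = 11))
  expect_equal(nrow(corpus), 15)
  tab <- table(corpus$country, corpus$gold)
  expect_equal(as.integer(tab["A", c("negative", "neutral", "positive")]),
               c(5, 2, 3))
  expect_equal(as.integer(tab["B", c("negative", "neutral", "positive")]),
               c(1, 0, 4))
  expect_true(all(nzchar(corpus$text)))
  expect_false(any(duplicated(corpus$id)))
})

test_that("default strata reproduce the study's stratified class counts", {
  corpus <- generate_survey_corpus(lexicon = tiny_lexicon())
  expect_equal(nrow(corpus), 365)
  expect_equal(sum(corpus$role == "student"), 225)
  expect_equal(sum(corpus$role == "staff"), 140)
  cell <- function(country, role) {
    sub <- corpus[corpus$country == country & corpus$role == role, ]
    as.integer(table(factor(sub$gold, c("negative", "neutral", "positive"))))
  }
  expect_equal(cell("Spain", "student"), c(88, 6, 12))
  expect_equal(cell("Colombia", "student"), c(84, 26, 9))
  expect_equal(cell("Spain", "staff"), c(41, 14, 27))
  expect_equal(cell("Colombia", "staff"), c(30, 14, 14))
})

test_that("a (0,0,1) stratum yields a single gold-positive testimony", {
  corpus <- generate_survey_corpus(list(stratum_spec("X", "staff", 0, 0, 1)),
                                   tiny_lexicon())
  expect_equal(nrow(corpus), 1)
  expect_equal(corpus$gold, "positive")
})

test_that("generation is seed-deterministic and seed-sensitive", {
  a <- generate_survey_corpus(lexicon = tiny_lexicon(seed = 7))
  b <- generate_survey_corpus(lexicon = tiny_lexicon(seed = 7))
  c <- generate_survey_corpus(lexicon = tiny_lexicon(seed = 8))
  expect_identical(a, b)
  expect_false(identical(a$text, c$text))
  expect_identical(table(a$gold), table(c$gold))  # counts unaffected by seed
})

test_that("generator rejects invalid configurations", {
  expect_error(stratum_spec("A", "student", -1, 0, 0), "non-negative")
  expect_error(generate_survey_corpus(list(), tiny_lexicon()), "non-empty")
  expect_error(lexicon_config(positive_terms = character()), "non-empty")
  expect_error(lexicon_config(positive_terms = c("x"),
                              negative_terms = c("x", "y")), "disjoint")
  expect_error(lexicon_config(polarity_purity = 0.8, noise_rate = 0.3),
               "purity")
  expect_error(lexicon_config(doc_length_range = c(0, 5)), "doc_length_range")
})

test_that("binary corpus honors balance, split ratio and seed", {
  corpus <- generate_binary_corpus(1000, 0.5, tiny_lexicon(seed = 3), 0.8)
  expect_equal(sum(corpus$split == "train"), 800)
  expect_equal(sum(corpus$split == "validation"), 200)
  expect_equal(sum(corpus$label == 1), 500)

  two <- generate_binary_corpus(2, 0.5, tiny_lexicon())
  expect_setequal(two$label, c(0L, 1L))

  again <- generate_binary_corpus(1000, 0.5, tiny_lexicon(seed = 3), 0.8)
  expect_identical(corpus, again)
  expect_error(generate_binary_corpus(1, 0.5, tiny_lexicon()), "at least 2")
  expect_error(generate_binary_corpus(10, 1.2, tiny_lexicon()), "balance")
  expect_error(generate_binary_corpus(10, 0.5, tiny_lexicon(),
                                      split_ratio = 1), "split_ratio")
})

test_that("higher polarity purity never hurts a lexicon-count classifier", {
  accs <- vapply(c(0.5, 0.7, 0.9), function(p) {
    lexicon_count_accuracy(
      generate_binary_corpus(400, 0.5, tiny_lexicon(purity = p, seed = 5)),
      tiny_lexicon())
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_gt(accs[3], 0.9)
})

test_that("corpora round-trip through CSV", {
  corpus <- generate_survey_corpus(list(stratum_spec("A", "student", 3, 1, 2)),
                                   tiny_lexicon())
  path <- withr::local_tempfile(fileext = ".csv")
  write_corpus_csv(corpus, path)
  back <- read_corpus_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(corpus))
})

test_that("strata YAML config is read into stratum specs", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("- country: Spain", "  role: student", "  n_negative: 88",
               "  n_neutral: 6", "  n_positive: 12"), path)
  strata <- read_strata_yaml(path)
  expect_length(strata, 1)
  expect_equal(strata[[1]]$n_negative, 88L)
})
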