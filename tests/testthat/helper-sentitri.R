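# Shared fixtures and independent oracles for the test suite.

# Tiny disjoint lexicons so generator-dependent tests stay fast.
tiny_lexicon <- function(purity = 0.9, noise = 0.05, seed = 1,
                         len = c(5L, 15L)) {
  lexicon_config(positive_terms = c("good", "happy", "hope"),
                 negative_terms = c("bad", "sad", "fear"),
                 neutral_terms = c("desk", "email", "screen"),
                 filler_terms = c("the", "and", "home", "day"),
                 doc_length_range = len, polarity_purity = purity,
                 noise_rate = noise, seed = seed)
}

# Independent brute-force threshold search: triple loop over all grid pairs,
# tie-breaking to the tightest neutral interval (largest a, then smallest b).
brute_force_pair <- function(score, gold, step = 0.05) {
  grid <- seq(-1, 1, by = step)
  best <- NULL
  best_correct <- -1
  for (a in grid) {
    for (b in grid[grid >= a]) {
      pred <- ifelse(score < a, "negative",
                     ifelse(score < b, "neutral", "positive"))
      correct <- sum(pred == gold)
      replace <- correct > best_correct ||
        (correct == best_correct &&
           (a > best[1] || (a == best[1] && b < best[2])))
      if (replace) {
        best_correct <- correct
        best <- c(a, b)
      }
    }
  }
  list(pair = best, correct = best_correct)
}

# Random 3x3 confusion matrix with strictly positive total.
random_cm3 <- function() {
  m <- matrix(rpois(9, lambda = sample(1:40, 1)), 3, 3,
              dimnames = list(predicted = c("negative", "neutral", "positive"),
                              real = c("negative", "neutral", "positive")))
  if (sum(m) == 0) m[1, 1] <- 1L
  m
}

# Deterministic evenly spaced scores spanning three class bands whose
# neutral edges are the planted decision boundaries (0.0, 0.7).
planted_band_scores <- function(n_per_class = 100) {
  list(score = c(seq(-1, -0.6, length.out = n_per_class),
                 seq(0, 0.693, length.out = n_per_class),
                 seq(0.8, 1, length.out = n_per_class)),
       gold = rep(c("negative", "neutral", "positive"),
                  each = n_per_class))
}

# Simple lexicon-count polarity classifier used to probe generator
# separability independently of any embedding or regressor.
lexicon_count_accuracy <- function(corpus, lexicon) {
  votes <- vapply(corpus$text, function(tx) {
    toks <- strsplit(tx, " ", fixed = TRUE)[[1]]
    sum(toks %in% lexicon$positive_terms) -
      sum(toks %in% lexicon$negative_terms)
  }, numeric(1))
  pred <- ifelse(votes > 0, 1L, 0L)
  mean(pred == corpus$label)
}
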