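#' Stratum specification for the survey generator
#'
#' One stratum is a (country, role) cell of the survey with its per-class
#' gold-label counts. The shipped defaults ([default_strata()]) reproduce the
#' class histograms of the lockdown survey study: 225 student and 140 staff
#' responses from Spain and Colombia.
#'
#' @param country country label, e.g. `"Spain"`.
#' @param role respondent role, `"student"` or `"staff"`.
#' @param n_negative,n_neutral,n_positive non-negative integer class counts.
#' @return A `stratum_spec` object (named list).
#' @export
#' @examples
#' stratum_spec("Spain", "student", 88, 6, 12)
stratum_spec <- function(country, role, n_negative, n_neutral, n_positive) {
  role <- match.arg(role, c("student", "staff"))
  counts <- c(n_negative, n_neutral, n_positive)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("class counts must be non-negative integers", call. = FALSE)
  }
  structure(list(country = country, role = role,
                 n_negative = as.integer(n_negative),
                 n_neutral = as.integer(n_neutral),
                 n_positive = as.integer(n_positive)),
            class = "stratum_spec")
}

#' Default survey strata
#'
#' The four (country, role) cells with the study's hand-label class counts:
#' Spain students 88/6/12, Colombia students 84/26/9, Spain staff 41/14/27,
#' Colombia staff 30/14/14 (negative/neutral/positive), totalling 225 students
#' and 140 staff (365 responses).
#'
#' @return list of [stratum_spec()] objects.
#' @export
default_strata <- function() {
  list(
    stratum_spec("Spain",    "student", 88, 6, 12),
    stratum_spec("Colombia", "student", 84, 26, 9),
    stratum_spec("Spain",    "staff",   41, 14, 27),
    stratum_spec("Colombia", "staff",   30, 14, 14)
  )
}

#' Class-conditional lexicon configuration
#'
#' Controls the token distributions of the synthetic corpus. Each document of
#' gold class c draws, per token position: with probability `polarity_purity`
#' a token from class c's lexicon, with probability `noise_rate` a random
#' junk token, and otherwise a shared filler token. The defaults emulate
#' class-separable lockdown testimony vocabulary.
#'
#' @param positive_terms,negative_terms,neutral_terms pairwise-disjoint
#'   character vectors (each non-empty).
#' @param filler_terms shared topic/function words available to every class.
#' @param doc_length_range integer pair, inclusive bounds on tokens per
#'   document; minimum must be >= 1.
#' @param polarity_purity fraction of tokens drawn from the class lexicon,
#'   in `[0, 1]`.
#' @param noise_rate fraction of random junk tokens, with
#'   `polarity_purity + noise_rate <= 1`.
#' @param seed integer RNG seed for the generator.
#' @return A `lexicon_config` object.
#' @export
lexicon_config <- function(positive_terms = NULL, negative_terms = NULL,
                           neutral_terms = NULL, filler_terms = NULL,
                           doc_length_range = c(8L, 40L),
                           polarity_purity = 0.9, noise_rate = 0.05,
                           seed = 1L) {
  if (is.null(positive_terms)) positive_terms <- c(
    "grateful", "hope", "opportunity", "appreciate", "calm", "learning",
    "solidarity", "support", "resilient", "growth", "together", "improve",
    "reflection", "teleworking", "wellbeing", "positive")
  if (is.null(negative_terms)) negative_terms <- c(
    "stress", "anxiety", "fear", "lonely", "exhausted", "uncertainty",
    "overwhelmed", "isolation", "worry", "sadness", "helpless", "workload",
    "insufficient", "precarious", "anguish", "negative")
  if (is.null(neutral_terms)) neutral_terms <- c(
    "routine", "schedule", "online", "classes", "computer", "meetings",
    "email", "screen", "lectures", "assignments", "platform", "videocall")
  if (is.null(filler_terms)) filler_terms <- c(
    "the", "and", "of", "to", "in", "we", "have", "our", "during", "this",
    "pandemic", "quarantine", "lockdown", "home", "family", "university",
    "time", "work", "people", "day", "situation", "life", "study")

  lex <- list(positive_terms, negative_terms, neutral_terms)
  if (any(lengths(lex) == 0)) {
    stop("every class lexicon must be non-empty", call. = FALSE)
  }
  pairs <- utils::combn(3, 2)
  for (k in seq_len(ncol(pairs))) {
    if (length(intersect(lex[[pairs[1, k]]], lex[[pairs[2, k]]])) > 0)
      stop("class lexicons must be pairwise disjoint", call. = FALSE)
  }
  doc_length_range <- as.integer(doc_length_range)
  if (length(doc_length_range) != 2 || doc_length_range[1] < 1 ||
      doc_length_range[2] < doc_length_range[1]) {
    stop("doc_length_range must be an increasing integer pair with min >= 1",
         call. = FALSE)
  }
  if (polarity_purity < 0 || polarity_purity > 1 || noise_rate < 0 ||
      noise_rate > 1 || polarity_purity + noise_rate > 1) {
    stop("need 0 <= polarity_purity, noise_rate and purity + noise <= 1",
         call. = FALSE)
  }
  structure(list(positive_terms = positive_terms,
                 negative_terms = negative_terms,
                 neutral_terms = neutral_terms,
                 filler_terms = filler_terms,
                 doc_length_range = doc_length_range,
                 polarity_purity = polarity_purity,
                 noise_rate = noise_rate,
                 seed = as.integer(seed)),
            class = "lexicon_config")
}

class_lexicon <- function(lexicon, class) {
  switch(class,
         positive = lexicon$positive_terms,
         negative = lexicon$negative_terms,
         neutral  = lexicon$neutral_terms)
}

# One synthetic document of the given gold class. Runs inside an active
# seeded RNG stream.
draw_document <- function(class, lexicon) {
  len <- sample(lexicon$doc_length_range[1]:lexicon$doc_length_range[2], 1)
  u <- stats::runif(len)
  pool <- class_lexicon(lexicon, class)
  tokens <- character(len)
  for (i in seq_len(len)) {
    tokens[i] <- if (u[i] < lexicon$polarity_purity) {
      pool[sample.int(length(pool), 1)]
    } else if (u[i] < lexicon$polarity_purity + lexicon$noise_rate) {
      paste(letters[sample.int(26, 6, replace = TRUE)], collapse = "")
    } else {
      lexicon$filler_terms[sample.int(length(lexicon$filler_terms), 1)]
    }
  }
  paste(tokens, collapse = " ")
}

#' Generate a labeled survey-style corpus
#'
#' Synthesizes free-text testimonies with exactly the class counts requested
#' per (country, role) stratum, drawing tokens from class-conditional
#' lexicons. Identical configuration and seed yield a byte-identical corpus.
#'
#' @param strata list of [stratum_spec()]; defaults to the study strata.
#' @param lexicon a [lexicon_config()].
#' @return tibble with columns `id`, `country`, `role`, `gold`, `text`.
#' @export
#' @examples
#' corpus <- generate_survey_corpus(list(stratum_spec("X", "staff", 2, 1, 1)),
#'                                  lexicon_config(seed = 7))
#' table(corpus$gold)
generate_survey_corpus <- function(strata = default_strata(),
                                   lexicon = lexicon_config()) {
  if (length(strata) == 0) stop("strata must be non-empty", call. = FALSE)
  stopifnot(all(vapply(strata, inherits, logical(1), "stratum_spec")),
            inherits(lexicon, "lexicon_config"))
  with_seed(lexicon$seed, {
    rows <- list()
    for (s in strata) {
      gold <- rep(SENTIMENT_CLASSES,
                  times = c(s$n_negative, s$n_neutral, s$n_positive))
      if (length(gold) == 0) next
      texts <- vapply(gold, draw_document, character(1), lexicon = lexicon)
      rows[[length(rows) + 1]] <- tibble::tibble(
        country = s$country, role = s$role, gold = gold, text = unname(texts))
    }
    out <- do.call(rbind, rows)
    out$id <- sprintf("t%04d", seq_len(nrow(out)))
    out[, c("id", "country", "role", "gold", "text")]
  })
}

#' Generate a binary-polarity training corpus
#'
#' Emulates a large movie-review-style corpus: texts labeled 0 (negative) or
#' 1 (positive), split into train and validation partitions (default 80/20).
#' Class-1 documents draw from the positive lexicon, class-0 from the
#' negative one.
#'
#' @param n total number of reviews (>= 2).
#' @param balance fraction of class-1 documents, in (0, 1).
#' @param lexicon a [lexicon_config()].
#' @param split_ratio fraction assigned to the training split, in (0, 1).
#' @return tibble with columns `text`, `label` (0/1), `split`
#'   (`"train"`/`"validation"`).
#' @export
generate_binary_corpus <- function(n, balance = 0.5,
                                   lexicon = lexicon_config(),
                                   split_ratio = 0.8) {
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  if (balance <= 0 || balance >= 1) stop("balance must be in (0, 1)",
                                         call. = FALSE)
  if (split_ratio <= 0 || split_ratio >= 1)
    stop("split_ratio must be in (0, 1)", call. = FALSE)
  n <- as.integer(n)
  n_pos <- as.integer(round(n * balance))
  n_pos <- max(1L, min(n - 1L, n_pos))
  with_seed(lexicon$seed + 1L, {
    label <- sample(rep(c(1L, 0L), times = c(n_pos, n - n_pos)))
    texts <- vapply(ifelse(label == 1L, "positive", "negative"),
                    draw_document, character(1), lexicon = lexicon)
    n_train <- as.integer(round(n * split_ratio))
    split <- rep("validation", n)
    split[sample.int(n, n_train)] <- "train"
    tibble::tibble(text = unname(texts), label = label, split = split)
  })
}

#' Write / read corpora as UTF-8 CSV
#'
#' Survey corpora use the header `id,country,role,gold,text`; binary corpora
#' use `text,label,split`.
#'
#' @param corpus tibble as produced by the generators.
#' @param path file path.
#' @return `path` (write) or a tibble (read).
#' @export
write_corpus_csv <- function(corpus, path) {
  utils::write.csv(corpus, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_corpus_csv
#' @export
read_corpus_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    fileEncoding = "UTF-8"))
}

#' Read a strata configuration from YAML
#'
#' Expects a list of maps with keys `country`, `role`, `n_negative`,
#' `n_neutral`, `n_positive`.
#'
#' @param path YAML file path.
#' @return list of [stratum_spec()].
#' @export
read_strata_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(s) stratum_spec(s$country, s$role, s$n_negative,
                                       s$n_neutral, s$n_positive))
}
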