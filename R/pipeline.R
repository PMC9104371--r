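#' Pipeline run configuration
#'
#' Bundles every stage's settings with one global seed that fans out
#' deterministically into per-stage seeds (generation, training,
#' calibration, layout). Referenced files are checked at construction, so a
#' bad path fails before any stage runs.
#'
#' @param out_dir run directory; created by [run_pipeline()].
#' @param strata survey strata, default the study cells ([default_strata()]).
#' @param lexicon a [lexicon_config()]; its seed is overridden by the fanned
#'   out stage seed.
#' @param model `"mlp"` or `"svm"` scorer.
#' @param binary_n,binary_balance,split_ratio binary training-corpus size,
#'   class-1 fraction and train fraction (defaults 2000, 0.5, 0.8).
#' @param mlp,svr scorer configurations ([mlp_config()], [svr_config()]).
#' @param calibration a [calibration_config()].
#' @param embedding_dim,polarity_axis hash-provider settings.
#' @param stopwords_path stop-word file for the word-cloud stage; default is
#'   the bundled English list.
#' @param min_count word-cloud frequency threshold (default 20).
#' @param seed global integer seed.
#' @return A `run_config` object.
#' @export
run_config <- function(out_dir, strata = default_strata(),
                       lexicon = lexicon_config(), model = c("mlp", "svm"),
                       binary_n = 2000, binary_balance = 0.5,
                       split_ratio = 0.8, mlp = mlp_config(),
                       svr = svr_config(),
                       calibration = calibration_config(),
                       embedding_dim = 20, polarity_axis = 1,
                       stopwords_path = system.file("extdata",
                                                    "stopwords_en.txt",
                                                    package = "sentitri"),
                       min_count = 20, seed = 1) {
  model <- match.arg(model)
  if (!file.exists(stopwords_path)) {
    stop("stopwords_path does not exist: ", stopwords_path, call. = FALSE)
  }
  structure(list(out_dir = out_dir, strata = strata, lexicon = lexicon,
                 model = model, binary_n = as.integer(binary_n),
                 binary_balance = binary_balance, split_ratio = split_ratio,
                 mlp = mlp, svr = svr, calibration = calibration,
                 embedding_dim = as.integer(embedding_dim),
                 polarity_axis = as.integer(polarity_axis),
                 stopwords_path = stopwords_path,
                 min_count = as.integer(min_count), seed = as.integer(seed)),
            class = "run_config")
}

stage_log <- function(stage, ...) {
  message(sprintf("[sentitri:%s] %s", stage, sprintf(...)))
}

#' Run the full sentiment-analysis pipeline
#'
#' Orchestrates generate, preprocess, embed, train, score, calibrate,
#' decide, evaluate and word-cloud as one logged run, writing every
#' artifact plus a manifest (config snapshot, stage seeds, package version)
#' into `config$out_dir`. Rerunning with the same configuration reproduces
#' the same predictions bit for bit.
#'
#' @param config a [run_config()].
#' @return Invisibly, a `pipeline_run` list: the corpus, scores,
#'   thresholds, predictions, confusion matrix, metric report,
#'   misclassification report, term table and all artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  seeds <- list(survey = stage_seed(config$seed, 1),
                binary = stage_seed(config$seed, 2),
                train = stage_seed(config$seed, 3),
                calibration = stage_seed(config$seed, 4),
                cloud = stage_seed(config$seed, 5))

  lex_survey <- config$lexicon; lex_survey$seed <- as.integer(seeds$survey)
  corpus <- generate_survey_corpus(config$strata, lex_survey)
  write_corpus_csv(corpus, p("corpus.csv"))
  stage_log("generate", "survey corpus: %d testimonies", nrow(corpus))

  lex_binary <- config$lexicon; lex_binary$seed <- as.integer(seeds$binary)
  binary <- generate_binary_corpus(config$binary_n, config$binary_balance,
                                   lex_binary, config$split_ratio)
  write_corpus_csv(binary, p("binary_corpus.csv"))
  stage_log("generate", "binary corpus: %d reviews (%d train)",
            nrow(binary), sum(binary$split == "train"))

  provider <- hash_provider(config$embedding_dim, seed = config$seed,
                            polarity_axis = config$polarity_axis,
                            lexicon = config$lexicon)
  scorer <- if (config$model == "mlp") {
    cfg <- config$mlp; cfg$seed <- as.integer(seeds$train)
    cfg$input_dim <- config$embedding_dim
    train_mlp(binary, provider, cfg)
  } else {
    cfg <- config$svr; cfg$seed <- as.integer(seeds$train)
    train_svr(binary, provider, cfg)
  }
  stage_log("train", "%s scorer trained on %d documents", config$model,
            sum(binary$split == "train"))

  scores <- score_corpus(corpus, scorer)
  utils::write.csv(scores, p("scores.csv"), row.names = FALSE)
  stage_log("score", "%d testimonies scored", nrow(scores))

  cal <- config$calibration; cal$seed <- as.integer(seeds$calibration)
  thresholds <- calibrate(scores$score, corpus$gold, cal)
  write_thresholds_yaml(thresholds, p("thresholds.yaml"),
                        model = config$model, dataset = "synthetic",
                        config = cal)
  stage_log("calibrate", "thresholds: t_neu_neg = %.3f, t_pos_neu = %.3f",
            thresholds$t_neu_neg, thresholds$t_pos_neu)

  predicted <- decide(scores$score, thresholds)
  predictions <- tibble::tibble(id = corpus$id, gold = corpus$gold,
                                score = scores$score, predicted = predicted)
  utils::write.csv(predictions, p("predictions.csv"), row.names = FALSE)

  cm <- confusion_matrix(predicted, corpus$gold)
  write_confusion_tsv(cm, p("confusion_matrix.tsv"))
  report <- weighted_one_vs_all(cm)
  write_metrics_json(report, p("metrics.json"))
  mis <- misclassification_report(corpus, predicted)
  utils::write.csv(as.data.frame(mis), p("misclassifications.csv"),
                   row.names = FALSE)
  stage_log("evaluate", "accuracy %.2f%%, %d misclassified",
            report$accuracy, nrow(mis))

  stopwords <- read_stopwords(config$stopwords_path)
  terms <- term_frequencies(corpus, stopwords, config$min_count)
  write_term_tsv(terms, p("term_frequencies.tsv"))
  cloud_layout <- NULL
  if (nrow(terms) > 0) {
    cloud_layout <- render_cloud(terms, p("wordcloud.png"),
                                 seed = seeds$cloud)
  }
  stage_log("wordcloud", "%d terms at min_count %d", nrow(terms),
            config$min_count)

  manifest <- list(
    package_version = as.character(utils::packageVersion("sentitri")),
    seed = config$seed, stage_seeds = seeds, model = config$model,
    binary_n = config$binary_n, split_ratio = config$split_ratio,
    polarity_purity = config$lexicon$polarity_purity,
    noise_rate = config$lexicon$noise_rate,
    embedding = provider$name,
    calibration = list(k_folds = cal$k_folds, grid_step = cal$grid_step),
    min_count = config$min_count,
    artifacts = list.files(config$out_dir))
  yaml::write_yaml(manifest, p("manifest.yaml"))

  invisible(structure(list(corpus = corpus, binary = binary, scorer = scorer,
                           scores = scores, thresholds = thresholds,
                           predictions = predictions, confusion = cm,
                           metrics = report, misclassifications = mis,
                           terms = terms, cloud_layout = cloud_layout,
                           out_dir = config$out_dir, manifest = manifest),
                      class = "pipeline_run"))
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d testimonies -> accuracy %.2f%% (dir: %s)\n",
              nrow(x$corpus), x$metrics$accuracy, x$out_dir))
  invisible(x)
}

#' Bundled reference confusion matrices
#'
#' The four published confusion matrices of the reference study (MLP and
#' SVM scorers on the student and staff datasets), transcribed in the
#' rows-predicted/columns-real convention.
#'
#' @return named list of `confusion_matrix3` objects
#'   (`mlp-students`, `mlp-staff`, `svm-students`, `svm-staff`).
#' @export
reference_matrices <- function() {
  tab <- utils::read.delim(system.file("extdata",
                                       "reference_confusion_matrices.tsv",
                                       package = "sentitri"),
                           stringsAsFactors = FALSE)
  out <- list()
  for (key in unique(paste(tab$model, tab$dataset, sep = "-"))) {
    sub <- tab[paste(tab$model, tab$dataset, sep = "-") == key, ]
    sub <- sub[match(SENTIMENT_CLASSES, sub$predicted), ]
    cm <- as.matrix(sub[, SENTIMENT_CLASSES])
    dimnames(cm) <- list(predicted = SENTIMENT_CLASSES,
                         real = SENTIMENT_CLASSES)
    out[[key]] <- structure(cm, class = c("confusion_matrix3", "matrix",
                                          "array"))
  }
  out
}

#' Verify the published reference metrics
#'
#' Recomputes the metric suite from each bundled reference confusion matrix
#' and compares it with the bundled published values. The published table
#' labels its precision and recall rows in the opposite of the standard
#' convention for its matrix orientation, so the comparison maps the
#' published "precision" row to support-weighted recall and vice versa; the
#' published accuracy values 88.88 and 72.85 are truncations of 88.889 and
#' 72.857, which the default tolerance absorbs.
#'
#' @param matrices optional named list of 3x3 matrices to verify instead of
#'   the bundled ones (used e.g. for negative controls).
#' @param reference optional data frame of expected values
#'   (`model`, `dataset`, `metric`, `value`) replacing the bundled table.
#' @param tolerance maximum absolute difference in percentage points,
#'   default 0.02.
#' @return A `verification_report` tibble (`model`, `dataset`, `metric`,
#'   `reference`, `computed`, `delta`, `pass`) with attribute `pass`
#'   (all cells within tolerance). Failures are listed by `print()`.
#' @export
verify_reference_metrics <- function(matrices = NULL, reference = NULL,
                                     tolerance = 0.02) {
  if (is.null(matrices)) matrices <- reference_matrices()
  if (is.null(reference)) {
    reference <- utils::read.delim(system.file("extdata",
                                               "reference_metrics.tsv",
                                               package = "sentitri"),
                                   stringsAsFactors = FALSE)
  }
  # published row label -> field of our metric_report (precision/recall
  # swapped relative to standard definitions, see Details)
  field_map <- c(Accuracy = "accuracy", WeightedAccuracy = "weighted_accuracy",
                 WeightedPrecision = "weighted_recall",
                 WeightedRecall = "weighted_precision",
                 WeightedF1 = "weighted_f1")
  rows <- lapply(seq_len(nrow(reference)), function(i) {
    r <- reference[i, ]
    key <- paste(r$model, r$dataset, sep = "-")
    if (is.null(matrices[[key]])) {
      stop("no matrix for dataset ", key, call. = FALSE)
    }
    rep <- weighted_one_vs_all(matrices[[key]])
    computed <- rep[[field_map[[r$metric]]]]
    tibble::tibble(model = r$model, dataset = r$dataset, metric = r$metric,
                   reference = r$value, computed = computed,
                   delta = computed - r$value,
                   pass = abs(round_half_up(computed, 2) - r$value) <=
                     tolerance + 1e-9)
  })
  out <- do.call(rbind, rows)
  structure(out, pass = all(out$pass),
            class = c("verification_report", class(out)))
}

#' @export
print.verification_report <- function(x, ...) {
  ok <- attr(x, "pass")
  cat(sprintf("<verification_report> %d checks, %s\n", nrow(x),
              if (ok) "all within tolerance" else "FAILURES:"))
  if (!ok) {
    bad <- x[!x$pass, ]
    for (i in seq_len(nrow(bad))) {
      cat(sprintf("  %s %s %s: reference %.2f, computed %.4f\n",
                  bad$model[i], bad$dataset[i], bad$metric[i],
                  bad$reference[i], bad$computed[i]))
    }
  }
  invisible(x)
}
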