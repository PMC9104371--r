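#' Configuration for the feed-forward sentiment regressor
#'
#' The network mirrors the study's architecture: an input layer matching the
#' 20-dimensional document embedding, one hidden layer of 16 rectified-linear
#' units, and a single output neuron with hyperbolic-tangent activation so
#' the score lies in \eqn{[-1, 1]}. Binary labels \{0, 1\} are mapped to
#' regression targets \{-1, +1\} and the squared error is minimized by
#' mini-batch stochastic gradient descent with momentum.
#'
#' @param input_dim input dimension (must match the embedding provider).
#' @param hidden_units hidden-layer width (>= 1).
#' @param epochs,learning_rate,momentum,batch_size SGD hyperparameters.
#' @param seed integer seed fixing initialization and batch shuffling.
#' @return An `mlp_config` object.
#' @export
mlp_config <- function(input_dim = 20, hidden_units = 16, epochs = 50,
                       learning_rate = 0.05, momentum = 0.9, batch_size = 32,
                       seed = 1) {
  stopifnot(input_dim >= 1, hidden_units >= 1, epochs >= 1,
            learning_rate > 0, batch_size >= 1)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_units = as.integer(hidden_units),
                 hidden_activation = "relu", output_activation = "tanh",
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "mlp_config")
}

#' Configuration for the support-vector sentiment regressor
#'
#' Epsilon-regression with a radial-basis kernel (via \pkg{e1071}); raw
#' predictions are clipped into \eqn{[-1, 1]}.
#'
#' @param kernel kernel label understood by [e1071::svm()].
#' @param regularization cost parameter C (> 0).
#' @param epsilon epsilon-tube width (>= 0).
#' @param seed integer seed.
#' @return An `svr_config` object.
#' @export
svr_config <- function(kernel = "radial", regularization = 1, epsilon = 0.1,
                       seed = 1) {
  stopifnot(regularization > 0, epsilon >= 0)
  structure(list(kernel = kernel, regularization = regularization,
                 epsilon = epsilon, seed = as.integer(seed)),
            class = "svr_config")
}

check_binary_corpus <- function(corpus) {
  stopifnot(is.data.frame(corpus),
            all(c("text", "label", "split") %in% names(corpus)))
  train <- corpus[corpus$split == "train", ]
  if (nrow(train) == 0) stop("training split is empty", call. = FALSE)
  if (length(unique(train$label)) < 2) {
    stop("training split must contain both labels 0 and 1", call. = FALSE)
  }
  train
}

relu <- function(x) (x > 0) * x

mlp_forward <- function(W, X) {
  Z1 <- sweep(X %*% W$W1, 2, W$b1, `+`)
  H <- relu(Z1)
  o <- tanh(drop(H %*% W$W2) + W$b2)
  list(Z1 = Z1, H = H, o = o)
}

# Mini-batch SGD with momentum on squared error; targets in {-1, +1}.
fit_mlp <- function(X, y, config) {
  d <- ncol(X); h <- config$hidden_units
  with_seed(config$seed, {
    lim1 <- sqrt(6 / (d + h)); lim2 <- sqrt(6 / (h + 1))
    W <- list(W1 = matrix(stats::runif(d * h, -lim1, lim1), d, h),
              b1 = numeric(h),
              W2 = matrix(stats::runif(h, -lim2, lim2), h, 1),
              b2 = 0)
    V <- list(W1 = W$W1 * 0, b1 = W$b1 * 0, W2 = W$W2 * 0, b2 = 0)
    n <- nrow(X); lr <- config$learning_rate; mom <- config$momentum
    for (epoch in seq_len(config$epochs)) {
      idx <- sample.int(n)
      for (start in seq(1, n, by = config$batch_size)) {
        b <- idx[start:min(start + config$batch_size - 1, n)]
        Xb <- X[b, , drop = FALSE]; yb <- y[b]
        fw <- mlp_forward(W, Xb)
        # dL/do for mean squared error, chained through tanh then relu
        delta_o <- (2 / length(b)) * (fw$o - yb) * (1 - fw$o^2)
        gW2 <- crossprod(fw$H, delta_o)
        gb2 <- sum(delta_o)
        delta_h <- (delta_o %*% t(W$W2)) * (fw$Z1 > 0)
        gW1 <- crossprod(Xb, delta_h)
        gb1 <- colSums(delta_h)
        V$W1 <- mom * V$W1 - lr * gW1; W$W1 <- W$W1 + V$W1
        V$b1 <- mom * V$b1 - lr * gb1; W$b1 <- W$b1 + V$b1
        V$W2 <- mom * V$W2 - lr * gW2; W$W2 <- W$W2 + V$W2
        V$b2 <- mom * V$b2 - lr * gb2; W$b2 <- W$b2 + V$b2
      }
    }
    W
  })
}

new_scorer <- function(type, model, provider, config, stopwords) {
  structure(list(type = type, model = model, provider = provider,
                 config = config, stopwords = stopwords),
            class = "sentiment_scorer")
}

#' Train the feed-forward sentiment scorer
#'
#' Embeds the training split of a binary-polarity corpus with the given
#' provider, maps labels \{0, 1\} to targets \{-1, +1\}, and fits the
#' 20-16-1 ReLU/tanh network by seeded mini-batch SGD. The result is a
#' deterministic (given the seed) scorer mapping raw text to a sentiment
#' score in \eqn{[-1, 1]}.
#'
#' @param corpus tibble with columns `text`, `label` (0/1), `split`.
#' @param provider an [embedding_provider()] whose dimension equals
#'   `config$input_dim`.
#' @param config an [mlp_config()].
#' @param stopwords stop words removed before embedding (default none).
#' @return A `sentiment_scorer`; use [predict()][predict.sentiment_scorer]
#'   or [score_corpus()] to apply it.
#' @export
train_mlp <- function(corpus, provider, config = mlp_config(),
                      stopwords = character()) {
  train <- check_binary_corpus(corpus)
  stopifnot(inherits(provider, "embedding_provider"))
  if (provider$dimension != config$input_dim) {
    stop(sprintf("provider dimension %d does not match input_dim %d",
                 provider$dimension, config$input_dim), call. = FALSE)
  }
  X <- embed_texts(train$text, provider, stopwords)
  y <- 2 * train$label - 1
  new_scorer("mlp", fit_mlp(X, y, config), provider, config, stopwords)
}

#' Train the support-vector sentiment scorer
#'
#' As [train_mlp()] but fits an epsilon-SVR ([e1071::svm()]) on the embedded
#' training split with targets \{-1, +1\}; raw predictions are clipped into
#' \eqn{[-1, 1]}.
#'
#' @inheritParams train_mlp
#' @param config an [svr_config()].
#' @return A `sentiment_scorer`.
#' @export
train_svr <- function(corpus, provider, config = svr_config(),
                      stopwords = character()) {
  train <- check_binary_corpus(corpus)
  stopifnot(inherits(provider, "embedding_provider"))
  X <- embed_texts(train$text, provider, stopwords)
  y <- 2 * train$label - 1
  model <- with_seed(config$seed,
    e1071::svm(x = X, y = y, type = "eps-regression",
               kernel = config$kernel, cost = config$regularization,
               epsilon = config$epsilon, scale = FALSE))
  new_scorer("svr", model, provider, config, stopwords)
}

#' Score raw texts with a trained scorer
#'
#' @param object a `sentiment_scorer`.
#' @param texts character vector of raw texts.
#' @param ... unused.
#' @return numeric vector of sentiment scores, each in \eqn{[-1, 1]}.
#' @export
predict.sentiment_scorer <- function(object, texts, ...) {
  if (length(texts) == 0) return(numeric(0))
  X <- embed_texts(texts, object$provider, object$stopwords)
  raw <- if (object$type == "mlp") {
    mlp_forward(object$model, X)$o
  } else {
    as.numeric(stats::predict(object$model, X))
  }
  pmin(1, pmax(-1, raw))
}

#' Score every testimony of a corpus
#'
#' Order-preserving: one score per testimony, in corpus order.
#'
#' @param testimonies tibble with columns `id` and `text`.
#' @param scorer a trained `sentiment_scorer`.
#' @return tibble with columns `id`, `score`.
#' @export
score_corpus <- function(testimonies, scorer) {
  stopifnot(is.data.frame(testimonies),
            all(c("id", "text") %in% names(testimonies)),
            inherits(scorer, "sentiment_scorer"))
  tibble::tibble(id = testimonies$id,
                 score = predict(scorer, testimonies$text))
}

#' @export
print.sentiment_scorer <- function(x, ...) {
  cat(sprintf("<sentiment_scorer %s over %s (d = %d)>\n", x$type,
              x$provider$name, x$provider$dimension))
  invisible(x)
}
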