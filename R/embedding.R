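#' Embedding provider contract
#'
#' A provider maps any token to a fixed-dimension real vector (total lookup:
#' out-of-vocabulary tokens map to a defined fallback, by default the zero
#' vector). The study consumed a pretrained 20-dimensional Swivel embedding;
#' here that is a contract with two implementations: a deterministic offline
#' hash provider ([hash_provider()]) and a TSV adapter for real pretrained
#' vectors ([tsv_provider()]).
#'
#' @param lookup function `character(1) -> numeric(dimension)`.
#' @param dimension positive integer vector dimension.
#' @param name provider label.
#' @return An `embedding_provider` object.
#' @export
embedding_provider <- function(lookup, dimension, name = "custom") {
  stopifnot(is.function(lookup), dimension >= 1)
  structure(list(lookup = lookup, dimension = as.integer(dimension),
                 name = name),
            class = "embedding_provider")
}

# 32-bit-safe polynomial string hash, mixed with the provider seed.
token_hash <- function(token, seed) {
  h <- 0
  for (b in utf8ToInt(enc2utf8(token))) h <- (h * 31 + b) %% 2147483629
  (h + as.double(seed) * 69621) %% 2147483629
}

#' Deterministic offline embedding provider
#'
#' Assigns each token a reproducible pseudo-random vector seeded from a hash
#' of the token and the provider seed. When `polarity_axis` is set, tokens in
#' the lexicon's positive list receive +1 and tokens in its negative list -1
#' on that coordinate (all other tokens 0 there), so a downstream regressor
#' has a learnable polarity signal without any downloaded asset.
#'
#' @param dimension vector dimension, default 20.
#' @param seed integer seed; same token + seed always gives the same vector.
#' @param polarity_axis optional coordinate index in `1:dimension`.
#' @param lexicon a [lexicon_config()]; required when `polarity_axis` is set.
#' @return An [embedding_provider()].
#' @export
hash_provider <- function(dimension = 20, seed = 1, polarity_axis = NULL,
                          lexicon = NULL) {
  if (dimension < 1) stop("dimension must be >= 1", call. = FALSE)
  if (!is.null(polarity_axis)) {
    if (polarity_axis < 1 || polarity_axis > dimension) {
      stop("polarity_axis out of range", call. = FALSE)
    }
    if (is.null(lexicon)) stop("polarity_axis requires a lexicon",
                               call. = FALSE)
  }
  cache <- new.env(parent = emptyenv())
  lookup <- function(token) {
    if (!is.null(cache[[token]])) return(cache[[token]])
    v <- with_seed(token_hash(token, seed),
                   stats::runif(dimension, -0.5, 0.5))
    if (!is.null(polarity_axis)) {
      v[polarity_axis] <- if (token %in% lexicon$positive_terms) 1
        else if (token %in% lexicon$negative_terms) -1 else 0
    }
    cache[[token]] <- v
    v
  }
  embedding_provider(lookup, dimension,
                     name = sprintf("hash-%dd-seed%d", dimension,
                                    as.integer(seed)))
}

#' Load pretrained embeddings from TSV
#'
#' Adapter for real pretrained vectors. Dialect: one token per line,
#' `token \t v1 \t ... \t vd`, UTF-8, no header. Out-of-vocabulary tokens
#' map to the zero vector.
#'
#' @param path TSV file path.
#' @return An [embedding_provider()].
#' @export
tsv_provider <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8", quote = "")
  dimension <- ncol(tab) - 1L
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1]]
  zero <- numeric(dimension)
  lookup <- function(token) {
    if (token %in% rownames(mat)) as.numeric(mat[token, ]) else zero
  }
  embedding_provider(lookup, dimension, name = basename(path))
}

#' Mean-pooled document vector
#'
#' The document representation is the arithmetic mean of its token vectors
#' (hence permutation-invariant); an empty token stream maps to the zero
#' vector.
#'
#' @param tokens a `token_stream` from [preprocess()] or a character vector.
#' @param provider an [embedding_provider()].
#' @return numeric vector of length `provider$dimension`.
#' @export
embed_document <- function(tokens, provider) {
  stopifnot(inherits(provider, "embedding_provider"))
  if (inherits(tokens, "token_stream")) tokens <- tokens$tokens
  if (length(tokens) == 0) return(numeric(provider$dimension))
  mat <- vapply(tokens, provider$lookup, numeric(provider$dimension))
  rowMeans(mat)
}

# Embed a whole character vector of raw texts: preprocess then mean-pool.
embed_texts <- function(texts, provider, stopwords = character()) {
  t(vapply(texts, function(tx)
    embed_document(preprocess(tx, stopwords), provider),
    numeric(provider$dimension), USE.NAMES = FALSE))
}

#' @export
print.embedding_provider <- function(x, ...) {
  cat(sprintf("<embedding_provider '%s', dimension %d>\n", x$name,
              x$dimension))
  invisible(x)
}
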