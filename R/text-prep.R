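#' Normalize and tokenize text
#'
#' Lowercases, strips everything that is not a Unicode letter, splits on
#' whitespace, and removes stop words. A total function on strings: empty or
#' all-punctuation input yields an empty stream.
#'
#' @param text a single character string.
#' @param stopwords character vector of tokens to drop (possibly empty);
#'   compared after lowercasing.
#' @param source_id optional identifier carried along with the stream.
#' @return A `token_stream`: list with `tokens` (character vector of
#'   lowercase, whitespace-free tokens) and `source_id`.
#' @export
#' @examples
#' preprocess("The pandemic, the pandemic!", stopwords = "the")$tokens
preprocess <- function(text, stopwords = character(), source_id = NA_character_) {
  stopifnot(is.character(text), length(text) == 1)
  x <- tolower(text)
  x <- gsub("[^\\p{L}\\s]", " ", x, perl = TRUE)
  tokens <- strsplit(trimws(x), "\\s+", perl = TRUE)[[1]]
  tokens <- tokens[nzchar(tokens)]
  tokens <- tokens[!(tokens %in% tolower(stopwords))]
  structure(list(tokens = tokens, source_id = source_id),
            class = "token_stream")
}

#' Apply a pluggable text transform
#'
#' The slot where automatic Spanish-to-English translation sat in the
#' original workflow. The default transform is the identity, so the pipeline
#' runs fully offline; any total string-to-string function can be plugged in.
#' A transform failure is re-thrown as a stage error naming the testimony.
#'
#' @param text a single character string.
#' @param transform a function `character(1) -> character(1)`.
#' @param id optional testimony id used in error messages.
#' @return the transformed string.
#' @export
transform_text <- function(text, transform = identity, id = NULL) {
  stopifnot(is.function(transform))
  out <- tryCatch(transform(text), error = function(e) {
    stop(sprintf("text transform failed%s: %s",
                 if (is.null(id)) "" else paste0(" for testimony ", id),
                 conditionMessage(e)), call. = FALSE)
  })
  if (!is.character(out) || length(out) != 1) {
    stop("text transform must return a single string", call. = FALSE)
  }
  out
}

#' Read a stop-word list
#'
#' Plain-text format: one token per line, `#` starts a comment, blank lines
#' ignored. The package ships a default English list.
#'
#' @param path file path; default is the bundled English list.
#' @return character vector of stop words.
#' @export
read_stopwords <- function(path = system.file("extdata", "stopwords_en.txt",
                                              package = "sentitri")) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(tolower(lines[nzchar(lines)]))
}

#' @export
print.token_stream <- function(x, ...) {
  cat(sprintf("<token_stream %s: %d tokens>\n",
              if (is.na(x$source_id)) "" else x$source_id, length(x$tokens)))
  if (length(x$tokens)) cat(" ", paste(utils::head(x$tokens, 12), collapse = " "),
                            if (length(x$tokens) > 12) "..." else "", "\n")
  invisible(x)
}
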