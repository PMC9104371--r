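#' Frequency-thresholded term table
#'
#' Tokenizes every text with [preprocess()] (so stop words are removed),
#' tallies corpus-wide token counts, and keeps only tokens occurring at
#' least `min_count` times — the study's word clouds used a minimum of 20
#' repetitions. Counts are raw occurrence totals; set `relative = TRUE` for
#' normalized frequencies in an extra column.
#'
#' @param corpus tibble with a `text` column, or a character vector of
#'   texts.
#' @param stopwords stop-word vector (see [read_stopwords()]).
#' @param min_count minimum raw count to keep a token (>= 1), default 20.
#' @param relative also report count / total-token-count?
#' @return A `term_frequency_table` tibble (`token`, `count`, optionally
#'   `frequency`), sorted by decreasing count then token.
#' @export
term_frequencies <- function(corpus, stopwords = character(),
                             min_count = 20, relative = FALSE) {
  if (min_count < 1) stop("min_count must be >= 1", call. = FALSE)
  texts <- if (is.data.frame(corpus)) corpus$text else corpus
  tokens <- unlist(lapply(texts, function(tx) preprocess(tx, stopwords)$tokens),
                   use.names = FALSE)
  total <- length(tokens)
  tab <- table(tokens)
  tab <- tab[tab >= min_count]
  out <- tibble::tibble(token = as.character(if (is.null(names(tab)))
    character(0) else names(tab)), count = as.integer(tab))
  out <- out[order(-out$count, out$token), ]
  if (relative) out$frequency <- if (total > 0) out$count / total else numeric(0)
  structure(out, min_count = min_count, total_tokens = total,
            class = c("term_frequency_table", class(out)))
}

#' Write a term table as two-column TSV
#'
#' @param table a [term_frequencies()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_term_tsv <- function(table, path) {
  utils::write.table(as.data.frame(table)[, c("token", "count")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Axis-aligned box overlap (boxes as x0/x1/y0/y1 rows).
boxes_overlap <- function(b, placed) {
  if (nrow(placed) == 0) return(FALSE)
  any(b[1] < placed[, 2] & b[2] > placed[, 1] &
      b[3] < placed[, 4] & b[4] > placed[, 3])
}

#' Render a word cloud to PNG
#'
#' Font size is directly proportional to the term count (`cex =
#' max_cex * count / max(count)`). Terms are placed largest-first on an
#' Archimedean spiral from the canvas center, skipping positions that would
#' overlap already-placed terms; the per-term starting angle is drawn from a
#' seeded RNG, so the layout is reproducible.
#'
#' @param table a non-empty [term_frequencies()] table.
#' @param out_path PNG output path.
#' @param seed layout seed.
#' @param width,height image size in pixels.
#' @param max_cex character expansion of the most frequent term.
#' @return Invisibly, the layout metadata tibble (`token`, `count`, `cex`,
#'   `x`, `y`, placed flag); also attached to the file as a side table is
#'   not — query the returned object in code.
#' @export
render_cloud <- function(table, out_path, seed = 1, width = 800,
                         height = 600, max_cex = 4) {
  stopifnot(inherits(table, "term_frequency_table") || is.data.frame(table))
  if (nrow(table) == 0) stop("cannot render an empty term table",
                             call. = FALSE)
  tab <- table[order(-table$count, table$token), ]
  cex <- max_cex * tab$count / max(tab$count)
  grDevices::png(out_path, width = width, height = height)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 1), ylim = c(0, 1), asp = NA)
  placed <- matrix(numeric(0), 0, 4)
  layout <- with_seed(seed, {
    pos <- matrix(NA_real_, nrow(tab), 2)
    for (i in seq_len(nrow(tab))) {
      w <- graphics::strwidth(tab$token[i], cex = cex[i]) * 1.1
      h <- graphics::strheight(tab$token[i], cex = cex[i]) * 1.25
      theta <- stats::runif(1, 0, 2 * pi)
      r <- 0
      for (step in 0:400) {
        x <- 0.5 + r * cos(theta)
        y <- 0.5 + r * sin(theta)
        box <- c(x - w / 2, x + w / 2, y - h / 2, y + h / 2)
        inside <- box[1] >= 0 && box[2] <= 1 && box[3] >= 0 && box[4] <= 1
        if (inside && !boxes_overlap(box, placed)) {
          placed <- rbind(placed, box)
          pos[i, ] <- c(x, y)
          break
        }
        theta <- theta + 0.35
        r <- r + 0.004
      }
    }
    pos
  })
  ok <- !is.na(layout[, 1])
  graphics::text(layout[ok, 1], layout[ok, 2], tab$token[ok], cex = cex[ok],
                 col = grDevices::hcl.colors(max(3, nrow(tab)), "Dark 3")[
                   seq_len(nrow(tab))][ok])
  invisible(tibble::tibble(token = tab$token, count = tab$count, cex = cex,
                           x = layout[, 1], y = layout[, 2], placed = ok))
}
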