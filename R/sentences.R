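sentence_delimiters <- function() c("\n", ".", ";", "?", "!")

#' Split a document into sentence windows
#'
#' Splits the text on the five sentence-ending symbols
#' \code{'\\n' '.' ';' '?' '!'}; each delimiter terminates a sentence and
#' remains the final character (and, if non-whitespace, the final token) of
#' its window, so offsets are preserved and a delimiter can never start a
#' mention. Fragments that are blank apart from the delimiter are dropped.
#' Gold mentions fully inside a window are re-expressed as inclusive token
#' ranges; mentions crossing a window boundary or not aligned to token
#' boundaries are excluded from that window's supervision, counted, and
#' reported through a warning, never silently dropped.
#'
#' @param doc A \code{brat_document}.
#' @param tokenizer Tokenizer function (see \code{\link{basic_tokenizer}}).
#' @return List of \code{sentence_window} objects, in document order, with
#'   attributes \code{n_cross_boundary} and \code{n_misaligned}.
#' @export
split_sentences <- function(doc, tokenizer = basic_tokenizer()) {
  text <- doc$text
  n <- nchar(text)
  windows <- list()
  n_cross <- 0L
  n_misaligned <- 0L
  if (n > 0L) {
    dpos <- gregexpr("[\n.;?!]", text)[[1L]]
    dpos <- if (dpos[1L] == -1L) integer() else as.integer(dpos)
    seg_start <- c(0L, dpos)                   # 0-based inclusive
    seg_end <- c(dpos, n)                      # 0-based exclusive
    for (k in seq_along(seg_start)) {
      a <- seg_start[k]
      b <- seg_end[k]
      if (a >= b) next
      seg_text <- slice_chars(text, a, b)
      # content excluding the terminating delimiter must be non-blank
      has_delim <- k <= length(dpos)
      content <- if (has_delim) substr(seg_text, 1L, nchar(seg_text) - 1L) else seg_text
      if (!nzchar(trimws(content))) next
      tk <- tokenize_and_align(seg_text, tokenizer)
      if (nrow(tk) == 0L) next
      win <- structure(
        list(
          doc_id = doc$doc_id,
          char_start = a, char_end = b,
          tokens = tk$token,
          token_starts = tk$start + a,   # document coordinates
          token_ends = tk$end + a,
          gold = data.frame(type_label = character(), token_start = integer(),
                            token_end = integer(), char_start = integer(),
                            char_end = integer(), stringsAsFactors = FALSE)
        ),
        class = "sentence_window"
      )
      windows[[length(windows) + 1L]] <- win
    }
  }
  # project gold mentions onto windows
  m <- doc$mentions
  if (nrow(m)) {
    bounds <- vapply(windows, function(w) c(w$char_start, w$char_end), numeric(2))
    for (i in seq_len(nrow(m))) {
      hit <- which(bounds[1L, ] <= m$char_start[i] & m$char_end[i] <= bounds[2L, ])
      if (length(hit) != 1L) {
        n_cross <- n_cross + 1L
        next
      }
      w <- windows[[hit]]
      ts <- which(w$token_starts == m$char_start[i])
      te <- which(w$token_ends == m$char_end[i])
      if (length(ts) != 1L || length(te) != 1L || ts > te) {
        n_misaligned <- n_misaligned + 1L
        next
      }
      windows[[hit]]$gold <- rbind(
        w$gold,
        data.frame(type_label = m$type_label[i], token_start = ts,
                   token_end = te, char_start = m$char_start[i],
                   char_end = m$char_end[i], stringsAsFactors = FALSE)
      )
    }
  }
  if (n_cross > 0L) {
    warning(sprintf("document '%s': %d gold mention(s) cross a sentence boundary and were excluded from supervision",
                    doc$doc_id, n_cross), call. = FALSE)
  }
  if (n_misaligned > 0L) {
    warning(sprintf("document '%s': %d gold mention(s) not aligned to token boundaries were excluded from supervision",
                    doc$doc_id, n_misaligned), call. = FALSE)
  }
  attr(windows, "n_cross_boundary") <- n_cross
  attr(windows, "n_misaligned") <- n_misaligned
  windows
}

#' @export
print.sentence_window <- function(x, ...) {
  cat(sprintf("<sentence_window %s[%d,%d): %d tokens, %d gold mentions>\n",
              x$doc_id, x$char_start, x$char_end, length(x$tokens), nrow(x$gold)))
  invisible(x)
}

#' Export sentence windows in CoNLL column format
#'
#' One \code{token<TAB>tag} line per token with BIO tags derived from the
#' window's gold mentions, blank line between sentences.
#'
#' @param windows List of \code{sentence_window}s.
#' @return Character scalar with the CoNLL-formatted content.
#' @export
write_conll <- function(windows) {
  blocks <- vapply(windows, function(w) {
    tags <- rep("O", length(w$tokens))
    for (i in seq_len(nrow(w$gold))) {
      rng <- w$gold$token_start[i]:w$gold$token_end[i]
      tags[rng] <- paste0("I-", w$gold$type_label[i])
      tags[rng[1L]] <- paste0("B-", w$gold$type_label[i])
    }
    paste(paste(w$tokens, tags, sep = "\t"), collapse = "\n")
  }, "")
  paste0(paste(blocks, collapse = "\n\n"), "\n")
}
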