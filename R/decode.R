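# Convert boundary probability tables into entity mentions.

#' Extract start/end index sets from boundary scores
#'
#' A position enters \code{I_start} iff its class-1 ("is a start")
#' probability strictly exceeds its class-0 probability in \code{P_start};
#' likewise for \code{I_end}. An exact tie is treated as negative. Only
#' scored positions are eligible — special/query positions can never be
#' extracted.
#'
#' @param scores A \code{boundary_scores}.
#' @return An \code{index_sets} object: list with ordered integer vectors
#'   \code{I_start} and \code{I_end} (row positions).
#' @export
extract_indices <- function(scores) {
  sp <- scores$scored_positions
  is_ <- sp[scores$P_start[sp, 2L] > scores$P_start[sp, 1L]]
  ie_ <- sp[scores$P_end[sp, 2L] > scores$P_end[sp, 1L]]
  structure(list(I_start = sort(is_), I_end = sort(ie_)), class = "index_sets")
}

#' Pair start and end indices into spans
#'
#' Nearest-end greedy matching: starts are scanned in order; each start
#' pairs with the smallest unused end at or after it that precedes the next
#' start (when there is one). Unmatched boundaries are dropped and counted.
#' The output spans are non-overlapping and ordered; their count is at most
#' \code{min(|I_start|, |I_end|)}.
#'
#' @param idx An \code{index_sets} (or list with \code{I_start},
#'   \code{I_end}).
#' @return Data frame with columns \code{token_start}, \code{token_end}
#'   (inclusive positions) and attributes \code{n_unmatched_starts},
#'   \code{n_unmatched_ends}.
#' @export
pair_spans <- function(idx) {
  starts <- sort(idx$I_start)
  ends <- sort(idx$I_end)
  used <- rep(FALSE, length(ends))
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(starts)) {
    s <- starts[i]
    lim <- if (i < length(starts)) starts[i + 1L] else Inf
    cand <- which(!used & ends >= s & ends < lim)
    if (length(cand)) {
      j <- cand[1L]
      used[j] <- TRUE
      out_s <- c(out_s, s)
      out_e <- c(out_e, ends[j])
    }
  }
  res <- data.frame(token_start = out_s, token_end = out_e)
  attr(res, "n_unmatched_starts") <- length(starts) - nrow(res)
  attr(res, "n_unmatched_ends") <- length(ends) - nrow(res)
  res
}

#' Map token spans back to document-coordinate mentions
#'
#' Converts spans over score rows into character-offset mentions using the
#' window's token/character alignment: the mention starts at its first
#' token's start offset and ends at its last token's end offset, in document
#' coordinates. The diagnostic \code{score} is the product of the two
#' boundary class-1 probabilities when scores are supplied.
#'
#' @param spans Data frame from \code{\link{pair_spans}} (positions in score
#'   rows).
#' @param window The \code{sentence_window} the scores came from.
#' @param type_label Entity type to attach.
#' @param context_map Integer vector mapping score rows to window token
#'   indices (from the scores' \code{context_map} attribute); identity if
#'   \code{NULL}.
#' @param scores Optional \code{boundary_scores} for the diagnostic score.
#' @return Data frame with columns \code{doc_id}, \code{type_label},
#'   \code{char_start}, \code{char_end}, \code{token_start},
#'   \code{token_end}, \code{score}.
#' @export
spans_to_mentions <- function(spans, window, type_label, context_map = NULL,
                              scores = NULL) {
  n <- nrow(spans)
  empty <- data.frame(doc_id = character(), type_label = character(),
                      char_start = integer(), char_end = integer(),
                      token_start = integer(), token_end = integer(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  to_tok <- function(pos) {
    tk <- if (is.null(context_map)) pos else context_map[pos]
    if (anyNA(tk) || any(tk < 1L) || any(tk > length(window$tokens))) {
      defner_error("span position outside the window token range",
                   "defner_decode_error")
    }
    tk
  }
  ts <- to_tok(spans$token_start)
  te <- to_tok(spans$token_end)
  sc <- if (is.null(scores)) rep(NA_real_, n) else
    scores$P_start[spans$token_start, 2L] * scores$P_end[spans$token_end, 2L]
  data.frame(
    doc_id = window$doc_id, type_label = type_label,
    char_start = window$token_starts[ts], char_end = window$token_ends[te],
    token_start = ts, token_end = te, score = sc, stringsAsFactors = FALSE
  )
}

# Decode a full per-type score list for one window into a mention table.
decode_window <- function(per_type_scores, window) {
  rows <- lapply(names(per_type_scores), function(t) {
    sc <- per_type_scores[[t]]
    spans <- pair_spans(extract_indices(sc))
    spans_to_mentions(spans, window, t, attr(sc, "context_map"), sc)
  })
  do.call(rbind, rows)
}
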