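# Machine-reading-comprehension formulation: the entity type's definition
# text is the query; query and sentence are packed into one sequence and a
# per-type boundary head predicts answer spans.

#' Pack a (query, sentence) pair for the MRC model
#'
#' Builds the packed input \code{[CLS] query [SEP] context [SEP]} with
#' segment ids 0 over the query part and 1 over the context part. The
#' special-token mask is true at \code{[CLS]}, every query token and both
#' \code{[SEP]}s; only context positions are eligible answer positions.
#' When the packed length exceeds \code{max_len} the context tail is
#' truncated (never the query) and the final \code{[SEP]} kept.
#'
#' @param query A \code{query_spec}.
#' @param window A \code{sentence_window}.
#' @param vocab Vocabulary for id lookup.
#' @param max_len Maximum packed length (default 250).
#' @return An object of class \code{packed_input}: list with \code{ids},
#'   \code{segments}, \code{special_mask}, \code{context_map} (packed index
#'   -> window token index, NA at specials), \code{scored_positions},
#'   \code{n_truncated}.
#' @export
pack_mrc_input <- function(query, window, vocab, max_len = 250L) {
  n_ctx <- length(window$tokens)
  if (n_ctx == 0L) defner_error("sentence window has no tokens", "defner_empty_context")
  q_ids <- tokens_to_ids(query$tokens, vocab)
  budget <- max_len - (length(q_ids) + 3L)   # [CLS], two [SEP]
  if (budget < 1L) {
    defner_error("query alone exceeds the maximum packed length",
                 "defner_truncation_error")
  }
  n_keep <- min(n_ctx, budget)
  c_ids <- tokens_to_ids(window$tokens[seq_len(n_keep)], vocab)
  cls <- unname(vocab[["[CLS]"]]); sep <- unname(vocab[["[SEP]"]])
  ids <- c(cls, q_ids, sep, c_ids, sep)
  s <- length(ids)
  qlen <- length(q_ids)
  segments <- c(rep(0L, qlen + 2L), rep(1L, n_keep + 1L))
  special <- rep(TRUE, s)
  ctx_rows <- (qlen + 3L):(qlen + 2L + n_keep)
  special[ctx_rows] <- FALSE
  context_map <- rep(NA_integer_, s)
  context_map[ctx_rows] <- seq_len(n_keep)
  structure(
    list(ids = ids, segments = segments, special_mask = special,
         context_map = context_map, scored_positions = ctx_rows,
         n_truncated = n_ctx - n_keep),
    class = "packed_input"
  )
}

#' One MRC forward pass per entity type
#'
#' Packs the window with each type's query, encodes each packed sequence,
#' and applies that type's separate boundary head: four packed inputs, four
#' encoder passes, four score tables.
#'
#' @param window A \code{sentence_window}.
#' @param queries Named list of \code{query_spec}s, one per entity type.
#' @param encoder A contextual encoder.
#' @param heads Named list of \code{boundary_head}s (width \code{d}), one
#'   per entity type.
#' @param max_len Maximum packed length (default 250).
#' @return Named list of \code{boundary_scores}, one per type, each with a
#'   \code{packed} attribute holding its \code{packed_input}.
#' @export
mrc_forward <- function(window, queries, encoder, heads, max_len = 250L) {
  types <- names(queries)
  if (is.null(types) || !setequal(intersect(types, names(heads)), types)) {
    defner_error("queries and heads must be named lists covering the same types",
                 "defner_config_error")
  }
  out <- lapply(types, function(t) {
    pk <- pack_mrc_input(queries[[t]], window, encoder$vocab, max_len)
    H <- encode(encoder, pk$ids, pk$segments)$H
    sc <- boundary_probs(H, heads[[t]], pk$scored_positions, pk$context_map)
    attr(sc, "packed") <- pk
    sc
  })
  names(out) <- types
  out
}
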