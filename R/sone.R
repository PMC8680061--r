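# Span-level one-pass formulation: the sentence is encoded once and each
# entity type's fixed-dimension definition vector is concatenated to every
# token representation before that type's boundary predictor.

#' Concatenate a definition vector to every token representation
#'
#' Builds the definition-augmented input \code{[Z, E]} where \code{E} is the
#' definition vector \code{e} copied to all \code{n} rows: row i is
#' \code{c(Z[i, ], e)}.
#'
#' @param Z Numeric matrix of token representations (n x d).
#' @param e A \code{definition_vector}, a bare numeric vector of length
#'   \code{d_e}, or \code{NULL}/length-0 for the no-definition ablation
#'   (returns \code{Z} unchanged).
#' @return An \code{n x (d + d_e)} matrix of class
#'   \code{augmented_representation}.
#' @export
augment_with_definition <- function(Z, e) {
  if (inherits(e, "definition_vector")) e <- e$vector
  if (is.null(e) || length(e) == 0L) {
    return(structure(Z, class = c("augmented_representation", class(Z))))
  }
  if (!is.numeric(e) || !is.null(dim(e))) {
    defner_error("definition must be a plain numeric vector", "defner_shape_error")
  }
  out <- cbind(Z, matrix(e, nrow(Z), length(e), byrow = TRUE))
  structure(out, class = c("augmented_representation", "matrix", "array"))
}

# Pack [CLS] X [SEP] for the one-pass model (single segment).
pack_sone_input <- function(window, vocab, max_len = 230L) {
  n_ctx <- length(window$tokens)
  if (n_ctx == 0L) defner_error("sentence window has no tokens", "defner_empty_context")
  budget <- max_len - 2L
  n_keep <- min(n_ctx, budget)
  cls <- unname(vocab[["[CLS]"]]); sep <- unname(vocab[["[SEP]"]])
  ids <- c(cls, tokens_to_ids(window$tokens[seq_len(n_keep)], vocab), sep)
  ctx_rows <- 2L:(n_keep + 1L)
  context_map <- rep(NA_integer_, length(ids))
  context_map[ctx_rows] <- seq_len(n_keep)
  structure(
    list(ids = ids, segments = rep(0L, length(ids)),
         special_mask = is.na(context_map), context_map = context_map,
         scored_positions = ctx_rows, n_truncated = n_ctx - n_keep),
    class = "packed_input"
  )
}

#' One-pass forward over all entity types
#'
#' Encodes the sentence exactly once, then for each entity type concatenates
#' that type's definition vector to every token row and applies the type's
#' boundary head (same structure, different parameters). The single encoder
#' pass per window is observable via \code{\link{encoder_call_count}}.
#'
#' @param window A \code{sentence_window}.
#' @param definition_vectors Named list of \code{definition_vector}s (or bare
#'   numeric vectors), one per entity type; \code{NULL} for the
#'   no-definition ablation (heads must then have width \code{d}).
#' @param encoder A contextual encoder.
#' @param heads Named list of \code{boundary_head}s of width \code{d + d_e}.
#' @param max_len Maximum packed length (default 230).
#' @return Named list of \code{boundary_scores}, one per type; scores are
#'   indexed over the \code{n} context tokens (identity \code{context_map}).
#' @export
sone_forward <- function(window, definition_vectors, encoder, heads,
                         max_len = 230L) {
  types <- names(heads)
  if (is.null(types)) {
    defner_error("heads must be a named list (one per entity type)",
                 "defner_config_error")
  }
  if (!is.null(definition_vectors) && !all(types %in% names(definition_vectors))) {
    defner_error("missing definition vector for at least one entity type",
                 "defner_config_error")
  }
  pk <- pack_sone_input(window, encoder$vocab, max_len)
  H <- encode(encoder, pk$ids, pk$segments)$H
  Z <- H[pk$scored_positions, , drop = FALSE]
  n <- nrow(Z)
  out <- lapply(types, function(t) {
    e <- if (is.null(definition_vectors)) NULL else definition_vectors[[t]]
    ZA <- augment_with_definition(Z, e)
    sc <- boundary_probs(unclass(ZA), heads[[t]], seq_len(n), seq_len(n))
    attr(sc, "packed") <- pk
    sc
  })
  names(out) <- types
  out
}

#' Joint one-pass loss over entity types
#'
#' \code{L_start} (resp. \code{L_end}) is the sum over the entity types of
#' that type's mean per-position start (resp. end) cross-entropy, and
#' \code{L = L_start + L_end}.
#'
#' @param per_type_scores Named list of \code{boundary_scores}.
#' @param per_type_gold Named list; for each type a list with integer
#'   vectors \code{starts} and \code{ends} (positions whose target class is
#'   1). Missing types contribute all-negative targets.
#' @return A \code{loss_report}.
#' @export
sone_loss <- function(per_type_scores, per_type_gold = list()) {
  ls <- 0; le <- 0
  for (t in names(per_type_scores)) {
    g <- per_type_gold[[t]] %||% list(starts = integer(), ends = integer())
    rep_t <- mrc_loss(per_type_scores[[t]], g$starts, g$ends)
    ls <- ls + rep_t$L_start
    le <- le + rep_t$L_end
  }
  structure(list(L_start = ls, L_end = le, L = ls + le), class = "loss_report")
}
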