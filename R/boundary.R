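# Start/end boundary prediction heads shared by both model formulations.

#' Create a boundary head
#'
#' A pair of trainable affine maps from a position's representation to
#' 2-class (is-start, is-end) logits: \code{W_start, b_start, W_end, b_end}.
#'
#' @param d_in Input width (encoder width \code{d}, or \code{d + d_e} for
#'   definition-augmented inputs).
#' @param seed Initialisation seed.
#' @return An object of class \code{boundary_head}.
#' @export
boundary_head <- function(d_in, seed = 1L) {
  with_seed(seed, {
    structure(
      list(W_start = matrix(stats::rnorm(d_in * 2L, sd = 0.05), d_in, 2L),
           b_start = matrix(0, 1L, 2L),
           W_end = matrix(stats::rnorm(d_in * 2L, sd = 0.05), d_in, 2L),
           b_end = matrix(0, 1L, 2L),
           d_in = d_in),
      class = "boundary_head"
    )
  })
}

#' Per-position start/end boundary probabilities
#'
#' Applies the head's affine maps to every row of \code{H} and takes a
#' softmax over the two classes at each position, yielding the probability
#' tables \code{P_start} and \code{P_end}. Rows at special/query positions
#' are retained in the tables but excluded from \code{scored_positions}, so
#' they can never be extracted as answers.
#'
#' @param H Numeric matrix of per-position representations (s x d_in), or an
#'   \code{encode()} result.
#' @param head A \code{boundary_head}.
#' @param scored_positions Integer row indices eligible as answers (default:
#'   all rows).
#' @param context_map Optional integer vector, length s: for each row the
#'   window token index it represents (NA at special positions).
#' @return An object of class \code{boundary_scores}: list with
#'   \code{P_start}, \code{P_end} (s x 2), \code{scored_positions}, and the
#'   \code{context_map} attribute.
#' @export
boundary_probs <- function(H, head, scored_positions = NULL,
                           context_map = NULL) {
  if (is.list(H)) H <- H$H
  if (ncol(H) != head$d_in) {
    defner_error(sprintf("representation width %d does not match head input width %d",
                         ncol(H), head$d_in),
                 "defner_shape_error")
  }
  logit_s <- sweep(H %*% head$W_start, 2L, head$b_start, `+`)
  logit_e <- sweep(H %*% head$W_end, 2L, head$b_end, `+`)
  if (is.null(scored_positions)) scored_positions <- seq_len(nrow(H))
  sc <- structure(
    list(P_start = softmax_rows(logit_s), P_end = softmax_rows(logit_e),
         scored_positions = as.integer(scored_positions)),
    class = "boundary_scores"
  )
  attr(sc, "context_map") <- context_map
  sc
}

#' @export
print.boundary_scores <- function(x, ...) {
  cat(sprintf("<boundary_scores: %d positions, %d scored>\n",
              nrow(x$P_start), length(x$scored_positions)))
  invisible(x)
}

# Mean 2-class cross-entropy over scored positions for one table.
# gold: integer positions (rows) whose target class is 1 ("is a boundary").
position_ce <- function(P, scored, gold) {
  if (length(gold) && !all(gold %in% scored)) {
    defner_error("gold boundary index falls on a masked (special/query) position",
                 "defner_labeling_error")
  }
  target <- rep(1L, length(scored))            # column index: class 0
  target[scored %in% gold] <- 2L               # class 1
  probs <- P[cbind(scored, target)]
  mean(-log(pmax(probs, 1e-12)))
}

#' Boundary prediction loss
#'
#' The training objective \code{L = L_start + L_end}, where each term is the
#' mean per-position 2-class cross-entropy over the scored positions (special
#' and query positions contribute nothing).
#'
#' @param scores A \code{boundary_scores}.
#' @param gold_starts,gold_ends Integer vectors of positions (row indices)
#'   whose start/end target class is 1. Must lie within
#'   \code{scored_positions}.
#' @return A \code{loss_report}: list with \code{L_start}, \code{L_end},
#'   \code{L = L_start + L_end}.
#' @export
mrc_loss <- function(scores, gold_starts = integer(), gold_ends = integer()) {
  ls <- position_ce(scores$P_start, scores$scored_positions, gold_starts)
  le <- position_ce(scores$P_end, scores$scored_positions, gold_ends)
  structure(list(L_start = ls, L_end = le, L = ls + le), class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("<loss: L=%.6f (start %.6f + end %.6f)>\n", x$L, x$L_start, x$L_end))
  invisible(x)
}
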