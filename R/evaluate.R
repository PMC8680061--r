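# Strict exact-match micro-averaged evaluation, overall and per type.

mention_keys <- function(m) {
  paste(m$doc_id, m$type_label, m$char_start, m$char_end, sep = "\r")
}

#' Strict exact-match TP/FP/FN counts
#'
#' A prediction is a true positive iff a gold mention with identical
#' (document id, type, character start, character end) exists; matching is
#' one-to-one, so duplicate identical predictions are counted once as TP and
#' the extras as FP. Excluded types are removed from both gold and
#' predictions before counting. Type labels match by case-sensitive string
#' equality.
#'
#' @param gold,pred Data frames with columns \code{doc_id},
#'   \code{type_label}, \code{char_start}, \code{char_end}.
#' @param excluded_types Character vector of type labels to drop from both
#'   sides (default \code{"UNCLEAR"}).
#' @return An \code{eval_counts} object: list with \code{overall} (named
#'   vector TP/FP/FN), \code{per_type} (data frame), and
#'   \code{excluded_types}.
#' @export
strict_match_counts <- function(gold, pred, excluded_types = "UNCLEAR") {
  gold <- gold[!(gold$type_label %in% excluded_types), , drop = FALSE]
  pred <- pred[!(pred$type_label %in% excluded_types), , drop = FALSE]
  types <- sort(unique(c(gold$type_label, pred$type_label)))
  per <- lapply(types, function(t) {
    gk <- mention_keys(gold[gold$type_label == t, , drop = FALSE])
    pk <- mention_keys(pred[pred$type_label == t, , drop = FALSE])
    gt <- table(gk); pt <- table(pk)
    keys <- union(names(gt), names(pt))
    ng <- as.integer(gt[keys]); ng[is.na(ng)] <- 0L
    np <- as.integer(pt[keys]); np[is.na(np)] <- 0L
    tp <- sum(pmin(ng, np))
    data.frame(type_label = t, TP = tp, FP = sum(np) - tp, FN = sum(ng) - tp,
               stringsAsFactors = FALSE)
  })
  per <- if (length(per)) do.call(rbind, per) else
    data.frame(type_label = character(), TP = integer(), FP = integer(),
               FN = integer(), stringsAsFactors = FALSE)
  structure(
    list(overall = c(TP = sum(per$TP), FP = sum(per$FP), FN = sum(per$FN)),
         per_type = per, excluded_types = excluded_types),
    class = "eval_counts"
  )
}

#' Precision, recall and F1 from precision/recall or counts
#'
#' \code{f1_score} is the harmonic mean \code{2PR/(P+R)}, with the
#' convention that it is 0 when \code{P + R = 0}.
#'
#' @param precision,recall Numeric scalars in [0, 1].
#' @return Numeric F1 score.
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

prf_from_counts <- function(tp, fp, fn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
  p <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  c(precision = p, recall = r, f1 = f1_score(p, r))
}

#' Micro-averaged precision/recall/F1 report
#'
#' Computes \code{P = TP/(TP+FP)}, \code{R = TP/(TP+FN)} and their harmonic
#' mean, overall and per type, from exact-match counts. Any metric whose
#' denominator is zero is reported as 0.
#'
#' @param counts An \code{eval_counts} from
#'   \code{\link{strict_match_counts}}.
#' @return An \code{eval_report}: list with \code{precision}, \code{recall},
#'   \code{f1}, \code{counts}, \code{per_type} (data frame with counts and
#'   metrics per type), \code{excluded_types}.
#' @export
micro_prf <- function(counts) {
  ov <- prf_from_counts(counts$overall["TP"], counts$overall["FP"],
                        counts$overall["FN"])
  per <- counts$per_type
  if (nrow(per)) {
    met <- t(mapply(prf_from_counts, per$TP, per$FP, per$FN))
    per <- cbind(per, as.data.frame(met))
  } else {
    per <- cbind(per, data.frame(precision = numeric(), recall = numeric(),
                                 f1 = numeric()))
  }
  structure(
    list(precision = unname(ov["precision"]), recall = unname(ov["recall"]),
         f1 = unname(ov["f1"]), counts = counts, per_type = per,
         excluded_types = counts$excluded_types),
    class = "eval_report"
  )
}

#' Per-type and overall evaluation report
#'
#' Convenience wrapper: strict exact-match counts followed by micro-averaged
#' metrics, per included type plus the overall micro aggregate.
#'
#' @inheritParams strict_match_counts
#' @return An \code{eval_report}.
#' @export
per_type_report <- function(gold, pred, excluded_types = "UNCLEAR") {
  micro_prf(strict_match_counts(gold, pred, excluded_types))
}

#' Evaluate predictions against gold documents
#'
#' @param gold_docs List of \code{brat_document}s carrying gold mentions.
#' @param pred Prediction data frame (e.g. from
#'   \code{\link{predict.definition_ner}}).
#' @param excluded_types Types excluded from scoring (default
#'   \code{"UNCLEAR"}).
#' @return An \code{eval_report}.
#' @export
evaluate_ner <- function(gold_docs, pred, excluded_types = "UNCLEAR") {
  per_type_report(gold_mention_table(gold_docs), pred, excluded_types)
}

# Flatten document gold annotations into an evaluation mention table.
gold_mention_table <- function(docs) {
  if (inherits(docs, "brat_document")) docs <- list(docs)
  rows <- lapply(docs, function(d) {
    m <- d$mentions
    if (nrow(m) == 0L) return(NULL)
    data.frame(doc_id = d$doc_id, type_label = m$type_label,
               char_start = m$char_start, char_end = m$char_end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(doc_id = character(), type_label = character(),
                      char_start = integer(), char_end = integer(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  tab <- report_table(x)
  num <- c("precision", "recall", "f1")
  tab[num] <- lapply(tab[num], round, digits = digits)
  cat("Strict exact-match micro-averaged evaluation")
  if (length(x$excluded_types)) {
    cat(sprintf(" (excluding %s)", paste(x$excluded_types, collapse = ", ")))
  }
  cat("\n")
  print(tab, row.names = FALSE)
  invisible(x)
}

# Per-type rows plus a final OVERALL row, unrounded.
report_table <- function(x) {
  per <- x$per_type
  ov <- data.frame(type_label = "OVERALL",
                   TP = unname(x$counts$overall["TP"]),
                   FP = unname(x$counts$overall["FP"]),
                   FN = unname(x$counts$overall["FN"]),
                   precision = x$precision, recall = x$recall, f1 = x$f1,
                   stringsAsFactors = FALSE)
  rbind(per, ov)
}

#' Write an evaluation report to TSV and/or JSON
#'
#' Columns: type, TP, FP, FN, P, R, F1, with a final OVERALL row; metrics
#' rounded to 4 decimal places (round-half-even).
#'
#' @param report An \code{eval_report}.
#' @param tsv,json Output paths (either may be \code{NULL}).
#' @return The report, invisibly.
#' @export
write_eval_report <- function(report, tsv = NULL, json = NULL) {
  tab <- report_table(report)
  num <- c("precision", "recall", "f1")
  tab[num] <- lapply(tab[num], round, digits = 4)
  names(tab) <- c("type", "TP", "FP", "FN", "P", "R", "F1")
  if (!is.null(tsv)) {
    utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(tab, json, dataframe = "rows", auto_unbox = TRUE)
  }
  invisible(report)
}
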