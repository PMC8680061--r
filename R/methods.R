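# S3 methods for fitted models.

#' @export
print.definition_ner <- function(x, ...) {
  cat(sprintf("%s: definition-enhanced span NER (%s formulation)\n",
              x$variant,
              if (x$method == "mrc") "machine reading comprehension"
              else "span-level one-pass"))
  cat(sprintf("  encoder: tiny self-attention, d=%d, %d layers, vocab %d\n",
              x$d, x$encoder$n_layers, length(x$vocab)))
  if (x$method == "sone") {
    cat(sprintf("  definition source: %s (d_e=%d%s)\n",
                x$config$definition_source, x$d_e,
                if (isTRUE(x$config$definition_trainable)) ", trainable" else ""))
  } else {
    cat(sprintf("  query strategy: %s\n", x$config$query_strategy))
  }
  cat(sprintf("  trained %d steps (batch %d, lr %g); final loss %.4f\n",
              x$config$steps, x$config$batch_size, x$config$lr,
              utils::tail(x$loss_history, 1L)))
  invisible(x)
}

#' Predict entity mentions in documents
#'
#' Runs the fitted model over each document: sentences are split, scored by
#' the formulation's forward pass, boundary index sets are extracted
#' (strict class-1 argmax), paired into spans by nearest-end greedy
#' matching, and mapped back to document character offsets.
#'
#' @param object A fitted \code{definition_ner}.
#' @param newdata List of \code{brat_document}s, a single document, or a
#'   \code{synthetic_corpus}. Defaults to the training documents.
#' @param ... Unused.
#' @return Data frame with columns \code{doc_id}, \code{type_label},
#'   \code{char_start}, \code{char_end}, \code{surface}, \code{score}.
#' @export
predict.definition_ner <- function(object, newdata = NULL, ...) {
  docs <- newdata %||% object$train_docs
  if (inherits(docs, "synthetic_corpus")) docs <- docs$documents
  if (inherits(docs, "brat_document")) docs <- list(docs)
  rows <- lapply(docs, function(doc) {
    windows <- suppressWarnings(split_sentences(doc))
    wrows <- lapply(windows, function(w) {
      if (length(w$tokens) == 0L) return(NULL)
      scores <- if (object$method == "mrc") {
        mrc_forward(w, object$queries, object$encoder, object$heads,
                    object$max_len)
      } else {
        sone_forward(w, object$definitions, object$encoder, object$heads,
                     object$max_len)
      }
      decode_window(scores, w)
    })
    out <- do.call(rbind, wrows)
    if (is.null(out) || nrow(out) == 0L) return(NULL)
    out$surface <- mapply(slice_chars, out$char_start, out$char_end,
                          MoreArgs = list(text = doc$text),
                          USE.NAMES = FALSE)
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(doc_id = character(), type_label = character(),
                      char_start = integer(), char_end = integer(),
                      surface = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out[c("doc_id", "type_label", "char_start", "char_end", "surface", "score")]
}

#' Write predictions as BRAT .ann files
#'
#' One \code{.ann} file per predicted document id, plus a JSON-lines
#' diagnostic with per-span scores.
#'
#' @param pred Prediction data frame from
#'   \code{\link{predict.definition_ner}}.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_predictions <- function(pred, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in unique(pred$doc_id)) {
    m <- pred[pred$doc_id == id, , drop = FALSE]
    m <- m[order(m$char_start, m$char_end), , drop = FALSE]
    ann <- sprintf("T%d\t%s %d %d\t%s", seq_len(nrow(m)), m$type_label,
                   m$char_start, m$char_end, m$surface)
    write_text_file(paste0(paste(ann, collapse = "\n"), "\n"),
                    file.path(dir, paste0(id, ".ann")))
  }
  jl <- vapply(seq_len(nrow(pred)), function(i) {
    jsonlite::toJSON(as.list(pred[i, ]), auto_unbox = TRUE)
  }, "")
  writeLines(jl, file.path(dir, "spans.jsonl"), useBytes = TRUE)
  invisible(dir)
}

#' @export
summary.definition_ner <- function(object, newdata = NULL,
                                   excluded_types = "UNCLEAR", ...) {
  docs <- newdata %||% object$train_docs
  pred <- predict(object, docs)
  report <- evaluate_ner(docs, pred, excluded_types)
  structure(list(model = object, report = report,
                 on_training = is.null(newdata)),
            class = "summary.definition_ner")
}

#' @export
print.summary.definition_ner <- function(x, ...) {
  print(x$model)
  cat(if (x$on_training) "\nTraining-set evaluation:\n" else "\nEvaluation:\n")
  print(x$report)
  invisible(x)
}

#' @export
coef.definition_ner <- function(object, ...) {
  out <- lapply(object$heads, unclass)
  if (!is.null(object$definitions)) {
    out$definitions <- lapply(object$definitions, `[[`, "vector")
  }
  out
}

#' @export
plot.definition_ner <- function(x, ...) {
  plot(seq_along(x$loss_history), x$loss_history, type = "l",
       xlab = "optimisation step", ylab = "batch loss (L_start + L_end)",
       main = x$variant, ...)
  invisible(x)
}
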