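# Model fitting: one entry point for both formulations.

variant_name <- function(method, query_strategy, definition_source) {
  if (method == "mrc") {
    if (query_strategy == "guideline") "MRC_guideline" else "MRC_rule"
  } else {
    switch(definition_source,
           none = "SOne", w2v = "SOne_w2v", rule_query = "SOne_rule",
           guideline = "SOne_guideline")
  }
}

head_param_names <- function(t) {
  paste0("head_", t, "_", c("W_start", "b_start", "W_end", "b_end"))
}

heads_from_theta <- function(theta, types, d_in) {
  hs <- lapply(types, function(t) {
    structure(list(W_start = theta[[paste0("head_", t, "_W_start")]],
                   b_start = theta[[paste0("head_", t, "_b_start")]],
                   W_end = theta[[paste0("head_", t, "_W_end")]],
                   b_end = theta[[paste0("head_", t, "_b_end")]],
                   d_in = d_in),
              class = "boundary_head")
  })
  names(hs) <- types
  hs
}

# CE loss and logit gradients for one boundary table.
# Returns list(loss, dlogits) with dlogits dense (s x 2), zero off-scored.
ce_and_grad <- function(logits, scored, gold) {
  s <- nrow(logits)
  P <- softmax_rows(logits[scored, , drop = FALSE])
  target <- rep(1L, length(scored))
  target[scored %in% gold] <- 2L
  k <- length(scored)
  loss <- mean(-log(pmax(P[cbind(seq_len(k), target)], 1e-12)))
  G <- P
  G[cbind(seq_len(k), target)] <- G[cbind(seq_len(k), target)] - 1
  d <- matrix(0, s, 2L)
  d[scored, ] <- G / k
  list(loss = loss, dlogits = d)
}

affine_grads <- function(H, dlogits) {
  list(W = crossprod(H, dlogits), b = colSums(dlogits))
}

#' Fit a definition-enhanced named entity recognizer
#'
#' Trains either formulation on a BRAT corpus with the bundled small
#' trainable encoder:
#' \itemize{
#'   \item \code{method = "mrc"}: each entity type's definition text (the
#'     annotation-guideline sentence or the rule-template question) is
#'     packed with the sentence as \code{[CLS] query [SEP] X [SEP]}; four
#'     separate boundary heads (one per type) share the encoder.
#'   \item \code{method = "sone"}: the sentence is encoded once; each
#'     type's fixed-dimension definition vector (pooled mention embeddings,
#'     an encoded rule query, an encoded guideline, or none) is concatenated
#'     to every token row before that type's boundary head.
#' }
#' The objective is \code{L = L_start + L_end}, per-position 2-class
#' cross-entropy over context positions, minimised with Adam.
#'
#' @param corpus List of \code{brat_document}s or a
#'   \code{synthetic_corpus}.
#' @param method \code{"mrc"} or \code{"sone"}.
#' @param query_strategy Query source for MRC: \code{"guideline"} or
#'   \code{"rule_template"}.
#' @param definition_source Definition source for SOne: \code{"guideline"},
#'   \code{"rule_query"}, \code{"w2v"} or \code{"none"} (ablation).
#' @param embedding_table Word-embedding matrix (rows named by word) for
#'   \code{definition_source = "w2v"}; defaults to the table bundled with a
#'   \code{synthetic_corpus}.
#' @param d Encoder width (default 32).
#' @param n_layers Encoder depth (default 2).
#' @param d_ff Feed-forward width of the encoder blocks (default \code{4 * d}).
#' @param d_e Definition-vector dimension (default 300; ignored for
#'   \code{"none"}, taken from the table for \code{"w2v"}).
#' @param max_len Maximum packed length: defaults to 250 for MRC and 230
#'   for SOne (the MRC budget is larger because it must also hold the
#'   query).
#' @param steps Optimisation steps (default 300).
#' @param batch_size Examples per step (default 20).
#' @param lr Peak Adam learning rate. Default 1e-2, suited to the randomly
#'   initialised small encoder; fine-tuning a pretrained encoder would use
#'   2e-5.
#' @param lr_schedule \code{"cosine"} (default): 5\% linear warmup then
#'   cosine decay to a tenth of the peak rate; or \code{"constant"}.
#' @param definition_trainable Should the per-type definition vectors be
#'   updated jointly with the model? Defaults to \code{TRUE} for the
#'   encoded-query sources and \code{FALSE} for \code{"w2v"}.
#' @param seed Seed controlling initialisation and batch sampling.
#' @param verbose Print the loss every 50 steps?
#' @return An object of class \code{c("mrc_ner"|"sone_ner",
#'   "definition_ner")} with \code{print}, \code{summary}, \code{coef},
#'   \code{predict} and \code{plot} methods.
#' @export
definition_ner <- function(corpus, method = c("mrc", "sone"),
                           query_strategy = c("guideline", "rule_template"),
                           definition_source = c("guideline", "rule_query",
                                                 "w2v", "none"),
                           embedding_table = NULL,
                           d = 32L, n_layers = 2L, d_ff = 4L * d, d_e = 300L,
                           max_len = NULL, steps = 300L, batch_size = 20L,
                           lr = 1e-2, lr_schedule = c("cosine", "constant"),
                           definition_trainable = NULL,
                           seed = 1L, verbose = FALSE) {
  lr_schedule <- match.arg(lr_schedule)
  method <- match.arg(method)
  query_strategy <- match.arg(query_strategy)
  definition_source <- match.arg(definition_source)
  if (inherits(corpus, "synthetic_corpus")) {
    if (is.null(embedding_table)) embedding_table <- corpus$embeddings
    corpus <- corpus$documents
  }
  if (inherits(corpus, "brat_document")) corpus <- list(corpus)
  if (is.null(max_len)) max_len <- if (method == "mrc") 250L else 230L
  types <- entity_types()

  windows <- unlist(lapply(corpus, split_sentences), recursive = FALSE)
  windows <- Filter(function(w) length(w$tokens) > 0L, windows)
  if (length(windows) == 0L) {
    defner_error("corpus yields no sentence windows", "defner_empty_context")
  }

  strategy <- if (method == "mrc") query_strategy
              else if (definition_source == "rule_query") "rule_template"
              else "guideline"
  queries <- lapply(types, function(t) {
    if (strategy == "guideline") guideline_query(t) else rule_template_query(t)
  })
  names(queries) <- types

  vocab <- build_vocab(c(lapply(windows, `[[`, "tokens"),
                         lapply(queries, `[[`, "tokens")))
  encoder <- tiny_encoder(vocab, d = d, n_layers = n_layers, d_ff = d_ff,
                          max_len = max_len, seed = seed)

  defs <- NULL
  if (method == "sone") {
    if (definition_source == "none") {
      d_e <- 0L
    } else if (definition_source == "w2v") {
      if (is.null(embedding_table)) {
        defner_error("definition_source = 'w2v' needs an embedding_table",
                     "defner_config_error")
      }
      d_e <- ncol(embedding_table)
      defs <- lapply(types, function(t) {
        surf <- unlist(lapply(corpus, function(doc) {
          doc$mentions$surface[doc$mentions$type_label == t]
        }), use.names = FALSE)
        if (length(surf) == 0L) {
          return(new_definition_vector(t, "w2v_mentions", numeric(d_e)))
        }
        w2v_definition_vector(surf, embedding_table, t, on_empty = "zero")
      })
    } else {
      defs <- lapply(types, function(t) {
        encoded_definition_vector(queries[[t]], encoder, NULL, d_e)
      })
    }
    if (!is.null(defs)) names(defs) <- types
  }
  if (is.null(definition_trainable)) {
    definition_trainable <- method == "sone" &&
      definition_source %in% c("guideline", "rule_query")
  }

  d_in <- if (method == "mrc") d else d + d_e
  theta <- encoder$env$params
  for (i in seq_along(types)) {
    h <- boundary_head(d_in, seed = seed * 100L + i)
    for (nm in c("W_start", "b_start", "W_end", "b_end")) {
      theta[[paste0("head_", types[i], "_", nm)]] <- h[[nm]]
    }
  }
  if (method == "sone" && definition_trainable && d_e > 0L) {
    for (t in types) theta[[paste0("def_", t)]] <- matrix(defs[[t]]$vector, 1L)
  }
  enc_names <- names(encoder$env$params)

  # Precompute packed inputs and gold boundary positions.
  if (method == "mrc") {
    examples <- list()
    for (w in windows) {
      for (t in types) {
        pk <- pack_mrc_input(queries[[t]], w, vocab, max_len)
        g <- w$gold[w$gold$type_label == t, , drop = FALSE]
        starts <- pk$scored_positions[match(g$token_start, pk$context_map[pk$scored_positions])]
        ends <- pk$scored_positions[match(g$token_end, pk$context_map[pk$scored_positions])]
        keep <- !is.na(starts) & !is.na(ends)
        examples[[length(examples) + 1L]] <-
          list(pk = pk, type = t,
               gold = list(starts = starts[keep], ends = ends[keep]), win = w)
      }
    }
  } else {
    examples <- lapply(windows, function(w) {
      pk <- pack_sone_input(w, vocab, max_len)
      n_keep <- sum(!is.na(pk$context_map))
      gold <- lapply(types, function(t) {
        g <- w$gold[w$gold$type_label == t, , drop = FALSE]
        keep <- g$token_start <= n_keep & g$token_end <= n_keep
        list(starts = g$token_start[keep], ends = g$token_end[keep])
      })
      names(gold) <- types
      list(pk = pk, gold = gold, win = w)
    })
  }

  # Adam state
  mstate <- lapply(theta, function(x) array(0, dim(x)))
  vstate <- lapply(theta, function(x) array(0, dim(x)))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  loss_history <- numeric(steps)

  with_seed(seed + 1L, {
    for (step in seq_len(steps)) {
      encoder$env$params <- theta[enc_names]
      batch <- sample(length(examples), min(batch_size, length(examples)))
      gacc <- lapply(theta, function(x) array(0, dim(x)))
      bl <- 0
      for (bi in batch) {
        ex <- examples[[bi]]
        eo <- encode(encoder, ex$pk$ids, ex$pk$segments, with_cache = TRUE)
        H <- eo$H
        scored <- ex$pk$scored_positions
        if (method == "mrc") {
          t <- ex$type
          hn <- head_param_names(t)
          ls <- ce_and_grad(sweep(H %*% theta[[hn[1L]]], 2L, theta[[hn[2L]]], `+`),
                            scored, ex$gold$starts)
          le <- ce_and_grad(sweep(H %*% theta[[hn[3L]]], 2L, theta[[hn[4L]]], `+`),
                            scored, ex$gold$ends)
          bl <- bl + ls$loss + le$loss
          gs <- affine_grads(H, ls$dlogits); ge <- affine_grads(H, le$dlogits)
          gacc[[hn[1L]]] <- gacc[[hn[1L]]] + gs$W
          gacc[[hn[2L]]] <- gacc[[hn[2L]]] + gs$b
          gacc[[hn[3L]]] <- gacc[[hn[3L]]] + ge$W
          gacc[[hn[4L]]] <- gacc[[hn[4L]]] + ge$b
          dH <- ls$dlogits %*% t(theta[[hn[1L]]]) +
            le$dlogits %*% t(theta[[hn[3L]]])
        } else {
          Z <- H[scored, , drop = FALSE]
          n <- nrow(Z)
          dZ <- matrix(0, n, d)
          for (t in types) {
            e_t <- if (d_e == 0L) NULL else if (definition_trainable)
              as.numeric(theta[[paste0("def_", t)]]) else defs[[t]]$vector
            ZA <- if (is.null(e_t)) Z else
              cbind(Z, matrix(e_t, n, d_e, byrow = TRUE))
            hn <- head_param_names(t)
            ls <- ce_and_grad(sweep(ZA %*% theta[[hn[1L]]], 2L, theta[[hn[2L]]], `+`),
                              seq_len(n), ex$gold[[t]]$starts)
            le <- ce_and_grad(sweep(ZA %*% theta[[hn[3L]]], 2L, theta[[hn[4L]]], `+`),
                              seq_len(n), ex$gold[[t]]$ends)
            bl <- bl + ls$loss + le$loss
            gs <- affine_grads(ZA, ls$dlogits); ge <- affine_grads(ZA, le$dlogits)
            gacc[[hn[1L]]] <- gacc[[hn[1L]]] + gs$W
            gacc[[hn[2L]]] <- gacc[[hn[2L]]] + gs$b
            gacc[[hn[3L]]] <- gacc[[hn[3L]]] + ge$W
            gacc[[hn[4L]]] <- gacc[[hn[4L]]] + ge$b
            dZA <- ls$dlogits %*% t(theta[[hn[1L]]]) +
              le$dlogits %*% t(theta[[hn[3L]]])
            dZ <- dZ + dZA[, seq_len(d), drop = FALSE]
            if (d_e > 0L && definition_trainable) {
              dn <- paste0("def_", t)
              gacc[[dn]] <- gacc[[dn]] +
                matrix(colSums(dZA[, d + seq_len(d_e), drop = FALSE]), 1L)
            }
          }
          dH <- matrix(0, nrow(H), d)
          dH[scored, ] <- dZ
        }
        genc <- encoder_backward(encoder, eo$cache, dH)
        for (nm in enc_names) gacc[[nm]] <- gacc[[nm]] + genc[[nm]]
      }
      nb <- length(batch)
      loss_history[step] <- bl / nb
      lr_t <- if (lr_schedule == "cosine") {
        warm <- max(1L, ceiling(0.05 * steps))
        if (step <= warm) lr * step / warm
        else lr * (0.1 + 0.9 * 0.5 * (1 + cos(pi * (step - warm) / (steps - warm))))
      } else {
        lr
      }
      for (nm in names(theta)) {
        g <- gacc[[nm]] / nb
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g * g
        mhat <- mstate[[nm]] / (1 - b1^step)
        vhat <- vstate[[nm]] / (1 - b2^step)
        theta[[nm]] <- theta[[nm]] - lr_t * mhat / (sqrt(vhat) + eps)
      }
      if (verbose && step %% 50L == 0L) {
        message(sprintf("step %d: loss %.4f", step, loss_history[step]))
      }
    }
  })
  encoder$env$params <- theta[enc_names]
  if (method == "sone" && definition_trainable && d_e > 0L) {
    defs <- lapply(types, function(t) {
      new_definition_vector(t, defs[[t]]$source,
                            as.numeric(theta[[paste0("def_", t)]]))
    })
    names(defs) <- types
  }

  structure(
    list(method = method, variant = variant_name(method, query_strategy,
                                                 definition_source),
         encoder = encoder, heads = heads_from_theta(theta, types, d_in),
         definitions = defs, queries = queries, vocab = vocab,
         d = d, d_e = if (method == "sone") d_e else NA_integer_,
         max_len = max_len, loss_history = loss_history,
         config = list(query_strategy = query_strategy,
                       definition_source = definition_source,
                       steps = steps, batch_size = batch_size, lr = lr,
                       lr_schedule = lr_schedule, seed = seed,
                       definition_trainable = definition_trainable),
         train_docs = corpus, call = match.call()),
    class = c(if (method == "mrc") "mrc_ner" else "sone_ner", "definition_ner")
  )
}
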