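# Contextual-encoder contract and its small trainable implementation.
#
# Both model formulations only assume an encoder that maps (token ids,
# segment ids) to a matrix H of per-position representations; any
# transformer satisfying that contract is admissible. The implementation
# shipped here is a compact 2-layer single-head self-attention encoder with
# residual feed-forward blocks, written with explicit forward caches and an
# analytic backward pass so the whole pipeline is trainable on one CPU.
# There is no dropout, so evaluation-mode determinism is immediate.

special_tokens <- function() c("[PAD]", "[UNK]", "[CLS]", "[SEP]")

#' Build a vocabulary over corpus and query tokens
#'
#' @param tokens Character vector (or list of vectors) of tokens.
#' @return Named integer vector mapping token to id; the four special tokens
#'   \code{[PAD] [UNK] [CLS] [SEP]} occupy ids 1-4.
#' @export
build_vocab <- function(tokens) {
  toks <- unique(unlist(tokens, use.names = FALSE))
  toks <- setdiff(toks, special_tokens())
  v <- seq_len(length(toks) + 4L)
  names(v) <- c(special_tokens(), toks)
  v
}

#' Map tokens to vocabulary ids
#'
#' @param tokens Character vector.
#' @param vocab Vocabulary from \code{\link{build_vocab}}.
#' @return Integer ids; unknown tokens map to \code{[UNK]}.
#' @export
tokens_to_ids <- function(tokens, vocab) {
  ids <- unname(vocab[tokens])
  ids[is.na(ids)] <- unname(vocab[["[UNK]"]])
  as.integer(ids)
}

#' Small trainable self-attention encoder
#'
#' A randomly initialised \code{n_layers}-layer single-head self-attention
#' encoder of width \code{d} with residual position-wise feed-forward blocks
#' and learned token/position/segment embeddings. It exercises exactly the
#' same code paths a pretrained transformer adapter would (packing, masking,
#' per-position heads, gradient flow) at desk scale. Parameters live in an
#' environment so training updates are visible through the object.
#'
#' @param vocab Vocabulary from \code{\link{build_vocab}}.
#' @param d Hidden width (default 32).
#' @param n_layers Number of attention blocks (default 2).
#' @param d_ff Feed-forward width (default \code{2 * d}).
#' @param max_len Maximum packed sequence length the encoder accepts.
#' @param seed Seed for the random initialisation.
#' @return An object of class \code{tiny_encoder}.
#' @export
tiny_encoder <- function(vocab, d = 32L, n_layers = 2L, d_ff = 2L * d,
                         max_len = 256L, seed = 42L) {
  V <- length(vocab)
  init <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.05), nr, nc)
  params <- with_seed(seed, {
    p <- list(tok = init(V, d), pos = init(max_len, d), seg = init(2L, d))
    for (l in seq_len(n_layers)) {
      p[[paste0("l", l, "_Wq")]] <- init(d, d)
      p[[paste0("l", l, "_Wk")]] <- init(d, d)
      p[[paste0("l", l, "_Wv")]] <- init(d, d)
      p[[paste0("l", l, "_Wo")]] <- init(d, d)
      p[[paste0("l", l, "_W1")]] <- init(d, d_ff)
      p[[paste0("l", l, "_b1")]] <- matrix(0, 1L, d_ff)
      p[[paste0("l", l, "_W2")]] <- init(d_ff, d)
      p[[paste0("l", l, "_b2")]] <- matrix(0, 1L, d)
    }
    p
  })
  env <- new.env(parent = emptyenv())
  env$params <- params
  env$calls <- 0L
  structure(
    list(kind = "tiny", vocab = vocab, d = d, n_layers = n_layers,
         d_ff = d_ff, max_len = max_len, seed = seed, env = env),
    class = "tiny_encoder"
  )
}

#' @export
print.tiny_encoder <- function(x, ...) {
  cat(sprintf("<tiny_encoder: d=%d, %d layers, vocab %d, max_len %d>\n",
              x$d, x$n_layers, length(x$vocab), x$max_len))
  invisible(x)
}

#' Number of forward passes an encoder has run
#'
#' @param encoder A \code{tiny_encoder}.
#' @return Integer call count (see \code{\link{reset_encoder_calls}}).
#' @export
encoder_call_count <- function(encoder) encoder$env$calls

#' @rdname encoder_call_count
#' @export
reset_encoder_calls <- function(encoder) {
  encoder$env$calls <- 0L
  invisible(encoder)
}

#' Encode a packed token sequence
#'
#' Forward pass of the encoder. Positions whose id is \code{[PAD]} are
#' excluded from attention (their columns are masked before the row softmax),
#' so padding can never change the representation of real positions.
#'
#' @param encoder A \code{tiny_encoder}.
#' @param ids Integer token ids (length s <= \code{max_len}).
#' @param segments Integer segment ids in \{0, 1\}, length s (default all 0).
#' @param with_cache Keep the intermediate activations needed for
#'   \code{\link{encoder_backward}}?
#' @return List with \code{H} (s x d matrix) and, if requested, \code{cache}.
#' @export
encode <- function(encoder, ids, segments = NULL, with_cache = FALSE) {
  p <- encoder$env$params
  s <- length(ids)
  if (s == 0L) defner_error("empty input sequence", "defner_empty_context")
  if (s > encoder$max_len) {
    defner_error(sprintf("input length %d exceeds encoder max_len %d; truncate upstream",
                         s, encoder$max_len),
                 "defner_truncation_error")
  }
  if (is.null(segments)) segments <- rep(0L, s)
  pad_id <- unname(encoder$vocab[["[PAD]"]])
  real <- ids != pad_id
  X <- p$tok[ids, , drop = FALSE] + p$pos[seq_len(s), , drop = FALSE] +
    p$seg[segments + 1L, , drop = FALSE]
  scale <- 1 / sqrt(encoder$d)
  cache <- if (with_cache) list(ids = ids, segments = segments, real = real,
                                layers = vector("list", encoder$n_layers))
  for (l in seq_len(encoder$n_layers)) {
    Wq <- p[[paste0("l", l, "_Wq")]]; Wk <- p[[paste0("l", l, "_Wk")]]
    Wv <- p[[paste0("l", l, "_Wv")]]; Wo <- p[[paste0("l", l, "_Wo")]]
    W1 <- p[[paste0("l", l, "_W1")]]; b1 <- p[[paste0("l", l, "_b1")]]
    W2 <- p[[paste0("l", l, "_W2")]]; b2 <- p[[paste0("l", l, "_b2")]]
    Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
    S <- tcrossprod(Q, K) * scale
    if (!all(real)) S[, !real] <- -1e30
    A <- softmax_rows(S)
    C <- A %*% V
    O <- C %*% Wo
    X1 <- X + O
    U <- sweep(X1 %*% W1, 2L, b1, `+`)
    Rl <- pmax(U, 0)
    Fo <- sweep(Rl %*% W2, 2L, b2, `+`)
    X2 <- X1 + Fo
    if (with_cache) {
      cache$layers[[l]] <- list(X = X, Q = Q, K = K, V = V, A = A, C = C,
                                X1 = X1, U = U, Rl = Rl)
    }
    X <- X2
  }
  if (!all(is.finite(X))) {
    defner_error("encoder produced non-finite activations", "defner_numeric_error")
  }
  encoder$env$calls <- encoder$env$calls + 1L
  out <- list(H = X)
  if (with_cache) out$cache <- cache
  out
}

# Analytic backward pass. `cache` comes from encode(..., with_cache = TRUE),
# `dH` is the loss gradient w.r.t. the final H. Returns a flat named list of
# gradients matching encoder$env$params.
encoder_backward <- function(encoder, cache, dH) {
  p <- encoder$env$params
  g <- lapply(p, function(m) array(0, dim(m)))
  scale <- 1 / sqrt(encoder$d)
  dX <- dH
  for (l in rev(seq_len(encoder$n_layers))) {
    cl <- cache$layers[[l]]
    W1 <- p[[paste0("l", l, "_W1")]]; W2 <- p[[paste0("l", l, "_W2")]]
    Wq <- p[[paste0("l", l, "_Wq")]]; Wk <- p[[paste0("l", l, "_Wk")]]
    Wv <- p[[paste0("l", l, "_Wv")]]; Wo <- p[[paste0("l", l, "_Wo")]]
    dF <- dX
    g[[paste0("l", l, "_W2")]] <- g[[paste0("l", l, "_W2")]] + crossprod(cl$Rl, dF)
    g[[paste0("l", l, "_b2")]] <- g[[paste0("l", l, "_b2")]] + colSums(dF)
    dU <- (dF %*% t(W2)) * (cl$U > 0)
    g[[paste0("l", l, "_W1")]] <- g[[paste0("l", l, "_W1")]] + crossprod(cl$X1, dU)
    g[[paste0("l", l, "_b1")]] <- g[[paste0("l", l, "_b1")]] + colSums(dU)
    dX1 <- dX + dU %*% t(W1)
    dO <- dX1
    g[[paste0("l", l, "_Wo")]] <- g[[paste0("l", l, "_Wo")]] + crossprod(cl$C, dO)
    dC <- dO %*% t(Wo)
    dA <- tcrossprod(dC, cl$V)
    dV <- crossprod(cl$A, dC)
    dS <- (dA - rowSums(dA * cl$A)) * cl$A
    dQ <- (dS %*% cl$K) * scale
    dK <- (crossprod(dS, cl$Q)) * scale
    g[[paste0("l", l, "_Wq")]] <- g[[paste0("l", l, "_Wq")]] + crossprod(cl$X, dQ)
    g[[paste0("l", l, "_Wk")]] <- g[[paste0("l", l, "_Wk")]] + crossprod(cl$X, dK)
    g[[paste0("l", l, "_Wv")]] <- g[[paste0("l", l, "_Wv")]] + crossprod(cl$X, dV)
    dX <- dX1 + dQ %*% t(Wq) + dK %*% t(Wk) + dV %*% t(Wv)
  }
  ids <- cache$ids
  for (i in seq_along(ids)) {
    g$tok[ids[i], ] <- g$tok[ids[i], ] + dX[i, ]
    g$pos[i, ] <- g$pos[i, ] + dX[i, ]
    g$seg[cache$segments[i] + 1L, ] <- g$seg[cache$segments[i] + 1L, ] + dX[i, ]
  }
  g
}
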