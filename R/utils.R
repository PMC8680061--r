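# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

defner_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "defner_error")))
}

# Row-wise softmax of a numeric matrix, numerically stabilised.
softmax_rows <- function(M) {
  if (!all(is.finite(M))) {
    defner_error("non-finite logits passed to softmax", "defner_numeric_error")
  }
  M <- M - apply(M, 1L, max)
  E <- exp(M)
  E / rowSums(E)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# substr() on 0-based half-open character offsets.
slice_chars <- function(text, start, end) {
  substr(text, start + 1L, end)
}
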