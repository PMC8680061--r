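mrc_fixture <- function(seed = 2L) {
  corpus <- generate_corpus(overfit_spec())
  windows <- unlist(lapply(corpus$documents, split_sentences),
                    recursive = FALSE)
  queries <- lapply(entity_types(), guideline_query)
  names(queries) <- entity_types()
  vocab <- build_vocab(c(lapply(windows, `[[`, "tokens"),
                         lapply(queries, `[[`, "tokens")))
  list(windows = windows, queries = queries, vocab = vocab)
}

test_that("packing places [CLS] query [SEP] context [SEP] with correct masks", {
  fx <- mrc_fixture()
  w <- fx$windows[[1L]]
  q <- rule_template_query("PROTEINAS")   # 10 tokens: ¿ Qué ... ?
  pk <- pack_mrc_input(q, w, fx$vocab)
  n <- length(w$tokens)
  m <- q$token_length
  expect_equal(length(pk$ids), m + n + 3L)
  expect_equal(sum(!pk$special_mask), n)
  # first context position sits right after [CLS], query, [SEP]
  expect_equal(pk$context_map[m + 3L], 1L)
  expect_true(all(pk$segments[seq_len(m + 2L)] == 0L))
  expect_true(all(pk$segments[(m + 3L):(m + n + 3L)] == 1L))
  # an 8-token query with a 10-token context packs to 21 positions
  q8 <- q; q8$tokens <- q$tokens[1:8]
  w10 <- w; w10$tokens <- rep("x", 10L)
  expect_equal(length(pack_mrc_input(q8, w10, fx$vocab)$ids), 21L)
})

test_that("packing round-trips queries and contexts over random pairs", {
  fx <- mrc_fixture()
  rev_vocab <- names(fx$vocab)
  set.seed(8)
  for (rep in 1:200) {
    w <- fx$windows[[sample(length(fx$windows), 1L)]]
    q <- fx$queries[[sample(4L, 1L)]]
    pk <- pack_mrc_input(q, w, fx$vocab)
    toks <- rev_vocab[pk$ids]
    m <- q$token_length
    expect_identical(toks[1L], "[CLS]")
    expect_identical(toks[m + 2L], "[SEP]")
    expect_identical(toks[length(toks)], "[SEP]")
    expect_identical(toks[2:(m + 1L)], q$tokens)
    expect_identical(toks[(m + 3L):(length(toks) - 1L)], w$tokens)
  }
})

test_that("query truncation never happens; context tail truncation is counted", {
  fx <- mrc_fixture()
  w <- fx$windows[[1L]]
  q <- fx$queries$UNCLEAR   # longest query
  pk <- pack_mrc_input(q, w, fx$vocab, max_len = q$token_length + 3L + 2L)
  expect_equal(pk$n_truncated, length(w$tokens) - 2L)
  expect_equal(sum(!is.na(pk$context_map)), 2L)
  expect_error(pack_mrc_input(q, w, fx$vocab, max_len = 10L),
               class = "defner_truncation_error")
  w0 <- w; w0$tokens <- character()
  expect_error(pack_mrc_input(q, w0, fx$vocab), class = "defner_empty_context")
})

test_that("boundary probabilities are per-position 2-way softmaxes", {
  # zero representations and zero parameters: every row is (0.5, 0.5)
  h0 <- boundary_head(4L)
  h0$W_start[] <- 0; h0$b_start[] <- 0; h0$W_end[] <- 0; h0$b_end[] <- 0
  sc0 <- boundary_probs(matrix(0, 6L, 4L), h0)
  expect_true(all(abs(sc0$P_start - 0.5) < 1e-12))
  # a very large class-1 logit saturates to probability 1
  h1 <- h0
  h1$b_start <- matrix(c(0, 50), 1L)
  sc1 <- boundary_probs(matrix(0, 3L, 4L), h1)
  expect_true(all(sc1$P_start[, 2L] > 1 - 1e-12))
  # rows sum to one
  set.seed(5)
  H <- matrix(rnorm(40), 10L, 4L)
  sc <- boundary_probs(H, boundary_head(4L, seed = 9L))
  expect_true(all(abs(rowSums(sc$P_start) - 1) < 1e-6))
  expect_true(all(abs(rowSums(sc$P_end) - 1) < 1e-6))
  expect_error(boundary_probs(matrix(Inf, 2L, 4L), h0),
               class = "defner_numeric_error")
})

test_that("boundary probabilities match a scalar exp/normalize oracle", {
  set.seed(11)
  H <- matrix(rnorm(15 * 6), 15L, 6L)
  head <- boundary_head(6L, seed = 2L)
  sc <- boundary_probs(H, head)
  for (i in seq_len(nrow(H))) {
    z <- as.numeric(H[i, ] %*% head$W_start + head$b_start)
    p <- exp(z) / sum(exp(z))
    expect_lt(max(abs(sc$P_start[i, ] - p)), 1e-10)
    z <- as.numeric(H[i, ] %*% head$W_end + head$b_end)
    p <- exp(z) / sum(exp(z))
    expect_lt(max(abs(sc$P_end[i, ] - p)), 1e-10)
  }
})

test_that("the loss is mean position cross-entropy with exact start/end decomposition", {
  mk_scores <- function(P_start, P_end, scored) {
    structure(list(P_start = P_start, P_end = P_end,
                   scored_positions = scored), class = "boundary_scores")
  }
  # perfect one-hot predictions give zero loss
  P <- matrix(rep(c(1, 0), each = 5L), 5L, 2L)
  P[2L, ] <- c(0, 1)
  rep0 <- mrc_loss(mk_scores(P, P, 1:5), gold_starts = 2L, gold_ends = 2L)
  expect_equal(rep0$L, 0)
  # uniform predictions: each term is ln 2, total 2 ln 2
  U <- matrix(0.5, 7L, 2L)
  rep1 <- mrc_loss(mk_scores(U, U, 1:7), 3L, 5L)
  expect_equal(rep1$L_start, log(2))
  expect_equal(rep1$L, 2 * log(2))
  # random case equals a hand-rolled -log p accumulation
  set.seed(21)
  Ps <- t(apply(matrix(runif(16), 8L), 1L, function(r) r / sum(r)))
  Pe <- t(apply(matrix(runif(16), 8L), 1L, function(r) r / sum(r)))
  scored <- c(2L, 3L, 5L, 7L)
  gs <- c(3L, 7L); ge <- 5L
  got <- mrc_loss(mk_scores(Ps, Pe, scored), gs, ge)
  acc_s <- 0; acc_e <- 0
  for (j in scored) {
    acc_s <- acc_s - log(if (j %in% gs) Ps[j, 2L] else Ps[j, 1L])
    acc_e <- acc_e - log(if (j %in% ge) Pe[j, 2L] else Pe[j, 1L])
  }
  expect_lt(abs(got$L_start - acc_s / 4), 1e-10)
  expect_lt(abs(got$L_end - acc_e / 4), 1e-10)
  expect_identical(got$L, got$L_start + got$L_end)
  # gold on a masked position is a labeling error
  expect_error(mrc_loss(mk_scores(U, U, 3:7), gold_starts = 1L),
               class = "defner_labeling_error")
})

test_that("mrc_forward produces one packed input and score table per type", {
  fx <- mrc_fixture()
  enc <- tiny_encoder(fx$vocab, d = 16L, n_layers = 1L, max_len = 250L, seed = 3L)
  heads <- lapply(1:4, function(i) boundary_head(16L, seed = i))
  names(heads) <- entity_types()
  w <- fx$windows[[2L]]
  reset_encoder_calls(enc)
  out <- mrc_forward(w, fx$queries, enc, heads)
  expect_named(out, entity_types())
  expect_equal(encoder_call_count(enc), 4L)
  for (t in entity_types()) {
    pk <- attr(out[[t]], "packed")
    expect_equal(length(pk$ids),
                 fx$queries[[t]]$token_length + length(w$tokens) + 3L)
  }
})

test_that("swapping two type queries swaps the score tables when heads are tied", {
  fx <- mrc_fixture()
  enc <- tiny_encoder(fx$vocab, d = 16L, n_layers = 1L, max_len = 250L, seed = 3L)
  shared <- boundary_head(16L, seed = 1L)
  heads <- list(NORMALIZABLES = shared, NO_NORMALIZABLES = shared,
                PROTEINAS = shared, UNCLEAR = shared)
  w <- fx$windows[[3L]]
  out1 <- mrc_forward(w, fx$queries, enc, heads)
  q_swapped <- fx$queries
  q_swapped$PROTEINAS <- fx$queries$UNCLEAR
  q_swapped$UNCLEAR <- fx$queries$PROTEINAS
  out2 <- mrc_forward(w, q_swapped, enc, heads)
  expect_equal(out2$PROTEINAS$P_start, out1$UNCLEAR$P_start)
  expect_equal(out2$UNCLEAR$P_end, out1$PROTEINAS$P_end)
})
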