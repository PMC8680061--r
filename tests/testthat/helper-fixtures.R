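# Shared fixture builders: everything is generated in code at test time.

# Dense, short-sentence corpus spec used for desk-scale training runs:
# 4 documents x 5 sentences = 20 sentences, disjoint per-type gazetteers.
overfit_spec <- function(seed = 11L) {
  corpus_spec(
    n_documents = 4L, sentences_per_doc = c(5L, 5L),
    mention_rate = c(NORMALIZABLES = 0.5, NO_NORMALIZABLES = 0.25,
                     PROTEINAS = 0.5, UNCLEAR = 0.25),
    gazetteer_size = 6L, mention_length = c(1L, 2L),
    tokens_min = 5L, tokens_mean = 9, long_sentence_frac = 0,
    filler_vocab_size = 40L, embedding_dim = 25L, seed = seed
  )
}

# Small mixed corpus for plumbing properties (fast to generate).
plumbing_spec <- function(n_documents = 50L, seed = 7L) {
  corpus_spec(
    n_documents = n_documents, sentences_per_doc = c(2L, 5L),
    mention_rate = c(NORMALIZABLES = 0.4, NO_NORMALIZABLES = 0.1,
                     PROTEINAS = 0.3, UNCLEAR = 0.1),
    gazetteer_size = 10L, mention_length = c(1L, 2L),
    tokens_min = 4L, tokens_mean = 10, long_sentence_frac = 0,
    filler_vocab_size = 60L, embedding_dim = 20L, seed = seed
  )
}

first_window <- function(text, ann = "", id = "w") {
  split_sentences(read_brat(text, ann, id))[[1L]]
}

# Oracle-perfect boundary scores for a window: probability 1 on class 1 at
# gold start/end token positions of the given type, probability 1 on class 0
# elsewhere. Indexed over the window's tokens (identity context map).
oracle_scores <- function(window, type_label) {
  n <- length(window$tokens)
  g <- window$gold[window$gold$type_label == type_label, , drop = FALSE]
  mk <- function(pos) {
    P <- matrix(rep(c(1, 0), each = n), n, 2L)
    P[pos, ] <- rep(c(0, 1), each = length(pos))
    P
  }
  sc <- structure(
    list(P_start = mk(g$token_start), P_end = mk(g$token_end),
         scored_positions = seq_len(n)),
    class = "boundary_scores"
  )
  attr(sc, "context_map") <- seq_len(n)
  sc
}

oracle_scores_all_types <- function(window) {
  out <- lapply(entity_types(), oracle_scores, window = window)
  names(out) <- entity_types()
  out
}

# Independent regex oracle for the sentence splitter: non-blank fragments
# after splitting on the five sentence-ending symbols.
oracle_sentence_count <- function(text) {
  frags <- strsplit(text, "[\n.;?!]")[[1L]]
  sum(nzchar(trimws(frags)))
}

random_mention_table <- function(n, n_docs = 20L, types = entity_types()) {
  st <- sample.int(400L, n, replace = TRUE)
  data.frame(
    doc_id = sprintf("d%02d", sample.int(n_docs, n, replace = TRUE)),
    type_label = sample(types, n, replace = TRUE),
    char_start = st,
    char_end = st + sample.int(15L, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}
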