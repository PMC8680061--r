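# Synthetic BRAT corpus generator: multi-sentence pseudo-Spanish clinical
# documents with flat typed mentions planted at exact character offsets,
# plus a matching random word-embedding table. Each entity type draws its
# mentions from its own disjoint gazetteer, so type identity is lexically
# learnable by a small model — which is what makes overfit and recovery
# tests on these corpora meaningful.

#' Specification of a synthetic corpus
#'
#' Defaults emulate the statistical shape of a PharmaCoNER-style clinical
#' corpus: multi-sentence records terminated by the five sentence-ending
#' symbols, per-sentence mention rates echoing the real corpus profile
#' (chemicals most frequent, proteins next, the two rare types floored at
#' 0.01/sentence), and a sentence-length mixture in which about 95% of
#' sentences are short and the remaining 5% exceed 230 tokens.
#'
#' @param n_documents Number of documents.
#' @param sentences_per_doc Integer range \code{c(min, max)}.
#' @param mention_rate Named per-sentence Poisson rates, one per entity type.
#' @param gazetteer_size Words per entity-type gazetteer.
#' @param mention_length Integer range of mention lengths in words.
#' @param tokens_min,tokens_mean Minimum and mean token count of short
#'   sentences (lengths are \code{tokens_min + Poisson}).
#' @param long_sentence_frac Fraction of sentences drawn from
#'   \code{long_sentence_range} instead.
#' @param long_sentence_range Token-count range of long sentences.
#' @param delimiter_weights Named sampling weights over the five
#'   sentence-ending symbols.
#' @param filler_vocab_size Number of non-entity filler words.
#' @param embedding_dim Dimension of the emitted embedding table (default
#'   300).
#' @param seed RNG seed; generation is a pure function of (spec, seed).
#' @return An object of class \code{corpus_spec}.
#' @export
corpus_spec <- function(n_documents = 100L,
                        sentences_per_doc = c(4L, 8L),
                        mention_rate = c(NORMALIZABLES = 0.26,
                                         NO_NORMALIZABLES = 0.01,
                                         PROTEINAS = 0.16,
                                         UNCLEAR = 0.01),
                        gazetteer_size = 25L,
                        mention_length = c(1L, 2L),
                        tokens_min = 4L, tokens_mean = 14,
                        long_sentence_frac = 0.05,
                        long_sentence_range = c(231L, 250L),
                        delimiter_weights = c("\n" = 0.25, "." = 0.45,
                                              ";" = 0.12, "?" = 0.10,
                                              "!" = 0.08),
                        filler_vocab_size = 300L,
                        embedding_dim = 300L,
                        seed = 1L) {
  if (any(mention_rate < 0)) {
    defner_error("mention rates must be non-negative", "defner_generation_error")
  }
  if (!setequal(names(mention_rate), entity_types())) {
    defner_error("mention_rate must be named by the four entity types",
                 "defner_generation_error")
  }
  if (!setequal(names(delimiter_weights), sentence_delimiters())) {
    defner_error("delimiter_weights must cover exactly the five sentence-ending symbols",
                 "defner_generation_error")
  }
  structure(
    list(n_documents = as.integer(n_documents),
         sentences_per_doc = as.integer(sentences_per_doc),
         mention_rate = mention_rate[entity_types()],
         gazetteer_size = as.integer(gazetteer_size),
         mention_length = as.integer(mention_length),
         tokens_min = as.integer(tokens_min), tokens_mean = tokens_mean,
         long_sentence_frac = long_sentence_frac,
         long_sentence_range = as.integer(long_sentence_range),
         delimiter_weights = delimiter_weights,
         filler_vocab_size = as.integer(filler_vocab_size),
         embedding_dim = as.integer(embedding_dim),
         seed = as.integer(seed)),
    class = "corpus_spec"
  )
}

# Uniform draw from an inclusive integer range (safe for a == b, unlike
# sample(a:b, 1)).
sample_range <- function(a, b) {
  if (a >= b) return(a)
  a + sample.int(b - a + 1L, 1L) - 1L
}

# Pseudo-Spanish word maker: 2-4 syllables of onset+vowel(+coda).
make_words <- function(n) {
  onsets <- c("b", "c", "d", "f", "g", "l", "ll", "m", "n", "p", "qu", "r",
              "s", "t", "v", "z", "ch", "tr", "pl", "br", "gr", "cl")
  vowels <- c("a", "e", "i", "o", "u")
  codas <- c("", "", "", "", "n", "s", "r", "l")
  words <- character(0)
  while (length(words) < n) {
    need <- n - length(words)
    batch <- vapply(seq_len(need * 2L), function(i) {
      k <- sample(2:4, 1L)
      paste(vapply(seq_len(k), function(j) {
        paste0(sample(onsets, 1L), sample(vowels, 1L), sample(codas, 1L))
      }, ""), collapse = "")
    }, "")
    words <- unique(c(words, batch))
  }
  words[seq_len(n)]
}

#' Generate a synthetic BRAT corpus
#'
#' Produces documents whose mentions are placed at exact character offsets
#' (the surface/slice invariant holds by construction and is re-validated),
#' together with a random embedding table covering every gazetteer word.
#' Mentions never contain sentence delimiters, so the sentence splitter
#' never bisects a gold span under the default spec.
#'
#' @param spec A \code{corpus_spec}.
#' @return An object of class \code{synthetic_corpus}: list with
#'   \code{documents} (list of \code{brat_document}), \code{embeddings}
#'   (matrix, one row per gazetteer word) and \code{spec}.
#' @export
generate_corpus <- function(spec) {
  max_mlen <- max(spec$mention_length)
  if (sum(spec$mention_rate) * (max_mlen + 1L) > spec$tokens_min) {
    defner_error("infeasible spec: expected mention tokens exceed the shortest sentences",
                 "defner_generation_error")
  }
  with_seed(spec$seed, {
    types <- entity_types()
    active <- types[spec$mention_rate > 0]
    n_gaz_words <- spec$gazetteer_size * length(types)
    pool <- make_words(spec$filler_vocab_size + n_gaz_words)
    gaz <- split(pool[seq_len(n_gaz_words)],
                 rep(types, each = spec$gazetteer_size))
    fillers <- pool[(n_gaz_words + 1L):length(pool)]
    delims <- names(spec$delimiter_weights)

    docs <- lapply(seq_len(spec$n_documents), function(di) {
      n_sent <- sample_range(spec$sentences_per_doc[1L], spec$sentences_per_doc[2L])
      text <- character(0)
      cursor <- 0L
      mrows <- list()
      for (si in seq_len(n_sent)) {
        n_tok <- if (stats::runif(1) < spec$long_sentence_frac) {
          sample_range(spec$long_sentence_range[1L], spec$long_sentence_range[2L])
        } else {
          spec$tokens_min +
            stats::rpois(1L, max(spec$tokens_mean - spec$tokens_min, 0))
        }
        # sample mentions, truncating to what fits in the sentence
        ments <- list()
        for (t in types) {
          k <- stats::rpois(1L, spec$mention_rate[[t]])
          for (j in seq_len(k)) {
            len <- sample_range(spec$mention_length[1L], spec$mention_length[2L])
            ments[[length(ments) + 1L]] <-
              list(type = t, words = sample(gaz[[t]], len, replace = FALSE))
          }
        }
        if (length(ments)) ments <- sample(ments)
        while (length(ments) &&
               sum(vapply(ments, function(m) length(m$words), 0L)) > n_tok) {
          ments <- ments[-length(ments)]
        }
        m_tok <- sum(vapply(ments, function(m) length(m$words), 0L))
        units <- c(ments, as.list(sample(fillers, n_tok - m_tok, replace = TRUE)))
        units <- sample(units)
        # lay the sentence out, tracking character offsets
        toks <- character(0)
        sent_start <- cursor
        pos <- cursor
        for (u in units) {
          if (is.list(u)) {
            surface <- paste(u$words, collapse = " ")
            mrows[[length(mrows) + 1L]] <- data.frame(
              type_label = u$type, char_start = pos,
              char_end = pos + nchar(surface), surface = surface,
              stringsAsFactors = FALSE
            )
            toks <- c(toks, u$words)
            pos <- pos + nchar(surface) + 1L
          } else {
            toks <- c(toks, u)
            pos <- pos + nchar(u) + 1L
          }
        }
        sent <- paste(toks, collapse = " ")
        delim <- sample(delims, 1L, prob = spec$delimiter_weights)
        sep <- if (si < n_sent && delim != "\n") " " else ""
        text <- c(text, paste0(sent, delim, sep))
        cursor <- sent_start + nchar(sent) + nchar(delim) + nchar(sep)
      }
      mentions <- if (length(mrows)) do.call(rbind, mrows) else NULL
      new_document(sprintf("synth%04d", di), paste(text, collapse = ""), mentions)
    })

    emb_words <- unlist(gaz, use.names = FALSE)
    embeddings <- matrix(stats::rnorm(length(emb_words) * spec$embedding_dim,
                                      sd = 0.5),
                         nrow = length(emb_words))
    rownames(embeddings) <- emb_words
    structure(list(documents = docs, embeddings = embeddings, spec = spec),
              class = "synthetic_corpus")
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus: %d documents, %d embedding rows (d_e=%d), seed %d>\n",
              length(x$documents), nrow(x$embeddings), ncol(x$embeddings),
              x$spec$seed))
  invisible(x)
}

#' Corpus summary statistics
#'
#' Record, sentence and per-type mention counts; sentence counts are
#' computed through \code{\link{split_sentences}} so the splitter itself is
#' exercised.
#'
#' @param docs List of \code{brat_document}s (or a \code{synthetic_corpus}).
#' @return One-row data frame: \code{records}, \code{sentences}, then one
#'   column per entity type.
#' @export
corpus_stats <- function(docs) {
  if (inherits(docs, "synthetic_corpus")) docs <- docs$documents
  if (inherits(docs, "brat_document")) docs <- list(docs)
  sentences <- sum(vapply(docs, function(d) length(split_sentences(d)), 0L))
  counts <- vapply(entity_types(), function(t) {
    sum(vapply(docs, function(d) sum(d$mentions$type_label == t), 0L))
  }, 0L)
  cbind(data.frame(records = length(docs), sentences = sentences),
        as.data.frame(as.list(counts)))
}
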