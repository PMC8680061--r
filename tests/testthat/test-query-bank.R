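md5_of_string <- function(x) {
  tf <- withr::local_tempfile()
  con <- file(tf, "wb")
  writeBin(charToRaw(enc2utf8(x)), con)
  close(con)
  unname(tools::md5sum(tf))
}

test_that("guideline query texts are the published definitions, pinned by checksum", {
  expect_equal(
    guideline_query("PROTEINAS")$text,
    "Las menciones de proteínas y genes incluyen péptidos, hormonas peptídicas y anticuerpos."
  )
  expect_equal(
    guideline_query("NORMALIZABLES")$text,
    "Menciones de productos químicos que pueden normalizarse manualmente a un identificador de concepto único."
  )
  pinned <- c(
    NORMALIZABLES = "d130871f3d38c539b538a483de694f72",
    NO_NORMALIZABLES = "1d6f3eb2d55a98a4d68c7e9e814a1932",
    PROTEINAS = "9e943aff26783f3db82a3a16642c3f35",
    UNCLEAR = "f3a27871c7ba51662ed43ee6be2da1bd"
  )
  for (t in entity_types()) {
    expect_equal(md5_of_string(guideline_query(t)$text), unname(pinned[t]),
                 label = paste("guideline checksum for", t))
  }
  expect_error(guideline_query("DRUG"), class = "defner_unknown_type")
})

test_that("rule-template queries instantiate the fixed question frame", {
  expect_equal(rule_template_query("PROTEINAS")$text,
               "¿Qué entidades PROTEINAS se mencionan en el texto?")
  expect_equal(rule_template_query("UNCLEAR")$text,
               "¿Qué entidades UNCLEAR se mencionan en el texto?")
  pinned <- c(
    NORMALIZABLES = "2e72d4e7f171be8a7e2c0628df5f275c",
    NO_NORMALIZABLES = "b6066284d3519865a12a3fcca45b7956",
    PROTEINAS = "7295c0d92d86a509f829545fecdae63d",
    UNCLEAR = "cb69912f32d63a01797435a22ac8396f"
  )
  for (t in entity_types()) {
    expect_equal(md5_of_string(rule_template_query(t)$text), unname(pinned[t]),
                 label = paste("rule-template checksum for", t))
  }
  # the two chemical-type templates differ only in the type token
  a <- rule_template_query("NORMALIZABLES")$text
  b <- rule_template_query("NO_NORMALIZABLES")$text
  expect_equal(sub("No_NORMALIZABLES", "", b, fixed = TRUE),
               sub("NORMALIZABLES", "", a, fixed = TRUE))
  expect_error(rule_template_query("DRUG"), class = "defner_unknown_type")
})

test_that("mention-pooled definition vectors are exact means over in-vocabulary tokens", {
  tab <- matrix(0, 3L, 4L, dimnames = list(c("insulina", "a", "b"), NULL))
  tab["insulina", ] <- c(1, 2, 3, 4)
  tab["a", ] <- c(1, 0, 0, 0)
  tab["b", ] <- c(0, 1, 0, 0)

  v1 <- w2v_definition_vector("insulina", tab, "NORMALIZABLES")
  expect_equal(v1$vector, c(1, 2, 3, 4))

  v2 <- w2v_definition_vector("a b", tab, "NORMALIZABLES")
  expect_equal(v2$vector, c(0.5, 0.5, 0, 0))

  expect_error(w2v_definition_vector("fuera", tab), class = "defner_empty_definition")
  expect_equal(w2v_definition_vector("fuera", tab, on_empty = "zero")$vector,
               rep(0, 4))
})

test_that("mention pooling matches a token-by-token accumulation oracle and is order-invariant", {
  set.seed(42)
  words <- paste0("w", 1:40)
  tab <- matrix(rnorm(40 * 8), 40L, 8L, dimnames = list(words, NULL))
  mentions <- replicate(50, paste(sample(c(words, "oov1", "oov2"),
                                         sample(1:3, 1), replace = TRUE),
                                  collapse = " "))
  got <- w2v_definition_vector(mentions, tab)$vector
  # independent accumulation
  acc <- numeric(8L); n <- 0L
  for (m in mentions) {
    for (tok in strsplit(tolower(m), "\\s+")[[1L]]) {
      if (tok %in% words) { acc <- acc + tab[tok, ]; n <- n + 1L }
    }
  }
  expect_lt(max(abs(got - acc / n)), 1e-12)
  # permutation invariance in mention order
  got2 <- w2v_definition_vector(rev(mentions), tab)$vector
  expect_equal(got2, got)
})

test_that("encoded definition vectors are deterministic, type-distinct, and pool as stated", {
  vocab <- build_vocab(lapply(entity_types(),
                              function(t) guideline_query(t)$tokens))
  enc <- tiny_encoder(vocab, d = 12L, n_layers = 1L, max_len = 128L, seed = 4L)
  q <- guideline_query("PROTEINAS")
  v1 <- encoded_definition_vector(q, enc, d_e = 10L)
  v2 <- encoded_definition_vector(q, enc, d_e = 10L)
  expect_identical(v1$vector, v2$vector)
  expect_length(v1$vector, 10L)
  expect_equal(v1$source, "guideline_encoded")

  v_other <- encoded_definition_vector(guideline_query("UNCLEAR"), enc, d_e = 10L)
  expect_false(isTRUE(all.equal(v1$vector, v_other$vector)))

  # identity projection: vector equals the mean-pooled encoder rows,
  # checked against a by-hand pooling on a 2-token query
  q2 <- rule_template_query("UNCLEAR")
  q2$tokens <- q2$tokens[1:2]
  H <- encode(enc, tokens_to_ids(q2$tokens, vocab))$H
  v_id <- encoded_definition_vector(q2, enc, projection = "identity", d_e = 12L)
  expect_equal(v_id$vector, (H[1L, ] + H[2L, ]) / 2)

  # over-length queries are truncated with a warning
  enc_small <- tiny_encoder(vocab, d = 8L, n_layers = 1L, max_len = 5L, seed = 4L)
  expect_warning(encoded_definition_vector(q, enc_small, d_e = 6L), "truncated")
})

test_that("word2vec text and binary formats round trip", {
  set.seed(3)
  tab <- matrix(rnorm(12), 3L, 4L,
                dimnames = list(c("uno", "dos", "tres"), NULL))
  tf <- withr::local_tempfile(fileext = ".txt")
  write_word2vec(tab, tf)
  back <- read_word2vec(tf)
  expect_equal(rownames(back), rownames(tab))
  expect_lt(max(abs(back - tab)), 1e-6)

  # classic binary layout: "vocab dim\n" then word, space, float32s
  bf <- withr::local_tempfile(fileext = ".bin")
  con <- file(bf, "wb")
  writeBin(charToRaw("3 4\n"), con)
  for (w in rownames(tab)) {
    writeBin(charToRaw(paste0(w, " ")), con)
    writeBin(as.numeric(tab[w, ]), con, size = 4L, endian = "little")
  }
  close(con)
  back2 <- read_word2vec(bf, binary = TRUE)
  expect_equal(rownames(back2), rownames(tab))
  expect_lt(max(abs(back2 - tab)), 1e-6)
})
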