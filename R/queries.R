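# Per-type definition queries and fixed-dimension definition representations.
#
# The guideline texts are the Spanish annotation-guideline definitions of the
# four PharmaCoNER entity types; the rule template is the fixed question
# frame instantiated with the type token. Both are byte-stable constants.

guideline_texts <- c(
  PROTEINAS = "Las menciones de proteínas y genes incluyen péptidos, hormonas peptídicas y anticuerpos.",
  NORMALIZABLES = "Menciones de productos químicos que pueden normalizarse manualmente a un identificador de concepto único.",
  NO_NORMALIZABLES = "Menciones de productos químicos que no se pudieron normalizar manualmente a un identificador de concepto único.",
  UNCLEAR = "Casos de menciones generales de clase de sustancias de relevancia clínica y biomédica, incluidas ciertas formulaciones farmacéuticas, tratamientos generales, programas de quimioterapia, vacunas y un conjunto predefinido de sustancias generales ( por ejemplo: Estragón, Silimarina, Bromelaína, Melanina, Vaselina, Lanolina, Alcohol, Tabaco, Marihuana, cannabis, opio y gluten)."
)

# The published question frame writes the NO_NORMALIZABLES type token in
# mixed case; kept verbatim.
rule_template_tokens <- c(
  PROTEINAS = "PROTEINAS",
  NORMALIZABLES = "NORMALIZABLES",
  NO_NORMALIZABLES = "No_NORMALIZABLES",
  UNCLEAR = "UNCLEAR"
)

check_type <- function(type_label) {
  if (length(type_label) != 1L || !type_label %in% entity_types()) {
    defner_error(sprintf("unknown entity type: %s", dQuote(type_label)),
                 "defner_unknown_type")
  }
  type_label
}

new_query_spec <- function(type_label, strategy, text) {
  tk <- basic_tokenizer()(text)
  structure(
    list(type_label = type_label, strategy = strategy, text = text,
         tokens = tk$token, token_length = nrow(tk)),
    class = "query_spec"
  )
}

#' Annotation-guideline query for an entity type
#'
#' Returns the verbatim Spanish guideline definition of the entity type, used
#' as the query text by the guideline model variants.
#'
#' @param type_label One of \code{entity_types()}.
#' @return A \code{query_spec} with fields \code{type_label}, \code{strategy},
#'   \code{text}, \code{tokens}, \code{token_length}.
#' @export
guideline_query <- function(type_label) {
  check_type(type_label)
  new_query_spec(type_label, "guideline", unname(guideline_texts[type_label]))
}

#' Rule-template query for an entity type
#'
#' Instantiates the fixed question template
#' \dQuote{¿Qué entidades <TYPE> se mencionan en el texto?} with the
#' entity type token.
#'
#' @inheritParams guideline_query
#' @return A \code{query_spec}.
#' @export
rule_template_query <- function(type_label) {
  check_type(type_label)
  text <- sprintf("¿Qué entidades %s se mencionan en el texto?",
                  rule_template_tokens[type_label])
  new_query_spec(type_label, "rule_template", unname(text))
}

#' @export
print.query_spec <- function(x, ...) {
  cat(sprintf("<query_spec %s/%s, %d tokens>\n  %s\n",
              x$type_label, x$strategy, x$token_length, x$text))
  invisible(x)
}

#' Definition vector from pooled mention-word embeddings
#'
#' Represents an entity type by the arithmetic mean of the word embeddings of
#' all tokens in all known mentions of that type. Mention strings are
#' whitespace-split and lowercased; out-of-vocabulary tokens are skipped.
#'
#' @param mentions Character vector of mention surface strings (training
#'   split only, to avoid label leakage).
#' @param embedding_table Numeric matrix, one row per word (rownames are the
#'   words), \code{d_e} columns.
#' @param type_label Entity type the vector describes.
#' @param on_empty What to do when no mention token is in vocabulary:
#'   \code{"error"} (default) or \code{"zero"} to fall back to a zero vector.
#' @return A \code{definition_vector}: list with \code{type_label},
#'   \code{source = "w2v_mentions"} and \code{vector} of length \code{d_e}.
#' @export
w2v_definition_vector <- function(mentions, embedding_table, type_label = NA,
                                  on_empty = c("error", "zero")) {
  on_empty <- match.arg(on_empty)
  toks <- tolower(unlist(strsplit(mentions, "\\s+"), use.names = FALSE))
  toks <- toks[nzchar(toks)]
  hit <- toks[toks %in% rownames(embedding_table)]
  if (length(hit) == 0L) {
    if (on_empty == "error") {
      defner_error("no mention token found in the embedding vocabulary",
                   "defner_empty_definition")
    }
    v <- numeric(ncol(embedding_table))
  } else {
    v <- colMeans(embedding_table[hit, , drop = FALSE])
  }
  new_definition_vector(type_label, "w2v_mentions", unname(v))
}

new_definition_vector <- function(type_label, source, vector) {
  if (!all(is.finite(vector))) {
    defner_error("definition vector has non-finite components",
                 "defner_numeric_error")
  }
  structure(list(type_label = type_label, source = source, vector = vector),
            class = "definition_vector")
}

#' Definition vector from an encoded query
#'
#' Encodes the query text with a contextual encoder, mean-pools the final
#' layer over the query's token positions, and linearly projects the pooled
#' encoding from the encoder width \code{d} to the definition dimension
#' \code{d_e}. Deterministic for fixed encoder and projection parameters.
#'
#' @param query A \code{query_spec}.
#' @param encoder A contextual encoder (see \code{\link{tiny_encoder}}).
#' @param projection Numeric \code{d x d_e} matrix, or \code{NULL} for a
#'   deterministic random projection derived from the encoder seed, or
#'   \code{"identity"} (requires \code{d_e == d}).
#' @param d_e Definition dimension (default 300).
#' @return A \code{definition_vector} with source
#'   \code{"rule_query_encoded"} or \code{"guideline_encoded"}.
#' @export
encoded_definition_vector <- function(query, encoder, projection = NULL,
                                      d_e = 300L) {
  toks <- query$tokens
  if (length(toks) > encoder$max_len) {
    warning(sprintf("query for %s truncated from %d to %d tokens",
                    query$type_label, length(toks), encoder$max_len),
            call. = FALSE)
    toks <- toks[seq_len(encoder$max_len)]
  }
  ids <- tokens_to_ids(toks, encoder$vocab)
  H <- encode(encoder, ids)$H
  pooled <- colMeans(H)
  if (identical(projection, "identity")) {
    if (d_e != encoder$d) {
      defner_error("identity projection requires d_e equal to the encoder width",
                   "defner_shape_error")
    }
    v <- pooled
  } else {
    if (is.null(projection)) {
      projection <- with_seed(encoder$seed + 7L,
                              matrix(stats::rnorm(encoder$d * d_e, sd = 0.1),
                                     encoder$d, d_e))
    }
    if (nrow(projection) != encoder$d || ncol(projection) != d_e) {
      defner_error("projection matrix shape does not match (d, d_e)",
                   "defner_shape_error")
    }
    v <- as.numeric(pooled %*% projection)
  }
  src <- if (identical(query$strategy, "guideline")) "guideline_encoded" else "rule_query_encoded"
  new_definition_vector(query$type_label, src, v)
}
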