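#' Entity types of the PharmaCoNER annotation scheme
#'
#' The four entity types used throughout the package: chemicals normalizable
#' to a concept identifier, chemicals that are not, proteins/genes, and
#' general substance-class mentions (\code{UNCLEAR}, conventionally excluded
#' from scoring).
#'
#' @return Character vector of the four type labels.
#' @export
entity_types <- function() {
  c("NORMALIZABLES", "NO_NORMALIZABLES", "PROTEINAS", "UNCLEAR")
}

empty_mentions <- function() {
  data.frame(
    type_label = character(), char_start = integer(), char_end = integer(),
    surface = character(), stringsAsFactors = FALSE
  )
}

#' Construct a document with typed character-offset mentions
#'
#' A document pairs raw text with a table of flat (non-overlapping) entity
#' mentions addressed by 0-based half-open character offsets, the coordinate
#' convention of the BRAT standoff format.
#'
#' @param doc_id Document identifier.
#' @param text Document text (UTF-8).
#' @param mentions Data frame with columns \code{type_label},
#'   \code{char_start}, \code{char_end}, \code{surface}. May be \code{NULL}
#'   for an unannotated document.
#' @return An object of class \code{brat_document}.
#' @export
new_document <- function(doc_id, text, mentions = NULL) {
  if (is.null(mentions)) mentions <- empty_mentions()
  mentions$char_start <- as.integer(mentions$char_start)
  mentions$char_end <- as.integer(mentions$char_end)
  doc <- structure(
    list(doc_id = doc_id, text = text, mentions = mentions),
    class = "brat_document"
  )
  validate_document(doc)
  doc
}

#' Validate the invariants of a document
#'
#' Checks that all mention offsets are in range, that every surface string
#' equals the text slice it points at, and that mentions are flat
#' (no two overlap in character range).
#'
#' @param doc A \code{brat_document}.
#' @return The document, invisibly.
#' @export
validate_document <- function(doc) {
  m <- doc$mentions
  n <- nchar(doc$text)
  if (nrow(m) == 0L) return(invisible(doc))
  bad <- which(!(m$char_start >= 0L & m$char_start < m$char_end & m$char_end <= n))
  if (length(bad)) {
    defner_error(
      sprintf("mention %d of document '%s': offsets [%d, %d) out of range for text of %d characters",
              bad[1L], doc$doc_id, m$char_start[bad[1L]], m$char_end[bad[1L]], n),
      "defner_malformed_annotation"
    )
  }
  sl <- mapply(slice_chars, m$char_start, m$char_end,
               MoreArgs = list(text = doc$text), USE.NAMES = FALSE)
  mism <- which(sl != m$surface)
  if (length(mism)) {
    defner_error(
      sprintf("mention %d of document '%s': annotated surface %s does not match text slice %s",
              mism[1L], doc$doc_id, dQuote(m$surface[mism[1L]]), dQuote(sl[mism[1L]])),
      "defner_surface_mismatch"
    )
  }
  o <- order(m$char_start, m$char_end)
  ms <- m[o, , drop = FALSE]
  if (nrow(ms) > 1L && any(ms$char_start[-1L] < ms$char_end[-nrow(ms)])) {
    defner_error(
      sprintf("document '%s' has overlapping mentions; only flat annotation is supported",
              doc$doc_id),
      "defner_overlapping_mentions"
    )
  }
  invisible(doc)
}

#' Read a BRAT standoff document
#'
#' Parses the paired \code{.txt}/\code{.ann} contents of the BRAT standoff
#' format. Only \code{T} (text-bound entity) lines are consumed; note
#' (\code{#}), normalization (\code{N}) and other line kinds are skipped.
#' Every annotated surface is verified against the corresponding text slice.
#'
#' @param txt_content Document text as a single string.
#' @param ann_content Annotation file content as a single string (may be "").
#' @param doc_id Document identifier to attach.
#' @return A \code{brat_document}.
#' @export
read_brat <- function(txt_content, ann_content, doc_id = "doc") {
  lines <- strsplit(ann_content, "\n", fixed = TRUE)[[1L]]
  lines <- lines[nzchar(trimws(lines))]
  tl <- lines[startsWith(lines, "T")]
  if (length(tl) == 0L) return(new_document(doc_id, txt_content))
  rows <- vector("list", length(tl))
  for (i in seq_along(tl)) {
    parts <- strsplit(tl[i], "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) {
      defner_error(sprintf("malformed annotation line: %s", dQuote(tl[i])),
                   "defner_malformed_annotation")
    }
    mid <- strsplit(parts[2L], " ", fixed = TRUE)[[1L]]
    if (length(mid) != 3L || anyNA(suppressWarnings(as.integer(mid[2:3])))) {
      defner_error(
        sprintf("malformed annotation line (expected 'TYPE start end', discontinuous spans unsupported): %s",
                dQuote(tl[i])),
        "defner_malformed_annotation"
      )
    }
    rows[[i]] <- data.frame(
      type_label = mid[1L],
      char_start = as.integer(mid[2L]),
      char_end = as.integer(mid[3L]),
      surface = paste(parts[-(1:2)], collapse = "\t"),
      stringsAsFactors = FALSE
    )
  }
  new_document(doc_id, txt_content, do.call(rbind, rows))
}

#' Write a document to BRAT standoff format
#'
#' Inverse of \code{\link{read_brat}}: mention order is normalised by
#' character start offset and T-ids are renumbered, so writing then reading
#' is the identity on valid documents and a second write cycle is
#' byte-identical to the first.
#'
#' @param doc A \code{brat_document}.
#' @return List with elements \code{txt} and \code{ann} (single strings).
#' @export
write_brat <- function(doc) {
  validate_document(doc)
  m <- doc$mentions
  if (nrow(m) == 0L) return(list(txt = doc$text, ann = ""))
  m <- m[order(m$char_start, m$char_end), , drop = FALSE]
  ann <- sprintf("T%d\t%s %d %d\t%s", seq_len(nrow(m)),
                 m$type_label, m$char_start, m$char_end, m$surface)
  list(txt = doc$text, ann = paste0(paste(ann, collapse = "\n"), "\n"))
}

read_text_file <- function(path) {
  size <- file.info(path)$size
  txt <- readChar(path, size, useBytes = TRUE)
  Encoding(txt) <- "UTF-8"
  txt
}

write_text_file <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(x)), con)
  invisible(path)
}

#' Read a directory of BRAT documents
#'
#' @param dir Directory containing paired \code{.txt}/\code{.ann} files.
#'   A missing \code{.ann} file is treated as an unannotated document.
#' @return List of \code{brat_document}s, named by document id.
#' @export
read_brat_dir <- function(dir) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  docs <- lapply(txts, function(p) {
    id <- sub("\\.txt$", "", basename(p))
    annp <- file.path(dir, paste0(id, ".ann"))
    ann <- if (file.exists(annp)) read_text_file(annp) else ""
    read_brat(read_text_file(p), ann, doc_id = id)
  })
  names(docs) <- vapply(docs, `[[`, "", "doc_id")
  docs
}

#' Write a list of documents as paired .txt/.ann files
#'
#' @param docs List of \code{brat_document}s.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_brat_dir <- function(docs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (doc in docs) {
    out <- write_brat(doc)
    write_text_file(out$txt, file.path(dir, paste0(doc$doc_id, ".txt")))
    write_text_file(out$ann, file.path(dir, paste0(doc$doc_id, ".ann")))
  }
  invisible(dir)
}

#' @export
print.brat_document <- function(x, ...) {
  cat(sprintf("<brat_document '%s': %d characters, %d mentions>\n",
              x$doc_id, nchar(x$text), nrow(x$mentions)))
  if (nrow(x$mentions)) {
    print(utils::head(x$mentions, 10L))
    if (nrow(x$mentions) > 10L) cat("...\n")
  }
  invisible(x)
}
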