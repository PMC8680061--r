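#' Read a word2vec embedding table
#'
#' Reads the word2vec text format (optionally with the leading
#' \code{"<vocab> <dim>"} header line) or the classic binary format (header
#' line, then per word: the word, a space, and \code{dim} little-endian
#' float32 values).
#'
#' @param path File path.
#' @param binary Logical; read the binary format?
#' @return Numeric matrix, one row per word, rownames set to the words.
#' @export
read_word2vec <- function(path, binary = FALSE) {
  if (binary) return(read_word2vec_binary(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(matrix(numeric(), 0L, 0L))
  first <- strsplit(lines[1L], " ", fixed = TRUE)[[1L]]
  if (length(first) == 2L && !anyNA(suppressWarnings(as.integer(first)))) {
    lines <- lines[-1L]   # gensim-style header
  }
  parts <- strsplit(lines, " ", fixed = TRUE)
  words <- vapply(parts, `[[`, "", 1L)
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1L]),
                   numeric(length(parts[[1L]]) - 1L)))
  rownames(vecs) <- words
  vecs
}

read_word2vec_binary <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (identical(ch, "\n")) break
    header <- c(header, ch)
  }
  hd <- as.integer(strsplit(paste(header, collapse = ""), " ")[[1L]])
  nv <- hd[1L]; dim <- hd[2L]
  out <- matrix(0, nv, dim)
  words <- character(nv)
  for (i in seq_len(nv)) {
    wchars <- character()
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (identical(ch, " ")) break
      if (!identical(ch, "\n")) wchars <- c(wchars, ch)
    }
    w <- paste(wchars, collapse = "")
    Encoding(w) <- "UTF-8"
    words[i] <- w
    out[i, ] <- readBin(con, "numeric", n = dim, size = 4L, endian = "little")
  }
  rownames(out) <- words
  out
}

#' Write an embedding table in word2vec text format
#'
#' @param table Numeric matrix with words as rownames.
#' @param path Output path.
#' @param header Write the \code{"<vocab> <dim>"} header line?
#' @return The path, invisibly.
#' @export
write_word2vec <- function(table, path, header = TRUE) {
  lines <- vapply(seq_len(nrow(table)), function(i) {
    paste(rownames(table)[i],
          paste(formatC(table[i, ], format = "g", digits = 8), collapse = " "))
  }, "")
  if (header) lines <- c(paste(nrow(table), ncol(table)), lines)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
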