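#' Whitespace-and-punctuation tokenizer with character spans
#'
#' Returns a tokenizer function mapping a string to a data frame with columns
#' \code{token}, \code{start}, \code{end} (0-based, half-open character
#' offsets). Tokens are maximal runs of letters/digits/underscore; every other
#' non-whitespace character becomes a single-character token. This guarantees
#' that each non-whitespace character is covered by exactly one token span,
#' which is what offset-exact label projection requires.
#'
#' @return A function \code{function(text) -> data.frame(token, start, end)}.
#' @export
basic_tokenizer <- function() {
  pat <- "[\\p{L}\\p{N}_]+|[^\\p{L}\\p{N}_\\s]"
  function(text) {
    if (!nzchar(text)) {
      return(data.frame(token = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE))
    }
    m <- gregexpr(pat, text, perl = TRUE)[[1L]]
    if (m[1L] == -1L) {
      return(data.frame(token = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE))
    }
    start <- as.integer(m) - 1L
    len <- attr(m, "match.length")
    data.frame(
      token = substring(text, m, m + len - 1L),
      start = start, end = start + len, stringsAsFactors = FALSE
    )
  }
}

#' Tokenize a text window and verify offset alignment
#'
#' Runs a tokenizer over a window of text and checks the alignment contract:
#' token spans lie inside the window, are ordered and non-overlapping, and
#' jointly cover every non-whitespace character, so that the char -> token ->
#' char projection is invertible.
#'
#' @param window_text The text to tokenize.
#' @param tokenizer A tokenizer function as returned by
#'   \code{\link{basic_tokenizer}} (or any function honouring its contract).
#' @return Data frame with columns \code{token}, \code{start}, \code{end}
#'   (0-based, half-open, window-local).
#' @export
tokenize_and_align <- function(window_text, tokenizer = basic_tokenizer()) {
  tk <- tokenizer(window_text)
  n <- nchar(window_text)
  if (nrow(tk)) {
    if (any(tk$start < 0L) || any(tk$end > n) || any(tk$start >= tk$end)) {
      defner_error("tokenizer produced a span outside the window",
                   "defner_alignment_error")
    }
    if (nrow(tk) > 1L && any(tk$start[-1L] < tk$end[-nrow(tk)])) {
      defner_error("tokenizer produced overlapping or unordered spans",
                   "defner_alignment_error")
    }
  }
  covered <- rep(FALSE, n)
  for (i in seq_len(nrow(tk))) covered[(tk$start[i] + 1L):tk$end[i]] <- TRUE
  chars <- strsplit(window_text, "", fixed = TRUE)[[1L]]
  need <- !grepl("^\\s$", chars)
  if (any(need & !covered)) {
    defner_error("tokenizer left a non-whitespace character uncovered",
                 "defner_alignment_error")
  }
  tk
}
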