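#' Tokenize text at letter/digit boundaries
#'
#' Splits text into maximal runs of letters, maximal runs of digits, and
#' single non-alphanumeric characters, discarding whitespace. Contiguous
#' letters and digits are split apart, so `"P53"` becomes `"P"`, `"53"` —
#' the convention used by mutation-mention taggers, which keeps identifiers
#' with numeric suffixes comparable across spelling variants.
#'
#' @param text A single character string.
#' @return A tibble with one row per token: `token` (the surface string),
#'   `start`, `end` (0-based, half-open character offsets into `text`).
#' @examples
#' lx_tokenize("P53")
#' lx_tokenize("GFP-tagged2")
#' @export
lx_tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || nchar(text) == 0L) {
    return(tibble(token = character(), start = integer(), end = integer()))
  }
  m <- gregexpr("[A-Za-z]+|[0-9]+|[^A-Za-z0-9[:space:]]", text)[[1]]
  if (m[1] == -1L) {
    return(tibble(token = character(), start = integer(), end = integer()))
  }
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  tibble(token = slice_text(text, start, end), start = start, end = end)
}
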