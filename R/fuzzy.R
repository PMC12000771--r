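#' Levenshtein similarity ratio between two tokens
#'
#' Similarity on the familiar 0-100 scale used by fuzzy string matchers:
#' `round(100 * (1 - D(a, b) / max(nchar(a), nchar(b))))` where `D` is the
#' unit-cost edit distance (insertions, deletions, substitutions). Symmetric;
#' 100 iff the tokens are equal. Vectorised over `b` for one `a`.
#'
#' @param a single non-empty lowercase token.
#' @param b character vector of non-empty lowercase tokens.
#' @return integer vector of scores in 0-100, one per element of `b`.
#' @examples
#' levenshtein_similarity("astma", "asthma")  # one deletion, length 6 -> 83
#' @export
levenshtein_similarity <- function(a, b) {
  if (length(a) != 1L || is.na(a) || !nzchar(a)) {
    stop("'a' must be a single non-empty token", call. = FALSE)
  }
  if (length(b) == 0L) return(integer(0))
  if (anyNA(b) || any(!nzchar(b))) {
    stop("'b' must contain non-empty tokens", call. = FALSE)
  }
  d <- drop(utils::adist(a, b))
  as.integer(round(100 * (1 - d / pmax(nchar(a), nchar(b)))))
}
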