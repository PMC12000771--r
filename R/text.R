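#' Normalise a free-text condition field
#'
#' Lowercases the text, replaces ASCII punctuation with spaces, removes
#' tokens made up solely of digits (year-like noise such as "2019"), and
#' collapses runs of whitespace. Alphanumeric tokens that contain at least
#' one letter (clinical shorthand such as "t2dm") are preserved intact.
#' The function is total and idempotent; `NA` is treated as an empty field.
#'
#' @param raw character vector of raw field contents.
#' @return character vector of cleaned, lowercase text.
#' @examples
#' clean_text("Asthma;  DEPRESSION (2019)!!")
#' clean_text("GDM in 2018, t2dm")
#' @export
clean_text <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  x <- as.character(raw)
  x[is.na(x)] <- ""
  x <- tolower(x)
  x <- gsub("[[:punct:]]+", " ", x)
  # digit-only tokens; \b does not split letter-digit runs, so "t2dm" survives
  x <- gsub("\\b[0-9]+\\b", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Split cleaned text into word tokens
#'
#' @param cleaned character scalar, already passed through [clean_text()].
#' @return character vector of tokens (empty for empty input), order preserved.
#' @examples
#' tokenize("iron deficiency anaemia")
#' @export
tokenize <- function(cleaned) {
  stopifnot(length(cleaned) <= 1L)
  if (length(cleaned) == 0L || is.na(cleaned) || !nzchar(cleaned)) {
    return(character(0))
  }
  strsplit(cleaned, " ", fixed = TRUE)[[1L]]
}

#' Remove stop words from a token vector
#'
#' Order-preserving filter: a token is dropped iff it appears in `stopwords`.
#'
#' @param tokens lowercase character vector.
#' @param stopwords character vector of words to drop; defaults to the shipped
#'   English list (see [default_stopwords()]).
#' @return filtered character vector.
#' @export
remove_stopwords <- function(tokens, stopwords = default_stopwords()) {
  tokens[!(tokens %in% stopwords)]
}

#' The shipped English stop-word list
#'
#' A standard English stop-word list (function words with no clinical
#' content), stored one word per line at
#' `system.file("extdata", "stopwords_en.txt", package = "pregmorbid")` and
#' overridable everywhere a stop-word set is accepted.
#'
#' @return character vector of lowercase stop words.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "pregmorbid")
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

#' Corpus term-frequency table
#'
#' Counts each term's total occurrences across a tokenized corpus and returns
#' the `top_n` most frequent, in descending count order with lexicographic
#' tie-break. This is the tabular counterpart of the usual word-frequency /
#' word-cloud view of a clinical free-text column.
#'
#' @param corpus list of character token vectors (one per record).
#' @param top_n maximum number of terms to return (>= 1).
#' @return data.frame with columns `term` and `count`, at most `top_n` rows.
#' @examples
#' term_frequencies(list(c("asthma", "asthma", "gdm")), top_n = 2)
#' @export
term_frequencies <- function(corpus, top_n = 25L) {
  stopifnot(is.list(corpus), top_n >= 1L)
  all_tokens <- unlist(corpus, use.names = FALSE)
  if (length(all_tokens) == 0L) {
    return(data.frame(term = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- table(all_tokens)
  out <- data.frame(term = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$term), , drop = FALSE]
  out <- utils::head(out, top_n)
  rownames(out) <- NULL
  out
}
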