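#' Extraction configuration
#'
#' Bundles the tunable settings of the morbidity extractor: the fuzzy-match
#' similarity threshold, the minimum token length eligible for fuzzy
#' matching, the BMI cut-points for the derived overweight (25.0 to <30
#' kg/m2) and obesity (>= 30 kg/m2) flags, the advanced-maternal-age
#' cut-point (>= 35 years), and the set of conditions counted into the
#' multimorbidity burden.
#'
#' @param default_fuzzy_threshold integer 0-100; minimum
#'   [levenshtein_similarity()] for a fuzzy keyword match (default 85: one
#'   edit in a 7-letter token passes, short-token noise does not).
#' @param min_fuzzy_token_length tokens shorter than this are never fuzzily
#'   matched (default 5).
#' @param overweight_lower,obese_lower BMI band edges in kg/m2 (inclusive
#'   lower bounds; overweight is `[overweight_lower, obese_lower)`).
#' @param advanced_age_lower age in completed years, inclusive.
#' @param conditions_counted_in_burden character vector of condition ids
#'   summed into `morbidity_count`, or `NULL` (default) for: every lexicon
#'   condition plus `overweight` and `obesity`, minus `advanced_age` and
#'   `substance_use`.
#' @return an object of class `extraction_config`.
#' @export
extraction_config <- function(default_fuzzy_threshold = 85L,
                              min_fuzzy_token_length = 5L,
                              overweight_lower = 25.0,
                              obese_lower = 30.0,
                              advanced_age_lower = 35,
                              conditions_counted_in_burden = NULL) {
  if (default_fuzzy_threshold < 0 || default_fuzzy_threshold > 100) {
    stop("default_fuzzy_threshold must be in [0, 100]", call. = FALSE)
  }
  if (!(overweight_lower < obese_lower)) {
    stop("overweight_lower must be < obese_lower", call. = FALSE)
  }
  structure(list(
    default_fuzzy_threshold = as.integer(default_fuzzy_threshold),
    min_fuzzy_token_length = as.integer(min_fuzzy_token_length),
    overweight_lower = overweight_lower,
    obese_lower = obese_lower,
    advanced_age_lower = advanced_age_lower,
    conditions_counted_in_burden = conditions_counted_in_burden
  ), class = "extraction_config")
}

burden_conditions <- function(config, lexicon) {
  if (!is.null(config$conditions_counted_in_burden)) {
    return(config$conditions_counted_in_burden)
  }
  setdiff(c(names(lexicon), "overweight", "obesity"), "substance_use")
}

#' Match lexicon conditions in a tokenized field
#'
#' Two-phase rule-based matcher. Phase 1 matches multi-token phrases (and
#' exclusion phrases) as contiguous token runs, longest phrase first; a
#' matched span is consumed, so "iron deficiency anaemia" sets only the
#' iron-deficiency condition and never the generic anaemia keyword, and an
#' exclusion span (e.g. "gestational diabetes" under preexisting diabetes)
#' consumes its tokens without setting any flag. Phase 2 compares each
#' remaining token exactly against all single-token keywords and, on
#' failure, fuzzily ([levenshtein_similarity()] at or above the condition's
#' threshold, token length at least `min_fuzzy_token_length`). A condition's
#' flag is 1 iff it matched at least once.
#'
#' @param tokens cleaned, tokenized field (stop words need not be removed).
#' @param lexicon a [morbidity_lexicon()].
#' @param config an [extraction_config()].
#' @param index optional precomputed index (internal; used by
#'   [extract_cohort()] to avoid rebuilding it per record).
#' @return named integer vector of 0/1 flags, one per lexicon condition.
#' @export
match_conditions <- function(tokens, lexicon, config = extraction_config(),
                             index = NULL) {
  if (is.null(index)) index <- lexicon_index(lexicon)
  flags <- setNames(integer(length(index$conditions)), index$conditions)
  n <- length(tokens)
  if (n == 0L) return(flags)
  consumed <- logical(n)
  for (p in seq_along(index$phrases)) {
    ph <- index$phrases[[p]]
    L <- length(ph)
    if (L > n) next
    for (i in seq_len(n - L + 1L)) {
      span <- i:(i + L - 1L)
      if (any(consumed[span])) next
      if (all(tokens[span] == ph)) {
        consumed[span] <- TRUE
        if (!index$phrase_excl[p]) {
          flags[index$phrase_cond[p]] <- 1L
        }
      }
    }
  }
  rest <- unique(tokens[!consumed])
  thr <- ifelse(is.na(index$cond_threshold), config$default_fuzzy_threshold,
                index$cond_threshold)
  names(thr) <- index$conditions
  for (tok in rest) {
    hit <- index$single_cond[index$single_token == tok]
    if (length(hit)) {
      flags[unique(hit)] <- 1L
    } else if (nchar(tok) >= config$min_fuzzy_token_length &&
               length(index$single_token)) {
      score <- levenshtein_similarity(tok, index$single_token)
      ok <- unique(index$single_cond[score >= thr[index$single_cond]])
      if (length(ok)) flags[ok] <- 1L
    }
  }
  flags
}

#' Derive overweight/obesity flags from prepregnancy BMI
#'
#' Overweight is BMI in `[25.0, 30.0)` and obesity BMI `>= 30.0` (kg/m2) by
#' default; the two flags are mutually exclusive by construction. Missing
#' BMI yields both flags 0 (absence of evidence, never an error).
#'
#' @param bmi numeric vector of BMI values (kg/m2), possibly `NA`.
#' @param config an [extraction_config()].
#' @return data.frame with integer columns `overweight` and `obesity`.
#' @export
derive_bmi_flags <- function(bmi, config = extraction_config()) {
  if (any(!is.na(bmi) & bmi <= 0)) {
    stop("BMI must be positive where present", call. = FALSE)
  }
  ow <- as.integer(!is.na(bmi) & bmi >= config$overweight_lower &
                     bmi < config$obese_lower)
  ob <- as.integer(!is.na(bmi) & bmi >= config$obese_lower)
  data.frame(overweight = ow, obesity = ob)
}

#' Derive the advanced-maternal-age flag
#'
#' 1 iff age is 35 years or older (configurable); missing age yields 0.
#'
#' @param age numeric vector of maternal ages in years, possibly `NA`.
#' @param config an [extraction_config()].
#' @return integer 0/1 vector.
#' @export
derive_advanced_age <- function(age, config = extraction_config()) {
  if (any(!is.na(age) & age < 0)) {
    stop("age must be non-negative where present", call. = FALSE)
  }
  as.integer(!is.na(age) & age >= config$advanced_age_lower)
}

#' Extract morbidity profiles for a whole cohort
#'
#' Runs the cleaning/tokenizing/matching pipeline over each record's medical
#' conditions text, adds the BMI- and age-derived flags, and computes the
#' multimorbidity burden: `morbidity_count` sums the flags of the counted
#' condition set and `burden_class` is `none` (0), `single` (1) or
#' `multimorbidity` (>= 2).
#'
#' @param records data.frame with at least `record_id`, `maternal_age`,
#'   `bmi` and `medical_conditions_text` columns (the cohort table schema).
#' @param lexicon a [morbidity_lexicon()]; default [default_lexicon()].
#' @param config an [extraction_config()].
#' @return a data.frame of class `morbidity_profiles`: `record_id`, one 0/1
#'   column per condition (lexicon conditions plus `overweight`, `obesity`,
#'   `advanced_age`), `morbidity_count` and `burden_class`. The counted
#'   condition set is attached as attribute `"counted"`; records whose text
#'   contains the tokens "no" or "denies" are tallied (not interpreted) in
#'   attribute `"negation_audit"`.
#' @export
extract_cohort <- function(records, lexicon = default_lexicon(),
                           config = extraction_config()) {
  required <- c("record_id", "maternal_age", "bmi", "medical_conditions_text")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("records table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  idx <- lexicon_index(lexicon)
  token_lists <- lapply(clean_text(records$medical_conditions_text), tokenize)
  flag_mat <- t(vapply(token_lists, match_conditions,
                       setNames(integer(length(idx$conditions)),
                                idx$conditions),
                       lexicon = lexicon, config = config, index = idx))
  derived <- derive_bmi_flags(records$bmi, config)
  derived$advanced_age <- derive_advanced_age(records$maternal_age, config)
  out <- data.frame(record_id = records$record_id, flag_mat, derived,
                    stringsAsFactors = FALSE, check.names = FALSE)
  counted <- burden_conditions(config, lexicon)
  counted <- intersect(counted, names(out))
  out$morbidity_count <- as.integer(rowSums(out[, counted, drop = FALSE]))
  out$burden_class <- burden_class(out$morbidity_count)
  attr(out, "counted") <- counted
  attr(out, "negation_audit") <-
    sum(vapply(token_lists, function(tk) any(tk %in% c("no", "denies")),
               logical(1)))
  class(out) <- c("morbidity_profiles", "data.frame")
  out
}

burden_class <- function(count) {
  factor(ifelse(count == 0L, "none", ifelse(count == 1L, "single",
                                            "multimorbidity")),
         levels = c("none", "single", "multimorbidity"))
}

#' @export
print.morbidity_profiles <- function(x, ...) {
  cat("Morbidity profiles:", nrow(x), "records,",
      length(setdiff(names(x), c("record_id", "morbidity_count",
                                 "burden_class"))), "conditions\n")
  print(table(burden = x$burden_class))
  invisible(x)
}
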