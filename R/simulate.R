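# marginal prevalences of the free-text conditions emulated by default
default_condition_prevalences <- function() {
  c(vitamin_deficiency = 0.289, blood_disorders = 0.099,
    mental_disorders = 0.089, asthma = 0.085, thyroid_disease = 0.074,
    endometrial_disease = 0.039, cardiovascular_disease = 0.031,
    pcos = 0.030, iron_deficiency_anemia = 0.027, migraine = 0.026,
    urinary_tract_infection = 0.020, diabetes_mellitus = 0.015,
    musculoskeletal_disease = 0.014, hypertension = 0.012,
    kidney_disease = 0.008, substance_use = 0.124, bowel_disease = 0.006,
    genital_herpes = 0.006, hemorrhoids = 0.005, autoimmune_disease = 0.007,
    respiratory_disease = 0.005, infertility = 0.003, epilepsy = 0.005)
}

default_outcome_model <- function() {
  list(intercept = stats::qlogis(0.18),
       log_or = c(vitamin_deficiency = log(1.4), thyroid_disease = log(1.6),
                  pcos = log(2.2), hypertension = log(2.5),
                  diabetes_mellitus = log(3.0), infertility = log(2.0),
                  substance_use = log(1.2)))
}

default_age_distribution <- function() {
  list(labels = c("<=24", "25-29", "30-34", "35-39", ">=40"),
       lower = c(18, 25, 30, 35, 40), upper = c(24, 29, 34, 39, 45),
       weights = c(0.127, 0.285, 0.363, 0.182, 0.043))
}

default_bmi_distribution <- function() {
  list(labels = c("<=19.9", "20-24.9", "25-26.9", "27-29.9", "30-34.9",
                  "35+"),
       lower = c(16, 20, 25, 27, 30, 35),
       upper = c(19.9, 24.9, 26.9, 29.9, 34.9, 45),
       weights = c(0.086, 0.395, 0.137, 0.150, 0.129, 0.098))
}

default_complication_prevalences <- function() {
  c(induction = 0.301, cesarean = 0.289, scn_nicu = 0.181,
    macrosomia = 0.089, preterm = 0.084, preeclampsia = 0.035,
    shoulder_dystocia = 0.022, birth_defect = 0.051, pih = 0.023)
}

#' Configuration of a synthetic pregnancy cohort
#'
#' Defaults emulate the study conditions the package targets: a maternity
#' cohort with the published marginal condition prevalences (vitamin
#' deficiency ~29%, substance use ~12%, ...), age and BMI band frequencies
#' matching the published baseline table, and a logistic GDM-analogue
#' outcome. Free-text rendering noise (typos, abbreviations, filler tokens,
#' stray capitalisation) exercises the extractor's normalisation and fuzzy
#' matching.
#'
#' @param n_records number of pregnancies to simulate (>= 1).
#' @param condition_prevalences named probability vector, condition id ->
#'   marginal prevalence (ignored for conditions governed by
#'   `cluster_spec`).
#' @param outcome_model list with `intercept` (log-odds) and `log_or`
#'   (named log odds-ratios over condition ids) for the simulated outcome,
#'   applied to the *true* flags so measurement error never contaminates
#'   the association truth.
#' @param cluster_spec `NULL` for independent conditions, or a list with
#'   `weights` (mixture weights, sum 1) and `profiles` (L x conditions
#'   matrix of within-profile condition probabilities, named columns).
#' @param noise list with `typo_rate`, `abbreviation_rate`, `filler_rate`,
#'   `uppercase_rate`, each in `[0, 1]`.
#' @param age_distribution,bmi_distribution band specifications: lists with
#'   `labels`, `lower`, `upper`, `weights`; values are sampled uniformly
#'   within the chosen band (ages as whole years).
#' @param complication_prevalences named marginal probabilities for the
#'   non-outcome complications rendered into the complications text column.
#' @param seed integer master seed; the same configuration reproduces
#'   byte-identical cohorts.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_records = 1000L,
                              condition_prevalences =
                                default_condition_prevalences(),
                              outcome_model = default_outcome_model(),
                              cluster_spec = NULL,
                              noise = list(typo_rate = 0.05,
                                           abbreviation_rate = 0.2,
                                           filler_rate = 0.1,
                                           uppercase_rate = 0.1),
                              age_distribution = default_age_distribution(),
                              bmi_distribution = default_bmi_distribution(),
                              complication_prevalences =
                                default_complication_prevalences(),
                              seed = 1L) {
  fail <- function(field, why) {
    stop("invalid simulation config: ", field, " ", why, call. = FALSE)
  }
  if (!is.numeric(n_records) || n_records < 1) fail("n_records", "must be >= 1")
  if (anyNA(condition_prevalences) || any(condition_prevalences < 0) ||
      any(condition_prevalences > 1)) {
    fail("condition_prevalences", "must lie in [0, 1]")
  }
  if (is.null(names(condition_prevalences))) {
    fail("condition_prevalences", "must be named by condition id")
  }
  for (r in c("typo_rate", "abbreviation_rate", "filler_rate",
              "uppercase_rate")) {
    v <- noise[[r]]
    if (is.null(v) || v < 0 || v > 1) fail(paste0("noise$", r),
                                           "must lie in [0, 1]")
  }
  if (!is.null(cluster_spec)) {
    w <- cluster_spec$weights
    if (is.null(w) || length(w) < 1) fail("cluster_spec$weights", "missing")
    if (abs(sum(w) - 1) > 1e-9) fail("cluster_spec$weights", "must sum to 1")
    pr <- cluster_spec$profiles
    if (is.null(pr) || nrow(pr) != length(w)) {
      fail("cluster_spec$profiles", "must have one row per mixture weight")
    }
    if (any(pr < 0) || any(pr > 1)) fail("cluster_spec$profiles",
                                         "must lie in [0, 1]")
    if (is.null(colnames(pr))) fail("cluster_spec$profiles",
                                    "must have condition-id column names")
  }
  for (nm in c("age_distribution", "bmi_distribution")) {
    d <- get(nm)
    # published band percentages carry printed rounding; renormalised at draw
    if (abs(sum(d$weights) - 1) > 0.02) fail(nm, "weights must sum to ~1")
  }
  if (!is.numeric(outcome_model$intercept)) fail("outcome_model$intercept",
                                                 "missing")
  structure(list(n_records = as.integer(n_records),
                 condition_prevalences = condition_prevalences,
                 outcome_model = outcome_model, cluster_spec = cluster_spec,
                 noise = noise, age_distribution = age_distribution,
                 bmi_distribution = bmi_distribution,
                 complication_prevalences = complication_prevalences,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

sample_bands <- function(n, dist, integer_values = FALSE) {
  band <- sample.int(length(dist$weights), n, replace = TRUE,
                     prob = dist$weights / sum(dist$weights))
  lo <- dist$lower[band]; hi <- dist$upper[band]
  if (integer_values) {
    lo + floor(stats::runif(n) * (hi - lo + 1))
  } else {
    round(stats::runif(n, lo, hi), 1)
  }
}

filler_words <- c("history", "of", "known", "ongoing", "since")

perturb_token <- function(token, noise) {
  if (noise$typo_rate > 0 && stats::runif(1) < noise$typo_rate) {
    n <- nchar(token)
    pos <- sample.int(n, 1)
    ch <- substr(token, pos, pos)
    if (n >= 2 && stats::runif(1) < 0.5) {
      token <- paste0(substr(token, 1, pos - 1), substr(token, pos + 1, n))
    } else {
      repl <- sample(setdiff(letters, ch), 1)
      token <- paste0(substr(token, 1, pos - 1), repl,
                      substr(token, pos + 1, n))
    }
  }
  if (noise$uppercase_rate > 0 && stats::runif(1) < noise$uppercase_rate) {
    token <- if (stats::runif(1) < 0.5) toupper(token) else
      paste0(toupper(substr(token, 1, 1)), substr(token, 2, nchar(token)))
  }
  token
}

#' Render condition flags into semi-structured free text
#'
#' The inverse of the extractor: emits one randomly chosen keyword or
#' phrase per flagged condition, joined by `"; "`, perturbed per the noise
#' settings (single-character substitution/deletion typos per token,
#' stray capitalisation, interleaved filler words and year-like numbers,
#' occasional trailing punctuation). No flags set yields the empty string —
#' the empty-field convention of semi-structured EMR columns. Draws from
#' the current RNG state.
#'
#' @param flags named 0/1 vector of condition flags.
#' @param lexicon the [morbidity_lexicon()] to draw surface forms from;
#'   every flagged condition must be present.
#' @param noise list as in [simulation_config()].
#' @return a single character string.
#' @export
render_condition_text <- function(flags, lexicon = default_lexicon(),
                                  noise = list(typo_rate = 0,
                                               abbreviation_rate = 0,
                                               filler_rate = 0,
                                               uppercase_rate = 0)) {
  set_ids <- names(flags)[flags == 1]
  if (length(set_ids) == 0L) return("")
  absent <- setdiff(set_ids, names(lexicon))
  if (length(absent)) {
    stop("flagged condition(s) not covered by the lexicon: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  pieces <- character(0)
  for (id in set_ids) {
    kws <- lexicon[[id]]$keywords
    short <- which(lengths(kws) == 1L &
                     vapply(kws, function(k) nchar(k[1]) <= 5L, logical(1)))
    pick <- if (length(short) && noise$abbreviation_rate > 0 &&
                stats::runif(1) < noise$abbreviation_rate) {
      kws[[short[sample.int(length(short), 1)]]]
    } else {
      kws[[sample.int(length(kws), 1)]]
    }
    toks <- vapply(pick, perturb_token, character(1), noise = noise)
    phrase <- paste(toks, collapse = " ")
    if (noise$filler_rate > 0 && stats::runif(1) < noise$filler_rate) {
      filler <- if (stats::runif(1) < 0.5) {
        sample(filler_words, 1)
      } else {
        as.character(1990L + sample.int(35L, 1))
      }
      phrase <- paste(filler, phrase)
    }
    pieces <- c(pieces, phrase)
  }
  out <- paste(pieces, collapse = "; ")
  if (noise$filler_rate > 0 && stats::runif(1) < noise$filler_rate) {
    out <- paste0(out, ".")
  }
  out
}

record_stream_seed <- function(seed, i) {
  ((abs(seed) %% 1000003L) * 2097593 + i * 7919) %% 2147483647
}

#' Generate a synthetic pregnancy cohort with recoverable ground truth
#'
#' Draws per-record condition flags (independently per prevalence, or from
#' latent comorbidity profiles when `cluster_spec` is set), a logistic
#' GDM-analogue outcome on the true flags, banded age/BMI, parity and
#' ethnicity, and renders the flags into semi-structured free text. The
#' structured variables are drawn vectorised from the master seed in a
#' fixed order; text rendering uses an independent substream per record
#' derived from `(seed, record index)`, so the same configuration always
#' reproduces byte-identical output.
#'
#' @param config a [simulation_config()].
#' @param lexicon morbidity lexicon used for rendering condition text.
#' @param complications_lexicon lexicon used for rendering the
#'   complications text column.
#' @param render_text set `FALSE` to skip free-text rendering (the truth
#'   and structured columns are unchanged); useful for large
#'   simulation-only studies.
#' @return list with `records` (the cohort table: `record_id`,
#'   `maternal_age`, `bmi`, `parity`, `ethnicity`,
#'   `medical_conditions_text`, `complications_text`) and `truth`
#'   (`record_id`, one 0/1 column per condition, `cluster_id` — `NA`
#'   without `cluster_spec` — and `outcome`).
#' @export
generate_cohort <- function(config, lexicon = default_lexicon(),
                            complications_lexicon =
                              default_complications_lexicon(),
                            render_text = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_records
  set.seed(config$seed)
  if (!is.null(config$cluster_spec)) {
    w <- config$cluster_spec$weights
    prof <- config$cluster_spec$profiles
    cond <- colnames(prof)
    cluster_id <- sample.int(length(w), n, replace = TRUE, prob = w)
    flags <- matrix(0L, n, length(cond), dimnames = list(NULL, cond))
    for (j in seq_along(cond)) {
      flags[, j] <- stats::rbinom(n, 1L, prof[cluster_id, j])
    }
    cluster_id <- cluster_id - 1L  # 0-based ids in [0, L)
  } else {
    cond <- names(config$condition_prevalences)
    cluster_id <- rep(NA_integer_, n)
    flags <- matrix(0L, n, length(cond), dimnames = list(NULL, cond))
    for (j in seq_along(cond)) {
      flags[, j] <- stats::rbinom(n, 1L, config$condition_prevalences[j])
    }
  }
  age <- sample_bands(n, config$age_distribution, integer_values = TRUE)
  bmi <- sample_bands(n, config$bmi_distribution)
  parity <- sample(0:3, n, replace = TRUE, prob = c(0.40, 0.36, 0.17, 0.07))
  ethnicity <- sample(c("Caucasian", "Oceania", "Middle-Eastern/African",
                        "Southern/Central Asian", "SE/NE Asian", "Other"),
                      n, replace = TRUE,
                      prob = c(0.038, 0.438, 0.061, 0.300, 0.160, 0.003))
  lor <- config$outcome_model$log_or
  eta <- rep(config$outcome_model$intercept, n)
  for (nm in intersect(names(lor), colnames(flags))) {
    eta <- eta + lor[[nm]] * flags[, nm]
  }
  outcome <- stats::rbinom(n, 1L, stats::plogis(eta))
  comp_prev <- config$complication_prevalences
  comp <- matrix(0L, n, length(comp_prev),
                 dimnames = list(NULL, names(comp_prev)))
  for (j in seq_along(comp_prev)) {
    comp[, j] <- stats::rbinom(n, 1L, comp_prev[j])
  }
  cond_text <- comp_text <- rep("", n)
  if (render_text) {
    for (i in seq_len(n)) {
      set.seed(record_stream_seed(config$seed, i))
      cond_text[i] <- render_condition_text(flags[i, ], lexicon,
                                            config$noise)
      comp_flags <- c(gdm = outcome[i], comp[i, ])
      comp_text[i] <- render_condition_text(comp_flags,
                                            complications_lexicon,
                                            config$noise)
    }
  }
  record_id <- sprintf("R%06d", seq_len(n))
  records <- data.frame(record_id = record_id, maternal_age = age,
                        bmi = bmi, parity = parity, ethnicity = ethnicity,
                        medical_conditions_text = cond_text,
                        complications_text = comp_text,
                        stringsAsFactors = FALSE)
  truth <- data.frame(record_id = record_id, flags, cluster_id = cluster_id,
                      outcome = outcome, stringsAsFactors = FALSE,
                      check.names = FALSE)
  list(records = records, truth = truth)
}
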