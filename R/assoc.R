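#' Build a 2x2 contingency table from binary vectors
#'
#' Layout: rows = exposure (no, yes), columns = outcome (no, yes), with
#' cells `a` = (no, no), `b` = (no, yes), `c` = (yes, no), `d` = (yes, yes).
#'
#' @param exposure_flags,outcome_flags equal-length 0/1 vectors.
#' @return object of class `contingency_2x2`: list with integer cells
#'   `a, b, c, d` and margins `r1, r2, c1, c2, N`.
#' @export
contingency_2x2 <- function(exposure_flags, outcome_flags) {
  if (length(exposure_flags) != length(outcome_flags)) {
    stop("exposure and outcome vectors must have equal length", call. = FALSE)
  }
  e <- as.integer(exposure_flags); o <- as.integer(outcome_flags)
  if (anyNA(e) || anyNA(o) || !all(e %in% 0:1) || !all(o %in% 0:1)) {
    stop("flags must be binary 0/1", call. = FALSE)
  }
  new_table2x2(a = sum(e == 0L & o == 0L), b = sum(e == 0L & o == 1L),
               c = sum(e == 1L & o == 0L), d = sum(e == 1L & o == 1L))
}

#' Construct a 2x2 table directly from its four cells
#'
#' Useful for published tables where only the cell counts are printed.
#'
#' @param a,b,c,d non-negative integer counts in the
#'   [contingency_2x2()] layout.
#' @return object of class `contingency_2x2`.
#' @export
new_table2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) < 1) stop("table must contain at least one observation",
                           call. = FALSE)
  structure(list(a = a, b = b, c = c, d = d,
                 r1 = a + b, r2 = c + d, c1 = a + c, c2 = b + d,
                 N = a + b + c + d),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(exposure = c("no", "yes"),
                              outcome = c("no", "yes")))
  print(m)
  invisible(x)
}

check_margins <- function(t) {
  if (any(c(t$r1, t$r2, t$c1, t$c2) == 0)) {
    stop("chi-square statistic undefined: a table margin is zero",
         call. = FALSE)
  }
}

#' Pearson chi-square statistic (uncorrected), 2x2
#'
#' `N (ad - bc)^2 / (r1 r2 c1 c2)`, algebraically identical to the cellwise
#' sum of `(O - E)^2 / E`.
#'
#' @param t a [contingency_2x2()] table with all margins positive.
#' @return the statistic (non-negative real).
#' @export
chi_square_uncorrected <- function(t) {
  check_margins(t)
  # counts are stored as integers; products overflow 32-bit, so go double
  a <- as.numeric(t$a); b <- as.numeric(t$b)
  c <- as.numeric(t$c); d <- as.numeric(t$d)
  N <- a + b + c + d
  N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

#' Continuity-corrected (Yates) chi-square statistic, 2x2
#'
#' `N (max(|ad - bc| - N/2, 0))^2 / (r1 r2 c1 c2)`. This is the form that
#' reproduces the published condition-by-GDM association statistics and is
#' the default reported statistic throughout the package.
#'
#' @inheritParams chi_square_uncorrected
#' @return the corrected statistic (non-negative, never exceeding the
#'   uncorrected one).
#' @export
chi_square_corrected <- function(t) {
  check_margins(t)
  a <- as.numeric(t$a); b <- as.numeric(t$b)
  c <- as.numeric(t$c); d <- as.numeric(t$d)
  N <- a + b + c + d
  N * max(abs(a * d - b * c) - N / 2, 0)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

#' Upper-tail chi-square p-value, 1 degree of freedom
#'
#' @param stat non-negative statistic.
#' @return p-value in `[0, 1]`, strictly decreasing in `stat`.
#' @export
chi2_pvalue_1df <- function(stat) {
  if (any(stat < 0)) stop("statistic must be non-negative", call. = FALSE)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Phi coefficient of a 2x2 table
#'
#' `(ad - bc) / sqrt(r1 r2 c1 c2)`; the signed effect size satisfying
#' `phi^2 * N = ` uncorrected chi-square.
#'
#' @inheritParams chi_square_uncorrected
#' @return real in `[-1, 1]`.
#' @export
phi_coefficient <- function(t) {
  check_margins(t)
  a <- as.numeric(t$a); b <- as.numeric(t$b)
  c <- as.numeric(t$c); d <- as.numeric(t$d)
  (a * d - b * c) /
    (sqrt(a + b) * sqrt(c + d) * sqrt(a + c) * sqrt(b + d))
}

#' Test one exposure/outcome pair
#'
#' @param exposure_flags,outcome_flags equal-length 0/1 vectors.
#' @param exposure,outcome identifiers carried into the result.
#' @return a one-row data.frame (see [associate_all()] for columns).
#' @export
association_test <- function(exposure_flags, outcome_flags,
                             exposure = "exposure", outcome = "outcome") {
  t <- contingency_2x2(exposure_flags, outcome_flags)
  degenerate <- any(c(t$r1, t$r2, t$c1, t$c2) == 0)
  if (degenerate) {
    chi2c <- chi2u <- p <- phi <- NA_real_
  } else {
    chi2c <- chi_square_corrected(t)
    chi2u <- chi_square_uncorrected(t)
    p <- chi2_pvalue_1df(chi2c)
    phi <- phi_coefficient(t)
  }
  data.frame(exposure = exposure, outcome = outcome,
             a = t$a, b = t$b, c = t$c, d = t$d,
             chi2_corrected = chi2c, chi2_uncorrected = chi2u,
             p_value = p, phi = phi, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Screen all morbidity-by-complication pairs
#'
#' Cross-tabulates every exposure column against every outcome column and
#' computes the corrected and uncorrected chi-square, the df = 1 p-value
#' (from the corrected statistic, the reported form) and the phi
#' coefficient. Pairs with a zero margin are flagged `degenerate` and carry
#' `NA` statistics rather than pseudo-count patches.
#'
#' @param profiles data.frame holding the exposure 0/1 columns (typically a
#'   [extract_cohort()] result).
#' @param complication_flags data.frame holding the outcome 0/1 columns.
#' @param exposures,outcomes character vectors of column names; default all
#'   0/1 condition columns of `profiles` and all columns of
#'   `complication_flags`.
#' @param p_adjust one of `"none"` (default, raw screening), `"bonferroni"`
#'   or `"BH"`; adds an adjusted `p_adjusted` column.
#' @return data.frame of class `association_results`, one row per pair.
#' @export
associate_all <- function(profiles, complication_flags,
                          exposures = NULL, outcomes = NULL,
                          p_adjust = c("none", "bonferroni", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (is.null(exposures)) {
    exposures <- setdiff(names(profiles),
                         c("record_id", "morbidity_count", "burden_class"))
  }
  if (is.null(outcomes)) outcomes <- names(complication_flags)
  bad <- c(setdiff(exposures, names(profiles)),
           setdiff(outcomes, names(complication_flags)))
  if (length(bad)) {
    stop("unknown column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (nrow(profiles) != nrow(complication_flags)) {
    stop("profiles and complication flags must cover the same records",
         call. = FALSE)
  }
  rows <- vector("list", length(exposures) * length(outcomes))
  i <- 0L
  for (e in exposures) {
    for (o in outcomes) {
      i <- i + 1L
      rows[[i]] <- association_test(profiles[[e]], complication_flags[[o]],
                                    exposure = e, outcome = o)
    }
  }
  out <- do.call(rbind, rows)
  if (p_adjust != "none") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  }
  rownames(out) <- NULL
  class(out) <- c("association_results", "data.frame")
  out
}

#' @export
print.association_results <- function(x, digits = 3, max_rows = 20L, ...) {
  cat("Association screen:", nrow(x), "exposure x outcome pairs",
      if (any(x$degenerate)) paste0("(", sum(x$degenerate), " degenerate)"),
      "\n")
  y <- as.data.frame(x)[seq_len(min(nrow(x), max_rows)), ]
  if (!is.null(y$p_value)) y$p_value <- format_pvalue(y$p_value)
  for (col in intersect(c("chi2_corrected", "chi2_uncorrected", "phi"),
                        names(y))) {
    y[[col]] <- signif(y[[col]], digits)
  }
  print(y)
  if (nrow(x) > max_rows) cat("...", nrow(x) - max_rows, "more rows\n")
  invisible(x)
}

# published-table style: "<0.001" below the reporting threshold
format_pvalue <- function(p, threshold = 0.001) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < threshold, paste0("<", format(threshold)),
                formatC(p, format = "g", digits = 3)))
}

#' Rank associations by significance
#'
#' Ascending p-value; ties broken by descending corrected chi-square, then
#' lexicographic exposure/outcome name. Degenerate pairs are excluded.
#'
#' @param results an [associate_all()] result.
#' @param k number of top associations to return.
#' @return data.frame of the first `k` ranked rows.
#' @export
rank_associations <- function(results, k = 40L) {
  r <- results[!results$degenerate, , drop = FALSE]
  ord <- order(r$p_value, -r$chi2_corrected, r$exposure, r$outcome)
  out <- r[ord, , drop = FALSE][seq_len(min(k, nrow(r))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-k complications per morbidity
#'
#' For each exposure, its `k` smallest-p outcomes (same tie-break as
#' [rank_associations()]); degenerate pairs are excluded.
#'
#' @param results an [associate_all()] result.
#' @param k outcomes per exposure (default 3).
#' @return named list: exposure id -> character vector of outcome ids.
#' @export
top_complications_per_morbidity <- function(results, k = 3L) {
  r <- results[!results$degenerate, , drop = FALSE]
  out <- lapply(split(r, r$exposure), function(g) {
    ord <- order(g$p_value, -g$chi2_corrected, g$outcome)
    utils::head(g$outcome[ord], k)
  })
  out[unique(r$exposure)]
}
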