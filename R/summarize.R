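# rounding half away from zero, matching the printed-table style
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Multimorbidity burden distribution
#'
#' Tabulates the number of records at each morbidity count (0, 1, 2, ...)
#' with cohort percentages (one decimal, half away from zero), and totals
#' for the three burden classes: none (0 conditions), single (1) and
#' multimorbidity (>= 2).
#'
#' @param profiles a [extract_cohort()] result, or any data.frame with a
#'   `morbidity_count` column.
#' @param digits decimal places for percentages.
#' @return object of class `burden_distribution`: list with `by_count`
#'   (data.frame: count, n, percent), `classes` (named counts for
#'   none/single/multimorbidity), `class_percent`, and `n_total`.
#' @export
burden_distribution <- function(profiles, digits = 1L) {
  if (NROW(profiles) == 0L) stop("profiles table is empty", call. = FALSE)
  cnt <- profiles$morbidity_count
  stopifnot(!is.null(cnt))
  tab <- table(factor(cnt, levels = 0:max(cnt)))
  by_count <- data.frame(count = as.integer(names(tab)), n = as.integer(tab))
  by_count <- by_count[by_count$n > 0L, , drop = FALSE]
  n_total <- length(cnt)
  by_count$percent <- round_half_up(100 * by_count$n / n_total, digits)
  cls <- table(burden_class(cnt))
  structure(list(
    by_count = by_count,
    classes = setNames(as.integer(cls), names(cls)),
    class_percent = setNames(round_half_up(100 * as.integer(cls) / n_total,
                                           digits), names(cls)),
    n_total = n_total
  ), class = "burden_distribution")
}

#' @export
print.burden_distribution <- function(x, ...) {
  cat("Burden distribution over", x$n_total, "records\n")
  print(x$by_count, row.names = FALSE)
  cat(sprintf("none %d (%.1f%%), single %d (%.1f%%), multimorbidity %d (%.1f%%)\n",
              x$classes["none"], x$class_percent["none"],
              x$classes["single"], x$class_percent["single"],
              x$classes["multimorbidity"], x$class_percent["multimorbidity"]))
  invisible(x)
}

# default strata reproducing the published baseline-characteristics bands;
# bands are half-open [lower, upper) so a BMI of 24.95 compares against 25.0
# without any rounding step
default_strata_bounds <- function(var) {
  switch(var,
    maternal_age = list(labels = c("<=24", "25-29", "30-34", "35-39", ">=40"),
                        lower = c(-Inf, 25, 30, 35, 40),
                        upper = c(25, 30, 35, 40, Inf)),
    bmi = list(labels = c("<=19.9", "20-24.9", "25-26.9", "27-29.9",
                          "30-34.9", "35+"),
               lower = c(-Inf, 20, 25, 27, 30, 35),
               upper = c(20, 25, 27, 30, 35, Inf)),
    NULL)
}

#' Burden by stratum cross-tabulation
#'
#' Cross-tabulates the burden class against strata of a record variable:
#' numeric variables are banded by half-open `[lower, upper)` intervals
#' (defaults reproduce the published age and BMI bands); categorical
#' variables (ethnicity, parity) or 0/1 flag columns stratify by value.
#'
#' @param profiles a [extract_cohort()] result.
#' @param records the cohort table the profiles were extracted from.
#' @param strata_var column of `records` to stratify by (e.g.
#'   `"maternal_age"`, `"bmi"`, `"ethnicity"`).
#' @param strata_bounds optional list with `labels`, `lower`, `upper`
#'   defining disjoint exhaustive half-open bands for a numeric variable.
#' @param digits decimal places for column percentages.
#' @return object of class `stratified_table`: data.frame with one row per
#'   stratum: `stratum`, `n_total`, and n/percent per burden class (column
#'   percentages, i.e. within burden class).
#' @export
stratified_table <- function(profiles, records, strata_var,
                             strata_bounds = NULL, digits = 1L) {
  if (!strata_var %in% names(records)) {
    stop("strata variable '", strata_var, "' not found in records",
         call. = FALSE)
  }
  v <- records[[strata_var]]
  if (is.numeric(v) && is.null(strata_bounds)) {
    strata_bounds <- default_strata_bounds(strata_var)
  }
  if (is.numeric(v) && !is.null(strata_bounds)) {
    b <- strata_bounds
    stopifnot(length(b$labels) == length(b$lower),
              length(b$lower) == length(b$upper))
    ord <- order(b$lower)
    if (any(b$upper[ord][-length(ord)] > b$lower[ord][-1])) {
      stop("strata bands overlap", call. = FALSE)
    }
    stratum <- rep(NA_character_, length(v))
    for (i in seq_along(b$labels)) {
      stratum[!is.na(v) & v >= b$lower[i] & v < b$upper[i]] <- b$labels[i]
    }
    stratum <- factor(stratum, levels = b$labels)
  } else {
    stratum <- factor(v)
  }
  cls <- profiles$burden_class
  tab <- table(stratum, cls)
  col_n <- colSums(tab)
  out <- data.frame(stratum = rownames(tab),
                    n_total = as.integer(rowSums(tab)),
                    stringsAsFactors = FALSE)
  for (cl in colnames(tab)) {
    out[[paste0("n_", cl)]] <- as.integer(tab[, cl])
    out[[paste0("pct_", cl)]] <-
      round_half_up(100 * tab[, cl] / max(col_n[cl], 1L), digits)
  }
  rownames(out) <- NULL
  class(out) <- c("stratified_table", "data.frame")
  attr(out, "strata_var") <- strata_var
  out
}

#' @export
print.stratified_table <- function(x, ...) {
  cat("Burden by", attr(x, "strata_var"), "\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
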