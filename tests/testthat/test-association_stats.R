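test_that("2x2 cross-tabulation is exact and validates its input", {
  t <- contingency_2x2(c(0, 0, 1, 1), c(0, 1, 0, 1))
  expect_identical(c(t$a, t$b, t$c, t$d), c(1L, 1L, 1L, 1L))
  expect_error(contingency_2x2(c(0, 1), c(0, 1, 1)), "equal length")
  expect_error(contingency_2x2(c(0, 2), c(0, 1)), "binary")
  set.seed(401)
  e <- rbinom(10000, 1, 0.3); o <- rbinom(10000, 1, 0.2)
  t2 <- contingency_2x2(e, o)
  # brute-force paired counting
  expect_identical(t2$d, sum(e & o))
  expect_identical(t2$a, sum(!e & !o))
  expect_identical(t2$N, 10000L)
})

test_that("uncorrected chi-square agrees with the cellwise (O-E)^2/E oracle", {
  expect_identical(chi_square_uncorrected(new_table2x2(10, 10, 10, 10)), 0)
  expect_identical(chi_square_uncorrected(new_table2x2(10, 0, 0, 10)), 20)
  for (t in random_tables(100, seed = 403)) {
    expect_equal(chi_square_uncorrected(t),
                 oracle_chi2_cellwise(t$a, t$b, t$c, t$d),
                 tolerance = 1e-9)
  }
  expect_error(chi_square_uncorrected(new_table2x2(0, 0, 3, 4)), "margin")
})

test_that("the continuity correction floors at zero and never exceeds the raw statistic", {
  expect_identical(chi_square_corrected(new_table2x2(10, 10, 10, 10)), 0)
  for (t in random_tables(100, seed = 407)) {
    expect_lte(chi_square_corrected(t), chi_square_uncorrected(t))
  }
})

test_that("chi-square statistics are transpose-invariant and scale linearly", {
  for (t in random_tables(30, seed = 409)) {
    tt <- new_table2x2(t$a, t$c, t$b, t$d)  # swap exposure/outcome roles
    expect_equal(chi_square_uncorrected(t), chi_square_uncorrected(tt))
    expect_equal(chi_square_corrected(t), chi_square_corrected(tt))
    expect_equal(abs(phi_coefficient(t)), abs(phi_coefficient(tt)))
    m <- 3L
    ts <- new_table2x2(m * t$a, m * t$b, m * t$c, m * t$d)
    expect_equal(chi_square_uncorrected(ts), m * chi_square_uncorrected(t),
                 tolerance = 1e-12)
  }
})

test_that("df=1 p-values agree with numerical integration of the density", {
  expect_identical(chi2_pvalue_1df(0), 1)
  expect_equal(chi2_pvalue_1df(3.841), 0.05, tolerance = 1e-3)
  for (stat in c(0.01, 0.5, 3.841, 10, 25)) {
    expect_equal(chi2_pvalue_1df(stat), oracle_chi2_pvalue(stat),
                 tolerance = 1e-6)
  }
  stats <- seq(0, 30, by = 0.5)
  expect_true(all(diff(chi2_pvalue_1df(stats)) < 0))
  expect_error(chi2_pvalue_1df(-1), "non-negative")
})

test_that("phi is signed, bounded and tied to the uncorrected statistic", {
  expect_equal(phi_coefficient(new_table2x2(10, 0, 0, 10)), 1)
  expect_equal(phi_coefficient(new_table2x2(0, 10, 10, 0)), -1)
  for (t in random_tables(100, seed = 419)) {
    phi <- phi_coefficient(t)
    expect_true(phi >= -1 && phi <= 1)
    expect_equal(phi^2 * t$N, chi_square_uncorrected(t), tolerance = 1e-9)
  }
})

test_that("associate_all screens the full cartesian grid and flags degeneracy", {
  set.seed(421)
  n <- 400
  profiles <- data.frame(record_id = seq_len(n),
                         cond_a = rbinom(n, 1, 0.4),
                         cond_b = rbinom(n, 1, 0.1),
                         cond_zero = 0L)
  outcomes <- data.frame(out_x = rbinom(n, 1, 0.3),
                         out_y = rbinom(n, 1, 0.05))
  res <- associate_all(profiles, outcomes,
                       exposures = c("cond_a", "cond_b", "cond_zero"))
  expect_identical(nrow(res), 6L)
  expect_true(all(res$degenerate[res$exposure == "cond_zero"]))
  expect_true(all(is.na(res$p_value[res$degenerate])))
  expect_true(all(res$chi2_corrected <= res$chi2_uncorrected, na.rm = TRUE))
  expect_error(associate_all(profiles, outcomes, exposures = "nope"),
               "unknown")
  one <- associate_all(profiles, outcomes, exposures = "cond_a",
                       outcomes = "out_x")
  expect_identical(nrow(one), 1L)
})

test_that("ranking is by p, then corrected statistic, then names, against a sort oracle", {
  set.seed(431)
  res <- do.call(rbind, lapply(random_tables(40, seed = 433), function(t) {
    data.frame(exposure = paste0("e", sample.int(1e6, 1)), outcome = "o",
               a = t$a, b = t$b, c = t$c, d = t$d,
               chi2_corrected = chi_square_corrected(t),
               chi2_uncorrected = chi_square_uncorrected(t),
               p_value = chi2_pvalue_1df(chi_square_corrected(t)),
               phi = phi_coefficient(t), degenerate = FALSE)
  }))
  class(res) <- c("association_results", "data.frame")
  ranked <- rank_associations(res, k = 40)
  oracle <- res[order(res$p_value, -res$chi2_corrected, res$exposure,
                      res$outcome), ]
  expect_identical(ranked$exposure, oracle$exposure)
  expect_identical(nrow(rank_associations(res, k = 0)), 0L)
  expect_identical(nrow(rank_associations(res, k = 5)), 5L)
})

test_that("top complications per morbidity follow the same ordering", {
  set.seed(439)
  n <- 3000
  profiles <- data.frame(exp_a = rbinom(n, 1, 0.3))
  strong <- rbinom(n, 1, plogis(qlogis(0.1) + log(6) * profiles$exp_a))
  outcomes <- data.frame(out_strong = strong,
                         out_null1 = rbinom(n, 1, 0.2),
                         out_null2 = rbinom(n, 1, 0.2))
  res <- associate_all(profiles, outcomes, exposures = "exp_a")
  top <- top_complications_per_morbidity(res, k = 3)
  expect_identical(top$exp_a[1], "out_strong")
  top2 <- top_complications_per_morbidity(res, k = 5)
  expect_identical(length(top2$exp_a), 3L)  # only three outcomes exist
})

test_that("power against a planted odds ratio rises with effect size", {
  set.seed(443)
  reps <- 100; n <- 5000
  power <- vapply(c(1.5, 2, 3), function(or) {
    hits <- 0L
    for (r in seq_len(reps)) {
      e <- rbinom(n, 1, 0.3)
      o <- rbinom(n, 1, plogis(qlogis(0.15) + log(or) * e))
      p <- chi2_pvalue_1df(chi_square_corrected(contingency_2x2(e, o)))
      if (p < 0.05) hits <- hits + 1L
    }
    hits / reps
  }, numeric(1))
  expect_true(all(diff(power) >= 0))
  expect_gt(power[3], 0.99)
})
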