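test_that("matcher sets flags for exact keyword and phrase hits", {
  lex <- mini_lexicon()
  f <- match_conditions(c("hx", "depression", "ptsd"), lex)
  expect_identical(unname(f["mental_disorders"]), 1L)
  expect_identical(sum(f), 1L)
  expect_identical(sum(match_conditions(character(0), lex)), 0L)
})

test_that("fuzzy matching straddles the similarity threshold as scored", {
  lex <- mini_lexicon()
  f80 <- match_conditions("astma", lex,
                          extraction_config(default_fuzzy_threshold = 80))
  f90 <- match_conditions("astma", lex,
                          extraction_config(default_fuzzy_threshold = 90))
  expect_identical(unname(f80["asthma"]), 1L)
  expect_identical(sum(f90), 0L)
})

test_that("phrase spans are consumed longest-first and exclusions suppress", {
  lex <- mini_lexicon()
  f <- match_conditions(c("iron", "deficiency", "anaemia"), lex)
  expect_identical(unname(f["iron_deficiency_anemia"]), 1L)
  expect_identical(unname(f["blood_disorders"]), 0L)
  # generic anaemia alone maps to the blood-disorders condition
  f2 <- match_conditions("anaemia", lex)
  expect_identical(unname(f2["blood_disorders"]), 1L)
  # exclusion phrase consumes its span without setting the flag
  f3 <- match_conditions(c("gestational", "diabetes"), lex)
  expect_identical(unname(f3["diabetes"]), 0L)
  f4 <- match_conditions("diabetes", lex)
  expect_identical(unname(f4["diabetes"]), 1L)
})

test_that("lowering the fuzzy threshold never unsets a flag", {
  lex <- default_lexicon()
  set.seed(59)
  for (i in 1:30) {
    tokens <- c(paste(sample(letters, 7, TRUE), collapse = ""),
                "asthmaa", "migrane", "depresion")
    prev <- NULL
    for (thr in c(95, 90, 85, 80, 70)) {
      f <- match_conditions(tokens, lex,
                            extraction_config(default_fuzzy_threshold = thr))
      if (!is.null(prev)) expect_true(all(f >= prev))
      prev <- f
    }
  }
})

test_that("BMI flags use inclusive cut-points and are mutually exclusive", {
  cfg <- extraction_config()
  expect_identical(derive_bmi_flags(c(24.99, 25.0, 29.99, 30.0, NA), cfg),
                   data.frame(overweight = c(0L, 1L, 1L, 0L, 0L),
                              obesity = c(0L, 0L, 0L, 1L, 0L)))
  expect_error(derive_bmi_flags(-1, cfg), "positive")
  set.seed(61)
  bmi <- c(runif(500, 10, 60), rep(NA, 10))
  fl <- derive_bmi_flags(bmi, cfg)
  expect_true(all(fl$overweight + fl$obesity <= 1))
})

test_that("advanced age is >= 35 with missing treated as unexposed", {
  expect_identical(derive_advanced_age(c(34, 35, NA)), c(0L, 1L, 0L))
  expect_error(derive_advanced_age(-2), "non-negative")
})

test_that("extract_cohort combines text, BMI and age into burden classes", {
  rec <- data.frame(record_id = c("r1", "r2"),
                    maternal_age = c(28, 36), bmi = c(22, 31),
                    medical_conditions_text = c("", "PCOS; hypothyroid"),
                    stringsAsFactors = FALSE)
  pr <- extract_cohort(rec)
  expect_identical(sum(as.matrix(pr[1, !names(pr) %in%
                                      c("record_id", "burden_class")])), 0L)
  expect_identical(as.character(pr$burden_class[1]), "none")
  expect_identical(unname(pr$pcos[2]), 1L)
  expect_identical(unname(pr$thyroid_disease[2]), 1L)
  expect_identical(unname(pr$obesity[2]), 1L)
  expect_identical(unname(pr$advanced_age[2]), 1L)
  # advanced age is excluded from the default counted set
  expect_identical(pr$morbidity_count[2], 3L)
  expect_identical(as.character(pr$burden_class[2]), "multimorbidity")
  expect_error(extract_cohort(rec[, -2]), "maternal_age")
})

test_that("zero-noise synthetic text is recovered exactly", {
  cfg <- simulation_config(n_records = 500, seed = 101, noise = no_noise)
  g <- generate_cohort(cfg)
  pr <- extract_cohort(g$records)
  conds <- setdiff(names(g$truth), c("record_id", "cluster_id", "outcome"))
  expect_identical(unname(as.matrix(pr[, conds])),
                   unname(as.matrix(g$truth[, conds])))
})

test_that("extraction has no cross-record state: permuting rows permutes output", {
  cfg <- simulation_config(n_records = 80, seed = 103)
  g <- generate_cohort(cfg)
  pr <- extract_cohort(g$records)
  set.seed(5)
  perm <- sample.int(nrow(g$records))
  pr_perm <- extract_cohort(g$records[perm, ])
  reindexed <- as.data.frame(pr)[perm, ]
  rownames(reindexed) <- NULL
  out <- as.data.frame(pr_perm)
  rownames(out) <- NULL
  expect_identical(out, reindexed)
})
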