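# Independent oracles used to freeze expected values; each is deliberately
# written as the slow, obvious computation, never sharing code with the
# package internals it checks.

# full dynamic-programming unit-cost edit distance table
dp_edit_distance <- function(a, b) {
  sa <- strsplit(a, "")[[1]]
  sb <- strsplit(b, "")[[1]]
  n <- length(sa); m <- length(sb)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1L] <- 0:n
  D[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (sa[i] == sb[j]) 0L else 1L
      D[i + 1L, j + 1L] <- min(D[i, j + 1L] + 1L,
                               D[i + 1L, j] + 1L,
                               D[i, j] + cost)
    }
  }
  D[n + 1L, m + 1L]
}

oracle_similarity <- function(a, b) {
  round(100 * (1 - dp_edit_distance(a, b) / max(nchar(a), nchar(b))))
}

# brute-force mapping-based term recount
oracle_term_counts <- function(corpus) {
  env <- new.env(parent = emptyenv())
  for (doc in corpus) {
    for (tok in doc) {
      assign(tok, (if (exists(tok, envir = env)) get(tok, envir = env) else 0L) + 1L,
             envir = env)
    }
  }
  counts <- vapply(ls(env), get, integer(1), envir = env)
  counts[order(-counts, names(counts))]
}

# cellwise (O - E)^2 / E chi-square
oracle_chi2_cellwise <- function(a, b, c, d) {
  obs <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  N <- sum(obs)
  E <- outer(rowSums(obs), colSums(obs)) / N
  sum((obs - E)^2 / E)
}

# upper-tail df=1 chi-square probability by numerical integration
oracle_chi2_pvalue <- function(stat) {
  dens <- function(x) exp(-x / 2) / (sqrt(2 * pi) * sqrt(x))
  if (stat == 0) return(1)
  stats::integrate(dens, stat, Inf, rel.tol = 1e-10)$value
}

# random non-degenerate 2x2 tables
random_tables <- function(n, seed, max_cell = 500L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    repeat {
      cells <- sample.int(max_cell, 4L, replace = TRUE)
      t <- list(a = cells[1], b = cells[2], c = cells[3], d = cells[4])
      if (all(c(t$a + t$b, t$c + t$d, t$a + t$c, t$b + t$d) > 0)) {
        return(new_table2x2(t$a, t$b, t$c, t$d))
      }
    }
  })
}

# compact lexicon for focused matcher tests
mini_lexicon <- function() {
  morbidity_lexicon(list(
    asthma = list(display_name = "Asthma", keywords = c("asthma")),
    mental_disorders = list(display_name = "Mental",
                            keywords = c("depression", "ptsd", "anxiety")),
    iron_deficiency_anemia = list(
      display_name = "IDA", keywords = c("iron deficiency anaemia",
                                         "iron deficiency")),
    blood_disorders = list(display_name = "Blood",
                           keywords = c("anaemia", "thalassaemia")),
    diabetes = list(display_name = "DM", keywords = c("diabetes"),
                    exclusions = c("gestational diabetes"))
  ))
}

# lexicon of long single-token keywords for noisy-recall measurements
long_token_lexicon <- function() {
  morbidity_lexicon(list(
    asthma = list(keywords = c("asthma")),
    migraine = list(keywords = c("migraine")),
    hypertension = list(keywords = c("hypertension")),
    infertility = list(keywords = c("infertility")),
    depression = list(keywords = c("depression")),
    epilepsy = list(keywords = c("epilepsy"))
  ))
}

no_noise <- list(typo_rate = 0, abbreviation_rate = 0, filler_rate = 0,
                 uppercase_rate = 0)

# per-condition precision/recall of extracted vs true flags
extraction_pr <- function(profiles, truth, conditions) {
  vapply(conditions, function(cd) {
    ex <- profiles[[cd]]; tr <- truth[[cd]]
    tp <- sum(ex == 1 & tr == 1)
    prec <- if (sum(ex == 1) > 0) tp / sum(ex == 1) else NA_real_
    rec <- if (sum(tr == 1) > 0) tp / sum(tr == 1) else NA_real_
    c(precision = prec, recall = rec)
  }, c(precision = 0, recall = 0))
}

# three well-separated planted Bernoulli comorbidity profiles over 9 conditions
planted_cohort <- function(n = 3000, seed = 501, p_in = 0.9, p_out = 0.1) {
  profiles <- matrix(p_out, 3, 9)
  profiles[1, 1:3] <- p_in; profiles[2, 4:6] <- p_in; profiles[3, 7:9] <- p_in
  colnames(profiles) <- paste0("cond_", letters[1:9])
  cfg <- simulation_config(
    n_records = n,
    cluster_spec = list(weights = c(1, 1, 1) / 3, profiles = profiles),
    seed = seed)
  generate_cohort(cfg, render_text = FALSE)
}
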