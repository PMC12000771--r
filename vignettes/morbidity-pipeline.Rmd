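---
title: "From semi-structured maternity records to multimorbidity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From semi-structured maternity records to multimorbidity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pregmorbid)
```

## The problem

Maternity information systems routinely capture maternal medical conditions
in *semi-structured* columns: a free-text field is filled in only when the
woman has a condition and left empty otherwise, with no vocabulary
constraints. The same condition appears as "Iron deficiency anaemia",
"low ferritin" or "IDA 2019", with typos, stray capitalisation and year
annotations. Before any epidemiology can happen, those fields must be turned
into per-pregnancy binary condition flags. `pregmorbid` implements that
conversion and the analyses built on it: multimorbidity burden description,
association screening against pregnancy complications (gestational diabetes
mellitus, GDM, in particular), and comorbidity phenotyping by clustering.

Because real maternity records cannot be redistributed, the package includes
a synthetic-cohort generator whose output has the same semi-structured shape
*and* a recoverable ground truth, so every stage is testable end to end.

## Extraction model

Extraction is rule-based with a curated lexicon. Each condition id maps to a
set of surface keywords and phrases; a record's text is normalised
(lowercase, punctuation to spaces, digit-only tokens dropped — preserving
clinical shorthand such as `t2dm`), tokenized, and matched in two phases:

1. **Phrases first.** Multi-token phrases are matched as contiguous token
   runs, longest phrase first, and matched spans are *consumed*. This is
   what keeps "iron deficiency anaemia" from also firing the generic
   anaemia keyword, and it is how *exclusions* work: "gestational diabetes"
   consumes its span under the preexisting-diabetes entry without setting
   any flag.
2. **Tokens second.** Each remaining token is compared exactly against all
   single-token keywords; only if exact matching fails is fuzzy matching
   attempted, using the Levenshtein similarity ratio
   `round(100 (1 - D/max(|a|,|b|)))`.

No negation or uncertainty handling is attempted: the data model this
package targets records conditions only when present. Tokens such as "no"
or "denies" are tallied for audit but never interpreted.

### Parameters that matter

* `default_fuzzy_threshold = 85` (0–100). One edit in a 7-letter token
  scores 86 and passes; one edit in a 5-letter token scores 80 and does
  not. Lowering the threshold can only add matches (monotonicity is
  tested), at the cost of precision on short tokens.
* `min_fuzzy_token_length = 5`. Short tokens carry too little signal for
  edit-distance matching; they match exactly or not at all.
* BMI cut-points: overweight is `[25.0, 30.0)` kg/m², obesity `>= 30.0`,
  mutually exclusive by construction; advanced maternal age is `>= 35`
  completed years. Missing BMI or age yields flag 0, never an error —
  absence of evidence, the convention of routinely collected data.
* `conditions_counted_in_burden`: the default counts every lexicon
  condition plus overweight and obesity, and excludes advanced age and
  substance use. The choice follows the shape of the cohort tables this
  mirrors: every high-BMI stratum carries at least one morbidity (so BMI
  categories count), while women of advanced age can be morbidity-free and
  substance use is usually tabulated as a separate characteristic. The set
  is configurable because reasonable analyses differ here.

The shipped lexicon covers ~23 conditions. Only the mental-disorders entry
is a published, verbatim clinical keyword set; all other entries are
reconstructed surface forms and are meant to be curated per data source.
One known wrinkle: "substance" sits inside the mental-disorders keyword
list while substance use is a separate analysed condition. The default
keeps them separate; phrase consumption ("substance use"/"substance abuse")
ensures the bare token only fires when it appears alone.

## Association screening

Every morbidity × complication pair is cross-tabulated into a 2×2 table
(rows exposure no/yes, columns outcome no/yes) and summarised by:

* the Pearson chi-square `N(ad - bc)² / (r₁r₂c₁c₂)`,
* its Yates continuity-corrected form
  `N(max(|ad - bc| - N/2, 0))² / (r₁r₂c₁c₂)` — the *reported* statistic,
  chosen because it is the form that reproduces the published
  condition-by-GDM statistics this package's tests pin down,
* the df = 1 upper-tail p-value, and
* the phi coefficient `(ad - bc)/√(r₁r₂c₁c₂)`, the signed effect size with
  `φ²N` equal to the uncorrected chi-square (asserted to 1e-9 in tests).

Degenerate tables (a zero margin) are flagged and carry `NA` statistics
rather than pseudo-count patches; transparency beats convention here. No
multiple-testing adjustment is applied by default, matching the raw
`p < 0.05` screening style of the analyses this reproduces; Bonferroni and
Benjamini–Hochberg adjustments are available via `p_adjust`.

## Comorbidity clustering

Records are vectorised as binary condition indicators by default (count and
TF-IDF modes exist for the text-vectorizer route; TF-IDF uses
`idf(t) = ln((1+N)/(1+df(t))) + 1` with unit-norm rows). Binary flags are
the default because they are reproducible from any lexicon without the
original raw strings.

K-means is fitted with k-means++ initialisation, Lloyd iteration, and the
best of `n_init = 10` restarts (max 300 sweeps, centroid-shift tolerance
1e-4). An emptied cluster is repaired deterministically by relocating its
centroid to the point farthest from its current centroid. The cluster count
is chosen by the elbow method, formalised as the point of the inertia-vs-k
polyline (both axes rescaled to [0, 1] so the chord geometry is
scale-free) farthest from the chord between the scan endpoints; ties break
toward smaller k, a flat curve falls back to `k_min` with a warning, and a
manual override (`k_override` in the pipeline) supports domain choices such
as a five-cluster solution. Per-cluster outcome risk is the event
proportion, with pairwise cluster comparisons using the same corrected
chi-square as the association screen.

## What the synthetic generator does and does not emulate

`simulation_config()` defaults encode the cohort conditions the package
targets: marginal condition prevalences (vitamin deficiency 28.9%, blood
disorders 9.9%, ..., substance use 12.4%), age-band weights
(12.7/28.5/36.3/18.2/4.3%) and BMI-band weights
(8.6/39.5/13.7/15.0/12.9/9.8%) from the published baseline table, with
values drawn uniformly within the chosen band (only band frequencies are
published; the printed weights sum to 99.5% from rounding and are
renormalised). The outcome is logistic in the *true* flags — intercept
`logit(0.18)` with moderate odds ratios (1.2–3) on a plausible subset of
conditions, giving a ~21% marginal outcome rate — so measurement error in
extraction can never contaminate the association ground truth. Latent
comorbidity phenotypes are available through `cluster_spec` (mixture
weights plus per-profile condition probabilities).

Text is rendered per record by sampling one keyword per flagged condition,
joined with `"; "`, then perturbed: single-character substitution/deletion
typos per token, occasional abbreviation preference, stray capitalisation,
interleaved filler words and year-like numbers, and occasional trailing
punctuation. Structured variables are drawn vectorised from the master
seed in a fixed column order; text rendering uses an independent substream
per record derived from `(seed, record index)`, so skipping text rendering
(`render_text = FALSE`, useful in large replicate studies) leaves the
truth byte-identical.

What this does *not* emulate — and therefore what passing tests cannot
show about real data: real lexical diversity (synthetic text only uses
surface forms the lexicon already knows, so recall on real records is
bounded by lexicon curation, not by the matcher), negated or uncertain
mentions, abbreviations unknown to the lexicon, multi-condition run-on
narratives, and any correlation between conditions and ethnicity/parity.
The generator measures the pipeline's mechanics, not the lexicon's
clinical completeness.

## Numerical and design choices

* 2×2 statistics are computed in double precision from integer cells
  (32-bit products overflow at cohort scale).
* Percentages round half away from zero to one decimal, the printed-table
  convention; band membership uses half-open `[lower, upper)` intervals so
  a BMI of 24.95 is compared against 25.0 exactly, with no rounding step.
* Term-frequency ties break lexicographically; association ranking breaks
  p-value ties by descending corrected statistic, then names.
* Stop-word removal happens after cleaning and tokenization and only
  affects frequency reports — matching never removes stop words, since
  phrases may legitimately contain them.
* No stemming or lemmatization by default: published keyword sets in this
  domain are surface forms.
* The problem sizes used by the shipped verification suite (cohorts of
  3 000–20 000, 500 null replicates, 1 000 random tables) were chosen as
  the smallest sizes at which the binomial/chi-square error bands in the
  checks are comfortably narrower than the assertion windows.

## Worked example

```{r, eval = FALSE}
library(pregmorbid)

sim <- simulation_config(n_records = 2000, seed = 7)
gen <- generate_cohort(sim)
profiles <- extract_cohort(gen$records)
burden_distribution(profiles)

comp <- complication_flags(gen$records)
res <- associate_all(profiles, comp)
head(rank_associations(res, k = 10))

X <- build_feature_matrix(profiles, "binary")
elbow <- elbow_select_k(X, 1, 8, seed = 7)
model <- attr(elbow, "models")[[as.character(attr(elbow, "chosen_k"))]]
cluster_outcome_risk(model, comp$gdm)
```

Or end to end, writing a verifiable bundle:

```{r, eval = FALSE}
res <- run_pipeline(out_dir = "pregmorbid_out",
                    sim = simulation_config(n_records = 2000, seed = 7),
                    emit_truth = TRUE, seed = 7)
verify_bundle("pregmorbid_out")
```

## Known limitations

* Lexicon fidelity: reconstructed keyword sets cannot claim equivalence to
  any specific study's curated lists; real-data use requires curation
  against the local vocabulary (the unmatched-token report from the
  pipeline log is the starting point).
* The fuzzy matcher handles one-to-two character edits well but not word
  order variation, merged tokens ("irondeficiency") or semantic synonyms.
* Chi-square screening is marginal: it adjusts for nothing and makes no
  causal claim; it ranks candidate associations, no more.
* K-means with binary features is a pragmatic phenotyping device;
  model-based clustering may suit strongly correlated condition sets
  better.
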