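#' Read a cohort table from delimited text
#'
#' Comma-separated, UTF-8, header row; schema: `record_id`, `maternal_age`,
#' `bmi` (may be empty), `parity`, `ethnicity`,
#' `medical_conditions_text`, `complications_text`, plus optional 0/1
#' outcome columns (`gdm`, `preeclampsia`, ...).
#'
#' @param path CSV file path.
#' @return data.frame in the cohort schema.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(record_id = "character"),
                        encoding = "UTF-8")
  required <- c("record_id", "maternal_age", "bmi", "parity", "ethnicity",
                "medical_conditions_text", "complications_text")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("cohort table missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("medical_conditions_text", "complications_text")) {
    df[[col]][is.na(df[[col]])] <- ""
  }
  df
}

write_csv_out <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  path
}

#' Derive complication outcome flags for a cohort
#'
#' Uses explicit 0/1 outcome columns when present; otherwise extracts them
#' from the complications free-text column with the complications lexicon.
#'
#' @param records cohort table.
#' @param complications_lexicon a [morbidity_lexicon()].
#' @param config an [extraction_config()].
#' @return data.frame of 0/1 columns, one row per record.
#' @export
complication_flags <- function(records,
                               complications_lexicon =
                                 default_complications_lexicon(),
                               config = extraction_config()) {
  known <- c("gdm", "preeclampsia", "pih", "preterm", "induction",
             "cesarean", "birth_defect", "scn_nicu", "shoulder_dystocia",
             "macrosomia")
  explicit <- intersect(known, names(records))
  if (length(explicit)) {
    return(as.data.frame(lapply(records[explicit], as.integer)))
  }
  idx <- lexicon_index(complications_lexicon)
  token_lists <- lapply(clean_text(records$complications_text), tokenize)
  flag_mat <- t(vapply(token_lists, match_conditions,
                       setNames(integer(length(idx$conditions)),
                                idx$conditions),
                       lexicon = complications_lexicon, config = config,
                       index = idx))
  as.data.frame(flag_mat)
}

#' Run the full analysis pipeline
#'
#' simulate (optional) -> extract -> summarise -> associate -> cluster ->
#' report. Every intermediate table is written as comma-separated UTF-8
#' text under `out_dir`, and a manifest (`manifest.yaml`) records inputs,
#' seeds, package version and an MD5 checksum per output so a rerun can be
#' verified with [verify_bundle()].
#'
#' @param input path to a cohort CSV, or `NULL` to simulate a cohort.
#' @param out_dir output directory (created if absent).
#' @param lexicon,complications_lexicon lexicon objects or YAML paths;
#'   defaults are the shipped files.
#' @param config an [extraction_config()].
#' @param sim a [simulation_config()] used when `input` is `NULL`.
#' @param emit_truth write the simulation ground truth (`truth.csv`) and
#'   include the outcome column in the cohort file.
#' @param outcomes outcome columns/ids for the association screen.
#' @param k_min,k_max elbow scan range; `k_override` forces the cluster
#'   count (e.g. a domain choice) instead of the elbow pick.
#' @param feature_mode clustering feature representation
#'   (see [build_feature_matrix()]).
#' @param seed seed for clustering (and simulation when `sim` carries no
#'   explicit one).
#' @param top_n_terms,top_k_associations report sizes.
#' @return (invisibly) a list with the in-memory artifacts: `records`,
#'   `profiles`, `burden`, `associations`, `elbow`, `model`, `risk`,
#'   `manifest_path`.
#' @export
run_pipeline <- function(input = NULL, out_dir,
                         lexicon = default_lexicon(),
                         complications_lexicon =
                           default_complications_lexicon(),
                         config = extraction_config(),
                         sim = NULL, emit_truth = FALSE,
                         outcomes = NULL,
                         k_min = 1L, k_max = 8L, k_override = NULL,
                         feature_mode = "binary",
                         seed = 1L, top_n_terms = 25L,
                         top_k_associations = 40L) {
  if (!is.null(k_override) && !is.numeric(k_override)) {
    stop("k_override must be a cluster count", call. = FALSE)
  }
  if (is.character(lexicon)) lexicon <- load_lexicon(lexicon)
  if (is.character(complications_lexicon)) {
    complications_lexicon <- load_lexicon(complications_lexicon)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                    paste0(...)))
  }

  truth <- NULL
  if (is.null(input)) {
    if (is.null(sim)) sim <- simulation_config(seed = seed)
    log_stage("simulate", "n = ", sim$n_records, ", seed = ", sim$seed)
    gen <- generate_cohort(sim, lexicon, complications_lexicon)
    records <- gen$records
    truth <- gen$truth
    cohort_out <- records
    if (emit_truth) {
      cohort_out$gdm <- truth$outcome
      outputs <- c(outputs, write_csv_out(truth,
                                          file.path(out_dir, "truth.csv")))
    }
    outputs <- c(outputs, write_csv_out(cohort_out,
                                        file.path(out_dir, "cohort.csv")))
  } else {
    log_stage("load", input)
    records <- read_cohort(input)
  }

  log_stage("extract", nrow(records), " records")
  profiles <- extract_cohort(records, lexicon, config)
  outputs <- c(outputs, write_csv_out(as.data.frame(profiles),
                                      file.path(out_dir, "profiles.csv")))

  tokens <- lapply(lapply(clean_text(records$medical_conditions_text),
                          tokenize), remove_stopwords)
  tf <- term_frequencies(tokens, top_n = top_n_terms)
  outputs <- c(outputs, write_csv_out(tf, file.path(out_dir,
                                                    "term_frequencies.csv")))

  log_stage("summarize", "burden distribution and strata")
  burden <- burden_distribution(profiles)
  outputs <- c(outputs, write_csv_out(burden$by_count,
                                      file.path(out_dir, "burden_counts.csv")))
  for (v in c("maternal_age", "bmi")) {
    st <- stratified_table(profiles, records, v)
    outputs <- c(outputs,
                 write_csv_out(as.data.frame(st),
                               file.path(out_dir,
                                         paste0("burden_by_", v, ".csv"))))
  }

  log_stage("associate", "morbidity x complication screen")
  comp <- complication_flags(records, complications_lexicon, config)
  if (is.null(outcomes)) outcomes <- names(comp)
  assoc <- associate_all(profiles, comp, outcomes = outcomes)
  outputs <- c(outputs, write_csv_out(as.data.frame(assoc),
                                      file.path(out_dir,
                                                "associations.csv")))
  ranked <- rank_associations(assoc, k = top_k_associations)
  outputs <- c(outputs, write_csv_out(as.data.frame(ranked),
                                      file.path(out_dir,
                                                "associations_ranked.csv")))
  if (any(assoc$degenerate)) {
    log_stage("associate", sum(assoc$degenerate), " degenerate pairs")
  }

  log_stage("cluster", "elbow scan k = ", k_min, "..", k_max)
  X <- build_feature_matrix(profiles, mode = feature_mode)
  elbow <- elbow_select_k(X, k_min = k_min, k_max = k_max, seed = seed)
  outputs <- c(outputs, write_csv_out(as.data.frame(elbow),
                                      file.path(out_dir, "elbow_curve.csv")))
  k_use <- if (is.null(k_override)) attr(elbow, "chosen_k") else k_override
  model <- attr(elbow, "models")[[as.character(k_use)]]
  if (is.null(model)) model <- kmeans_fit(X, k_use, seed = seed + k_use)
  assignments <- data.frame(record_id = records$record_id,
                            cluster = model$assignments - 1L)
  outputs <- c(outputs, write_csv_out(assignments,
                                      file.path(out_dir,
                                                "cluster_assignments.csv")))
  risk <- cluster_outcome_risk(model, comp$gdm)
  outputs <- c(outputs, write_csv_out(risk$risk,
                                      file.path(out_dir,
                                                "cluster_gdm_risk.csv")))

  manifest <- list(
    package = "pregmorbid",
    version = as.character(utils::packageVersion("pregmorbid")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input = if (is.null(input)) "simulated" else normalizePath(input),
    seed = seed,
    simulation_seed = if (is.null(input)) sim$seed else NA,
    k_used = k_use,
    checksums = as.list(tools::md5sum(sort(outputs)))
  )
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  log_stage("report", length(outputs), " artifacts written to ", out_dir)
  invisible(list(records = records, truth = truth, profiles = profiles,
                 term_frequencies = tf, burden = burden,
                 associations = assoc, elbow = elbow, model = model,
                 risk = risk, manifest_path = manifest_path))
}

#' Verify a pipeline output bundle against its manifest
#'
#' Recomputes the MD5 checksum of every artifact listed in
#' `manifest.yaml` and reports mismatches or missing files.
#'
#' @param out_dir directory produced by [run_pipeline()].
#' @return (invisibly) logical: `TRUE` if all artifacts verify.
#' @export
verify_bundle <- function(out_dir) {
  manifest_path <- file.path(out_dir, "manifest.yaml")
  if (!file.exists(manifest_path)) {
    stop("no manifest.yaml in ", out_dir, call. = FALSE)
  }
  manifest <- yaml::read_yaml(manifest_path)
  ok <- TRUE
  for (path in names(manifest$checksums)) {
    f <- if (file.exists(path)) path else
      file.path(out_dir, basename(path))
    if (!file.exists(f)) {
      message("MISSING  ", path); ok <- FALSE; next
    }
    if (unname(tools::md5sum(f)) != manifest$checksums[[path]]) {
      message("CHANGED  ", path); ok <- FALSE
    }
  }
  if (ok) message("all ", length(manifest$checksums),
                  " artifacts verified")
  invisible(ok)
}
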