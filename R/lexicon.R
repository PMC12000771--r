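#' Construct a morbidity lexicon
#'
#' A lexicon maps condition identifiers to the surface keywords and phrases
#' used for rule-based extraction. Keywords are normalised through
#' [clean_text()] on construction, so a phrase like `"Iron Deficiency"` is
#' stored as the token sequence `c("iron", "deficiency")`.
#'
#' @param entries named list; each element a list with `display_name`
#'   (string), `keywords` (character vector of tokens/phrases, non-empty),
#'   optional `exclusions` (phrases whose match suppresses the condition for
#'   the overlapping span) and optional `fuzzy_threshold` (integer 0-100
#'   overriding the extraction default for this condition).
#' @return an object of class `morbidity_lexicon`: a named list of validated
#'   entries, each with `display_name`, `keywords` (list of token vectors),
#'   `exclusions` (list of token vectors) and `fuzzy_threshold` (NA to
#'   inherit the default).
#' @seealso [load_lexicon()], [default_lexicon()]
#' @export
morbidity_lexicon <- function(entries) {
  if (!is.list(entries) || is.null(names(entries)) ||
      any(!nzchar(names(entries)))) {
    stop("lexicon must be a named list of condition entries", call. = FALSE)
  }
  ids <- names(entries)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate condition id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  out <- vector("list", length(ids))
  names(out) <- ids
  for (id in ids) {
    e <- entries[[id]]
    if (!is.list(e)) stop("entry '", id, "' is not a mapping", call. = FALSE)
    kw <- e$keywords
    if (is.null(kw) || length(kw) == 0L) {
      stop("entry '", id, "' has an empty keyword list", call. = FALSE)
    }
    kw_tok <- lapply(clean_text(as.character(kw)), tokenize)
    if (any(lengths(kw_tok) == 0L)) {
      stop("entry '", id, "' has a keyword that is empty after normalisation",
           call. = FALSE)
    }
    ex <- e$exclusions
    ex_tok <- if (is.null(ex) || length(ex) == 0L) list() else
      lapply(clean_text(as.character(ex)), tokenize)
    if (any(lengths(ex_tok) == 0L)) {
      stop("entry '", id, "' has an exclusion empty after normalisation",
           call. = FALSE)
    }
    thr <- e$fuzzy_threshold
    if (is.null(thr)) thr <- NA_integer_
    thr <- as.integer(thr)
    if (!is.na(thr) && (thr < 0L || thr > 100L)) {
      stop("entry '", id, "': fuzzy_threshold must be in [0, 100]",
           call. = FALSE)
    }
    dn <- e$display_name
    if (is.null(dn)) dn <- id
    out[[id]] <- list(display_name = as.character(dn)[1L],
                      keywords = kw_tok, exclusions = ex_tok,
                      fuzzy_threshold = thr)
  }
  structure(out, class = "morbidity_lexicon")
}

#' Load a lexicon from a YAML file
#'
#' The file is a single YAML document mapping condition id to an entry with
#' `display_name`, `keywords`, optional `exclusions` and optional
#' `fuzzy_threshold` (see [morbidity_lexicon()]).
#'
#' @param path path to the YAML lexicon file.
#' @return a validated [morbidity_lexicon()] object.
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) {
    stop("lexicon file not found: ", path, call. = FALSE)
  }
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop("malformed lexicon file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  # yaml silently keeps the last duplicate key, so re-check the raw text
  keys <- grep("^[A-Za-z0-9_]+:", readLines(path, warn = FALSE), value = TRUE)
  keys <- sub(":.*$", "", keys)
  dup <- unique(keys[duplicated(keys)])
  if (length(dup)) {
    stop("duplicate condition id(s) in '", path, "': ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  morbidity_lexicon(raw)
}

#' The shipped default morbidity lexicon
#'
#' Around two dozen condition entries covering the common morbidities of
#' pregnancy (vitamin deficiency, mental disorders, asthma, thyroid disease,
#' PCOS, ...). The mental-disorders keyword list is a published clinical
#' keyword set reproduced verbatim; all other entries are reconstructed
#' surface forms intended to be curated per data source (the file lives at
#' `system.file("extdata", "morbidity_lexicon.yaml", package = "pregmorbid")`).
#'
#' @return a `morbidity_lexicon`.
#' @export
default_lexicon <- function() {
  load_lexicon(system.file("extdata", "morbidity_lexicon.yaml",
                           package = "pregmorbid"))
}

#' The shipped default complications lexicon
#'
#' Same schema as [default_lexicon()], covering the obstetric, labour and
#' fetal complications (GDM, preeclampsia, induction, cesarean, ...) used
#' when a cohort table carries a complications free-text column instead of
#' explicit 0/1 outcome columns.
#'
#' @return a `morbidity_lexicon`.
#' @export
default_complications_lexicon <- function() {
  load_lexicon(system.file("extdata", "complications_lexicon.yaml",
                           package = "pregmorbid"))
}

#' @export
print.morbidity_lexicon <- function(x, ...) {
  nkw <- sum(vapply(x, function(e) length(e$keywords), integer(1)))
  cat("Morbidity lexicon:", length(x), "conditions,", nkw, "keywords\n")
  for (id in names(x)) {
    e <- x[[id]]
    cat(sprintf("  %-24s %s (%d keywords%s)\n", id, e$display_name,
                length(e$keywords),
                if (length(e$exclusions)) paste0(", ", length(e$exclusions),
                                                 " exclusions") else ""))
  }
  invisible(x)
}

# Flattened matching index: phrase table (longest first, exclusions ahead of
# keywords at equal length) plus the single-token keyword map.
lexicon_index <- function(lexicon) {
  stopifnot(inherits(lexicon, "morbidity_lexicon"))
  ph_tokens <- list(); ph_cond <- character(0); ph_excl <- logical(0)
  sg_token <- character(0); sg_cond <- character(0)
  for (id in names(lexicon)) {
    e <- lexicon[[id]]
    for (kw in e$keywords) {
      if (length(kw) > 1L) {
        ph_tokens[[length(ph_tokens) + 1L]] <- kw
        ph_cond <- c(ph_cond, id); ph_excl <- c(ph_excl, FALSE)
      } else {
        sg_token <- c(sg_token, kw); sg_cond <- c(sg_cond, id)
      }
    }
    for (ex in e$exclusions) {
      ph_tokens[[length(ph_tokens) + 1L]] <- ex
      ph_cond <- c(ph_cond, id); ph_excl <- c(ph_excl, TRUE)
    }
  }
  ord <- order(-lengths(ph_tokens), !ph_excl)
  thr <- vapply(lexicon, function(e) e$fuzzy_threshold, integer(1))
  list(conditions = names(lexicon),
       phrases = ph_tokens[ord], phrase_cond = ph_cond[ord],
       phrase_excl = ph_excl[ord],
       single_token = sg_token, single_cond = sg_cond,
       cond_threshold = thr)
}
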