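ACMG_LABELS <- c("benign", "likely_benign", "vus", "likely_pathogenic",
                 "pathogenic")

# criterion -> side/strength of the implemented subset
ACMG_CRITERIA <- tibble::tribble(
  ~criterion, ~side,        ~strength,
  "PVS1",     "pathogenic", "very_strong",
  "PS1",      "pathogenic", "strong",
  "PM1",      "pathogenic", "moderate",
  "PM2",      "pathogenic", "moderate",
  "PM5",      "pathogenic", "moderate",
  "PP3",      "pathogenic", "supporting",
  "PP5",      "pathogenic", "supporting",
  "BA1",      "benign",     "stand_alone",
  "BS1",      "benign",     "strong",
  "BP4",      "benign",     "supporting",
  "BP6",      "benign",     "supporting"
)

# criterion -> evidence class, keyed for the combiner
ACMG_CLASS <- c(PVS1 = "P_vs", PS1 = "P_s", PM1 = "P_m", PM2 = "P_m",
                PM5 = "P_m", PP3 = "P_p", PP5 = "P_p",
                BA1 = "B_sa", BS1 = "B_s", BP4 = "B_p", BP6 = "B_p")

#' Load ACMG evaluation thresholds
#'
#' Numeric cutoffs for the frequency- and predictor-based criteria live in
#' a flat key-value configuration file; nothing is hard-coded. The packaged
#' defaults follow the ACMG/AMP guideline conventions (BA1 allele frequency
#' 0.05; BS1 0.01; PM2 rare cutoff 1e-4; per-predictor deleterious/benign
#' score cutoffs 0.7/0.3; predictor consensus fraction 0.75).
#'
#' @param path Optional path to an alternative configuration file
#'   (tab-separated `key value` lines, `#` comments).
#' @return Named list of thresholds, validated.
#' @export
acmg_config <- function(path = NULL) {
  path <- path %||% otr_extdata("acmg_defaults.cfg")
  kv <- readr::read_tsv(path, comment = "#", col_names = c("key", "value"),
                        col_types = "cd", progress = FALSE)
  cfg <- as.list(stats::setNames(kv$value, kv$key))
  need <- c("af_ba1", "af_bs1", "af_pm2", "predictor_deleterious",
            "predictor_benign", "predictor_consensus")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0) {
    otr_error(paste0("ACMG config is missing key(s): ",
                     paste(missing, collapse = ", ")),
              "oncotherapyr_config_error")
  }
  vals <- unlist(cfg[need])
  if (any(vals < 0 | vals > 1)) {
    otr_error("ACMG config cutoffs must lie in [0, 1]",
              "oncotherapyr_config_error")
  }
  if (!(cfg$af_pm2 < cfg$af_bs1 && cfg$af_bs1 < cfg$af_ba1)) {
    otr_error("ACMG config requires af_pm2 < af_bs1 < af_ba1",
              "oncotherapyr_config_error")
  }
  if (cfg$predictor_benign >= cfg$predictor_deleterious) {
    otr_error("ACMG config requires predictor_benign < predictor_deleterious",
              "oncotherapyr_config_error")
  }
  cfg
}

#' Construct a variant annotation bundle
#'
#' The annotation inputs the ACMG evaluator consumes: population allele
#' frequency, pathogenicity predictor scores, a ClinVar-style clinical
#' assertion, and precomputed knowledge flags.
#'
#' @param population_af Allele frequency in \[0, 1\], or `NA` when the
#'   variant is absent from population databases.
#' @param predictor_scores Named numeric vector of scores in \[0, 1\]
#'   (e.g. `c(revel_like = 0.9, am_like = 0.8)`).
#' @param clinical_assertion One of `pathogenic`, `likely_pathogenic`,
#'   `benign`, `likely_benign`, `vus`, `none`.
#' @param known_pathogenic_same_change Same amino-acid change previously
#'   established pathogenic.
#' @param known_pathogenic_same_residue Different pathogenic change at the
#'   same residue.
#' @param in_hotspot_or_functional_domain Located in a mutational hotspot
#'   or well-established functional domain.
#' @param null_variant_in_lof_gene Null variant in a gene where
#'   loss-of-function is a known disease mechanism.
#' @return A list of class `annotation_bundle`.
#' @export
annotation_bundle <- function(population_af = NA_real_,
                              predictor_scores = numeric(0),
                              clinical_assertion = "none",
                              known_pathogenic_same_change = FALSE,
                              known_pathogenic_same_residue = FALSE,
                              in_hotspot_or_functional_domain = FALSE,
                              null_variant_in_lof_gene = FALSE) {
  if (!is.na(population_af) && (population_af < 0 || population_af > 1)) {
    otr_error("population_af must lie in [0, 1]", "oncotherapyr_config_error")
  }
  if (length(predictor_scores) > 0 &&
      any(predictor_scores < 0 | predictor_scores > 1, na.rm = TRUE)) {
    otr_error("predictor scores must lie in [0, 1]",
              "oncotherapyr_config_error")
  }
  clinical_assertion <- match.arg(clinical_assertion,
                                  c("none", "pathogenic", "likely_pathogenic",
                                    "benign", "likely_benign", "vus"))
  structure(list(
    population_af = population_af,
    predictor_scores = predictor_scores,
    clinical_assertion = clinical_assertion,
    known_pathogenic_same_change = isTRUE(known_pathogenic_same_change),
    known_pathogenic_same_residue = isTRUE(known_pathogenic_same_residue),
    in_hotspot_or_functional_domain = isTRUE(in_hotspot_or_functional_domain),
    null_variant_in_lof_gene = isTRUE(null_variant_in_lof_gene)
  ), class = "annotation_bundle")
}

#' Evaluate ACMG criteria from variant annotations
#'
#' Deterministically maps an [annotation_bundle()] to the triggered subset
#' of implemented ACMG criteria: PVS1 (null variant), PS1 (same change
#' known pathogenic), PM5 (same residue), PM1 (hotspot/domain), PM2
#' (absent or rare in population), PP3/BP4 (predictor consensus), PP5/BP6
#' (clinical assertions), BA1 (common variant, stand-alone benign), BS1
#' (frequency above disease expectation). Every trigger is recorded with
#' the annotation and value that caused it (the derivation trace).
#'
#' @param bundle An [annotation_bundle()].
#' @param config Thresholds from [acmg_config()].
#' @return Tibble with columns `criterion`, `side`, `strength`,
#'   `annotation`, `value`.
#' @export
evaluate_criteria <- function(bundle, config = acmg_config()) {
  stopifnot(inherits(bundle, "annotation_bundle"))
  hits <- list()
  add <- function(criterion, annotation, value) {
    row <- ACMG_CRITERIA[ACMG_CRITERIA$criterion == criterion, ]
    hits[[length(hits) + 1]] <<- mutate(row, annotation = annotation,
                                        value = as.character(value))
  }
  af <- bundle$population_af
  if (bundle$null_variant_in_lof_gene) add("PVS1", "null_variant_in_lof_gene", TRUE)
  if (bundle$known_pathogenic_same_change) add("PS1", "known_pathogenic_same_change", TRUE)
  if (bundle$in_hotspot_or_functional_domain) add("PM1", "in_hotspot_or_functional_domain", TRUE)
  if (is.na(af)) {
    add("PM2", "population_af", "absent")
  } else if (af < config$af_pm2) {
    add("PM2", "population_af", af)
  }
  if (bundle$known_pathogenic_same_residue) add("PM5", "known_pathogenic_same_residue", TRUE)

  scores <- bundle$predictor_scores[!is.na(bundle$predictor_scores)]
  if (length(scores) > 0) {
    frac_del <- mean(scores >= config$predictor_deleterious)
    frac_ben <- mean(scores <= config$predictor_benign)
    if (frac_del >= config$predictor_consensus) {
      add("PP3", "predictor_consensus", round(frac_del, 3))
    }
    if (frac_ben >= config$predictor_consensus) {
      add("BP4", "predictor_consensus", round(frac_ben, 3))
    }
  }
  if (bundle$clinical_assertion %in% c("pathogenic", "likely_pathogenic")) {
    add("PP5", "clinical_assertion", bundle$clinical_assertion)
  }
  if (bundle$clinical_assertion %in% c("benign", "likely_benign")) {
    add("BP6", "clinical_assertion", bundle$clinical_assertion)
  }
  if (!is.na(af) && af > config$af_ba1) add("BA1", "population_af", af)
  if (!is.na(af) && af > config$af_bs1) add("BS1", "population_af", af)

  if (length(hits) == 0) {
    return(mutate(ACMG_CRITERIA[0, ], annotation = character(0),
                  value = character(0)))
  }
  bind_rows(hits)
}

#' Combine triggered ACMG criteria into a five-class label
#'
#' Applies the guideline combining rules for the pathogenic and benign
#' sides. Conflicting evidence (at least one trigger on each side not
#' resolving under the rules) and insufficient evidence both yield `vus`.
#'
#' @param triggered Character vector of criterion codes, or the tibble
#'   returned by [evaluate_criteria()].
#' @return One of `pathogenic`, `likely_pathogenic`, `vus`,
#'   `likely_benign`, `benign`.
#' @export
combine_criteria <- function(triggered) {
  codes <- if (is.data.frame(triggered)) triggered$criterion else triggered
  codes <- unique(codes)
  cls <- ACMG_CLASS[codes]
  if (anyNA(cls)) {
    otr_error(paste0("unknown ACMG criterion code(s): ",
                     paste(codes[is.na(cls)], collapse = ", ")),
              "oncotherapyr_config_error")
  }
  vs <- sum(cls == "P_vs"); s <- sum(cls == "P_s")
  m <- sum(cls == "P_m"); p <- sum(cls == "P_p")
  ba <- sum(cls == "B_sa"); bs <- sum(cls == "B_s")
  bp <- sum(cls == "B_p")

  any_path <- (vs + s + m + p) > 0
  any_ben <- (ba + bs + bp) > 0
  if (any_path && any_ben) return("vus")

  pathogenic <-
    (vs >= 1 && (s >= 1 || m >= 2 || (m == 1 && p >= 1) || p >= 2)) ||
    s >= 2 ||
    (s == 1 && (m >= 3 || (m == 2 && p >= 2) || (m == 1 && p >= 4)))
  if (pathogenic) return("pathogenic")

  likely_pathogenic <-
    (vs >= 1 && m >= 1) ||
    (s == 1 && m >= 1 && m <= 2) ||
    (s == 1 && p >= 2) ||
    m >= 3 ||
    (m == 2 && p >= 2) ||
    (m == 1 && p >= 4)
  if (likely_pathogenic) return("likely_pathogenic")

  if (ba >= 1 || bs >= 2) return("benign")
  if ((bs == 1 && bp >= 1) || bp >= 2) return("likely_benign")
  "vus"
}

#' Classify a variant into the five ACMG categories
#'
#' Convenience wrapper running [evaluate_criteria()] and
#' [combine_criteria()] and keeping the full derivation trace, as shown on
#' an interpretation report's classification tab.
#'
#' @inheritParams evaluate_criteria
#' @return Object of class `acmg_result`: list with `label`, `triggered`
#'   (the trace tibble), and `config`.
#' @export
acmg_classify <- function(bundle, config = acmg_config()) {
  triggered <- evaluate_criteria(bundle, config)
  structure(list(label = combine_criteria(triggered), triggered = triggered,
                 config = config),
            class = "acmg_result")
}

#' @method print acmg_result
#' @export
print.acmg_result <- function(x, ...) {
  cat("<acmg_result> ", x$label, " (", nrow(x$triggered),
      " criteria triggered: ", paste(x$triggered$criterion, collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Tidy an ACMG classification trace
#'
#' @param x An `acmg_result`.
#' @param ... Unused.
#' @return The trace tibble (criterion, side, strength, annotation, value).
#' @export
tidy.acmg_result <- function(x, ...) x$triggered

#' One-row summary of an ACMG classification
#'
#' @param x An `acmg_result`.
#' @param ... Unused.
#' @return Tibble with `label`, `n_triggered`, `n_pathogenic`, `n_benign`.
#' @export
glance.acmg_result <- function(x, ...) {
  tibble(label = x$label, n_triggered = nrow(x$triggered),
         n_pathogenic = sum(x$triggered$side == "pathogenic"),
         n_benign = sum(x$triggered$side == "benign"))
}

#' Prioritize variants for review
#'
#' Stable descending sort by estimated pathogenicity: the default key is
#' the ACMG label (pathogenic > likely pathogenic > VUS > likely benign >
#' benign), ties broken by genomic position (chrom, pos) ascending.
#' Alternative keys are the clinical assertion or any named predictor
#' score column (descending, absent scores last).
#'
#' @param variants Variant tibble carrying an `acmg_label` column (and
#'   optionally `clinical_assertion` or predictor score columns).
#' @param sort_key `"acmg"` (default), `"clinical_assertion"`, or a
#'   predictor score column name.
#' @return The reordered variant tibble.
#' @export
prioritize <- function(variants, sort_key = "acmg") {
  chrom_rank <- function(ch) {
    match(as.character(ch), c(as.character(1:22), "X", "Y", "M", "MT"))
  }
  tie <- order(chrom_rank(variants$chrom), variants$pos)
  v <- variants[tie, , drop = FALSE]
  if (identical(sort_key, "acmg")) {
    key <- match(v$acmg_label, rev(ACMG_LABELS))
  } else if (identical(sort_key, "clinical_assertion")) {
    key <- match(v$clinical_assertion,
                 c("pathogenic", "likely_pathogenic", "vus",
                   "likely_benign", "benign", "none"))
  } else if (sort_key %in% names(v) && is.numeric(v[[sort_key]])) {
    key <- -v[[sort_key]]
  } else {
    valid <- c("acmg", "clinical_assertion",
               names(v)[map_lgl(v, is.numeric)])
    otr_error(paste0("unknown sort key '", sort_key, "'; valid keys: ",
                     paste(valid, collapse = ", ")),
              "oncotherapyr_sort_error")
  }
  v[order(key, na.last = TRUE), , drop = FALSE]
}
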