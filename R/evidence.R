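#' Load the packaged evidence-level mapping configuration
#'
#' The mapping from source-specific evidence codes to harmonized
#' AMP/ASCO/CAP tier letters (A--D) ships as a flat tab-separated
#' configuration file and is fully user-replaceable.
#'
#' @param path Optional path to an alternative mapping file with columns
#'   source, code, tier (no header, `#` comments allowed).
#' @return Tibble with columns `source`, `code`, `tier`.
#' @export
evidence_level_map <- function(path = NULL) {
  path <- path %||% otr_extdata("evidence_level_map.cfg")
  readr::read_tsv(path, comment = "#", col_names = c("source", "code", "tier"),
                  col_types = "ccc", progress = FALSE)
}

#' Map a source-specific response value to a harmonized response type
#'
#' CIViC-like sources: significance values containing "Sensitivity" map to
#' sensitive and values containing "Resistance" to resistant. OncoKB-like
#' sources use the level code: `R1`/`R2` are resistant; `1`, `2`, `3A`,
#' `3B` sensitive. MetaKB-like sources carry a descriptive association
#' phrase mapped by keyword (sensitiv-/respon- vs resist-). Anything else
#' is `unknown`.
#'
#' @param source One of `"civic_like"`, `"oncokb_like"`, `"metakb_like"`.
#' @param raw_value Character vector of raw response/significance values.
#' @return Character vector in `{"sensitive", "resistant", "unknown"}`.
#' @export
map_response_type <- function(source, raw_value) {
  source <- match.arg(source, c("civic_like", "oncokb_like", "metakb_like"))
  raw_value <- as.character(raw_value)
  out <- rep("unknown", length(raw_value))
  if (source == "civic_like") {
    out[str_detect(raw_value, stringr::fixed("Sensitivity", ignore_case = TRUE))] <- "sensitive"
    out[str_detect(raw_value, stringr::fixed("Resistance", ignore_case = TRUE))] <- "resistant"
  } else if (source == "oncokb_like") {
    code <- str_to_upper(str_trim(raw_value))
    out[code %in% c("1", "2", "3A", "3B")] <- "sensitive"
    out[code %in% c("R1", "R2")] <- "resistant"
  } else {
    low <- str_to_lower(raw_value)
    out[str_detect(low, "sensitiv|respon")] <- "sensitive"
    out[str_detect(low, "resist")] <- "resistant"
  }
  out[is.na(raw_value)] <- "unknown"
  out
}

#' Map source evidence codes to AMP/ASCO/CAP tiers
#'
#' @inheritParams map_response_type
#' @param code Character vector of source evidence codes.
#' @param mapping Mapping tibble from [evidence_level_map()].
#' @return Character vector of tier letters `A`--`D`; unmapped codes yield
#'   `NA` with one warning (never an error).
#' @export
map_evidence_level <- function(source, code, mapping = evidence_level_map()) {
  key <- tibble(source = source, code = str_to_upper(str_trim(as.character(code))))
  hit <- left_join(key,
                   mutate(mapping, code = str_to_upper(.data$code)),
                   by = c("source", "code"))
  if (anyNA(hit$tier)) {
    bad <- unique(key$code[is.na(hit$tier)])
    warn(paste0("unmapped evidence code(s) for ", source[1], ": ",
                paste(bad, collapse = ", "), "; tier left unset"))
  }
  hit$tier
}

#' Expand "substitutes" therapy records into single-drug options
#'
#' Evidence rows whose drug interaction is labeled `substitutes` list
#' interchangeable drugs; each such row is expanded into one row per drug
#' (identical otherwise, interaction reset to `none`). All other rows pass
#' through unchanged, so the drug multiset is conserved.
#'
#' @param records Evidence tibble with list-column `drugs` and column
#'   `interaction`.
#' @return Evidence tibble with no remaining `substitutes` rows.
#' @export
split_substitutes <- function(records) {
  if (nrow(records) == 0) return(records)
  is_sub <- records$interaction == "substitutes" &
    lengths(records$drugs) > 1
  keep <- records[!is_sub, , drop = FALSE]
  expand <- records[is_sub, , drop = FALSE]
  if (nrow(expand) > 0) {
    expand <- tidyr::unnest(expand, "drugs") |>
      mutate(drugs = as.list(.data$drugs), interaction = "none")
  }
  out <- bind_rows(keep, expand)
  out$interaction[out$interaction == "substitutes"] <- "none"
  out
}

#' Load an evidence table in one of three knowledge-base dialects
#'
#' Reads a tab-separated evidence file, maps the dialect's columns onto the
#' common schema, and applies the normalization pipeline in order:
#' response type, evidence tier, substitutes splitting, cancer-type
#' normalization, drug classification. Therapy rows with an empty drug
#' field are rejected and counted (warning; count in the `"n_skipped"`
#' attribute).
#'
#' Expected columns per dialect (tab-separated, named header row):
#' * `civic_like`: gene, variant, disease, drugs, drug_interaction_type,
#'   significance, evidence_level, evidence_statement, citation_id
#' * `oncokb_like`: gene, alteration, cancer_type, drugs, level, statement,
#'   citation_id
#' * `metakb_like`: gene, variant, disease, therapies, association,
#'   evidence_label, statement, citation_id
#'
#' Multiple drugs within one record are `;`-separated.
#'
#' @param path Path to the evidence TSV.
#' @param dialect One of `"civic_like"`, `"oncokb_like"`, `"metakb_like"`.
#' @param level_mapping Tier mapping, see [evidence_level_map()].
#' @param cancer_types Cancer-type table, see [read_cancer_types()];
#'   `NULL` skips cancer-type normalization.
#' @param drug_classes Drug-class table, see [read_drug_classes()];
#'   `NULL` leaves drugs unclassified.
#' @param fuzzy_threshold Similarity threshold for cancer-type matching.
#' @return A normalized evidence tibble with columns `source`,
#'   `biomarker_gene`, `biomarker_spec`, `cancer_type_raw`,
#'   `cancer_type_main`, `drugs` (list), `drug_classes` (list),
#'   `interaction`, `response`, `evidence_level_raw`, `amp_tier`,
#'   `statement`, `citation_id`.
#' @export
load_evidence_source <- function(path, dialect = c("civic_like", "oncokb_like",
                                                   "metakb_like"),
                                 level_mapping = evidence_level_map(),
                                 cancer_types = read_cancer_types(),
                                 drug_classes = read_drug_classes(),
                                 fuzzy_threshold = 0.85) {
  dialect <- match.arg(dialect)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  cols <- switch(dialect,
    civic_like = c(gene = "gene", spec = "variant", cancer = "disease",
                   drugs = "drugs", interaction = "drug_interaction_type",
                   response_raw = "significance", level = "evidence_level",
                   statement = "evidence_statement", citation = "citation_id"),
    oncokb_like = c(gene = "gene", spec = "alteration", cancer = "cancer_type",
                    drugs = "drugs", interaction = NA, response_raw = "level",
                    level = "level", statement = "statement",
                    citation = "citation_id"),
    metakb_like = c(gene = "gene", spec = "variant", cancer = "disease",
                    drugs = "therapies", interaction = NA,
                    response_raw = "association", level = "evidence_label",
                    statement = "statement", citation = "citation_id"))
  need <- unname(cols[!is.na(cols)])
  missing <- setdiff(need, colnames(raw))
  if (length(missing) > 0) {
    otr_error(paste0(dialect, " evidence file is missing column(s): ",
                     paste(missing, collapse = ", ")),
              "oncotherapyr_format_error")
  }
  get <- function(key) {
    if (is.na(cols[[key]])) rep(NA_character_, nrow(raw)) else raw[[cols[[key]]]]
  }
  rec <- tibble(
    source = dialect,
    biomarker_gene = str_to_upper(str_trim(get("gene"))),
    biomarker_spec = str_trim(get("spec")),
    cancer_type_raw = get("cancer"),
    drugs = map(get("drugs"), function(d) {
      if (is.na(d) || !nzchar(str_trim(d))) character(0)
      else normalize_label(str_split(d, ";")[[1]])
    }),
    interaction = tolower(dplyr::coalesce(get("interaction"), "none")),
    response = map_response_type(dialect, get("response_raw")),
    evidence_level_raw = str_trim(get("level")),
    statement = get("statement"),
    citation_id = str_trim(get("citation"))
  )
  rec$interaction[!rec$interaction %in% c("none", "substitutes", "combination")] <- "none"

  # therapy records must name at least one drug
  empty <- lengths(rec$drugs) == 0
  if (any(empty)) {
    warn(paste0(sum(empty), " ", dialect,
                " record(s) without a drug were skipped"))
    rec <- rec[!empty, , drop = FALSE]
  }

  rec$amp_tier <- suppressWarnings(
    map_evidence_level(dialect, rec$evidence_level_raw, level_mapping))
  if (anyNA(rec$amp_tier)) {
    warn(paste0(sum(is.na(rec$amp_tier)), " ", dialect,
                " record(s) carry an unmapped evidence code; tier unset"))
  }
  rec <- split_substitutes(rec)
  rec$cancer_type_main <- if (is.null(cancer_types)) "Unmatched" else
    normalize_cancer_type(rec$cancer_type_raw, cancer_types,
                          threshold = fuzzy_threshold)
  rec$drug_classes <- map(rec$drugs, classify_drug, table = drug_classes)
  arrange(rec, .data$biomarker_gene, .data$biomarker_spec, .data$citation_id) |>
    structure(n_skipped = sum(empty))
}
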