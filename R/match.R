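MATCH_TYPES <- c("exact", "same_pos_other_aa", "same_pos_any", "same_exon",
                 "gene_level")

#' Parse knowledge-base biomarker specifications
#'
#' Classifies biomarker strings as printed by clinical knowledge bases into
#' one of four kinds: an exact protein change (`"G12A"`), a positional
#' specification with arbitrary exchange (`"G12"`), an exon specification
#' (`"exon 2"`, `"Exon 2 mutation"`), or a gene-level specification
#' (`"mutation"`, `"Oncogenic Mutations"`, empty).
#'
#' @param spec Character vector of biomarker specification strings
#'   (gene symbol not included).
#' @return Tibble with columns `spec`, `spec_kind` (`exact`, `positional`,
#'   `exon`, `gene`, `other`), `spec_ref`, `spec_pos`, `spec_alt`,
#'   `spec_exon`.
#' @export
parse_biomarker_spec <- function(spec) {
  spec <- as.character(spec)
  out <- tibble(spec = spec, spec_kind = "other",
                spec_ref = NA_character_, spec_pos = NA_integer_,
                spec_alt = NA_character_, spec_exon = NA_integer_)
  s <- str_trim(dplyr::coalesce(spec, ""))

  gene_lvl <- !nzchar(s) |
    str_detect(str_to_lower(s), "^((oncogenic\\s+)?mutations?|any\\s+mutation(\\s+in\\s+gene)?|alteration)$")
  out$spec_kind[gene_lvl] <- "gene"

  m <- str_match(s, stringr::regex("^exon\\s+([0-9]+)(\\s+mutations?)?$",
                                   ignore_case = TRUE))
  has_exon <- !is.na(m[, 1])
  out$spec_kind[has_exon] <- "exon"
  out$spec_exon[has_exon] <- as.integer(m[has_exon, 2])

  m <- str_match(s, "^(?:p\\.)?([A-Z])([0-9]+)([A-Z\\*])$")
  has_exact <- !is.na(m[, 1]) & m[, 2] %in% AA1 & m[, 4] %in% AA1
  out$spec_kind[has_exact] <- "exact"
  out$spec_ref[has_exact] <- m[has_exact, 2]
  out$spec_pos[has_exact] <- as.integer(m[has_exact, 3])
  out$spec_alt[has_exact] <- m[has_exact, 4]

  m <- str_match(s, "^(?:p\\.)?([A-Z])([0-9]+)$")
  has_pos <- !is.na(m[, 1]) & m[, 2] %in% AA1
  out$spec_kind[has_pos] <- "positional"
  out$spec_ref[has_pos] <- m[has_pos, 2]
  out$spec_pos[has_pos] <- as.integer(m[has_pos, 3])
  out
}

#' Match clinical evidence to a variant at five specificity levels
#'
#' Searches a normalized evidence table for records applying to a
#' protein-level variant, at five match types in decreasing specificity:
#'
#' 1. `exact` -- the identical amino-acid exchange,
#' 2. `same_pos_other_aa` -- a different exchange at the same residue,
#' 3. `same_pos_any` -- a positional biomarker with arbitrary exchange,
#' 4. `same_exon` -- a biomarker in the same exon (requires a
#'    [transcript_annotation()]; skipped with a warning otherwise),
#' 5. `gene_level` -- evidence on any mutation in the gene.
#'
#' Every evidence record is returned at most once, labeled with the most
#' specific match type it satisfies; broader matches are not suppressed by
#' narrower hits on other records.
#'
#' @param variant One-row variant tibble (protein-level fields populated).
#' @param kb Normalized evidence tibble from [load_evidence_source()].
#' @param annotation Optional [transcript_annotation()] for exon matching.
#' @return Tibble of matched treatments: the evidence columns plus
#'   `biomarker` (the query variant label), `match_type`, and `sources`
#'   (list of contributing source names).
#' @export
match_evidence <- function(variant, kb, annotation = NULL) {
  stopifnot(nrow(variant) == 1)
  if (is.na(variant$gene)) {
    otr_error("variant must be protein-level or resolvable to protein level",
              "oncotherapyr_match_error")
  }
  empty <- function() {
    kb0 <- kb[0, , drop = FALSE]
    kb0$biomarker <- character(0); kb0$match_type <- character(0)
    kb0$sources <- list()
    kb0
  }
  cand <- kb[kb$biomarker_gene == variant$gene, , drop = FALSE]
  if (nrow(cand) == 0) return(empty())

  ps <- parse_biomarker_spec(cand$biomarker_spec)
  v_pos <- variant$aa_pos
  v_alt <- variant$alt_aa
  v_exon <- NA_integer_

  want_exon <- any(ps$spec_kind %in% c("exact", "positional", "exon"))
  if (want_exon && !is.na(v_pos)) {
    if (is.null(annotation)) {
      warn("no transcript annotation supplied; same-exon matching skipped")
    } else {
      v_exon <- aa_pos_to_exon(annotation, v_pos)
    }
  }
  spec_exon_of <- function(kind, pos, exon) {
    # exon index of the kb biomarker itself (for exact/positional specs)
    if (kind == "exon") return(exon)
    if (is.null(annotation) || is.na(pos)) return(NA_integer_)
    aa_pos_to_exon(annotation, pos)
  }

  lab <- purrr::pmap_chr(
    list(ps$spec_kind, ps$spec_ref, ps$spec_pos, ps$spec_alt, ps$spec_exon),
    function(kind, sref, spos, salt, sexon) {
      if (kind == "exact" && !is.na(v_pos) && identical(spos, v_pos)) {
        if (identical(salt, v_alt)) return("exact")
        return("same_pos_other_aa")
      }
      if (kind == "positional" && !is.na(v_pos) && identical(spos, v_pos)) {
        return("same_pos_any")
      }
      if (kind %in% c("exact", "positional", "exon") && !is.na(v_exon)) {
        se <- spec_exon_of(kind, spos, sexon)
        if (!is.na(se) && se == v_exon) return("same_exon")
      }
      if (kind == "gene") return("gene_level")
      NA_character_
    }
  )
  hit <- !is.na(lab)
  out <- cand[hit, , drop = FALSE]
  if (nrow(out) == 0) return(empty())
  out$biomarker <- biomarker_label(variant)
  out$match_type <- factor(lab[hit], levels = MATCH_TYPES) |> as.character()
  out$sources <- as.list(out$source)
  arrange(out, match(.data$match_type, MATCH_TYPES), .data$citation_id)
}

biomarker_label <- function(variant) {
  if (!is.na(variant$ref_aa) && !is.na(variant$aa_pos)) {
    paste0(variant$gene, " ", variant$ref_aa, variant$aa_pos,
           dplyr::coalesce(variant$alt_aa, ""))
  } else {
    variant$gene
  }
}

merge_key <- function(matches) {
  paste(
    map_chr(matches$drugs, ~ paste(sort(normalize_label(.x)), collapse = "+")),
    dplyr::coalesce(matches$cancer_type_main, ""),
    dplyr::coalesce(matches$amp_tier, ""),
    matches$response,
    matches$citation_id,
    sep = "\r"
  )
}

#' Merge duplicate treatments across knowledge bases
#'
#' Treatments are merged when their normalized features are identical on
#' the five-field key (drug label, cancer entity, evidence level, response
#' type, citation ID); contributing source names are unioned and the most
#' specific match type is kept. Output order is deterministic (by key).
#'
#' @param matches Matched-treatment tibble from [match_evidence()].
#' @return Matched-treatment tibble with duplicates collapsed.
#' @export
merge_duplicates <- function(matches) {
  if (nrow(matches) == 0) return(matches)
  matches$.key <- merge_key(matches)
  grouped <- matches |>
    group_by(.data$biomarker, .data$.key) |>
    arrange(match(.data$match_type, MATCH_TYPES), .data$source,
            .by_group = TRUE)
  merged <- grouped |>
    summarise(
      across(-c("sources", "source", "match_type"), ~ .x[1]),
      sources = list(sort(unique(unlist(.data$sources)))),
      source = paste(sort(unique(.data$source)), collapse = ","),
      match_type = .data$match_type[1],
      .groups = "drop"
    ) |>
    arrange(.data$biomarker, .data$.key)
  merged$.key <- NULL
  merged
}

#' Build a patient-level treatment table
#'
#' Matches and merges evidence for every variant of a molecular profile and
#' concatenates the per-variant results, each row tagged with its
#' originating biomarker. Rows are sorted by evidence tier, then response,
#' then match-type specificity.
#'
#' @param variants Variant tibble (protein-level fields populated).
#' @param kb Normalized evidence tibble.
#' @param annotation Optional [transcript_annotation()] for exon matching.
#' @return Matched-treatment tibble covering all variants.
#' @export
build_treatment_table <- function(variants, kb, annotation = NULL) {
  stopifnot(nrow(variants) >= 1)
  rows <- map(seq_len(nrow(variants)), function(i) {
    v <- variants[i, , drop = FALSE]
    if (is.na(v$gene)) return(NULL)
    merge_duplicates(match_evidence(v, kb, annotation))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(out)
  arrange(out,
          match(dplyr::coalesce(.data$amp_tier, "Z"), c("A", "B", "C", "D", "Z")),
          match(.data$response, c("sensitive", "resistant", "unknown")),
          match(.data$match_type, MATCH_TYPES))
}

#' Export a treatment table as CSV
#'
#' Column layout of the interactive treatment table: biomarker, match type,
#' drugs, drug classification, evidence level, response type, citation ID.
#'
#' @param treatments Matched-treatment tibble.
#' @param path Output CSV path.
#' @return The output path, invisibly.
#' @export
write_treatment_table <- function(treatments, path) {
  flat <- tibble(
    biomarker = treatments$biomarker %||% character(0),
    match_type = treatments$match_type %||% character(0),
    drugs = map_chr(treatments$drugs %||% list(),
                    ~ paste(.x, collapse = ";")),
    drug_class = map_chr(treatments$drug_classes %||% list(),
                         ~ paste(unique(.x), collapse = ";")),
    evidence_level = treatments$amp_tier %||% character(0),
    response = treatments$response %||% character(0),
    citation_id = treatments$citation_id %||% character(0)
  )
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}
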