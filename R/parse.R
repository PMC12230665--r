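#' Parse a variant query string
#'
#' Accepts variant descriptions at three nomenclature levels and returns a
#' one-row tibble with the fields of the detected level populated:
#'
#' * DNA level, e.g. `"chr12:g.25245350C>T"` (the `chr` prefix is optional
#'   and stripped internally),
#' * transcript level, e.g. `"NM_004985.5:c.35G>A"`,
#' * protein level, e.g. `"KRAS:p.G12D"`; the shorthand `"KRAS G12D"`
#'   (as knowledge bases print biomarkers), three-letter codes
#'   (`"KRAS:p.Gly12Asp"`) and parenthesized HGVS (`"p.(G12D)"`) are all
#'   accepted and normalized to one-letter form.
#'
#' A bare gene symbol (`"BRAF"`) yields a `gene_only` record. HGVS
#' `ins`/`del`/`delins` descriptions are recognized and drive the
#' `variant_type` column (see [recognize_variant_type()]).
#'
#' @param text A single query string.
#' @param genome Reference genome label carried as metadata (no sequence
#'   validation is performed). Default `"hg38"`.
#' @return A one-row tibble with columns `query`, `level` (`"DNA"`,
#'   `"transcript"`, `"protein"`, or `"gene_only"`), `chrom`, `pos`, `ref`,
#'   `alt`, `transcript_id`, `cds_pos`, `gene`, `ref_aa`, `aa_pos`,
#'   `alt_aa`, `variant_type`, `genome`. Fields not belonging to the
#'   detected level are `NA`.
#' @examples
#' parse_query("chr12:g.25245350C>T")
#' parse_query("KRAS G12D")
#' @export
parse_query <- function(text, genome = "hg38") {
  stopifnot(is.character(text), length(text) == 1)
  text <- str_trim(text)
  if (!nzchar(text)) {
    otr_error("empty query string", "oncotherapyr_parse_error")
  }
  row <- parse_one(text, genome)
  if (!is.null(row$error)) {
    otr_error(
      paste0("cannot parse variant query '", text, "': ", row$error$msg,
             " (offending token: '", row$error$token, "')"),
      "oncotherapyr_parse_error"
    )
  }
  row$variant
}

#' Parse many variant query strings
#'
#' Vectorized companion of [parse_query()]. Unparseable entries are skipped
#' with one warning summarising the count; the skipped strings are kept in
#' the `"skipped"` attribute of the result.
#'
#' @param texts Character vector of query strings.
#' @inheritParams parse_query
#' @return A tibble with one row per successfully parsed query.
#' @export
parse_variants <- function(texts, genome = "hg38") {
  texts <- str_trim(texts[!is.na(texts) & nzchar(str_trim(texts))])
  parsed <- map(texts, parse_one, genome = genome)
  bad <- map_lgl(parsed, ~ !is.null(.x$error))
  if (any(bad)) {
    warn(paste0(sum(bad), " of ", length(texts),
                " queries could not be parsed and were skipped"))
  }
  out <- bind_rows(map(parsed[!bad], "variant"))
  if (nrow(out) == 0) out <- empty_variants()
  attr(out, "skipped") <- texts[bad]
  out
}

empty_variants <- function() {
  tibble(query = character(), level = character(), chrom = character(),
         pos = integer(), ref = character(), alt = character(),
         transcript_id = character(), cds_pos = integer(),
         gene = character(), ref_aa = character(), aa_pos = integer(),
         alt_aa = character(), variant_type = character(),
         genome = character())
}

variant_row <- function(query, level, genome, chrom = NA_character_,
                        pos = NA_integer_, ref = NA_character_,
                        alt = NA_character_,
                        transcript_id = NA_character_,
                        cds_pos = NA_integer_, gene = NA_character_,
                        ref_aa = NA_character_, aa_pos = NA_integer_,
                        alt_aa = NA_character_,
                        variant_type = NA_character_) {
  tibble(query = query, level = level, chrom = chrom, pos = as.integer(pos),
         ref = ref, alt = alt, transcript_id = transcript_id,
         cds_pos = as.integer(cds_pos), gene = gene, ref_aa = ref_aa,
         aa_pos = as.integer(aa_pos), alt_aa = alt_aa,
         variant_type = variant_type, genome = genome)
}

# Returns list(variant = <tibble>) or list(error = list(msg, token)).
parse_one <- function(text, genome) {
  fail <- function(msg, token) list(error = list(msg = msg, token = token))

  # --- DNA level: [chr]<chrom>:g.<pos><change> ------------------------------
  m <- str_match(text, "^(?:chr)?([0-9]{1,2}|[XYM]|MT):g\\.(.*)$")
  if (!is.na(m[1, 1])) {
    chrom <- m[1, 2]
    desc <- m[1, 3]
    ch <- parse_nt_change(desc)
    if (!is.null(ch$error)) return(fail(ch$error, desc))
    v <- variant_row(text, "DNA", genome, chrom = chrom, pos = ch$pos,
                     ref = ch$ref, alt = ch$alt, variant_type = ch$type)
    return(list(variant = finalize_type(v)))
  }
  if (str_detect(text, "^(?:chr)?[0-9XYM]{1,2}T?:g")) {
    return(fail("malformed genomic HGVS description", text))
  }

  # --- transcript level: <acc>.<ver>:c.<pos><change> ------------------------
  m <- str_match(text, "^([A-Z]{2}_[0-9]+(?:\\.[0-9]+)?):c\\.(.*)$")
  if (!is.na(m[1, 1])) {
    desc <- m[1, 3]
    ch <- parse_nt_change(desc)
    if (!is.null(ch$error)) return(fail(ch$error, desc))
    v <- variant_row(text, "transcript", genome, transcript_id = m[1, 2],
                     cds_pos = ch$pos, ref = ch$ref, alt = ch$alt,
                     variant_type = ch$type)
    return(list(variant = finalize_type(v)))
  }

  # --- protein level: GENE:p.X, GENE p.X, GENE X###X ------------------------
  m <- str_match(text, "^([A-Za-z][A-Za-z0-9-]*)[: ](?:p\\.)?\\(?(.+?)\\)?$")
  if (!is.na(m[1, 1])) {
    gene <- str_to_upper(m[1, 2])
    ch <- parse_aa_change(m[1, 3])
    if (is.null(ch$error)) {
      v <- variant_row(text, "protein", genome, gene = gene,
                       ref_aa = ch$ref_aa, aa_pos = ch$aa_pos,
                       alt_aa = ch$alt_aa, variant_type = ch$type)
      return(list(variant = finalize_type(v)))
    }
    if (str_detect(text, "[: ]p\\.")) return(fail(ch$error, m[1, 3]))
  }

  # --- bare gene symbol -----------------------------------------------------
  if (str_detect(text, "^[A-Za-z][A-Za-z0-9-]*$")) {
    v <- variant_row(text, "gene_only", genome, gene = str_to_upper(text),
                     variant_type = "gene_only")
    return(list(variant = v))
  }

  fail("unrecognized variant nomenclature", text)
}

# nucleotide-level change description after g./c. (substitution, ins, del,
# delins); returns pos (first affected base), ref, alt, type
parse_nt_change <- function(desc) {
  m <- str_match(desc, "^([0-9]+)([ACGT]+)>([ACGT]+)$")
  if (!is.na(m[1, 1])) {
    ref <- m[1, 3]; alt <- m[1, 4]
    if (ref == alt && nchar(ref) == 1) {
      return(list(error = "reference and alternate allele are identical"))
    }
    type <- if (nchar(ref) == 1 && nchar(alt) == 1) "SNV"
            else if (nchar(ref) < nchar(alt)) "insertion"
            else if (nchar(ref) > nchar(alt)) "deletion"
            else "indel"
    return(list(pos = as.integer(m[1, 2]), ref = ref, alt = alt, type = type))
  }
  m <- str_match(desc, "^([0-9]+)(?:_([0-9]+))?delins([ACGT]+)$")
  if (!is.na(m[1, 1])) {
    return(list(pos = as.integer(m[1, 2]), ref = NA_character_,
                alt = m[1, 3], type = "indel"))
  }
  m <- str_match(desc, "^([0-9]+)(?:_([0-9]+))?ins([ACGT]+)$")
  if (!is.na(m[1, 1])) {
    return(list(pos = as.integer(m[1, 2]), ref = NA_character_,
                alt = m[1, 3], type = "insertion"))
  }
  m <- str_match(desc, "^([0-9]+)(?:_([0-9]+))?del([ACGT]*)$")
  if (!is.na(m[1, 1])) {
    return(list(pos = as.integer(m[1, 2]),
                ref = if (nzchar(m[1, 3])) m[1, 3] else NA_character_,
                alt = NA_character_, type = "deletion"))
  }
  if (str_detect(desc, "^[ACGT]+>[ACGT]+$")) {
    return(list(error = "missing position"))
  }
  list(error = "unrecognized nucleotide change description")
}

# protein-level change: G12D, Gly12Asp, G12del, G12_V14del, G12 (positional)
parse_aa_change <- function(desc) {
  desc <- str_trim(desc)
  m <- str_match(desc, "^([A-Z\\*]|[A-Za-z]{3})([0-9]+)([A-Z\\*]|[A-Za-z]{3})$")
  if (!is.na(m[1, 1])) {
    ref <- if (nchar(m[1, 2]) == 3) aa3_to_1(m[1, 2]) else str_to_upper(m[1, 2])
    alt <- if (nchar(m[1, 4]) == 3) aa3_to_1(m[1, 4]) else str_to_upper(m[1, 4])
    if (is.na(ref) || is.na(alt) || !is_aa1(ref) || !is_aa1(alt)) {
      return(list(error = "unknown amino-acid code"))
    }
    return(list(ref_aa = ref, aa_pos = as.integer(m[1, 3]), alt_aa = alt,
                type = "SNV"))
  }
  m <- str_match(desc, "^([A-Z]|[A-Za-z]{3})([0-9]+)(?:_[A-Z]?[a-z]{0,2}[0-9]+)?(del|dup|ins[A-Za-z]*)$")
  if (!is.na(m[1, 1])) {
    ref <- if (nchar(m[1, 2]) == 3) aa3_to_1(m[1, 2]) else str_to_upper(m[1, 2])
    if (is.na(ref) || !is_aa1(ref)) return(list(error = "unknown amino-acid code"))
    type <- switch(str_sub(m[1, 4], 1, 3),
                   del = "deletion", dup = "insertion", ins = "insertion")
    return(list(ref_aa = ref, aa_pos = as.integer(m[1, 3]),
                alt_aa = NA_character_, type = type))
  }
  list(error = "unrecognized protein change description")
}

finalize_type <- function(v) {
  v$variant_type <- recognize_variant_type(v)
  v
}

#' Recognize the variant type of parsed variants
#'
#' Classifies each parsed variant as `SNV` (single-base substitution),
#' `insertion`, `deletion`, `indel` (length-preserving multi-base or
#' delins), `gene_only`, or `fusion`. Classification uses allele length
#' asymmetry and any HGVS `ins`/`del` keyword captured at parse time;
#' anything ambiguous falls back to `indel`.
#'
#' @param variants A variant tibble as returned by [parse_query()] /
#'   [parse_variants()].
#' @return Character vector of variant types, one per row.
#' @export
recognize_variant_type <- function(variants) {
  pmap_chr_safe <- function(...) purrr::pmap_chr(...)
  pmap_chr_safe(
    list(variants$level, variants$ref, variants$alt,
         variants$variant_type %||% rep(NA_character_, nrow(variants))),
    function(level, ref, alt, vt) {
      if (identical(level, "gene_only")) return("gene_only")
      if (!is.na(vt) && vt %in% c("insertion", "deletion", "indel", "fusion",
                                  "SNV", "gene_only")) {
        # parse-time keyword classification wins unless alleles disagree
        if (!is.na(ref) && !is.na(alt)) {
          if (nchar(ref) == 1 && nchar(alt) == 1) return("SNV")
          if (nchar(ref) < nchar(alt)) return("insertion")
          if (nchar(ref) > nchar(alt)) return("deletion")
          return("indel")
        }
        return(vt)
      }
      if (is.na(ref) || is.na(alt)) return("indel")
      if (nchar(ref) == 1 && nchar(alt) == 1) return("SNV")
      if (nchar(ref) < nchar(alt)) return("insertion")
      if (nchar(ref) > nchar(alt)) return("deletion")
      "indel"
    }
  )
}

#' Format parsed variants back to canonical query strings
#'
#' Inverse of [parse_query()] on canonical forms: DNA variants print as
#' `chr<chrom>:g.<pos><ref>><alt>`, transcript variants as
#' `<acc>:c.<pos><ref>><alt>`, protein variants as `<gene>:p.<ref><pos><alt>`,
#' bare genes as the symbol.
#'
#' @param variants A variant tibble.
#' @return Character vector of canonical query strings.
#' @export
format_variant <- function(variants) {
  purrr::pmap_chr(
    list(variants$level, variants$chrom, variants$pos, variants$ref,
         variants$alt, variants$transcript_id, variants$cds_pos,
         variants$gene, variants$ref_aa, variants$aa_pos, variants$alt_aa),
    function(level, chrom, pos, ref, alt, tx, cpos, gene, raa, apos, aaa) {
      switch(level,
        DNA = paste0("chr", chrom, ":g.", pos, ref, ">", alt),
        transcript = paste0(tx, ":c.", cpos, ref, ">", alt),
        protein = paste0(gene, ":p.", raa, apos, aaa),
        gene_only = gene,
        NA_character_)
    }
  )
}
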