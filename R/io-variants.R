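#' Read variants from VCF, MAF, or a plain query list
#'
#' * `vcf`: VCF 4.x via \pkg{vcfR}; multi-allelic records are expanded to one
#'   variant per alternate allele; the `##` meta header is kept in the
#'   `"vcf_header"` attribute so it can be passed through on export.
#' * `maf`: tab-delimited with a named header row. Only the columns
#'   `Hugo_Symbol`, `Chromosome`, `Start_Position`, `Reference_Allele`,
#'   `Tumor_Seq_Allele2` are required (`HGVSp_Short` is used when present
#'   to also populate the protein-level fields); other columns are ignored.
#' * `list`: one query string per line, parsed with [parse_variants()].
#'
#' Records failing validation are skipped and counted with a warning.
#'
#' @param path Path to the input file.
#' @param format One of `"vcf"`, `"maf"`, `"list"`.
#' @param genome Reference genome label carried as metadata.
#' @return A variant tibble (see [parse_query()] for columns).
#' @export
read_variant_file <- function(path, format = c("vcf", "maf", "list"),
                              genome = "hg38") {
  format <- match.arg(format)
  if (!file.exists(path)) {
    otr_error(paste0("input file not found: ", path), "oncotherapyr_io_error")
  }
  switch(format,
         vcf = read_vcf_variants(path, genome),
         maf = read_maf_variants(path, genome),
         list = parse_variants(readLines(path, warn = FALSE), genome = genome))
}

read_vcf_variants <- function(path, genome) {
  lines <- readLines(path, warn = FALSE)
  if (!any(!startsWith(lines, "#"))) {
    out <- empty_variants()
    attr(out, "vcf_header") <- grep("^##", lines, value = TRUE)
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  need <- c("CHROM", "POS", "REF", "ALT")
  missing <- setdiff(need, colnames(fix))
  if (length(missing) > 0) {
    otr_error(paste0("VCF is missing mandatory column(s): ",
                     paste(missing, collapse = ", ")),
              "oncotherapyr_format_error")
  }
  rows <- as_tibble(fix[need]) |>
    mutate(CHROM = str_replace_all(.data$CHROM, "^chr", ""),
           POS = suppressWarnings(as.integer(.data$POS))) |>
    tidyr::separate_rows("ALT", sep = ",")
  ok <- !is.na(rows$POS) & rows$POS >= 1 &
    str_detect(rows$REF, "^[ACGTN]+$") & str_detect(rows$ALT, "^[ACGTN*]+$")
  if (any(!ok)) {
    warn(paste0(sum(!ok), " VCF record(s) failed validation and were skipped"))
  }
  rows <- rows[ok, , drop = FALSE]
  out <- variant_row(
    query = paste0("chr", rows$CHROM, ":g.", rows$POS, rows$REF, ">", rows$ALT),
    level = "DNA", genome = genome, chrom = rows$CHROM, pos = rows$POS,
    ref = rows$REF, alt = rows$ALT
  )
  out$variant_type <- recognize_variant_type(out)
  attr(out, "vcf_header") <- vcf@meta
  attr(out, "n_skipped") <- sum(!ok)
  out
}

read_maf_variants <- function(path, genome) {
  maf <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  need <- c("Hugo_Symbol", "Chromosome", "Start_Position",
            "Reference_Allele", "Tumor_Seq_Allele2")
  missing <- setdiff(need, colnames(maf))
  if (length(missing) > 0) {
    otr_error(paste0("MAF is missing mandatory column(s): ",
                     paste(missing, collapse = ", ")),
              "oncotherapyr_format_error")
  }
  pos <- suppressWarnings(as.integer(maf$Start_Position))
  ok <- !is.na(pos) & pos >= 1
  if (any(!ok)) {
    warn(paste0(sum(!ok), " MAF record(s) failed validation and were skipped"))
  }
  maf <- maf[ok, , drop = FALSE]
  pos <- pos[ok]
  out <- variant_row(
    query = paste0("chr", str_replace_all(maf$Chromosome, "^chr", ""), ":g.",
                   pos, maf$Reference_Allele, ">", maf$Tumor_Seq_Allele2),
    level = "DNA", genome = genome,
    chrom = str_replace_all(as.character(maf$Chromosome), "^chr", ""),
    pos = pos, ref = maf$Reference_Allele, alt = maf$Tumor_Seq_Allele2,
    gene = maf$Hugo_Symbol
  )
  if ("HGVSp_Short" %in% colnames(maf)) {
    aa <- map(maf$HGVSp_Short, function(h) {
      if (is.na(h) || !nzchar(h)) return(NULL)
      ch <- parse_aa_change(str_replace_all(h, "^p\\.", ""))
      if (!is.null(ch$error)) NULL else ch
    })
    has <- !map_lgl(aa, is.null)
    out$ref_aa[has] <- map_chr(aa[has], "ref_aa")
    out$aa_pos[has] <- map_int(aa[has], "aa_pos")
    out$alt_aa[has] <- map_chr(aa[has], function(x) x$alt_aa %||% NA_character_)
  }
  out$variant_type <- recognize_variant_type(out)
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Export a variant table with selected annotation fields as CSV
#'
#' Writes one row per variant with exactly the requested columns in the
#' requested order, RFC-4180 quoted, UTF-8 encoded.
#'
#' @param variants A variant tibble.
#' @param annotations Optional tibble of per-variant annotations, row-aligned
#'   with `variants` (or `NULL`).
#' @param selected_fields Character vector of column names to export, drawn
#'   from the variant and annotation columns.
#' @param path Output CSV path.
#' @return The output path, invisibly.
#' @export
write_variant_table <- function(variants, annotations = NULL, selected_fields,
                                path) {
  full <- variants
  if (!is.null(annotations)) {
    stopifnot(nrow(annotations) == nrow(variants))
    full <- bind_cols(variants,
                      annotations[setdiff(names(annotations), names(variants))])
  }
  unknown <- setdiff(selected_fields, names(full))
  if (length(unknown) > 0) {
    otr_error(paste0("unknown field(s): ", paste(unknown, collapse = ", "),
                     "; valid fields are: ", paste(names(full), collapse = ", ")),
              "oncotherapyr_field_error")
  }
  readr::write_csv(full[, selected_fields, drop = FALSE], path, progress = FALSE)
  invisible(path)
}

#' Write DNA-level variants back to a VCF file
#'
#' Emits a plain-text VCF 4.2 file. A meta header captured by
#' [read_variant_file()] (the `"vcf_header"` attribute) is passed through
#' verbatim; otherwise a minimal header is written. CHROM, POS, REF, ALT
#' are preserved byte-exactly for records that were read from VCF.
#'
#' @param variants A variant tibble with DNA-level rows.
#' @param path Output path.
#' @return The output path, invisibly.
#' @export
write_vcf <- function(variants, path) {
  v <- filter(variants, .data$level == "DNA")
  header <- attr(variants, "vcf_header")
  if (is.null(header) || length(header) == 0) {
    header <- c("##fileformat=VCFv4.2",
                paste0("##reference=", v$genome[1] %||% "hg38"))
  }
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", ".", ".", sep = "\t")
  writeLines(c(header,
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", body), path)
  invisible(path)
}
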