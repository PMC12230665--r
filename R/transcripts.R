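#' Construct a transcript annotation
#'
#' Minimal transcript model used for exon-level therapy matching and fusion
#' frame determination: sorted non-overlapping exons (1-based inclusive
#' genomic intervals), a coding region lying within the exon union, and a
#' strand.
#'
#' @param transcript_id Versioned transcript accession.
#' @param gene Gene symbol.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with columns `start`, `end` (1-based inclusive),
#'   sorted by genomic start.
#' @param cds_start,cds_end Genomic bounds of the coding region (first and
#'   last coding base in genomic coordinates, `cds_start <= cds_end`).
#' @return An object of class `transcript_annotation`.
#' @export
transcript_annotation <- function(transcript_id, gene, strand, exons,
                                  cds_start, cds_end) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as_tibble(exons)[c("start", "end")]
  exons <- mutate(exons, start = as.integer(.data$start),
                  end = as.integer(.data$end))
  if (any(exons$end < exons$start)) {
    otr_error("exon end before start", "oncotherapyr_annotation_error")
  }
  if (is.unsorted(exons$start, strictly = TRUE) ||
      any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    otr_error("exons must be sorted and non-overlapping",
              "oncotherapyr_annotation_error")
  }
  for (p in c(cds_start, cds_end)) {
    if (!any(p >= exons$start & p <= exons$end)) {
      otr_error("CDS bounds must lie within the exon union",
                "oncotherapyr_annotation_error")
    }
  }
  structure(
    list(transcript_id = transcript_id, gene = gene, strand = strand,
         exons = exons, cds_start = as.integer(cds_start),
         cds_end = as.integer(cds_end)),
    class = "transcript_annotation"
  )
}

#' @method print transcript_annotation
#' @export
print.transcript_annotation <- function(x, ...) {
  cat("<transcript_annotation> ", x$transcript_id, " (", x$gene, ", ",
      x$strand, " strand, ", nrow(x$exons), " exons)\n", sep = "")
  invisible(x)
}

# 1-based CDS coordinate of a genomic position, or NA when the position is
# outside the coding exon region (UTR, intron, or outside the transcript).
genomic_to_cds <- function(ann, gpos) {
  if (gpos < ann$cds_start || gpos > ann$cds_end) return(NA_integer_)
  ex <- ann$exons
  hit <- which(gpos >= ex$start & gpos <= ex$end)
  if (length(hit) == 0) return(NA_integer_)
  # coding part of each exon
  cstart <- pmax(ex$start, ann$cds_start)
  cend <- pmin(ex$end, ann$cds_end)
  len <- pmax(0L, cend - cstart + 1L)
  if (ann$strand == "+") {
    before <- if (hit > 1) sum(len[seq_len(hit - 1)]) else 0L
    as.integer(before + (gpos - cstart[hit] + 1L))
  } else {
    n <- nrow(ex)
    after <- if (hit < n) sum(len[seq(hit + 1, n)]) else 0L
    as.integer(after + (cend[hit] - gpos + 1L))
  }
}

# genomic position of a 1-based CDS coordinate (inverse of genomic_to_cds)
cds_to_genomic <- function(ann, cpos) {
  ex <- ann$exons
  cstart <- pmax(ex$start, ann$cds_start)
  cend <- pmin(ex$end, ann$cds_end)
  len <- pmax(0L, cend - cstart + 1L)
  ord <- if (ann$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  run <- 0L
  for (i in ord) {
    if (len[i] == 0L) next
    if (cpos <= run + len[i]) {
      off <- cpos - run - 1L
      return(if (ann$strand == "+") cstart[i] + off else cend[i] - off)
    }
    run <- run + len[i]
  }
  NA_integer_
}

# exon index (1-based, genomic order) containing a protein residue position
aa_pos_to_exon <- function(ann, aa_pos) {
  gpos <- cds_to_genomic(ann, (aa_pos - 1L) * 3L + 1L)
  if (is.na(gpos)) return(NA_integer_)
  hit <- which(gpos >= ann$exons$start & gpos <= ann$exons$end)
  if (length(hit) == 0) NA_integer_ else hit
}

#' Construct a gene fusion event
#'
#' @param chrom_a,chrom_b Chromosome labels of the 5' and 3' partner.
#' @param breakpoint_a Last retained genomic base of the 5' partner.
#' @param breakpoint_b First retained genomic base of the 3' partner.
#' @param gene_a,gene_b Optional gene symbols.
#' @return An object of class `fusion_event`.
#' @export
fusion_event <- function(chrom_a, breakpoint_a, chrom_b, breakpoint_b,
                         gene_a = NA_character_, gene_b = NA_character_) {
  stopifnot(breakpoint_a >= 1, breakpoint_b >= 1)
  structure(
    list(chrom_a = str_replace_all(as.character(chrom_a), "^chr", ""),
         breakpoint_a = as.integer(breakpoint_a),
         chrom_b = str_replace_all(as.character(chrom_b), "^chr", ""),
         breakpoint_b = as.integer(breakpoint_b),
         gene_a = gene_a, gene_b = gene_b),
    class = "fusion_event"
  )
}

#' Determine whether a gene fusion is in frame
#'
#' The reading frame is preserved when the retained coding length of the 5'
#' partner (CDS start through `breakpoint_a`) modulo 3 equals the codon
#' offset of the 3' partner's junction base (`(cds_pos - 1) mod 3`), so that
#' translation continues in the downstream gene's frame. Both computations
#' are strand-aware. A breakpoint in a UTR, an intron, or outside the
#' transcript yields `"undetermined"`.
#'
#' @param fusion A [fusion_event()].
#' @param annotation_a,annotation_b [transcript_annotation()]s of the 5' and
#'   3' partner.
#' @return One of `"in_frame"`, `"out_of_frame"`, `"undetermined"`.
#' @export
fusion_in_frame <- function(fusion, annotation_a, annotation_b) {
  stopifnot(inherits(fusion, "fusion_event"),
            inherits(annotation_a, "transcript_annotation"),
            inherits(annotation_b, "transcript_annotation"))
  retained5 <- genomic_to_cds(annotation_a, fusion$breakpoint_a)
  cds_b <- genomic_to_cds(annotation_b, fusion$breakpoint_b)
  if (is.na(retained5) || is.na(cds_b)) return("undetermined")
  if (retained5 %% 3L == (cds_b - 1L) %% 3L) "in_frame" else "out_of_frame"
}
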