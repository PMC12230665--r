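#' Generate a deterministic toy knowledge base in three dialects
#'
#' Writes `civic_like.tsv`, `oncokb_like.tsv`, and `metakb_like.tsv` into
#' `dir`, shaped like the three evidence-source dialects. Deterministic
#' under `seed` (same seed, identical bytes). Guaranteed contents:
#'
#' * one cross-source duplicate (identical normalized assertion in the
#'   CIViC-like and MetaKB-like files),
#' * one `substitutes` record listing two interchangeable drugs,
#' * one biomarker of each of the five specification kinds for the
#'   designated gene (default KRAS): exact change, other exchange at the
#'   same position, positional, exon, gene-level,
#' * one record with an unmapped evidence code,
#' * a gene-level RET record (selpercatinib, level 1, sensitive, thyroid
#'   cancer), the retrieval showcase for the gene match type.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_per_source Number of additional randomized records per source
#'   (>= 1).
#' @param gene Designated gene for the five-match-kind records.
#' @return Named character vector of the three file paths, invisibly.
#' @export
generate_toy_kb <- function(dir, seed = 1, n_per_source = 10, gene = "KRAS") {
  stopifnot(n_per_source >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  genes <- c("BRAF", "EGFR", "ALK", "TP53", "PIK3CA", "NRAS")
  drugs <- c("dabrafenib", "vemurafenib", "trametinib", "osimertinib",
             "erlotinib", "cetuximab", "sotorasib", "cabozantinib")
  diseases <- c("Melanoma", "Lung Adenocarcinoma", "Colorectal Cancer",
                "Thyroid Cancer", "Glioblastoma", "Breast Invasive Ductal Carcinoma")
  rand_spec <- function(n) {
    paste0(sample(c("G", "V", "L", "E", "R"), n, TRUE),
           sample(c(12, 600, 790, 858, 61), n, TRUE),
           sample(c("D", "A", "C", "K", "M"), n, TRUE))
  }
  rand_rows <- function(n, levels) {
    tibble(gene = sample(genes, n, TRUE), spec = rand_spec(n),
           disease = sample(diseases, n, TRUE),
           drug = sample(drugs, n, TRUE),
           level = sample(levels, n, TRUE),
           pmid = paste0("PMID:", 10000000L + sample.int(19999999L, n)))
  }

  # --- civic_like ----------------------------------------------------------
  r <- rand_rows(n_per_source, c("A", "B", "C", "D"))
  civic <- tibble(
    gene = c(gene, gene, gene, gene, gene, "BRAF", "EGFR", r$gene),
    variant = c("G12A", "G12C", "G12", "exon 1", "mutation", "V600E",
                "L858R", r$spec),
    disease = c("Lung Adenocarcinoma", "Lung Adenocarcinoma",
                "Colorectal Cancer", "Lung Adenocarcinoma",
                "Colorectal Cancer", "Melanoma", "Lung Adenocarcinoma",
                r$disease),
    drugs = c("sotorasib", "adagrasib", "cetuximab", "sotorasib",
              "trametinib", "dabrafenib;vemurafenib", "erlotinib", r$drug),
    drug_interaction_type = c(rep("none", 5), "substitutes", "none",
                              rep("none", n_per_source)),
    significance = c("Sensitivity/Response", "Sensitivity/Response",
                     "Resistance", "Sensitivity/Response",
                     "Sensitivity/Response", "Sensitivity/Response",
                     "Sensitivity/Response",
                     sample(c("Sensitivity/Response", "Resistance", "N/A"),
                            n_per_source, TRUE)),
    evidence_level = c("B", "B", "B", "C", "C", "A", "A", r$level),
    evidence_statement = "toy evidence statement",
    citation_id = c("PMID:30000001", "PMID:30000002", "PMID:30000003",
                    "PMID:30000004", "PMID:30000005", "PMID:30000006",
                    "PMID:30000007", r$pmid)
  )

  # --- oncokb_like ---------------------------------------------------------
  r2 <- rand_rows(n_per_source, c("1", "2", "3A", "3B", "R1", "R2", "4"))
  oncokb <- tibble(
    gene = c(gene, "RET", "EGFR", "ALK", r2$gene),
    alteration = c("G12C", "mutation", "exon 19", "mutation", r2$spec),
    cancer_type = c("Non-Small Cell Lung Cancer", "Thyroid Cancer",
                    "Non-Small Cell Lung Cancer", "NSCLC", r2$disease),
    drugs = c("sotorasib", "selpercatinib", "osimertinib", "crizotinib",
              r2$drug),
    level = c("1", "1", "1", "Z9", r2$level),
    statement = "toy evidence statement",
    citation_id = c("PMID:31000001", "PMID:31000002", "PMID:31000003",
                    "PMID:31000004", r2$pmid)
  )

  # --- metakb_like ---------------------------------------------------------
  r3 <- rand_rows(n_per_source, c("A", "B", "C", "D"))
  metakb <- tibble(
    gene = c(gene, "BRAF", r3$gene),
    variant = c("G12A", "V600E", r3$spec),
    disease = c("Lung Adenocarcinoma", "Melanoma", r3$disease),
    therapies = c("sotorasib", "dabrafenib", r3$drug),
    association = c("predicts sensitivity to therapy",
                    "predicts sensitivity to therapy",
                    sample(c("predicts sensitivity to therapy",
                             "confers resistance", "no benefit observed"),
                           n_per_source, TRUE)),
    evidence_label = c("B", "A", r3$level),
    statement = "toy evidence statement",
    # first record duplicates the civic_like G12A assertion (same drug,
    # disease, level, response, citation)
    citation_id = c("PMID:30000001", "PMID:30000006", r3$pmid)
  )

  paths <- c(civic_like = file.path(dir, "civic_like.tsv"),
             oncokb_like = file.path(dir, "oncokb_like.tsv"),
             metakb_like = file.path(dir, "metakb_like.tsv"))
  readr::write_tsv(civic, paths[["civic_like"]], progress = FALSE)
  readr::write_tsv(oncokb, paths[["oncokb_like"]], progress = FALSE)
  readr::write_tsv(metakb, paths[["metakb_like"]], progress = FALSE)
  invisible(paths)
}

#' Load a toy knowledge-base directory
#'
#' Reads and normalizes all three dialect files written by
#' [generate_toy_kb()] into one evidence table.
#'
#' @param dir Directory holding `civic_like.tsv`, `oncokb_like.tsv`,
#'   `metakb_like.tsv` (any subset).
#' @param ... Passed to [load_evidence_source()].
#' @return Combined normalized evidence tibble.
#' @export
load_kb_dir <- function(dir, ...) {
  if (!dir.exists(dir)) {
    otr_error(paste0("knowledge-base directory not found: ", dir),
              "oncotherapyr_io_error")
  }
  dialects <- c("civic_like", "oncokb_like", "metakb_like")
  found <- dialects[file.exists(file.path(dir, paste0(dialects, ".tsv")))]
  if (length(found) == 0) {
    otr_error(paste0("no evidence files in ", dir),
              "oncotherapyr_io_error")
  }
  bind_rows(map(found, function(d) {
    load_evidence_source(file.path(dir, paste0(d, ".tsv")), dialect = d, ...)
  }))
}

#' Generate a toy VCF file
#'
#' Small deterministic VCF 4.2 with SNVs on KRAS/BRAF/EGFR-like loci,
#' including one multi-allelic record.
#'
#' @param path Output path.
#' @param n Number of records (>= 3).
#' @param seed Integer seed.
#' @return The path, invisibly.
#' @export
generate_toy_vcf <- function(path, n = 5, seed = 1) {
  stopifnot(n >= 3)
  set.seed(seed)
  chrom <- c("12", "7", "7", sample(c(as.character(1:22)), n - 3, TRUE))
  pos <- c(25245350L, 140753336L, 55191822L,
           sample.int(2e8, n - 3))
  ref <- c("C", "A", "G", sample(c("A", "C", "G", "T"), n - 3, TRUE))
  alt <- map_chr(seq_len(n), function(i) {
    if (i == 1) return("T")    # KRAS G12D locus
    if (i == 2) return("T,C")  # BRAF V600E locus, multi-allelic
    if (i == 3) return("A")    # EGFR L858R locus
    sample(setdiff(c("A", "C", "G", "T"), ref[i]), 1)
  })
  lines <- c("##fileformat=VCFv4.2", "##reference=hg38",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
             paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Generate a toy MAF file
#'
#' @param path Output path.
#' @param seed Integer seed.
#' @return The path, invisibly.
#' @export
generate_toy_maf <- function(path, seed = 1) {
  set.seed(seed)
  maf <- tibble(
    Hugo_Symbol = c("KRAS", "BRAF", "EGFR"),
    Chromosome = c("12", "7", "7"),
    Start_Position = c(25245350L, 140753336L, 55191822L),
    Reference_Allele = c("C", "A", "G"),
    Tumor_Seq_Allele2 = c("T", "T", "A"),
    HGVSp_Short = c("p.G12D", "p.V600E", "p.L858R"),
    Tumor_Sample_Barcode = "TOY-0001"
  )
  readr::write_tsv(maf, path, progress = FALSE)
  invisible(path)
}

#' Toy transcript annotation for exon-level matching and fusion tests
#'
#' A two-exon plus-strand transcript whose CDS covers part of both exons
#' (default), or a minus-strand variant of the same layout.
#'
#' @param transcript_id,gene Identifiers.
#' @param strand `"+"` or `"-"`.
#' @return A [transcript_annotation()].
#' @export
toy_transcript <- function(transcript_id = "NM_TOY001.1", gene = "KRAS",
                           strand = "+") {
  # exon1 1001..1180, exon2 1301..1600; CDS 1051..1500
  transcript_annotation(
    transcript_id, gene, strand,
    exons = tibble(start = c(1001L, 1301L), end = c(1180L, 1600L)),
    cds_start = 1051L, cds_end = 1500L
  )
}

#' Generate toy per-variant annotation bundles
#'
#' Deterministic fixture emulating the per-variant annotation tables
#' (population allele frequency, predictor scores, clinical assertions,
#' hotspot and null-variant flags) an interpretation server would
#' retrieve. Known driver changes (KRAS G12D, BRAF V600E, EGFR L858R) get
#' pathogenic-looking annotations; the rest are randomized under `seed`.
#'
#' @param variants Variant tibble.
#' @param seed Integer seed.
#' @return Tibble with one row per variant: protein recoding columns
#'   (`gene`, `ref_aa`, `aa_pos`, `alt_aa`) for known loci, plus
#'   `population_af`,
#'   `revel_like`, `am_like`, `clinical_assertion`,
#'   `known_pathogenic_same_change`, `known_pathogenic_same_residue`,
#'   `in_hotspot_or_functional_domain`, `null_variant_in_lof_gene`.
#' @export
generate_toy_annotations <- function(variants, seed = 1) {
  set.seed(seed)
  n <- nrow(variants)
  known <- c("chr12:g.25245350C>T", "chr7:g.140753336A>T",
             "chr7:g.55191822G>A")
  is_known <- variants$query %in% known |
    paste0(variants$gene, ":p.", variants$ref_aa, variants$aa_pos,
           variants$alt_aa) %in%
    c("KRAS:p.G12D", "BRAF:p.V600E", "EGFR:p.L858R")
  protein <- tibble(
    key = known,
    gene = c("KRAS", "BRAF", "EGFR"),
    ref_aa = c("G", "V", "L"), aa_pos = c(12L, 600L, 858L),
    alt_aa = c("D", "E", "R")
  )
  idx <- match(variants$query, protein$key)
  tibble(
    gene = protein$gene[idx], ref_aa = protein$ref_aa[idx],
    aa_pos = protein$aa_pos[idx], alt_aa = protein$alt_aa[idx],
    population_af = ifelse(is_known, NA_real_,
                           stats::runif(n, 0, 0.2)),
    revel_like = ifelse(is_known, stats::runif(n, 0.8, 0.99),
                        stats::runif(n, 0, 1)),
    am_like = ifelse(is_known, stats::runif(n, 0.8, 0.99),
                     stats::runif(n, 0, 1)),
    clinical_assertion = ifelse(is_known, "pathogenic",
                                sample(c("none", "vus", "benign"), n, TRUE)),
    known_pathogenic_same_change = is_known,
    known_pathogenic_same_residue = is_known,
    in_hotspot_or_functional_domain = is_known,
    null_variant_in_lof_gene = FALSE
  )
}
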