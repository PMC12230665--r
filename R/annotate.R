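#' Run the full variant-interpretation pipeline
#'
#' The end-to-end flow of an interpretation run: parse the input
#' variants, attach annotations, classify each variant into the five ACMG
#' categories, prioritize (pathogenic first), match and merge therapies
#' from the knowledge base, and export a variant table CSV, a treatment
#' table CSV, and per-variant classification traces as JSON. One
#' structured log line with record counts is emitted per stage; on
#' failure, partial outputs are removed and the failing stage is named.
#'
#' @param input Path to the variant input file.
#' @param format Input format: `"vcf"`, `"maf"`, or `"list"`.
#' @param kb_dir Directory of evidence files (see [generate_toy_kb()]);
#'   `NULL` skips therapy matching.
#' @param out_dir Output directory (created if needed).
#' @param annotations Per-variant annotation tibble (columns as in
#'   [generate_toy_annotations()]); `NULL` means no annotations (every
#'   variant classifies from an empty bundle).
#' @param annotation Optional [transcript_annotation()] for exon
#'   matching.
#' @param config ACMG thresholds, see [acmg_config()].
#' @param sort_key Prioritization key, see [prioritize()].
#' @param quiet Suppress stage logs.
#' @return (Invisibly) list with `variants`, `treatments`, `traces`,
#'   `counts`, and the output paths.
#' @export
run_annotate <- function(input, format = c("vcf", "maf", "list"),
                         kb_dir = NULL, out_dir = "onco-out",
                         annotations = NULL, annotation = NULL,
                         config = acmg_config(), sort_key = "acmg",
                         quiet = FALSE) {
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(variants = file.path(out_dir, "variant_table.csv"),
                treatments = file.path(out_dir, "treatments.csv"),
                traces = file.path(out_dir, "classification_traces.json"))
  stage <- "parse"
  log <- function(...) if (!quiet) inform(paste0("[", stage, "] ", ...))
  on_fail <- function(e) {
    stale <- unlist(paths)[file.exists(unlist(paths))]
    if (length(stale) > 0) suppressWarnings(file.remove(stale))
    otr_error(paste0("annotate failed at stage '", stage, "': ",
                     conditionMessage(e)),
              "oncotherapyr_pipeline_error")
  }
  tryCatch({
    variants <- read_variant_file(input, format)
    log(nrow(variants), " variant(s) parsed, ",
        attr(variants, "n_skipped") %||% 0, " skipped")

    stage <- "annotate"
    if (is.null(annotations)) {
      annotations <- tibble(population_af = rep(NA_real_, nrow(variants)),
                            clinical_assertion = "none")
    }
    stopifnot(nrow(annotations) == nrow(variants))
    # annotation tables may recode DNA loci to protein level (gene,
    # residue change); fill fields the input format did not carry
    for (f in c("gene", "ref_aa", "aa_pos", "alt_aa")) {
      if (f %in% names(annotations)) {
        variants[[f]] <- dplyr::coalesce(variants[[f]], annotations[[f]])
      }
    }
    log(nrow(annotations), " annotation bundle(s) attached")

    stage <- "classify"
    results <- map(seq_len(nrow(variants)), function(i) {
      a <- annotations[i, , drop = FALSE]
      scores <- unlist(a[intersect(c("revel_like", "am_like"), names(a))])
      acmg_classify(annotation_bundle(
        population_af = a[["population_af"]] %||% NA_real_,
        predictor_scores = scores[!is.na(scores)],
        clinical_assertion = a[["clinical_assertion"]] %||% "none",
        known_pathogenic_same_change =
          isTRUE(a[["known_pathogenic_same_change"]]),
        known_pathogenic_same_residue =
          isTRUE(a[["known_pathogenic_same_residue"]]),
        in_hotspot_or_functional_domain =
          isTRUE(a[["in_hotspot_or_functional_domain"]]),
        null_variant_in_lof_gene = isTRUE(a[["null_variant_in_lof_gene"]])
      ), config)
    })
    tab <- bind_cols(variants,
                     annotations[setdiff(names(annotations), names(variants))])
    tab$acmg_label <- map_chr(results, "label")
    tab$acmg_criteria <- map_chr(results,
                                 ~ paste(.x$triggered$criterion,
                                         collapse = ";"))
    log(nrow(tab), " variant(s) classified")

    stage <- "prioritize"
    ord <- prioritize(tab, sort_key)

    stage <- "therapy_match"
    treatments <- if (is.null(kb_dir)) {
      tibble()
    } else {
      kb <- suppressWarnings(load_kb_dir(kb_dir))
      # match on protein-level fields; DNA-only records fall back to the
      # gene symbol when present (MAF input carries both)
      matchable <- ord[!is.na(ord$gene), , drop = FALSE]
      if (nrow(matchable) == 0) tibble()
      else build_treatment_table(matchable, kb, annotation)
    }
    log(nrow(treatments), " treatment row(s) after merging")

    stage <- "export"
    fields <- intersect(
      c("query", "level", "chrom", "pos", "ref", "alt", "gene", "ref_aa",
        "aa_pos", "alt_aa", "variant_type", "acmg_label", "acmg_criteria",
        "population_af", "revel_like", "am_like", "clinical_assertion"),
      names(ord))
    write_variant_table(ord, NULL, fields, paths$variants)
    write_treatment_table(treatments, paths$treatments)
    traces <- map(seq_len(nrow(tab)), function(i) {
      list(query = tab$query[i], label = results[[i]]$label,
           criteria = results[[i]]$triggered[
             c("criterion", "strength", "annotation", "value")])
    })
    writeLines(jsonlite::toJSON(traces, auto_unbox = TRUE, pretty = TRUE),
               paths$traces)
    log("variant table, treatment table, and traces written to ", out_dir)

    invisible(list(variants = ord, treatments = treatments, traces = traces,
                   counts = list(parsed = nrow(variants),
                                 classified = nrow(tab),
                                 exported = nrow(ord),
                                 treatments = nrow(treatments)),
                   paths = paths))
  }, error = function(e) {
    if (inherits(e, "oncotherapyr_pipeline_error")) stop(e)
    on_fail(e)
  })
}
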