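test_that("response-type mapping reproduces the documented source rules", {
  # OncoKB-style level codes double as response codes
  expect_equal(map_response_type("oncokb_like",
                                 c("R1", "R2", "1", "2", "3A", "3B", "4")),
               c("resistant", "resistant", "sensitive", "sensitive",
                 "sensitive", "sensitive", "unknown"))
  # CIViC-style significance text
  expect_equal(map_response_type("civic_like",
                                 c("Sensitivity/Response", "Resistance",
                                   "N/A", "Reduced Sensitivity")),
               c("sensitive", "resistant", "unknown", "sensitive"))
  # MetaKB-style descriptive phrases
  expect_equal(map_response_type("metakb_like",
                                 c("predicts sensitivity to therapy",
                                   "better response when treated",
                                   "confers resistance", "no effect")),
               c("sensitive", "sensitive", "resistant", "unknown"))
})

test_that("evidence levels map to AMP/ASCO/CAP tiers with warning on unmapped", {
  expect_equal(map_evidence_level("oncokb_like", "1"), "A")
  expect_equal(map_evidence_level("oncokb_like", "3A"), "B")
  expect_equal(map_evidence_level("civic_like", "C"), "C")
  expect_equal(map_evidence_level("civic_like", "E"), "D")
  expect_warning(t <- map_evidence_level("oncokb_like", "Z9"), "unmapped")
  expect_true(is.na(t))
})

test_that("substitutes records split into single-drug options, conserving drugs", {
  rec <- tibble::tibble(
    biomarker_gene = c("BRAF", "BRAF", "KRAS"),
    drugs = list(c("dabrafenib", "vemurafenib"),
                 c("dabrafenib", "trametinib"), "sotorasib"),
    interaction = c("substitutes", "combination", "none"),
    citation_id = c("P1", "P2", "P3"))
  out <- split_substitutes(rec)
  expect_equal(nrow(out), 4)
  expect_false(any(out$interaction == "substitutes"))
  # combination and single-drug rows pass through unchanged
  expect_equal(out$drugs[out$citation_id == "P2"][[1]],
               c("dabrafenib", "trametinib"))
  # drug multiset is conserved
  expect_equal(sort(unlist(out$drugs)), sort(unlist(rec$drugs)))
  # expanded rows are single-drug
  expect_true(all(lengths(out$drugs[out$citation_id == "P1"]) == 1))
})

test_that("loading a dialect applies the full normalization pipeline", {
  dir <- local_kb_dir(seed = 7, n_per_source = 5)
  civ <- suppressWarnings(
    load_evidence_source(file.path(dir, "civic_like.tsv"), "civic_like"))
  expect_true(all(civ$source == "civic_like"))
  expect_true(all(civ$response %in% c("sensitive", "resistant", "unknown")))
  expect_true(all(is.na(civ$amp_tier) | civ$amp_tier %in% c("A", "B", "C", "D")))
  expect_false(any(civ$interaction == "substitutes"))
  expect_true(all(lengths(civ$drugs) >= 1))
  # determinism: loading the same file twice gives identical records
  civ2 <- suppressWarnings(
    load_evidence_source(file.path(dir, "civic_like.tsv"), "civic_like"))
  expect_identical(civ, civ2)
})

test_that("normalization is idempotent on already-normalized records", {
  dir <- local_kb_dir(seed = 3, n_per_source = 5)
  kb <- load_toy_kb(dir)
  again <- split_substitutes(kb)
  again$cancer_type_main <- normalize_cancer_type(
    again$cancer_type_main, read_cancer_types())
  expect_equal(nrow(again), nrow(kb))
  expect_equal(again$cancer_type_main, kb$cancer_type_main)
  expect_equal(again$drugs, kb$drugs)
})

test_that("records without a drug are rejected and counted", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    gene = c("KRAS", "BRAF"), variant = c("G12C", "V600E"),
    disease = "Melanoma", drugs = c("", "dabrafenib"),
    drug_interaction_type = "none", significance = "Sensitivity/Response",
    evidence_level = "B", evidence_statement = "s",
    citation_id = c("P1", "P2")), f)
  expect_warning(rec <- load_evidence_source(f, "civic_like"),
                 "without a drug")
  expect_equal(nrow(rec), 1)
  expect_equal(attr(rec, "n_skipped"), 1)
})

test_that("missing dialect columns raise a named format error", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(gene = "KRAS", variant = "G12C"), f)
  err <- expect_error(load_evidence_source(f, "civic_like"),
                      class = "oncotherapyr_format_error")
  expect_match(conditionMessage(err), "significance")
})
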