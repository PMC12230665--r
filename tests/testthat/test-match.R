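test_that("the five match types label the documented examples", {
  dir <- local_kb_dir(seed = 1)
  kb <- load_toy_kb(dir)
  v <- parse_query("KRAS:p.G12A")
  m <- match_evidence(v, kb, toy_transcript())

  expect_setequal(unique(m$match_type[m$biomarker_spec == "G12A"]), "exact")
  expect_setequal(unique(m$match_type[m$biomarker_spec == "G12C"]),
                  "same_pos_other_aa")
  expect_equal(unique(m$match_type[m$biomarker_spec == "G12"]),
               "same_pos_any")
  expect_equal(unique(m$match_type[m$biomarker_spec == "exon 1"]),
               "same_exon")
  expect_equal(unique(m$match_type[m$biomarker_spec == "mutation"]),
               "gene_level")
  # broader levels are not suppressed by the exact hit
  expect_true(all(c("exact", "gene_level") %in% m$match_type))
})

test_that("gene-level evidence is retrieved for a variant with no exact record", {
  dir <- local_kb_dir(seed = 1)
  kb <- load_toy_kb(dir)
  m <- match_evidence(parse_query("RET:p.M918T"), kb)
  expect_equal(nrow(m), 1)
  expect_equal(m$match_type, "gene_level")
  expect_equal(unlist(m$drugs), "selpercatinib")
  expect_equal(m$amp_tier, "A")
  expect_equal(m$response, "sensitive")
})

test_that("matching an absent gene returns an empty result, not an error", {
  dir <- local_kb_dir(seed = 1)
  kb <- load_toy_kb(dir)
  out <- match_evidence(parse_query("GENEX:p.A1V"), kb)
  expect_equal(nrow(out), 0)
})

test_that("labels equal a brute-force per-record matcher on a randomized kb", {
  dir <- local_kb_dir(seed = 11, n_per_source = 65)  # ~200 records
  kb <- load_toy_kb(dir)
  ann <- toy_transcript()
  queries <- c("KRAS:p.G12A", "KRAS:p.G12C", "BRAF:p.V600E", "EGFR:p.L858R",
               "TP53:p.R12C", "NRAS:p.G12D", "ALK:p.E790K")
  for (q in queries) {
    v <- parse_query(q)
    got <- suppressWarnings(match_evidence(v, kb, ann))
    want <- brute_force_match(v, kb, ann)
    # same set of matched records
    key <- function(tb) paste(tb$biomarker_gene, tb$biomarker_spec,
                              tb$citation_id, tb$source)
    expect_setequal(key(got), key(kb)[!is.na(want)])
    # identical label for every matched record
    idx <- match(key(got), key(kb))
    expect_equal(got$match_type, want[idx], info = q)
  }
})

test_that("match scope grows monotonically with specificity level", {
  dir <- local_kb_dir(seed = 5, n_per_source = 40)
  kb <- load_toy_kb(dir)
  ann <- toy_transcript()
  order <- c("exact", "same_pos_other_aa", "same_pos_any", "same_exon",
             "gene_level")
  for (q in c("KRAS:p.G12A", "BRAF:p.V600E", "EGFR:p.L858R")) {
    m <- suppressWarnings(match_evidence(parse_query(q), kb, ann))
    prev <- character(0)
    for (k in seq_along(order)) {
      cur <- m$citation_id[m$match_type %in% order[seq_len(k)]]
      expect_true(all(prev %in% cur), info = paste(q, order[k]))
      prev <- cur
    }
  }
})

test_that("same-exon matching without an annotation is skipped with a warning", {
  dir <- local_kb_dir(seed = 1)
  kb <- load_toy_kb(dir)
  expect_warning(m <- match_evidence(parse_query("KRAS:p.G12A"), kb),
                 "same-exon matching skipped")
  expect_false("same_exon" %in% m$match_type)
})

test_that("duplicates merge on the five-field key with sources unioned", {
  dir <- local_kb_dir(seed = 1)
  kb <- load_toy_kb(dir)
  m <- suppressWarnings(match_evidence(parse_query("KRAS:p.G12A"), kb))
  merged <- merge_duplicates(m)
  # the generated cross-source duplicate collapses
  dup <- merged[merged$citation_id == "PMID:30000001", ]
  expect_equal(nrow(dup), 1)
  expect_setequal(unlist(dup$sources), c("civic_like", "metakb_like"))
  # records differing in citation stay distinct
  expect_gte(nrow(merged[grepl("PMID:3000000", merged$citation_id), ]), 3)
  # idempotence and key-multiset conservation
  expect_equal(nrow(merge_duplicates(merged)), nrow(merged))
  expect_setequal(unique(oncotherapyr:::merge_key(m)),
                  oncotherapyr:::merge_key(merged))
})

test_that("the treatment table concatenates per-variant matches after merging", {
  dir <- local_kb_dir(seed = 9, n_per_source = 20)
  kb <- load_toy_kb(dir)
  variants <- parse_variants(c("KRAS:p.G12A", "RET:p.M918T", "GENEX:p.A1V"))
  tab <- suppressWarnings(build_treatment_table(variants, kb))
  # brute-force recount: per-variant merge counts sum to the table rows
  recount <- sum(vapply(seq_len(nrow(variants)), function(i) {
    nrow(merge_duplicates(suppressWarnings(
      match_evidence(variants[i, ], kb))))
  }, numeric(1)))
  expect_equal(nrow(tab), recount)
  # a variant with no hits contributes no rows
  expect_false(any(grepl("GENEX", tab$biomarker)))
  # sorted by tier first
  tiers <- match(dplyr::coalesce(tab$amp_tier, "Z"), c("A", "B", "C", "D", "Z"))
  expect_true(!is.unsorted(tiers))
})
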