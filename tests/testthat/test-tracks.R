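test_that("feature tracks align all five per-residue annotations", {
  st <- generate_synthetic_structure("helix", 20)
  domains <- tibble::tibble(start = 5L, end = 12L, label = "kinase-like")
  known <- tibble::tibble(aa_pos = c(3L, 9L), label = c("V3A", "K9E"))
  binding <- tibble::tibble(res_index = 1:20,
                            binding_prob = seq(0, 0.95, length.out = 20))
  ft <- build_feature_tracks(st, 8, domain_table = domains,
                             known_variants = known,
                             binding_table = binding, n_points = 500)
  expect_equal(nrow(ft), 20)
  expect_true(all(c("asa", "rsa", "calpha_dist", "ss", "domain",
                    "binding_prob", "known_variant") %in% names(ft)))
  expect_equal(ft$calpha_dist[ft$res_index == 8], 0)
  expect_true(all(ft$calpha_dist[ft$res_index != 8] > 0))
  expect_equal(ft$domain[6], "kinase-like")
  expect_true(is.na(ft$domain[2]))
  expect_equal(ft$known_variant[3], "V3A")
  expect_true(all(ft$rsa >= 0 & ft$rsa <= 1))
})

test_that("track length mismatches raise an error naming the track", {
  st <- generate_synthetic_structure("helix", 8)
  bad_binding <- tibble::tibble(res_index = 99L, binding_prob = 0.5)
  err <- expect_error(
    build_feature_tracks(st, 4, binding_table = bad_binding, n_points = 92),
    class = "oncotherapyr_track_error")
  expect_match(conditionMessage(err), "binding_sites")
  err2 <- expect_error(
    build_feature_tracks(st, 4, domain_table = tibble::tibble(a = 1),
                         n_points = 92),
    class = "oncotherapyr_track_error")
  expect_match(conditionMessage(err2), "domains")
})

test_that("the context summary encodes the interpretation rules", {
  st <- generate_synthetic_structure("helix", 20)
  # buried residue inside a domain with a high predictor score
  ft <- build_feature_tracks(st, 10,
                             domain_table = tibble::tibble(
                               start = 5L, end = 15L, label = "dom"),
                             predictor_score = 0.9, n_points = 500)
  expect_match(attr(ft, "context_summary"), "pathogenic-leaning context")
  # exposed loop residue outside any domain with a low score
  hp <- generate_synthetic_structure("hairpin", 16)
  ft2 <- build_feature_tracks(hp, 9, predictor_score = 0.1, n_points = 500)
  row9 <- ft2[ft2$res_index == 9, ]
  if (row9$ss == "C" && row9$rsa >= mean(ft2$rsa, na.rm = TRUE)) {
    expect_match(attr(ft2, "context_summary"), "benign-leaning context")
  }
  # no predictor score: indeterminate
  ft3 <- build_feature_tracks(st, 10, n_points = 92)
  expect_match(attr(ft3, "context_summary"), "indeterminate context")
})

test_that("tracks export to TSV and JSON", {
  st <- generate_synthetic_structure("helix", 8)
  ft <- build_feature_tracks(st, 4, n_points = 92)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_feature_tracks(ft, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(back), 8)
  expect_equal(colnames(back)[1:6],
               c("index", "aa", "asa", "rsa", "calpha_dist", "ss"))
  js <- withr::local_tempfile(fileext = ".json")
  write_feature_tracks(ft, js)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$mutated_index, 4)
  expect_equal(nrow(parsed$residues), 8)
})

test_that("autoplot produces a ggplot for tracks and hierarchies", {
  st <- generate_synthetic_structure("helix", 8)
  ft <- build_feature_tracks(st, 4, n_points = 92)
  expect_s3_class(ggplot2::autoplot(ft), "ggplot")
  dir <- local_kb_dir(seed = 1)
  kb <- load_toy_kb(dir)
  m <- merge_duplicates(suppressWarnings(
    match_evidence(parse_query("KRAS:p.G12A"), kb)))
  expect_s3_class(ggplot2::autoplot(build_hierarchy(m)), "ggplot")
})
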