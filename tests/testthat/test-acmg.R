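test_that("criteria trigger from the documented annotation patterns", {
  cfg <- acmg_config()
  # common variant: stand-alone benign plus BS1
  t1 <- evaluate_criteria(annotation_bundle(population_af = 0.20), cfg)
  expect_true(all(c("BA1", "BS1") %in% t1$criterion))
  # nothing known but absence from population databases
  t2 <- evaluate_criteria(annotation_bundle(), cfg)
  expect_equal(t2$criterion, "PM2")
  # direct flag mappings
  t3 <- evaluate_criteria(
    annotation_bundle(population_af = 0.5,
                      known_pathogenic_same_change = TRUE), cfg)
  expect_true("PS1" %in% t3$criterion)
  # predictor consensus both ways
  t4 <- evaluate_criteria(
    annotation_bundle(population_af = 0.001,
                      predictor_scores = c(a = 0.9, b = 0.95)), cfg)
  expect_true("PP3" %in% t4$criterion)
  t5 <- evaluate_criteria(
    annotation_bundle(population_af = 0.001,
                      predictor_scores = c(a = 0.1, b = 0.05)), cfg)
  expect_true("BP4" %in% t5$criterion)
  # clinical assertions
  t6 <- evaluate_criteria(
    annotation_bundle(population_af = 0.001,
                      clinical_assertion = "likely_benign"), cfg)
  expect_true("BP6" %in% t6$criterion)
  # every trigger carries a trace entry
  expect_true(all(nzchar(t1$annotation)))
})

test_that("malformed configurations are rejected", {
  bad <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("af_ba1\t0.0001", "af_bs1\t0.01", "af_pm2\t0.05",
               "predictor_deleterious\t0.7", "predictor_benign\t0.3",
               "predictor_consensus\t0.75"), bad)
  expect_error(acmg_config(bad), class = "oncotherapyr_config_error")
  bad2 <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("af_ba1\t1.5", "af_bs1\t0.01", "af_pm2\t0.0001",
               "predictor_deleterious\t0.7", "predictor_benign\t0.3",
               "predictor_consensus\t0.75"), bad2)
  expect_error(acmg_config(bad2), class = "oncotherapyr_config_error")
})

test_that("combining rules reproduce the documented verdicts", {
  expect_equal(combine_criteria(character(0)), "vus")
  expect_equal(combine_criteria(c("PVS1", "PS1")), "pathogenic")
  expect_equal(combine_criteria("BA1"), "benign")
  expect_equal(combine_criteria(c("PM2", "PP3")), "vus")
  expect_equal(combine_criteria(c("PS1", "BA1")), "vus")  # contradiction
  expect_equal(combine_criteria(c("PVS1", "PM2")), "likely_pathogenic")
  expect_equal(combine_criteria(c("PS1", "PM1", "PM2")), "likely_pathogenic")
  expect_equal(combine_criteria(c("BS1", "BP4")), "likely_benign")
  expect_error(combine_criteria("PX9"), class = "oncotherapyr_config_error")
})

all_subsets <- function(codes) {
  out <- list(character(0))
  for (c_ in codes) out <- c(out, lapply(out, function(s) c(s, c_)))
  out
}

test_that("the combiner matches an independent oracle on every subset", {
  codes <- c("PVS1", "PS1", "PM1", "PM2", "PM5", "PP3", "PP5",
             "BA1", "BS1", "BP4", "BP6")
  subsets <- all_subsets(codes)
  expect_equal(length(subsets), 2^11)
  got <- vapply(subsets, combine_criteria, character(1))
  want <- vapply(subsets, acmg_oracle, character(1))
  expect_identical(got, want)
})

test_that("adding pathogenic evidence never moves the label toward benign", {
  codes <- c("PVS1", "PS1", "PM1", "PM2", "PM5", "PP3", "PP5",
             "BA1", "BS1", "BP4", "BP6")
  path_codes <- c("PVS1", "PS1", "PM1", "PM2", "PM5", "PP3", "PP5")
  ok <- TRUE
  for (s in all_subsets(codes)) {
    base <- acmg_label_rank(combine_criteria(s))
    for (add in setdiff(path_codes, s)) {
      if (acmg_label_rank(combine_criteria(c(s, add))) < base) ok <- FALSE
    }
  }
  expect_true(ok)
})

test_that("classification results carry tidy traces and glance summaries", {
  r <- acmg_classify(annotation_bundle(population_af = 0.2))
  expect_s3_class(r, "acmg_result")
  expect_equal(r$label, "benign")
  tr <- tidy(r)
  expect_true(all(c("criterion", "strength", "annotation", "value") %in%
                    names(tr)))
  g <- glance(r)
  expect_equal(g$label, "benign")
  expect_equal(g$n_benign, nrow(tr))
  # trace non-empty iff triggered non-empty
  r0 <- acmg_classify(annotation_bundle(population_af = 0.02))
  expect_equal(nrow(tidy(r0)) > 0, r0$label != "vus" ||
                 nrow(r0$triggered) > 0)
})

test_that("prioritization sorts by label with genomic tie-breaks", {
  v <- tibble::tibble(
    query = paste0("q", 1:5),
    chrom = c("7", "2", "12", "7", "X"),
    pos = c(100L, 50L, 10L, 20L, 5L),
    acmg_label = c("benign", "pathogenic", "vus", "pathogenic",
                   "likely_benign"),
    clinical_assertion = c("benign", "pathogenic", "none", "vus", "none"),
    revel_like = c(0.1, 0.99, NA, 0.8, 0.3))
  out <- prioritize(v)
  expect_equal(out$acmg_label,
               c("pathogenic", "pathogenic", "vus", "likely_benign",
                 "benign"))
  # tie within pathogenic broken by (chrom, pos) ascending
  expect_equal(out$query[1:2], c("q2", "q4"))
  # permutation property
  expect_setequal(out$query, v$query)
  # predictor sort puts absent scores last
  out2 <- prioritize(v, "revel_like")
  expect_equal(out2$query[1], "q2")
  expect_true(is.na(out2$revel_like[5]))
  err <- expect_error(prioritize(v, "nonsense"),
                      class = "oncotherapyr_sort_error")
  expect_match(conditionMessage(err), "acmg")
})
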