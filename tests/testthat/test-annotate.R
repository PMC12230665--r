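run_toy_pipeline <- function(out_dir, seed = 1, env = parent.frame()) {
  vcf <- withr::local_tempfile(fileext = ".vcf", .local_envir = env)
  generate_toy_vcf(vcf, n = 5, seed = seed)
  kb <- local_kb_dir(seed = seed, env = env)
  v <- read_variant_file(vcf, "vcf")
  ann <- generate_toy_annotations(v, seed = seed)
  suppressMessages(suppressWarnings(
    run_annotate(vcf, "vcf", kb_dir = kb, out_dir = out_dir,
                 annotations = ann, annotation = toy_transcript(),
                 quiet = TRUE)))
}

test_that("the pipeline conserves counts across stages", {
  out <- withr::local_tempdir()
  res <- run_toy_pipeline(out)
  expect_equal(res$counts$parsed, res$counts$classified)
  expect_equal(res$counts$classified, res$counts$exported)
  csv <- readr::read_csv(file.path(out, "variant_table.csv"),
                         show_col_types = FALSE)
  expect_equal(nrow(csv), res$counts$parsed)
})

test_that("the variant table is sorted pathogenic-first by default", {
  out <- withr::local_tempdir()
  run_toy_pipeline(out)
  csv <- readr::read_csv(file.path(out, "variant_table.csv"),
                         show_col_types = FALSE)
  rank <- match(csv$acmg_label,
                c("pathogenic", "likely_pathogenic", "vus", "likely_benign",
                  "benign"))
  expect_true(!is.unsorted(rank))
  expect_equal(csv$acmg_label[1], "pathogenic")
})

test_that("the treatment table carries the documented column set", {
  out <- withr::local_tempdir()
  run_toy_pipeline(out)
  tt <- readr::read_csv(file.path(out, "treatments.csv"),
                        show_col_types = FALSE)
  expect_equal(colnames(tt),
               c("biomarker", "match_type", "drugs", "drug_class",
                 "evidence_level", "response", "citation_id"))
  expect_gt(nrow(tt), 0)
  # the known drivers retrieve evidence at several specificity levels
  expect_true(all(c("exact", "same_pos_other_aa", "gene_level") %in%
                    tt$match_type))
})

test_that("two identical runs produce byte-identical outputs", {
  o1 <- withr::local_tempdir(); o2 <- withr::local_tempdir()
  run_toy_pipeline(o1); run_toy_pipeline(o2)
  for (f in c("variant_table.csv", "treatments.csv",
              "classification_traces.json")) {
    expect_identical(readLines(file.path(o1, f)),
                     readLines(file.path(o2, f)), info = f)
  }
})

test_that("empty input yields header-only outputs without failure", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), vcf)
  out <- withr::local_tempdir()
  res <- suppressMessages(suppressWarnings(
    run_annotate(vcf, "vcf", out_dir = out, quiet = TRUE)))
  expect_equal(res$counts$parsed, 0)
  expect_equal(length(readLines(file.path(out, "variant_table.csv"))), 1)
})

test_that("a missing kb directory fails naming the therapy stage", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  generate_toy_vcf(vcf)
  out <- withr::local_tempdir()
  err <- expect_error(
    suppressMessages(run_annotate(vcf, "vcf", kb_dir = "no/such/dir",
                                  out_dir = out, quiet = TRUE)),
    class = "oncotherapyr_pipeline_error")
  expect_match(conditionMessage(err), "therapy_match")
  # partial outputs were removed
  expect_false(file.exists(file.path(out, "variant_table.csv")))
})

test_that("classification traces serialize one entry per variant", {
  out <- withr::local_tempdir()
  res <- run_toy_pipeline(out)
  tr <- jsonlite::fromJSON(file.path(out, "classification_traces.json"),
                           simplifyVector = FALSE)
  expect_equal(length(tr), res$counts$parsed)
  expect_true(all(vapply(tr, function(x) x$label %in%
                           c("pathogenic", "likely_pathogenic", "vus",
                             "likely_benign", "benign"), logical(1))))
})
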