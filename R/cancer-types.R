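#' Read a cancer-type table
#'
#' Three-column TSV (`label`, `main_type`, `synonyms`; synonyms
#' `;`-separated) emulating the OncoTree main-type hierarchy. The packaged
#' default is a small synthetic table used by the fixture generators.
#'
#' @param path Path to the table; default is the packaged synthetic table.
#' @return Tibble with columns `label`, `main_type`, `synonyms` (list).
#' @export
read_cancer_types <- function(path = NULL) {
  path <- path %||% otr_extdata("cancer_types_synthetic.tsv")
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = "ccc")
  need <- c("label", "main_type", "synonyms")
  missing <- setdiff(need, colnames(tab))
  if (length(missing) > 0) {
    otr_error(paste0("cancer-type table is missing column(s): ",
                     paste(missing, collapse = ", ")),
              "oncotherapyr_format_error")
  }
  mutate(tab, synonyms = map(.data$synonyms, function(s) {
    if (is.na(s) || !nzchar(s)) character(0) else str_trim(str_split(s, ";")[[1]])
  }))
}

# Levenshtein similarity normalized by the longer string, in [0, 1]
string_similarity <- function(a, b) {
  d <- as.numeric(utils::adist(a, b, ignore.case = TRUE))
  m <- pmax(nchar(a), nchar(b))
  ifelse(m == 0, 1, 1 - d / m)
}

#' Normalize free-text cancer types to main tumor types
#'
#' Exact case-insensitive matching against labels, main types, and synonyms
#' always wins; otherwise the highest-similarity entry at or above
#' `threshold` decides (similarity = 1 - edit distance / longer length),
#' ties broken by the lexicographically smallest main type. Anything below
#' threshold maps to `"Unmatched"`.
#'
#' @param raw Character vector of free-text cancer-type labels.
#' @param table Cancer-type table from [read_cancer_types()].
#' @param threshold Similarity threshold in (0, 1]; default 0.85.
#' @return Character vector of main types (or `"Unmatched"`).
#' @export
normalize_cancer_type <- function(raw, table = read_cancer_types(),
                                  threshold = 0.85) {
  stopifnot(nrow(table) > 0, threshold > 0, threshold <= 1)
  # flatten to (term, main_type) pairs
  terms <- bind_rows(
    tibble(term = table$label, main = table$main_type),
    tibble(term = table$main_type, main = table$main_type),
    tibble(term = unlist(table$synonyms),
           main = rep(table$main_type, lengths(table$synonyms)))
  ) |>
    mutate(key = normalize_label(.data$term)) |>
    distinct(.data$key, .data$main)

  map_chr(raw, function(x) {
    if (is.na(x) || !nzchar(str_trim(x))) return("Unmatched")
    key <- normalize_label(x)
    exact <- terms$main[terms$key == key]
    if (length(exact) > 0) return(sort(exact)[1])
    sim <- string_similarity(key, terms$key)
    best <- max(sim)
    if (best < threshold) return("Unmatched")
    sort(terms$main[sim == best])[1]
  })
}
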