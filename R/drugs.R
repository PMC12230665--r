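#' Read a drug-classification table
#'
#' Two-column TSV (`drug`, `class`). When a drug appears under several
#' classes the first row wins and a warning is emitted. The packaged
#' default is a small synthetic table.
#'
#' @param path Path to the table; default is the packaged synthetic table.
#' @return Tibble with columns `drug` (normalized label) and `class`.
#' @export
read_drug_classes <- function(path = NULL) {
  path <- path %||% otr_extdata("drug_classes_synthetic.tsv")
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = "cc")
  missing <- setdiff(c("drug", "class"), colnames(tab))
  if (length(missing) > 0) {
    otr_error(paste0("drug-class table is missing column(s): ",
                     paste(missing, collapse = ", ")),
              "oncotherapyr_format_error")
  }
  tab <- mutate(tab, drug = normalize_label(.data$drug))
  if (anyDuplicated(tab$drug)) {
    dup <- unique(tab$drug[duplicated(tab$drug)])
    warn(paste0("drug(s) listed under multiple classes (first wins): ",
                paste(dup, collapse = ", ")))
    tab <- distinct(tab, .data$drug, .keep_all = TRUE)
  }
  tab
}

#' Classify drugs by label
#'
#' Case-insensitive exact lookup (labels are trimmed, case-folded, internal
#' whitespace collapsed before comparison); unknown drugs are
#' `"Unclassified"`.
#'
#' @param label Character vector of drug labels.
#' @param table Drug-class table from [read_drug_classes()].
#' @return Character vector of class labels.
#' @export
classify_drug <- function(label, table = read_drug_classes()) {
  if (length(label) == 0) return(character(0))
  if (is.null(table)) return(rep("Unclassified", length(label)))
  hit <- table$class[match(normalize_label(label), table$drug)]
  dplyr::coalesce(hit, "Unclassified")
}
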