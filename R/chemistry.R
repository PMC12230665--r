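#' Load the packaged amino-acid property table
#'
#' Residue masses (average, Da), formal side-chain charge at pH 7 (His
#' counted as positive), polarity and aromaticity flags, the helix-breaker
#' set (Pro, Gly), Chou-Fasman beta-sheet propensities, and Kyte-Doolittle
#' hydropathy. All scales are replaceable via `path`.
#'
#' @param path Optional alternative table (same columns).
#' @return Tibble keyed by one-letter code `aa`.
#' @export
aa_properties <- function(path = NULL) {
  path <- path %||% otr_extdata("aa_properties.tsv")
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = "ccdiiiidd")
}

#' Load the packaged BLOSUM62 substitution matrix
#'
#' @return Integer matrix with the 20 amino acids plus `*`.
#' @export
blosum62_matrix <- function() {
  tab <- readr::read_tsv(otr_extdata("blosum62.tsv"), show_col_types = FALSE,
                         progress = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$aa
  storage.mode(m) <- "integer"
  m
}

#' Physicochemical profile of an amino-acid substitution
#'
#' Describes what changes when `ref_aa` is replaced by `alt_aa`: molecular
#' weight delta, side-chain charge transition at pH 7, polarity and
#' aromaticity changes, whether a helix breaker (Pro/Gly) is introduced,
#' beta-sheet propensity and hydropathy deltas, the BLOSUM62 substitution
#' score, whether a new cysteine (disulfide partner) appears, and whether
#' the new side chain can form charge pairs (salt bridges).
#'
#' @param ref_aa,alt_aa One-letter codes of the reference and alternate
#'   amino acid (canonical 20).
#' @param properties Property table from [aa_properties()].
#' @param blosum Substitution matrix from [blosum62_matrix()].
#' @return One-row tibble: `ref_aa`, `alt_aa`, `delta_weight`,
#'   `charge_from`, `charge_to`, `polarity_change`, `aromaticity_change`,
#'   `helix_breaker_introduced`, `delta_beta_propensity`,
#'   `delta_hydropathy`, `blosum62`, `new_cys`, `charge_pair_potential`.
#' @export
substitution_features <- function(ref_aa, alt_aa,
                                  properties = aa_properties(),
                                  blosum = blosum62_matrix()) {
  for (a in c(ref_aa, alt_aa)) {
    if (!a %in% properties$aa) {
      otr_error(paste0("not a canonical amino acid: '", a, "'"),
                "oncotherapyr_aa_error")
    }
  }
  r <- properties[properties$aa == ref_aa, ]
  a <- properties[properties$aa == alt_aa, ]
  charge_label <- function(c) c("negative", "neutral", "positive")[c + 2]
  tibble(
    ref_aa = ref_aa, alt_aa = alt_aa,
    delta_weight = a$residue_mass - r$residue_mass,
    charge_from = charge_label(r$charge),
    charge_to = charge_label(a$charge),
    polarity_change = r$polar != a$polar,
    aromaticity_change = r$aromatic != a$aromatic,
    helix_breaker_introduced = a$helix_breaker == 1 && r$helix_breaker == 0,
    delta_beta_propensity = a$beta_propensity - r$beta_propensity,
    delta_hydropathy = a$hydropathy - r$hydropathy,
    blosum62 = blosum[ref_aa, alt_aa],
    new_cys = alt_aa == "C" && ref_aa != "C",
    charge_pair_potential = a$charge != 0
  )
}
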