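# side-chain atoms relevant for charge pairs / disulfides
NEG_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
POS_ATOMS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                  HIS = c("ND1", "NE2"))

aa_charge_sign <- function(aa) {
  dplyr::case_when(aa %in% c("D", "E") ~ -1L,
                   aa %in% c("K", "R", "H") ~ 1L,
                   TRUE ~ 0L)
}

# terminal/functional atom coordinates of one residue for bridge geometry;
# falls back to CB then CA as proxy when the side chain is absent
residue_anchor <- function(structure, res_index, atoms_wanted) {
  at <- structure$atoms[structure$atoms$res_index == res_index, , drop = FALSE]
  sel <- at[at$atom %in% atoms_wanted, , drop = FALSE]
  if (nrow(sel) == 0) sel <- at[at$atom == "CB", , drop = FALSE]
  if (nrow(sel) == 0) sel <- at[at$atom == "CA", , drop = FALSE]
  sel[, c("atom", "x", "y", "z")]
}

#' Disulfide-bond and salt-bridge candidates introduced or lost by a
#' substitution
#'
#' Scans the wild-type structure around a mutated residue:
#'
#' * a disulfide candidate is reported when the alternate residue is
#'   cysteine and another cysteine's S-gamma (or C-beta proxy when absent)
#'   lies within `disulfide_cutoff` of the mutated residue's equivalent
#'   atom;
#' * a salt-bridge candidate is reported when the alternate residue is
#'   charged and an oppositely charged side-chain terminal atom lies
#'   within `salt_cutoff`;
#' * bridges lost are reported symmetrically when the reference residue
#'   was a cysteine or charged.
#'
#' @param structure A [read_structure()] result.
#' @param mutated_index Residue index of the mutated site.
#' @param ref_aa,alt_aa One-letter reference and alternate amino acid.
#' @param disulfide_cutoff S-gamma--S-gamma distance cutoff in Angstrom
#'   (default 2.5).
#' @param salt_cutoff Charged-atom distance cutoff in Angstrom
#'   (default 4.0).
#' @return Tibble with columns `kind` (`disulfide`/`salt_bridge`),
#'   `change` (`gained`/`lost`), `partner_res`, `partner_aa`, `distance`.
#' @export
detect_bridges <- function(structure, mutated_index, ref_aa, alt_aa,
                           disulfide_cutoff = 2.5, salt_cutoff = 4.0) {
  stopifnot(disulfide_cutoff > 0, salt_cutoff > 0)
  res <- structure$residues
  self <- residue_anchor(structure, mutated_index, "SG")
  out <- list()
  add <- function(kind, change, partner, dist) {
    out[[length(out) + 1]] <<- tibble(
      kind = kind, change = change, partner_res = partner,
      partner_aa = res$aa[res$res_index == partner][1], distance = dist)
  }
  others <- res$res_index[res$res_index != mutated_index]

  min_dist <- function(a, b) {
    if (nrow(a) == 0 || nrow(b) == 0) return(Inf)
    am <- as.matrix(a[, c("x", "y", "z")])
    bm <- as.matrix(b[, c("x", "y", "z")])
    min(apply(bm, 1, function(q) {
      min(sqrt(colSums((t(am) - q)^2)))
    }))
  }

  scan_disulfide <- function(change) {
    for (r in others) {
      if (res$aa[res$res_index == r][1] != "C") next
      d <- min_dist(self, residue_anchor(structure, r, "SG"))
      if (d <= disulfide_cutoff) add("disulfide", change, r, d)
    }
  }
  scan_salt <- function(sign, change) {
    partner_atoms <- if (sign > 0) NEG_ATOMS else POS_ATOMS
    self_anchor <- residue_anchor(
      structure, mutated_index,
      unlist(c(NEG_ATOMS, POS_ATOMS), use.names = FALSE))
    for (r in others) {
      raa <- res$aa[res$res_index == r][1]
      if (is.na(raa) || aa_charge_sign(raa) != -sign) next
      rname <- res$aa[res$res_index == r][1]
      wanted <- unlist(partner_atoms, use.names = FALSE)
      d <- min_dist(self_anchor, residue_anchor(structure, r, wanted))
      if (d <= salt_cutoff) add("salt_bridge", change, r, d)
    }
  }

  if (alt_aa == "C") scan_disulfide("gained")
  if (ref_aa == "C" && alt_aa != "C") scan_disulfide("lost")
  s_alt <- aa_charge_sign(alt_aa); s_ref <- aa_charge_sign(ref_aa)
  if (s_alt != 0) scan_salt(s_alt, "gained")
  if (s_ref != 0 && s_ref != s_alt) scan_salt(s_ref, "lost")

  if (length(out) == 0) {
    return(tibble(kind = character(0), change = character(0),
                  partner_res = integer(0), partner_aa = character(0),
                  distance = numeric(0)))
  }
  arrange(bind_rows(out), .data$kind, .data$change, .data$distance)
}

#' Spatially adjacent known variants around a mutated site
#'
#' Known variants whose residue C-alpha lies within `radius` of the
#' mutated residue's C-alpha, sorted by increasing 3D distance. Each entry
#' reports both the spatial distance and the sequence separation, making
#' residues that are close in space but distant in sequence visible.
#'
#' @param structure A [read_structure()] result.
#' @param mutated_index Residue index of the mutated site.
#' @param known_variants Tibble with columns `aa_pos`, `label`.
#' @param radius Search radius in Angstrom.
#' @return Tibble `aa_pos`, `label`, `calpha_dist`, `seq_sep`, sorted
#'   ascending by `calpha_dist`.
#' @export
spatial_neighbors <- function(structure, mutated_index, known_variants,
                              radius = 10) {
  stopifnot(radius > 0)
  d <- calpha_distances(structure, mutated_index)
  kv <- as_tibble(known_variants)
  kv <- kv[kv$aa_pos != mutated_index, , drop = FALSE]
  joined <- left_join(kv, d, by = c(aa_pos = "res_index")) |>
    filter(!is.na(.data$calpha_dist), .data$calpha_dist <= radius) |>
    arrange(.data$calpha_dist)
  joined[, c("aa_pos", "label", "calpha_dist", "seq_sep")]
}
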