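#' Three-state secondary-structure assignment
#'
#' A compact re-implementation of the hydrogen-bond-based assignment of
#' Kabsch and Sander: an amide hydrogen is placed on each backbone
#' nitrogen (along the bisector of the N-to-previous-C and
#' N-to-previous-O directions, 1.01 Angstrom from N), backbone H-bonds are
#' detected with the electrostatic energy
#' `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol
#' (bond iff `E < cutoff`), and states are reduced to three classes:
#' `H` for residues inside runs of at least two consecutive i -> i+4
#' bonds (alpha helix), `E` for residues in ladder-forming inter-strand
#' bridges (beta), else `C` (coil). Residues with missing backbone atoms
#' are assigned `C` with a warning.
#'
#' @param structure A [read_structure()] result.
#' @param cutoff H-bond energy cutoff in kcal/mol (default -0.5).
#' @return Tibble with `res_index`, `aa`, `ss` in `{H, E, C}`.
#' @export
assign_secondary_structure <- function(structure, cutoff = -0.5) {
  res <- structure$residues
  n <- nrow(res)
  N <- atom_coords(structure, "N")
  CA <- atom_coords(structure, "CA")
  C <- atom_coords(structure, "C")
  O <- atom_coords(structure, "O")
  incomplete <- apply(cbind(N, CA, C, O), 1, anyNA)
  if (any(incomplete)) {
    warn(paste0(sum(incomplete),
                " residue(s) with missing backbone atoms assigned coil"))
  }
  if (n < 3) return(tibble(res_index = res$res_index, aa = res$aa,
                           ss = rep("C", n)))

  # amide H on residue i from residue i-1's C and O; sequence-adjacent
  # residues only (chain breaks get no H and thus donate no bonds)
  H <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    if (res$res_index[i] != res$res_index[i - 1] + 1L) next
    if (anyNA(N[i, ]) || anyNA(C[i - 1, ]) || anyNA(O[i - 1, ])) next
    dir <- unit(unit(N[i, ] - C[i - 1, ]) + unit(N[i, ] - O[i - 1, ]))
    H[i, ] <- N[i, ] + 1.01 * dir
  }

  # hb[i, j]: N-H of residue i donates to C=O of residue j
  hb <- matrix(FALSE, n, n)
  q <- 0.084 * 332
  for (i in seq_len(n)) {
    if (anyNA(H[i, ]) || anyNA(N[i, ])) next
    for (j in seq_len(n)) {
      if (abs(i - j) < 2 || anyNA(C[j, ]) || anyNA(O[j, ])) next
      r_on <- vec_norm(O[j, ] - N[i, ])
      r_ch <- vec_norm(C[j, ] - H[i, ])
      r_oh <- vec_norm(O[j, ] - H[i, ])
      r_cn <- vec_norm(C[j, ] - N[i, ])
      if (r_oh > 5.5) next  # beyond plausible H-bond range
      e <- q * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
      hb[i, j] <- e < cutoff
    }
  }

  ss <- rep("C", n)

  # alpha helix: runs of >= 2 consecutive (i -> i+4) bonds mark i+1..i+4
  hb4 <- rep(FALSE, n)
  for (i in seq_len(max(0, n - 4))) hb4[i] <- hb[i + 4, i]
  for (i in seq_len(max(0, n - 5))) {
    if (hb4[i] && hb4[i + 1]) ss[(i + 1):(i + 4)] <- "H"
  }

  # beta bridges (Kabsch-Sander parallel/antiparallel patterns)
  bridge <- rep(FALSE, n)
  for (i in 2:(n - 1)) {
    for (j in 2:(n - 1)) {
      if (abs(i - j) < 3) next
      anti <- (hb[i, j] && hb[j, i]) ||
        (hb[i - 1, j + 1] && hb[j - 1, i + 1])
      para <- (hb[i - 1, j] && hb[j, i + 1]) ||
        (hb[j - 1, i] && hb[i, j + 1])
      if (anti || para) bridge[i] <- TRUE
    }
  }
  ss[bridge & ss != "H"] <- "E"
  ss[incomplete] <- "C"
  tibble(res_index = res$res_index, aa = res$aa, ss = ss)
}
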