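# quasi-uniform points on the unit sphere (Fibonacci / golden-section spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area by the Shrake-Rupley method
#'
#' Places `n_points` quasi-uniform test points on every atom's
#' solvent-expanded sphere (radius = van der Waals radius + probe radius);
#' a point is accessible iff it lies outside every other atom's expanded
#' sphere. The atom's ASA is the accessible fraction of its expanded
#' sphere area, `4 * pi * (r + probe)^2`; a residue's ASA is the sum over
#' its atoms.
#'
#' @param structure A [read_structure()] result.
#' @param probe_radius Solvent probe radius in Angstrom (water: 1.4).
#' @param n_points Test points per atom (>= 92; default 960).
#' @param level `"residue"` (default) or `"atom"`.
#' @return Tibble with `res_index`, `aa`, `asa` (residue level) or the
#'   atom table with an `asa` column (atom level).
#' @export
compute_asa <- function(structure, probe_radius = 1.4, n_points = 960,
                        level = c("residue", "atom")) {
  stopifnot(probe_radius > 0, n_points >= 92)
  level <- match.arg(level)
  at <- structure$atoms
  # hydrogens are conventionally excluded from heavy-atom ASA
  at <- at[at$element != "H", , drop = FALSE]
  n <- nrow(at)
  xyz <- cbind(at$x, at$y, at$z)
  rext <- at$radius + probe_radius
  pts <- sphere_points(n_points)

  asa <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (rext + rext[i])^2 & seq_len(n) != i)
    p <- pts * rext[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    if (length(nb) > 0) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        if (!any(acc)) break
        dd <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
          (p[, 3] - xyz[j, 3])^2
        acc <- acc & dd >= rext[j]^2
      }
      frac <- mean(acc)
    } else {
      frac <- 1
    }
    asa[i] <- frac * 4 * pi * rext[i]^2
  }
  if (level == "atom") {
    out <- at
    out$asa <- asa
    return(out)
  }
  tibble(res_index = at$res_index, aa = at$aa, asa = asa) |>
    group_by(.data$res_index) |>
    summarise(aa = .data$aa[1], asa = sum(.data$asa), .groups = "drop") |>
    arrange(.data$res_index)
}

#' Load the reference maximum ASA table
#'
#' Theoretical per-residue maximum accessible surface areas (the
#' Gly-X-Gly extended-state scale of Tien et al. 2013), shipped as an
#' editable table.
#'
#' @param path Optional path to an alternative two-column table
#'   (`aa`, `maxasa`).
#' @return Named numeric vector keyed by one-letter residue code.
#' @export
maxasa_table <- function(path = NULL) {
  path <- path %||% otr_extdata("maxasa_tien2013.tsv")
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = "cd")
  stats::setNames(tab$maxasa, tab$aa)
}

#' Relative solvent accessibility
#'
#' RSA = ASA / MaxASA for the residue type, clamped to \[0, 1\].
#'
#' @param asa Residue-level ASA tibble from [compute_asa()] (columns
#'   `res_index`, `aa`, `asa`).
#' @param maxasa Reference table from [maxasa_table()].
#' @return The input tibble with an `rsa` column added.
#' @export
compute_rsa <- function(asa, maxasa = maxasa_table()) {
  missing <- setdiff(unique(asa$aa), names(maxasa))
  missing <- missing[!is.na(missing)]
  if (length(missing) > 0) {
    otr_error(paste0("residue type(s) absent from MaxASA table: ",
                     paste(missing, collapse = ", ")),
              "oncotherapyr_config_error")
  }
  mutate(asa, rsa = pmin(.data$asa / unname(maxasa[.data$aa]), 1))
}

#' Alpha-carbon distances to a mutated residue
#'
#' Euclidean distance between every residue's C-alpha atom and the C-alpha
#' of the mutated residue,
#' `d_i = sqrt((x_i - x_m)^2 + (y_i - y_m)^2 + (z_i - z_m)^2)`.
#' Residues lacking a C-alpha are reported with `NA`.
#'
#' @param structure A [read_structure()] result.
#' @param mutated_index Residue index of the mutated site.
#' @return Tibble with `res_index`, `aa`, `calpha_dist`, `seq_sep`
#'   (absolute sequence separation from the mutated site).
#' @export
calpha_distances <- function(structure, mutated_index) {
  ca <- atom_coords(structure, "CA")
  res <- structure$residues
  m <- which(res$res_index == mutated_index)
  if (length(m) == 0 || is.na(ca[m, 1])) {
    otr_error("mutated residue has no C-alpha atom",
              "oncotherapyr_structure_error")
  }
  d <- sqrt((ca[, 1] - ca[m, 1])^2 + (ca[, 2] - ca[m, 2])^2 +
              (ca[, 3] - ca[m, 3])^2)
  tibble(res_index = res$res_index, aa = res$aa, calpha_dist = d,
         seq_sep = abs(res$res_index - mutated_index))
}
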