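vdw_radii <- function() {
  tab <- readr::read_tsv(otr_extdata("vdw_radii.tsv"), show_col_types = FALSE,
                         progress = FALSE, col_types = "cd")
  stats::setNames(tab$radius, tab$element)
}

#' Read a single-chain protein structure from a PDB file
#'
#' Parses ATOM records via \pkg{bio3d}, groups atoms into residues,
#' assigns element-typed van der Waals radii from the packaged table, and
#' reads the B-factor column as per-residue model confidence (the
#' convention of predicted structures, where B holds pLDDT).
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier to select when the file holds several
#'   chains; with more than one chain and no selection an error instructs
#'   you to pass `chain` (CLI flag `--chain`).
#' @return Object of class `protein_structure`: list with `atoms`
#'   (tibble: `res_index`, `resname`, `aa`, `atom`, `element`, `x`, `y`,
#'   `z`, `radius`, `confidence`) and `residues` (tibble: `res_index`,
#'   `aa`, `has_ca`, `confidence`).
#' @export
read_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) {
    otr_error(paste0("structure file not found: ", path),
              "oncotherapyr_io_error")
  }
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) {
                    otr_error(paste0("not a readable PDB file: ",
                                     conditionMessage(e)),
                              "oncotherapyr_format_error")
                  })
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) {
    otr_error("PDB file contains no ATOM records",
              "oncotherapyr_format_error")
  }
  chains <- unique(at$chain)
  if (length(chains) > 1) {
    if (is.null(chain)) {
      otr_error(paste0("structure has ", length(chains),
                       " chains (", paste(chains, collapse = ", "),
                       "); select one with the chain argument (--chain)"),
                "oncotherapyr_chain_error")
    }
    at <- at[at$chain == chain, , drop = FALSE]
    if (nrow(at) == 0) {
      otr_error(paste0("chain '", chain, "' not present"),
                "oncotherapyr_chain_error")
    }
  }
  element <- toupper(str_trim(dplyr::coalesce(at$elesy, "")))
  noel <- !nzchar(element)
  element[noel] <- str_sub(str_trim(at$elety[noel]), 1, 1)
  radii <- vdw_radii()
  atoms <- tibble(
    res_index = as.integer(at$resno),
    resname = at$resid,
    aa = aa3_to_1(str_to_title(at$resid)),
    atom = str_trim(at$elety),
    element = element,
    x = at$x, y = at$y, z = at$z,
    radius = unname(radii[element]),
    confidence = at$b
  )
  atoms$radius[is.na(atoms$radius)] <- 1.7  # unknown elements: carbon-like
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    otr_error("non-finite atom coordinates", "oncotherapyr_format_error")
  }
  residues <- atoms |>
    group_by(.data$res_index) |>
    summarise(aa = .data$aa[1], has_ca = any(.data$atom == "CA"),
              confidence = mean(.data$confidence), .groups = "drop") |>
    arrange(.data$res_index)
  if (is.unsorted(residues$res_index, strictly = TRUE)) {
    otr_error("residue indices must be strictly increasing",
              "oncotherapyr_format_error")
  }
  structure(list(atoms = atoms, residues = residues),
            class = "protein_structure")
}

#' @method print protein_structure
#' @export
print.protein_structure <- function(x, ...) {
  cat("<protein_structure> ", nrow(x$residues), " residues, ",
      nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

# coordinates of one named atom per residue (NA rows when absent)
atom_coords <- function(structure, atom_name) {
  sel <- structure$atoms[structure$atoms$atom == atom_name, , drop = FALSE]
  idx <- match(structure$residues$res_index, sel$res_index)
  cbind(x = sel$x[idx], y = sel$y[idx], z = sel$z[idx])
}

# write a protein_structure (or atom tibble) as minimal PDB ATOM records
write_structure_pdb <- function(atoms, path) {
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)),
    ifelse(nchar(atoms$atom) < 4, paste0(" ", atoms$atom), atoms$atom),
    atoms$resname, "A", atoms$res_index,
    atoms$x, atoms$y, atoms$z, 1.0, atoms$confidence, atoms$element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
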