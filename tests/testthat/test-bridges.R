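# small constructed coordinate sets: the mutated residue's anchor sits at
# the origin; partners are placed at known distances
anchored_residue <- function(res_index, aa, resname, atom, element,
                             x, y = 0, z = 0) {
  tibble::tibble(res_index = res_index, resname = resname, aa = aa,
                 atom = atom, element = element, x = x, y = y, z = z,
                 radius = NA_real_, confidence = 90)
}

test_that("a nearby cysteine S-gamma yields a disulfide candidate", {
  at <- dplyr::bind_rows(
    anchored_residue(10L, "S", "SER", "CB", "C", 0),
    anchored_residue(10L, "S", "SER", "CA", "C", -1.5),
    anchored_residue(25L, "C", "CYS", "SG", "S", 2.1),
    anchored_residue(25L, "C", "CYS", "CA", "C", 3.6))
  st <- as_structure(at)
  br <- detect_bridges(st, 10, ref_aa = "S", alt_aa = "C")
  expect_equal(nrow(br), 1)
  expect_equal(br$kind, "disulfide")
  expect_equal(br$change, "gained")
  expect_equal(br$partner_res, 25L)
  expect_equal(br$distance, 2.1, tolerance = 1e-6)
  # outside the cutoff: nothing
  br2 <- detect_bridges(st, 10, "S", "C", disulfide_cutoff = 2.0)
  expect_equal(nrow(br2), 0)
})

test_that("an oppositely charged terminal atom yields a salt-bridge candidate", {
  at <- dplyr::bind_rows(
    anchored_residue(5L, "A", "ALA", "CB", "C", 0),
    anchored_residue(5L, "A", "ALA", "CA", "C", -1.5),
    anchored_residue(40L, "E", "GLU", "OE1", "O", 3.5),
    anchored_residue(40L, "E", "GLU", "CA", "C", 6.0))
  st <- as_structure(at)
  br <- detect_bridges(st, 5, ref_aa = "A", alt_aa = "K")
  expect_equal(nrow(br), 1)
  expect_equal(br$kind, "salt_bridge")
  expect_equal(br$change, "gained")
  expect_equal(br$partner_res, 40L)
  # same-sign charge is not a salt bridge partner
  br2 <- detect_bridges(st, 5, "A", "D")
  expect_equal(nrow(br2), 0)
})

test_that("losing a charged or cysteine side chain reports lost bridges", {
  at <- dplyr::bind_rows(
    anchored_residue(5L, "K", "LYS", "NZ", "N", 0),
    anchored_residue(5L, "K", "LYS", "CA", "C", -2),
    anchored_residue(8L, "D", "ASP", "OD1", "O", 3.0),
    anchored_residue(8L, "D", "ASP", "CA", "C", 5.5))
  st <- as_structure(at)
  br <- detect_bridges(st, 5, ref_aa = "K", alt_aa = "A")
  expect_equal(br$change, "lost")
  expect_equal(br$kind, "salt_bridge")
})

test_that("an apolar substitution yields no candidates", {
  at <- dplyr::bind_rows(
    anchored_residue(5L, "K", "LYS", "NZ", "N", 0),
    anchored_residue(5L, "K", "LYS", "CA", "C", -2),
    anchored_residue(8L, "C", "CYS", "SG", "S", 2.0),
    anchored_residue(8L, "C", "CYS", "CA", "C", 4.0))
  st <- as_structure(at)
  # K->A loses the charge but A gains nothing; no cysteine involved on
  # the mutated side, no opposite charge nearby
  br <- detect_bridges(st, 5, ref_aa = "A", alt_aa = "A")
  expect_equal(nrow(br), 0)
})

test_that("spatial neighbors rank 3D-close residues above sequence-close ones", {
  st <- generate_synthetic_structure("hairpin", 16)
  known <- tibble::tibble(aa_pos = c(4L, 16L), label = c("seq-near",
                                                         "seq-far"))
  nb <- spatial_neighbors(st, 2, known, radius = 50)
  # the hairpin folds residue 16 back against residue 2
  expect_equal(nb$label[1], "seq-far")
  expect_lt(nb$calpha_dist[1], nb$calpha_dist[2])
  expect_gt(nb$seq_sep[1], nb$seq_sep[2])
  # radius smaller than any distance: empty
  expect_equal(nrow(spatial_neighbors(st, 2, known, radius = 0.5)), 0)
  # full-sort oracle
  all_known <- tibble::tibble(aa_pos = setdiff(1:16, 2L),
                              label = paste0("v", setdiff(1:16, 2L)))
  nb_all <- spatial_neighbors(st, 2, all_known, radius = 1e6)
  d <- calpha_distances(st, 2)
  want <- sort(d$calpha_dist[d$res_index != 2])
  expect_equal(nb_all$calpha_dist, want)
})
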