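test_that("an isolated atom's ASA matches the analytic sphere area", {
  st <- as_structure(lone_atom(radius = 1.9))
  asa <- compute_asa(st, probe_radius = 1.4, n_points = 960)
  analytic <- 4 * pi * (1.9 + 1.4)^2  # ~136.85 A^2
  expect_equal(asa$asa, analytic, tolerance = 0.01)
})

test_that("a fully occluded atom has zero ASA", {
  big <- lone_atom(radius = 3.0)
  small <- lone_atom(x = 0.5, radius = 0.3, res_index = 2L)
  small$atom <- "O"; small$element <- "O"
  st <- as_structure(dplyr::bind_rows(big, small))
  asa <- compute_asa(st, n_points = 500)
  expect_equal(asa$asa[asa$res_index == 2], 0)
})

test_that("per-atom ASA self-converges on a dipeptide against a dense rerun", {
  di <- oncotherapyr:::build_backbone(c(-57, -57), c(-47, -47),
                                      resname = "GLY")
  st <- as_structure(di)
  a1 <- compute_asa(st, n_points = 960, level = "atom")
  a2 <- compute_asa(st, n_points = 10000, level = "atom")
  # error measured on the accessible-fraction scale (each atom's own
  # expanded-sphere area is the natural unit)
  sphere <- 4 * pi * (a1$radius + 1.4)^2
  expect_lt(max(abs(a1$asa - a2$asa) / sphere), 0.02)
})

test_that("total ASA never exceeds the sum of isolated-atom areas", {
  st <- generate_synthetic_structure("helix", 10)
  asa <- compute_asa(st, n_points = 500)
  heavy <- st$atoms[st$atoms$element != "H", ]
  isolated <- sum(4 * pi * (heavy$radius + 1.4)^2)
  expect_lt(sum(asa$asa), isolated)
  # equality when spheres cannot intersect: two atoms far apart
  far <- dplyr::bind_rows(lone_atom(), lone_atom(x = 100, res_index = 2L))
  asa_far <- compute_asa(as_structure(far), n_points = 960)
  expect_equal(sum(asa_far$asa), 2 * 4 * pi * (1.9 + 1.4)^2,
               tolerance = 0.01)
})

test_that("doubling the point count shifts per-residue accessibility by < 1%", {
  st <- generate_synthetic_structure("helix", 12)
  a1 <- compute_rsa(compute_asa(st, n_points = 960))
  a2 <- compute_rsa(compute_asa(st, n_points = 1920))
  # stability on the relative-accessibility scale
  expect_lt(max(abs(a1$rsa - a2$rsa)), 0.01)
})

test_that("RSA equals ASA/MaxASA clamped to [0, 1]", {
  tab <- maxasa_table()
  x <- tibble::tibble(res_index = 1:3, aa = c("G", "W", "A"),
                      asa = c(tab[["G"]], 0, 1.1 * tab[["A"]]))
  r <- compute_rsa(x, tab)
  expect_equal(r$rsa, c(1, 0, 1))
  bad <- tibble::tibble(res_index = 1, aa = "X", asa = 10)
  expect_error(compute_rsa(bad, tab), class = "oncotherapyr_config_error")
})

test_that("burial is monotone: adding surrounding residues never raises RSA", {
  cl <- generate_synthetic_structure("cluster", 8, seed = 4)
  rsa_of_center <- function(k) {
    sub <- cl$atoms[cl$atoms$res_index <= k, ]
    st <- as_structure(sub)
    r <- compute_rsa(compute_asa(st, n_points = 500))
    r$rsa[r$res_index == 1]
  }
  vals <- vapply(c(1, 3, 5, 8), rsa_of_center, numeric(1))
  expect_true(all(diff(vals) <= 1e-9))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("C-alpha distances match brute-force recomputation and metric laws", {
  st <- generate_synthetic_structure("helix", 20)
  d <- calpha_distances(st, 8)
  ca <- st$atoms[st$atoms$atom == "CA", ]
  # elementwise oracle
  want <- sqrt((ca$x - ca$x[8])^2 + (ca$y - ca$y[8])^2 + (ca$z - ca$z[8])^2)
  expect_equal(d$calpha_dist, want)
  expect_equal(d$calpha_dist[d$res_index == 8], 0)
  expect_true(all(d$calpha_dist[d$res_index != 8] > 0))
  # symmetry and triangle inequality across all residue triples
  n <- nrow(ca)
  D <- as.matrix(stats::dist(ca[, c("x", "y", "z")]))
  for (m in c(3, 11, 17)) {
    dm <- calpha_distances(st, m)$calpha_dist
    expect_equal(dm, D[, m], ignore_attr = TRUE)
  }
  ok <- TRUE
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    if (D[i, j] > D[i, k] + D[k, j] + 1e-9) ok <- FALSE
  }
  expect_true(ok)
})

test_that("the 3-4-5 triangle gives distance 5", {
  a <- lone_atom(); a$atom <- "CA"; a$element <- "C"
  b <- lone_atom(x = 3, y = 4, res_index = 2L); b$atom <- "CA"; b$element <- "C"
  st <- as_structure(dplyr::bind_rows(a, b))
  expect_equal(calpha_distances(st, 1)$calpha_dist, c(0, 5))
})

test_that("a mutated residue without C-alpha raises an error", {
  a <- lone_atom()  # SG only
  expect_error(calpha_distances(as_structure(a), 1),
               class = "oncotherapyr_structure_error")
})
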