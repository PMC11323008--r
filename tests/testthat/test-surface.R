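test_that("an isolated atom's SASA matches the analytic sphere", {
  top <- element_topology("C", vdw_radius = 1.5)
  a <- shrake_rupley_sasa(matrix(0, 1, 3), top, probe_radius = 1.4,
                          n_sphere_points = 960)
  expect_equal(a, 4 * pi * 2.9^2, tolerance = 0.02)
})

test_that("SASA is additive for well-separated atoms", {
  top <- element_topology(c("C", "O"), residue_index = c(1L, 2L),
                          residue_name = c("ALA", "ALA"))
  xyz <- rbind(c(0, 0, 0), c(100, 0, 0))
  a <- shrake_rupley_sasa(xyz, top, 1.4, 960)
  iso <- 4 * pi * (c(1.70, 1.52) + 1.4)^2
  expect_equal(a, iso, tolerance = 0.02)
})

test_that("a fully caged atom has zero SASA", {
  ## central atom surrounded by a dense octahedral+cubic cage
  dirs <- rbind(diag(3), -diag(3),
                as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) / sqrt(3),
                as.matrix(expand.grid(c(-1, 1), c(-1, 1), 0)) / sqrt(2),
                as.matrix(expand.grid(c(-1, 1), 0, c(-1, 1))) / sqrt(2),
                as.matrix(expand.grid(0, c(-1, 1), c(-1, 1))) / sqrt(2))
  cage <- sweep(dirs, 1, rep(2.0, nrow(dirs)), `*`)
  xyz <- rbind(c(0, 0, 0), cage)
  n <- nrow(xyz)
  top <- element_topology(rep("C", n), residue_index = seq_len(n),
                          residue_name = rep("ALA", n))
  a <- shrake_rupley_sasa(xyz, top, 1.4, 480)
  expect_equal(a[1], 0)
})

test_that("SASA converges with sphere-point density", {
  ens <- mixed_ensemble()
  xyz <- frame_coords(ens, 3)
  s1 <- sum(shrake_rupley_sasa(xyz, ens$topology, 1.4, 480))
  s2 <- sum(shrake_rupley_sasa(xyz, ens$topology, 1.4, 960))
  expect_lt(abs(s2 - s1) / s2, 0.01)
})

test_that("SASA is invariant under rigid motion and conserved per residue", {
  set.seed(12)
  ens <- mixed_ensemble()
  xyz <- frame_coords(ens, 4)
  ## the deterministic sphere grid is fixed in the lab frame, so rotation
  ## invariance holds to the point-sampling resolution, not exactly
  a0 <- shrake_rupley_sasa(xyz, ens$topology, 1.4, 960)
  moved <- coedecomp:::random_rigid_motion(xyz)
  a1 <- shrake_rupley_sasa(moved, ens$topology, 1.4, 960)
  expect_lt(abs(sum(a1) - sum(a0)) / sum(a0), 0.005)
  expect_lt(max(abs(a1 - a0)), 1.5)
  per_res <- coedecomp:::per_residue_sum(a0, ens$topology)
  expect_equal(sum(per_res), sum(a0), tolerance = 1e-9)
  expect_length(per_res, n_residues(ens))
})

test_that("normalised SASA subtracts expected exposure", {
  labs <- c("D1", "S2")
  obs <- per_residue_matrix(values = rbind(c(193, 200), c(155, 150)),
                            variance = matrix(0, 2, 2),
                            residue_labels = labs, group_labels = c(10, 12),
                            units = "A^2")
  top <- topology(atom_names = c("CA", "CA"), residue_index = c(1L, 2L),
                  residue_name = c("ASP", "SER"), elements = c("C", "C"))
  norm <- normalized_sasa(obs, top)
  expect_equal(unname(norm$values),
               rbind(c(0, 7), c(0, -5)))
  ## observed == expected everywhere -> all zeros, zero variance
  obs0 <- per_residue_matrix(values = rbind(c(193, 193), c(155, 155)),
                             variance = matrix(0, 2, 2),
                             residue_labels = labs, group_labels = c(10, 12))
  norm0 <- normalized_sasa(obs0, top)
  expect_true(all(norm0$values == 0))
  expect_true(all(norm0$variance == 0))
  ## constant offset in one group only -> positive across-group variance
  expect_true(all(norm$variance > 0))
  ## unknown residue type
  top_bad <- topology(atom_names = c("CA", "CA"), residue_index = c(1L, 2L),
                      residue_name = c("ASP", "XXX"), elements = c("C", "C"))
  expect_error(normalized_sasa(obs, top_bad), "expected SASA")
})

test_that("mean normalised SASA rises with group Rg", {
  ens <- mixed_ensemble()
  gs <- assign_rg_groups(ens)
  sa <- cached("mixed60_sasa", function() {
    sasa_by_group(ens, gs, n_sphere_points = 120)
  })
  norm <- normalized_sasa(sa, ens$topology)
  rho <- cor(gs$labels, colMeans(norm$values), method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("Rg-SASA KDE integrates to one and resolves separated modes", {
  set.seed(14)
  rg <- c(rnorm(300, 9, 0.3), rnorm(300, 16, 0.3))
  sasa <- c(rnorm(300, 1800, 20), rnorm(300, 2400, 20))
  k <- sasa_rg_density(sasa, rg, n_grid = 101)
  cell <- diff(k$rg[1:2]) * diff(k$sasa[1:2])
  expect_equal(sum(k$density) * cell, 1, tolerance = 0.01)
  ## bimodal: density near the two centres far exceeds the midpoint
  at <- function(x, y) k$density[which.min(abs(k$rg - x)),
                                 which.min(abs(k$sasa - y))]
  expect_gt(at(9, 1800), 10 * at(12.5, 2100))
  expect_gt(at(16, 2400), 10 * at(12.5, 2100))
  expect_error(sasa_rg_density(rep(1, 10), rep(2, 10)), "variance")
})

test_that("geometric hydrogen-bond criterion fires only inside cutoffs", {
  top <- topology(atom_names = c("N", "H", "O"),
                  residue_index = c(1L, 1L, 3L),
                  residue_name = c("ALA", "ALA", "ALA"),
                  elements = c("N", "H", "O"))
  ideal <- rbind(c(0, 0, 0), c(1.01, 0, 0), c(2.9, 0, 0))
  expect_equal(nrow(detect_hydrogen_bonds(ideal, top)), 1)
  far <- rbind(c(0, 0, 0), c(1.01, 0, 0), c(4.0, 0, 0))
  expect_equal(nrow(detect_hydrogen_bonds(far, top)), 0)
  ## 45-degree H-D-A angle at 2.9 A
  bent <- rbind(c(0, 0, 0), 1.01 * c(cos(pi / 4), sin(pi / 4), 0),
                c(2.9, 0, 0))
  expect_equal(nrow(detect_hydrogen_bonds(bent, top)), 0)
  ## donors without hydrogen are skipped
  top_noh <- topology(atom_names = c("N", "O"), residue_index = c(1L, 3L),
                      residue_name = c("ALA", "GLY", "ALA"),
                      elements = c("N", "O"))
  expect_equal(nrow(detect_hydrogen_bonds(ideal[c(1, 3), ], top_noh)), 0)
})

test_that("detected bonds match a brute-force triple enumeration", {
  brute_force_hbonds <- function(coords, top, d_cut = 3.5, a_cut = 30) {
    hits <- 0
    n <- nrow(coords)
    for (d in seq_len(n)) {
      if (!top$elements[d] %in% c("N", "O")) next
      for (h in seq_len(n)) {
        if (top$elements[h] != "H") next
        if (sqrt(sum((coords[h, ] - coords[d, ])^2)) > 1.25) next
        for (a in seq_len(n)) {
          if (a == d || !top$elements[a] %in% c("N", "O")) next
          if (top$residue_index[a] == top$residue_index[d]) next
          if (sqrt(sum((coords[a, ] - coords[d, ])^2)) > d_cut) next
          vh <- coords[h, ] - coords[d, ]; va <- coords[a, ] - coords[d, ]
          ang <- acos(min(1, max(-1, sum(vh * va) /
                                   sqrt(sum(vh^2) * sum(va^2))))) * 180 / pi
          if (ang <= a_cut) hits <- hits + 1
        }
      }
    }
    hits
  }
  comp <- compact_ensemble()
  sel <- which(comp$topology$residue_index <= 10)   # 50 atoms
  top_sub <- topology(comp$topology$atom_names[sel],
                      comp$topology$residue_index[sel],
                      comp$topology$residue_name[1:10],
                      elements = comp$topology$elements[sel])
  for (i in 1:5) {
    xyz <- frame_coords(comp, i)[sel, ]
    mine <- nrow(detect_hydrogen_bonds(xyz, top_sub))
    expect_equal(mine, brute_force_hbonds(xyz, top_sub))
  }
})

test_that("occupancy maps count per-frame bonds once per residue pair", {
  ## 5 identical frames each containing one 3<->5 bond
  top <- topology(atom_names = c("N", "H", "CA", "O", "CA", "N", "H", "CA"),
                  residue_index = c(3L, 3L, 3L, 4L, 4L, 5L, 5L, 5L) - 2L,
                  residue_name = c("HIS", "ALA", "LYS"),
                  elements = c("N", "H", "C", "O", "C", "N", "H", "C"))
  xyz <- rbind(c(0, 0, 0), c(1.01, 0, 0),   # N3, H3 (donor)
               c(0, 3, 0),
               c(50, 0, 0), c(52, 0, 0),    # residue 4 far away
               c(2.9, 0, 0), c(4, 5, 6), c(2.9, 3, 0))  # N5 acceptor
  coords <- array(NA_real_, c(5, 8, 3))
  for (f in 1:5) coords[f, , ] <- xyz
  ens <- ensemble(coords, top)
  gs <- rg_group_set(labels = 10L, members = list(1:5),
                     rg_per_frame = ensemble_rg(ens))
  hb <- hbond_map(ens, gs)
  expect_equal(hb$maps[["10"]][1, 3], 1)
  expect_equal(hb$maps[["10"]][3, 1], 1)
  expect_equal(sum(hb$maps[["10"]]), 2)
  expect_identical(hb$pairs$residue_i, "H1")
  expect_identical(hb$pairs$residue_j, "K3")
  expect_equal(hb$pairs$occupancy, 1)
})

test_that("compact groups carry more hydrogen-bond occupancy", {
  hc <- hbond_map(compact_ensemble(), as_single_group(compact_ensemble()))
  he <- hbond_map(extended_ensemble(), as_single_group(extended_ensemble()))
  expect_gt(sum(hc$maps[[1]]), sum(he$maps[[1]]))
})

test_that("distance maps recover the rod closed form in CA mode", {
  n <- 8; d <- 3.8
  top <- topology(atom_names = rep("CA", n), residue_index = seq_len(n),
                  residue_name = rep("ALA", n), elements = rep("C", n))
  coords <- array(0, c(2, n, 3))
  coords[1, , 1] <- coords[2, , 1] <- d * (seq_len(n) - 1)
  ens <- ensemble(coords, top)
  gs <- rg_group_set(labels = 9L, members = list(1:2),
                     rg_per_frame = ensemble_rg(ens))
  cm <- residue_distance_map(ens, gs, mode = "ca")[[1]]
  for (i in 1:n) for (j in 1:n) {
    expect_equal(cm[i, j], d * abs(i - j), tolerance = 1e-9)
  }
  expect_true(isSymmetric(cm))
  expect_true(all(diag(cm) == 0))
})

test_that("extended groups show larger long-range residue distances", {
  cmc <- residue_distance_map(compact_ensemble(),
                              as_single_group(compact_ensemble()))[[1]]
  cme <- residue_distance_map(extended_ensemble(),
                              as_single_group(extended_ensemble()))[[1]]
  sep <- abs(row(cmc) - col(cmc))
  expect_gt(mean(cme[sep > 10]), mean(cmc[sep > 10]))
})
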