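test_that("superposing a rotated copy of itself gives zero RMSD", {
  set.seed(41)
  xyz <- matrix(rnorm(60, sd = 4), 20, 3)
  moved <- coedecomp:::random_rigid_motion(xyz)
  fit <- kabsch_superpose(moved, xyz)
  expect_lt(fit$rmsd, 1e-9)
  expect_lt(max(abs(fit$coords - xyz)), 1e-9)
})

test_that("Kabsch RMSD agrees with an independent reference", {
  set.seed(43)
  for (k in 1:10) {
    a <- matrix(rnorm(36, sd = 3), 12, 3)
    b <- a + matrix(rnorm(36, sd = 0.8), 12, 3)
    mine <- kabsch_superpose(b, a)$rmsd
    oracle <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b)),
                          fit = TRUE)
    expect_equal(mine, oracle, tolerance = 1e-3)
  }
})

test_that("reflection-requiring cases keep a proper rotation", {
  set.seed(44)
  xyz <- matrix(rnorm(30, sd = 3), 10, 3)
  mirrored <- xyz %*% diag(c(-1, 1, 1))
  fit <- kabsch_superpose(mirrored, xyz)
  expect_gt(fit$rmsd, 0.1)
  ## collinear selections are rejected
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "collinear|degenerate")
})

test_that("RMSF vanishes for identical frames and localises a moved residue", {
  ens <- mixed_ensemble()
  same <- subset_frames(ens, rep(2, 4))
  gs <- rg_group_set(labels = 10L, members = list(1:4),
                     rg_per_frame = rep(10, 4))
  r0 <- rmsf_per_group(same, gs)
  expect_lt(max(r0$values), 1e-9)

  ## alternate one CA by +-delta around the reference
  delta <- 0.9
  base <- frame_coords(ens, 2)
  ica <- which(ens$topology$atom_names == "CA")[12]
  coords <- array(NA_real_, c(4, n_atoms(ens), 3))
  for (f in 1:4) {
    x <- base
    x[ica, 3] <- x[ica, 3] + delta * c(1, -1, 1, -1)[f]
    coords[f, , ] <- x
  }
  pert <- ensemble(coords, ens$topology)
  r1 <- rmsf_per_group(pert, gs)
  ## the fit absorbs part of the shift into translation/rotation, so the
  ## moved residue reads slightly below delta and the rest slightly above 0
  expect_equal(r1$values[12, 1], delta, tolerance = 0.1)
  expect_lt(max(r1$values[-12, 1]), 0.25 * delta)
  expect_gt(r1$values[12, 1], 3 * max(r1$values[-12, 1]))

  gs1 <- rg_group_set(labels = 10L, members = list(1L),
                      rg_per_frame = 10)
  expect_error(rmsf_per_group(subset_frames(ens, 1), gs1), "single")
})

test_that("RMSF is invariant to per-frame rigid motion", {
  set.seed(45)
  ens <- cached("mix12", function() {
    generate_ensemble(generator_config(n_frames = 12, seed = 19))
  })
  gs <- rg_group_set(labels = 12L, members = list(1:12),
                     rg_per_frame = ensemble_rg(ens))
  r0 <- rmsf_per_group(ens, gs)
  coords <- ens$coords
  for (f in 1:12) {
    coords[f, , ] <- coedecomp:::random_rigid_motion(coords[f, , ])
  }
  r1 <- rmsf_per_group(ensemble(coords, ens$topology), gs)
  expect_equal(r1$values, r0$values, tolerance = 1e-6)
})

test_that("chain termini fluctuate more than the interior", {
  ens <- mixed_ensemble()
  gs <- rg_group_set(labels = 12L,
                     members = list(seq_len(n_frames(ens))),
                     rg_per_frame = ensemble_rg(ens))
  r <- rmsf_per_group(ens, gs)$values[, 1]
  n <- length(r)
  expect_gt(mean(r[c(1, 2, n - 1, n)]), median(r[5:(n - 4)]))
})

test_that("GROMOS clustering handles degenerate limits", {
  ens <- mixed_ensemble()
  same <- subset_frames(ens, rep(3, 5))
  cl <- gromos_cluster(same, rmsd_cutoff = 1)
  expect_true(all(cl$cluster == 1))
  expect_equal(sum(cl$is_center), 1)
  ## cutoff -> 0 puts every distinct frame in its own cluster
  sub <- subset_frames(ens, 1:6)
  cl0 <- gromos_cluster(sub, rmsd_cutoff = 1e-9)
  expect_equal(sort(unique(cl0$cluster)), 1:6)
})

test_that("two well-separated bundles form exactly two clusters", {
  ens <- mixed_ensemble()
  rg <- ensemble_rg(ens)
  compact <- order(rg)[1:4]
  extended <- order(rg, decreasing = TRUE)[1:4]
  sub <- subset_frames(ens, c(compact, extended))
  cl <- gromos_cluster(sub, rmsd_cutoff = 2)
  m <- attr(cl, "rmsd_matrix")
  ## only run the strict assertion when the bundles really separate
  if (max(m[1:4, 1:4]) < 2 && max(m[5:8, 5:8]) < 2 && min(m[1:4, 5:8]) > 2) {
    expect_equal(length(unique(cl$cluster)), 2)
    expect_equal(length(unique(cl$cluster[1:4])), 1)
  }
  expect_true(all(table(cl$cluster) == sort(table(cl$cluster),
                                            decreasing = TRUE)))
})

test_that("clustering equals an independently coded Daura oracle", {
  daura_oracle <- function(m, cutoff) {
    ## separate implementation: repeatedly pick max-neighbour frame
    n <- nrow(m)
    assign <- rep(NA_integer_, n)
    k <- 0
    while (anyNA(assign)) {
      k <- k + 1
      pool <- which(is.na(assign))
      best <- pool[1]; best_n <- -1
      for (c in pool) {
        nb <- sum(m[c, pool] <= cutoff)
        if (nb > best_n) { best <- c; best_n <- nb }
      }
      members <- pool[m[best, pool] <= cutoff]
      assign[members] <- k
    }
    ## relabel by decreasing size, ties by discovery order
    sizes <- tabulate(assign)
    match(assign, order(-sizes, seq_along(sizes)))
  }
  set.seed(47)
  ens <- mixed_ensemble()
  for (rep in 1:20) {
    frames <- sample(n_frames(ens), 10)
    cutoff <- runif(1, 1, 6)
    cl <- gromos_cluster(subset_frames(ens, frames), rmsd_cutoff = cutoff)
    m <- attr(cl, "rmsd_matrix")
    expect_identical(cl$cluster[order(cl$frame)], daura_oracle(m, cutoff))
  }
})

test_that("clustering is deterministic and stable under frame relabeling", {
  ens <- mixed_ensemble()
  sub <- subset_frames(ens, 1:10)
  c1 <- gromos_cluster(sub, rmsd_cutoff = 3)
  c2 <- gromos_cluster(sub, rmsd_cutoff = 3)
  expect_identical(c1$cluster, c2$cluster)
  ## reversal of frame order preserves the partition as sets
  rev_sub <- subset_frames(ens, 10:1)
  c3 <- gromos_cluster(rev_sub, rmsd_cutoff = 3)
  part1 <- lapply(split(c1$frame, c1$cluster), sort)
  part3 <- lapply(split(11 - c3$frame, c3$cluster), sort)
  expect_true(setequal(part1, part3))
})

test_that("featurize yields sequence-separated CA distances", {
  fr <- build_backbone("AGHR", c(NA, -60, -70, -80), c(120, 130, 140, NA))
  ens <- one_frame_ensemble(fr)
  x <- featurize(ens)
  expect_equal(ncol(x), 3)   # (1,3), (1,4), (2,4)
  expect_identical(attr(x, "feature_names"),
                   c("dCA_1_3", "dCA_1_4", "dCA_2_4"))
  ## rigid-motion invariance
  set.seed(48)
  moved <- ensemble(array(coedecomp:::random_rigid_motion(fr$coords),
                          c(1, nrow(fr$coords), 3)), fr$topology)
  expect_equal(featurize(moved), featurize(ens), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("dihedral featurization round-trips the angles", {
  ens <- mixed_ensemble()
  sub <- subset_frames(ens, 1:3)
  x <- featurize(sub, mode = "dihedral")
  dh <- backbone_dihedrals(sub)
  phi2 <- atan2(x[, 1], x[, 2]) * 180 / pi   # first residue with defined phi
  ## column order: residue 1 has psi only; residue 2 contributes sin/cos phi
  nm <- attr(x, "feature_names")
  i_phi2 <- match(c("sin_phi_2", "cos_phi_2"), nm)
  rec <- atan2(x[, i_phi2[1]], x[, i_phi2[2]]) * 180 / pi
  expect_equal(rec, dh$phi[, 2], tolerance = 1e-3)
})

test_that("tICA recovers AR(1) autocorrelation and rejects noise", {
  set.seed(50)
  n <- 20000
  x <- numeric(n)
  for (t in 2:n) x[t] <- 0.9 * x[t - 1] + rnorm(1)
  m <- tica_fit(matrix(x, ncol = 1), lag = 3, n_components = 1)
  expect_equal(m$eigenvalues[1], 0.9^3, tolerance = 0.05)

  w <- matrix(rnorm(5000 * 4), 5000, 4)
  m2 <- tica_fit(w, lag = 5, n_components = 4)
  expect_lt(max(abs(m2$eigenvalues)), 0.1)
})

test_that("tICA handles collinear features via regularisation", {
  set.seed(51)
  n <- 2000
  x <- numeric(n)
  for (t in 2:n) x[t] <- 0.8 * x[t - 1] + rnorm(1)
  feats <- cbind(x, x, rnorm(n))    # duplicated column
  m <- tica_fit(feats, lag = 2, n_components = 2, epsilon = 1e-6)
  expect_true(all(is.finite(m$eigenvalues)))
  expect_equal(m$eigenvalues[1], 0.8^2, tolerance = 0.1)
})

test_that("tICA components are orthonormal in the covariance metric", {
  set.seed(52)
  ens <- mixed_ensemble()
  feats <- featurize(ens)
  m <- tica_fit(feats, lag = 2, n_components = 3)
  gram <- t(m$components) %*% m$c0 %*% m$components
  expect_equal(gram, diag(3), tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
  expect_lt(max(abs(m$eigenvalues)), 1 + 1e-6)
  ## distinct components are uncorrelated in the estimator's metric,
  ## hence near-uncorrelated as plain time series too
  proj <- tica_transform(m, feats)
  cc <- cor(proj)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.01)
})

test_that("tICA validates its inputs", {
  expect_error(tica_fit(matrix(rnorm(20), 10, 2), lag = 10), "frames")
  bad <- matrix(c(rnorm(19), NA), 10, 2)
  expect_error(tica_fit(bad, lag = 2), "finite")
})

test_that("free-energy landscapes follow Boltzmann inversion", {
  set.seed(53)
  ## uniform occupancy -> flat landscape at 0
  u <- cbind(rep(1:6, each = 6) + 0.5, rep(1:6, times = 6) + 0.5)
  feu <- free_energy_landscape(u, n_bins = 3, probs = c(0, 1))
  expect_lt(max(feu$free_energy, na.rm = TRUE), 1e-12)
  ## 10:1 occupancy of two bins -> dF = ln 10
  pts <- rbind(matrix(rep(c(0.25, 0.25), 100), ncol = 2, byrow = TRUE),
               matrix(rep(c(0.75, 0.75), 10), ncol = 2, byrow = TRUE))
  fe <- free_energy_landscape(pts, n_bins = 2, probs = c(0, 1))
  occupied <- sort(fe$free_energy[fe$counts > 0])
  expect_equal(occupied[2] - occupied[1], log(10), tolerance = 1e-9)
  ## empty bins are masked and the minimum is zero
  expect_true(all(is.na(fe$free_energy[fe$counts == 0])))
  expect_equal(min(fe$free_energy, na.rm = TRUE), 0)
  expect_error(free_energy_landscape(matrix(1, 5, 2)), "degenerate|bins")
})

test_that("a slow two-state ensemble shows two landscape minima", {
  ens <- cached("twostate1500", function() {
    generate_ensemble(generator_config(n_frames = 1500, seed = 61,
                                       switch_prob = 0.01))
  })
  feats <- featurize(ens)
  m <- tica_fit(feats, lag = 5, n_components = 2)
  proj <- tica_transform(m, feats)
  ## the hidden compact/extended state is recoverable from tIC1
  st <- attr(ens, "hidden_states")
  split_at <- median(proj[, 1])
  agree <- max(mean((proj[, 1] > split_at) == (st == 1)),
               mean((proj[, 1] > split_at) == (st == 2)))
  expect_gt(agree, 0.8)
  ## the two states separate into two occupied basins on the 2D landscape
  fe <- free_energy_landscape(proj, n_bins = 20)
  mean_tic1 <- c(mean(proj[st == 1, 1]), mean(proj[st == 2, 1]))
  expect_gt(abs(diff(mean_tic1)), stats::sd(proj[, 1]))
  expect_gt(sum(fe$counts > 0), 2)
})
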