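## Shrake-Rupley solvent-accessible surface area and its per-residue,
## per-group summaries (raw and normalised against maximum-exposure
## baselines).

## deterministic golden-spiral (Fibonacci) points on the unit sphere
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  theta <- golden * (seq_len(n) - 1)
  cbind(r * cos(theta), r * sin(theta), z)
}

#' Shrake-Rupley per-atom solvent-accessible surface area
#'
#' Test points are placed on a sphere of radius r_vdw + probe around each
#' atom (deterministic golden-spiral layout); a point counts as accessible
#' iff it lies outside every other atom's expanded sphere. The atom's area
#' is the accessible fraction of 4 pi (r_vdw + probe)^2.
#'
#' @param coords atoms x 3 matrix (Angstrom).
#' @param top A [topology()] supplying van der Waals radii.
#' @param probe_radius Solvent probe radius (Angstrom, default 1.4).
#' @param n_sphere_points Test points per atom (default 960, minimum 16).
#' @return Numeric vector of per-atom areas (Angstrom^2).
#' @export
shrake_rupley_sasa <- function(coords, top, probe_radius = 1.4,
                               n_sphere_points = 960) {
  coords <- as.matrix(coords)
  stopifnot(probe_radius > 0, n_sphere_points >= 16,
            nrow(coords) == n_atoms(top))
  a <- nrow(coords)
  radii <- top$vdw_radius + probe_radius
  sphere <- fibonacci_sphere(n_sphere_points)
  ## neighbour candidates: centre distance < r_i + r_j
  dmat <- as.matrix(stats::dist(coords))
  area <- numeric(a)
  for (i in seq_len(a)) {
    pts <- sweep(sphere * radii[i], 2L, coords[i, ], "+")
    nb <- which(dmat[i, ] < radii[i] + radii & seq_len(a) != i)
    if (length(nb) == 0L) {
      frac <- 1
    } else {
      buried <- rep(FALSE, n_sphere_points)
      for (j in nb) {
        d2 <- (pts[, 1] - coords[j, 1])^2 + (pts[, 2] - coords[j, 2])^2 +
          (pts[, 3] - coords[j, 3])^2
        buried <- buried | d2 < radii[j]^2
        if (all(buried)) break
      }
      frac <- mean(!buried)
    }
    area[i] <- frac * 4 * pi * radii[i]^2
  }
  area
}

## per-residue totals of a per-atom quantity
per_residue_sum <- function(values, top) {
  as.vector(rowsum(values, top$residue_index))
}

#' Construct a residues x groups observable matrix
#'
#' @param values residues x groups numeric matrix.
#' @param variance Same-shape non-negative variance companion.
#' @param residue_labels 1-letter code + position labels for rows.
#' @param group_labels Integer Rg labels for columns.
#' @param units Unit string of the observable.
#' @return An object of class `per_residue_matrix`.
#' @export
per_residue_matrix <- function(values, variance, residue_labels,
                               group_labels, units = "") {
  values <- as.matrix(values); variance <- as.matrix(variance)
  stopifnot(all(dim(values) == dim(variance)),
            nrow(values) == length(residue_labels),
            ncol(values) == length(group_labels))
  if (any(!is.finite(values)) || any(variance < -1e-12, na.rm = TRUE)) {
    stop("values must be finite and variance non-negative")
  }
  dimnames(values) <- dimnames(variance) <-
    list(residue_labels, as.character(group_labels))
  structure(list(values = values, variance = variance,
                 residue_labels = residue_labels,
                 group_labels = as.integer(group_labels), units = units),
            class = "per_residue_matrix")
}

#' @export
print.per_residue_matrix <- function(x, ...) {
  cat("Per-residue matrix (", x$units, "): ", nrow(x$values), " residues x ",
      ncol(x$values), " Rg groups\n", sep = "")
  invisible(x)
}

#' Per-residue SASA by Rg group
#'
#' Mean (and across-frame variance of) per-residue SASA within each
#' selected Rg group.
#'
#' @param ens A [ensemble()].
#' @param groups An [rg_group_set()].
#' @param labels Group labels to analyse (default all).
#' @param ... Passed to [shrake_rupley_sasa()].
#' @return A [per_residue_matrix()] in Angstrom^2, with per-frame totals in
#'   attribute `total_per_frame` (named by frame index).
#' @export
sasa_by_group <- function(ens, groups, labels = groups$labels, ...) {
  stopifnot(inherits(ens, "coe_ensemble"), inherits(groups, "rg_group_set"))
  top <- ens$topology
  n_res <- n_residues(ens)
  vals <- vars <- matrix(NA_real_, n_res, length(labels))
  totals <- numeric(0)
  for (g in seq_along(labels)) {
    frames <- group_frames(groups, labels[g])
    per_res <- matrix(NA_real_, n_res, length(frames))
    for (k in seq_along(frames)) {
      at <- shrake_rupley_sasa(frame_coords(ens, frames[k]), top, ...)
      per_res[, k] <- per_residue_sum(at, top)
    }
    vals[, g] <- rowMeans(per_res)
    vars[, g] <- apply(per_res, 1L, stats::var)
    if (length(frames) == 1L) vars[, g] <- 0
    totals <- c(totals, stats::setNames(colSums(per_res), frames))
  }
  out <- per_residue_matrix(vals, vars, residue_labels(top), labels,
                            units = "A^2")
  attr(out, "total_per_frame") <- totals
  out
}

#' Normalised SASA (observed minus expected exposure)
#'
#' Subtracts a per-residue-type expected accessible area (default the
#' theoretical maximum-ASA baselines of [max_asa_table()]) from each
#' observed entry; the variance companion is the across-group variance of
#' the normalised values (one value per residue, replicated per column).
#'
#' @param observed A [per_residue_matrix()] of SASA values, with residue
#'   rows in chain order.
#' @param topology The matching [topology()] (for residue types).
#' @param expected Named expected-area table (3-letter codes, Angstrom^2).
#' @return A [per_residue_matrix()] of signed differences (Angstrom^2).
#' @export
normalized_sasa <- function(observed, topology,
                            expected = max_asa_table()) {
  stopifnot(inherits(observed, "per_residue_matrix"),
            inherits(topology, "coe_topology"))
  res_types <- topology$residue_name
  missing <- setdiff(unique(res_types), names(expected))
  if (length(missing)) {
    stop("no expected SASA for residue type(s): ",
         paste(missing, collapse = ", "))
  }
  base <- expected[res_types]
  vals <- sweep(observed$values, 1L, base)
  across_group_var <- apply(vals, 1L, stats::var)
  if (ncol(vals) == 1L) across_group_var <- rep(0, nrow(vals))
  vars <- matrix(across_group_var, nrow(vals), ncol(vals))
  per_residue_matrix(vals, vars, observed$residue_labels,
                     observed$group_labels, units = "A^2 (obs - expected)")
}

#' Kernel density estimate of conformations over (Rg, total SASA)
#'
#' Gaussian-product KDE on a rectangular grid (bandwidths by Scott's rule
#' unless given), normalised so the grid integral is 1.
#'
#' @param total_sasa Per-frame total SASA (Angstrom^2).
#' @param rg Per-frame Rg (Angstrom).
#' @param n_grid Grid points per axis (default 81).
#' @param bandwidths Optional c(h_rg, h_sasa) overrides.
#' @param pad Grid padding in bandwidths beyond the data range (default 3).
#' @return List with `rg`, `sasa` (grid axes) and `density` matrix.
#' @export
sasa_rg_density <- function(total_sasa, rg, n_grid = 81,
                            bandwidths = NULL, pad = 3) {
  stopifnot(length(total_sasa) == length(rg), length(rg) >= 2)
  if (stats::sd(rg) == 0 || stats::sd(total_sasa) == 0) {
    stop("zero variance in Rg or SASA; add jitter or more frames")
  }
  n <- length(rg)
  if (is.null(bandwidths)) {
    ## Scott's rule for 2D: h_j = sd_j * n^(-1/6)
    bandwidths <- c(stats::sd(rg), stats::sd(total_sasa)) * n^(-1 / 6)
  }
  ## MASS::kde2d's h is 4x the Gaussian sd
  gx <- range(rg) + c(-1, 1) * pad * bandwidths[1]
  gy <- range(total_sasa) + c(-1, 1) * pad * bandwidths[2]
  k <- MASS::kde2d(rg, total_sasa, h = 4 * bandwidths, n = n_grid,
                   lims = c(gx, gy))
  list(rg = k$x, sasa = k$y, density = k$z)
}
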