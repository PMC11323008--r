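## Per-group RMSF after iterative superposition, GROMOS (Daura) RMSD
## clustering, time-lagged independent component analysis, and
## free-energy landscapes over the leading components.

ca_selection <- function(top) {
  sel <- which(top$atom_names == "CA")
  if (length(sel) < 3L) stop("need at least 3 CA atoms")
  sel
}

#' Per-residue RMSF for each Rg group
#'
#' Each group's frames are superposed (CA atoms) onto the group mean
#' structure; the mean is re-averaged and the superposition repeated until
#' the mean shifts by less than `tol` (at most `max_iter` iterations). RMSF
#' is each residue's CA root-mean-square deviation from the converged mean.
#'
#' @param ens A [ensemble()].
#' @param groups An [rg_group_set()].
#' @param labels Group labels to analyse (default all); every selected
#'   group needs at least 2 frames.
#' @param tol Mean-structure convergence threshold (Angstrom RMS shift).
#' @param max_iter Maximum superposition iterations.
#' @return A [per_residue_matrix()] in Angstrom (variance companion holds
#'   the across-frame variance of per-frame deviations).
#' @export
rmsf_per_group <- function(ens, groups, labels = groups$labels,
                           tol = 1e-4, max_iter = 10) {
  stopifnot(inherits(ens, "coe_ensemble"), inherits(groups, "rg_group_set"))
  top <- ens$topology
  sel <- ca_selection(top)
  n_res <- n_residues(ens)
  vals <- vars <- matrix(NA_real_, n_res, length(labels))
  for (g in seq_along(labels)) {
    frames <- group_frames(groups, labels[g])
    if (length(frames) < 2L) {
      stop("Rg group ", labels[g], " has a single frame; RMSF needs >= 2")
    }
    xyz <- lapply(frames, function(i) frame_coords(ens, i)[sel, , drop = FALSE])
    ref <- xyz[[1]]
    for (it in seq_len(max_iter)) {
      fitted <- lapply(xyz, function(x) kabsch_superpose(x, ref)$coords)
      new_mean <- Reduce(`+`, fitted) / length(fitted)
      shift <- sqrt(mean(rowSums((new_mean - ref)^2)))
      ref <- new_mean
      if (shift < tol) break
    }
    fitted <- lapply(xyz, function(x) kabsch_superpose(x, ref)$coords)
    dev2 <- vapply(fitted, function(x) rowSums((x - ref)^2),
                   numeric(length(sel)))
    vals[, g] <- sqrt(rowMeans(dev2))
    vars[, g] <- apply(sqrt(dev2), 1L, stats::var)
  }
  per_residue_matrix(vals, vars, residue_labels(top), labels, units = "A")
}

## pairwise CA RMSD matrix after Kabsch superposition
pairwise_rmsd <- function(ens, frame_indices, selection = NULL) {
  top <- ens$topology
  if (is.null(selection)) selection <- ca_selection(top)
  xyz <- lapply(frame_indices,
                function(i) frame_coords(ens, i)[selection, , drop = FALSE])
  n <- length(xyz)
  m <- matrix(0, n, n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- kabsch_superpose(xyz[[i]], xyz[[j]])$rmsd
    }
  }
  m
}

#' GROMOS (Daura) RMSD clustering
#'
#' Computes the pairwise CA RMSD matrix after optimal superposition, then
#' repeatedly takes the frame with the most neighbours within `rmsd_cutoff`
#' as a cluster centre and removes it together with its neighbours. Ties
#' are broken by the lowest frame index; clusters are ordered by
#' decreasing size (ties again by centre index), making the output
#' deterministic.
#'
#' @param ens A [ensemble()].
#' @param frame_indices Frames to cluster (default all).
#' @param rmsd_cutoff Neighbour cutoff in Angstrom (default 7, i.e. the
#'   0.7 nm GROMOS convention).
#' @return data.frame with columns `frame`, `cluster` (1 = largest) and
#'   `is_center`; the RMSD matrix is attached as attribute `rmsd_matrix`.
#' @export
gromos_cluster <- function(ens, frame_indices = seq_len(n_frames(ens)),
                           rmsd_cutoff = 7) {
  stopifnot(rmsd_cutoff > 0, length(frame_indices) >= 1)
  m <- pairwise_rmsd(ens, frame_indices)
  cl <- daura_cluster_from_rmsd(m, rmsd_cutoff)
  out <- data.frame(frame = frame_indices[cl$order],
                    cluster = cl$cluster[cl$order],
                    is_center = cl$is_center[cl$order])
  out <- out[order(out$cluster, out$frame), ]
  rownames(out) <- NULL
  attr(out, "rmsd_matrix") <- m
  out
}

## Daura neighbour-counting on a precomputed RMSD matrix
daura_cluster_from_rmsd <- function(m, cutoff) {
  n <- nrow(m)
  remaining <- seq_len(n)
  cluster <- integer(n)
  is_center <- logical(n)
  centres <- integer(0)
  sizes <- integer(0)
  k <- 0L
  while (length(remaining) > 0L) {
    k <- k + 1L
    sub <- m[remaining, remaining, drop = FALSE]
    counts <- rowSums(sub <= cutoff)        # includes self
    centre_pos <- which.max(counts)          # ties -> lowest index
    centre <- remaining[centre_pos]
    members <- remaining[sub[centre_pos, ] <= cutoff]
    cluster[members] <- k
    is_center[centre] <- TRUE
    centres <- c(centres, centre)
    sizes <- c(sizes, length(members))
    remaining <- setdiff(remaining, members)
  }
  ## reorder cluster ids by decreasing size, ties by discovery order
  o <- order(-sizes, seq_along(sizes))
  relabel <- match(seq_len(k), o)
  list(cluster = relabel[cluster], is_center = is_center,
       order = seq_len(n))
}

#' Feature matrix for tICA
#'
#' Default features are all CA-CA distances with sequence separation of at
#' least 2 (rigid-motion invariant and defined for backbone-only chains);
#' `mode = "dihedral"` uses sin/cos of the defined phi/psi angles instead.
#'
#' @param ens A [ensemble()].
#' @param mode `"ca-distance"` (default) or `"dihedral"`.
#' @return frames x features numeric matrix with a `feature_names`
#'   attribute.
#' @export
featurize <- function(ens, mode = c("ca-distance", "dihedral")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ens, "coe_ensemble"))
  if (n_residues(ens) < 4L) stop("featurize needs at least 4 residues")
  if (mode == "ca-distance") {
    top <- ens$topology
    sel <- vapply(seq_len(n_residues(ens)),
                  function(r) atom_index(top, r, "CA"), integer(1))
    if (anyNA(sel)) stop("every residue needs a CA atom")
    pairs <- utils::combn(seq_along(sel), 2L)
    keep <- (pairs[2, ] - pairs[1, ]) >= 2L
    pairs <- pairs[, keep, drop = FALSE]
    x <- matrix(NA_real_, n_frames(ens), ncol(pairs))
    for (i in seq_len(n_frames(ens))) {
      xyz <- frame_coords(ens, i)[sel, , drop = FALSE]
      x[i, ] <- sqrt(rowSums((xyz[pairs[1, ], , drop = FALSE] -
                                xyz[pairs[2, ], , drop = FALSE])^2))
    }
    attr(x, "feature_names") <- paste0("dCA_", pairs[1, ], "_", pairs[2, ])
  } else {
    dh <- backbone_dihedrals(ens)
    cols <- list()
    nm <- character(0)
    for (r in seq_len(ncol(dh$phi))) {
      if (!all(is.na(dh$phi[, r]))) {
        rad <- dh$phi[, r] * pi / 180
        cols <- c(cols, list(sin(rad), cos(rad)))
        nm <- c(nm, paste0(c("sin_phi_", "cos_phi_"), r))
      }
      if (!all(is.na(dh$psi[, r]))) {
        rad <- dh$psi[, r] * pi / 180
        cols <- c(cols, list(sin(rad), cos(rad)))
        nm <- c(nm, paste0(c("sin_psi_", "cos_psi_"), r))
      }
    }
    x <- do.call(cbind, cols)
    attr(x, "feature_names") <- nm
  }
  x
}

#' Fit time-lagged independent component analysis
#'
#' Estimates the symmetrised lagged covariance C_tau and the instantaneous
#' covariance C0 (plus `epsilon` on the diagonal) of the mean-centred
#' features and solves the generalised eigenproblem
#' C_tau v = lambda (C0 + eps I) v. Components are sorted by decreasing
#' eigenvalue and normalised to unit variance in the C0 metric.
#'
#' @param features frames x features matrix (e.g. from [featurize()]).
#' @param lag Lag time in frames (default 10).
#' @param n_components Number of components to keep (default 2).
#' @param epsilon Diagonal regularisation; default
#'   `1e-6 * mean(diag(C0))`.
#' @return An object of class `tica_model` with `mean`, `components`
#'   (features x k), `eigenvalues`, `lag`, `epsilon`, and `c0` (the
#'   regularised instantaneous covariance the components are orthonormal
#'   against).
#' @export
tica_fit <- function(features, lag = 10, n_components = 2, epsilon = NULL) {
  x <- as.matrix(features)
  if (any(!is.finite(x))) stop("features must be finite")
  n <- nrow(x); p <- ncol(x)
  if (n <= lag + n_components) stop("need more frames than lag + components")
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  a <- xc[1:(n - lag), , drop = FALSE]
  b <- xc[(1 + lag):n, , drop = FALSE]
  c0 <- (crossprod(a) + crossprod(b)) / (2 * (n - lag))
  ctau <- (crossprod(a, b) + crossprod(b, a)) / (2 * (n - lag))
  if (is.null(epsilon)) epsilon <- 1e-6 * mean(diag(c0))
  c0r <- c0 + diag(epsilon, p)
  ## whiten with the Cholesky factor, then symmetric eigenproblem
  l <- chol(c0r)                       # c0r = l' l
  linv <- backsolve(l, diag(p))
  sym <- t(linv) %*% ctau %*% linv
  sym <- (sym + t(sym)) / 2
  eg <- eigen(sym, symmetric = TRUE)
  k <- min(n_components, p)
  comps <- linv %*% eg$vectors[, seq_len(k), drop = FALSE]
  structure(list(mean = mu, components = comps,
                 eigenvalues = eg$values[seq_len(k)],
                 lag = lag, epsilon = epsilon, c0 = c0r),
            class = "tica_model")
}

#' @export
print.tica_model <- function(x, ...) {
  cat("tICA model: lag", x$lag, "frames;",
      length(x$eigenvalues), "components; eigenvalues",
      paste(format(x$eigenvalues, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Project features onto tICA components
#'
#' @param model A [tica_fit()] model.
#' @param features frames x features matrix.
#' @return frames x components projection matrix.
#' @export
tica_transform <- function(model, features) {
  stopifnot(inherits(model, "tica_model"))
  sweep(as.matrix(features), 2L, model$mean) %*% model$components
}

#' Free-energy landscape over two collective coordinates
#'
#' Bins the projections on a regular 2D grid spanning the 1st-99th
#' percentile range of each coordinate and converts occupancies to free
#' energies F = -ln(density) in kT, shifted so the occupied minimum is 0.
#' Empty bins are masked (NA).
#'
#' @param projections frames x 2 matrix (e.g. leading tICs).
#' @param n_bins Bins per axis (default 60).
#' @param probs Percentile range of the grid (default c(0.01, 0.99)).
#' @return An object of class `fe_landscape`: list with `x_edges`,
#'   `y_edges`, `free_energy` (kT, NA where empty), `counts`.
#' @export
free_energy_landscape <- function(projections, n_bins = 60,
                                  probs = c(0.01, 0.99)) {
  pr <- as.matrix(projections)
  stopifnot(ncol(pr) == 2L, nrow(pr) >= 2L)
  xe <- seq(stats::quantile(pr[, 1], probs[1]),
            stats::quantile(pr[, 1], probs[2]), length.out = n_bins + 1L)
  ye <- seq(stats::quantile(pr[, 2], probs[1]),
            stats::quantile(pr[, 2], probs[2]), length.out = n_bins + 1L)
  if (diff(range(xe)) == 0 || diff(range(ye)) == 0) {
    stop("degenerate projection range; all points in one bin")
  }
  ix <- findInterval(pr[, 1], xe, rightmost.closed = TRUE)
  iy <- findInterval(pr[, 2], ye, rightmost.closed = TRUE)
  keep <- ix >= 1L & ix <= n_bins & iy >= 1L & iy <= n_bins
  counts <- matrix(0L, n_bins, n_bins)
  for (k in which(keep)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  if (sum(counts > 0) < 2L) stop("fewer than 2 occupied bins")
  fe <- -log(counts / sum(counts))
  fe[counts == 0L] <- NA_real_
  fe <- fe - min(fe, na.rm = TRUE)
  structure(list(x_edges = xe, y_edges = ye, free_energy = fe,
                 counts = counts),
            class = "fe_landscape")
}

#' @export
print.fe_landscape <- function(x, ...) {
  cat("Free-energy landscape:", nrow(x$free_energy), "x",
      ncol(x$free_energy), "bins;", sum(x$counts > 0), "occupied; max",
      format(max(x$free_energy, na.rm = TRUE), digits = 4), "kT\n")
  invisible(x)
}
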