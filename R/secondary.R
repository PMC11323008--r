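## Backbone dihedrals, Ramachandran region integration, and a simplified
## DSSP assignment (helix, sheet, hydrogen-bonded turn, PPII, coil) built
## on the Kabsch-Sander electrostatic hydrogen-bond energy.

#' Backbone phi/psi dihedrals of every frame
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i); psi(i) = N(i)-CA(i)-C(i)-N(i+1), IUPAC
#' sign convention, degrees in (-180, 180]. The first residue's phi and the
#' last residue's psi are undefined (NA); residues with missing backbone
#' atoms are masked with a warning.
#'
#' @param ens A [ensemble()].
#' @return An object of class `dihedral_table`: list of frames x residues
#'   matrices `phi` and `psi` (NA where undefined).
#' @export
backbone_dihedrals <- function(ens) {
  stopifnot(inherits(ens, "coe_ensemble"))
  top <- ens$topology
  n_res <- n_residues(ens)
  idx_n  <- vapply(seq_len(n_res), function(r) atom_index(top, r, "N"), integer(1))
  idx_ca <- vapply(seq_len(n_res), function(r) atom_index(top, r, "CA"), integer(1))
  idx_c  <- vapply(seq_len(n_res), function(r) atom_index(top, r, "C"), integer(1))
  incomplete <- is.na(idx_n) | is.na(idx_ca) | is.na(idx_c)
  if (any(incomplete)) {
    warning("residue(s) with missing backbone atoms masked: ",
            paste(which(incomplete), collapse = ", "))
  }
  nf <- n_frames(ens)
  phi <- psi <- matrix(NA_real_, nf, n_res)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(ens, f)
    for (r in seq_len(n_res)) {
      if (incomplete[r]) next
      if (r > 1 && !incomplete[r - 1]) {
        phi[f, r] <- dihedral_angle(xyz[idx_c[r - 1], ], xyz[idx_n[r], ],
                                    xyz[idx_ca[r], ], xyz[idx_c[r], ])
      }
      if (r < n_res && !incomplete[r + 1]) {
        psi[f, r] <- dihedral_angle(xyz[idx_n[r], ], xyz[idx_ca[r], ],
                                    xyz[idx_c[r], ], xyz[idx_n[r + 1], ])
      }
    }
  }
  structure(list(phi = phi, psi = psi), class = "dihedral_table")
}

#' @export
print.dihedral_table <- function(x, ...) {
  cat("Dihedral table:", nrow(x$phi), "frames x", ncol(x$phi), "residues;",
      sum(!is.na(x$phi) & !is.na(x$psi)), "defined (phi, psi) pairs\n")
  invisible(x)
}

## defined (phi, psi) pairs as a 2-column matrix
defined_pairs <- function(dihedrals) {
  ok <- !is.na(dihedrals$phi) & !is.na(dihedrals$psi)
  cbind(phi = dihedrals$phi[ok], psi = dihedrals$psi[ok])
}

#' 2D Ramachandran histogram
#'
#' Counts of defined (phi, psi) pairs on a regular grid covering
#' [-180, 180]^2; the grand total equals the number of defined pairs.
#'
#' @param dihedrals A [backbone_dihedrals()] table.
#' @param bin_width Bin width in degrees (default 2; must divide 360).
#' @return List with `phi_edges`, `psi_edges` and `counts` matrix.
#' @export
ramachandran_histogram <- function(dihedrals, bin_width = 2) {
  stopifnot(360 %% bin_width == 0)
  pairs <- defined_pairs(dihedrals)
  if (nrow(pairs) == 0L) stop("no defined (phi, psi) pairs")
  edges <- seq(-180, 180, by = bin_width)
  nb <- length(edges) - 1L
  ## angles live in (-180, 180]: put 180 into the last bin
  ix <- pmin(pmax(ceiling((pairs[, 1] + 180) / bin_width), 1L), nb)
  iy <- pmin(pmax(ceiling((pairs[, 2] + 180) / bin_width), 1L), nb)
  counts <- matrix(0L, nb, nb)
  for (k in seq_len(nrow(pairs))) {
    counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  }
  list(phi_edges = edges, psi_edges = edges, counts = counts)
}

## membership of (phi, psi) points in one region window,
## closed-low / open-high on both axes
in_region <- function(phi, psi, region_row) {
  phi >= region_row$phi_lo & phi < region_row$phi_hi &
    psi >= region_row$psi_lo & psi < region_row$psi_hi
}

#' Fraction of dihedral pairs inside each Ramachandran region
#'
#' fraction = defined pairs inside the window / all defined pairs, with
#' closed lower and open upper bounds per axis. Regions do not tile the
#' plane, so fractions need not sum to 1.
#'
#' @param dihedrals A [backbone_dihedrals()] table (or anything with
#'   `phi`/`psi` matrices).
#' @param regions Region table as from [ramachandran_regions()].
#' @return Named numeric vector of fractions.
#' @export
region_fractions <- function(dihedrals, regions = ramachandran_regions()) {
  pairs <- defined_pairs(dihedrals)
  if (nrow(pairs) == 0L) stop("no defined (phi, psi) pairs")
  out <- stats::setNames(numeric(nrow(regions)), regions$name)
  for (i in seq_len(nrow(regions))) {
    out[i] <- mean(in_region(pairs[, 1], pairs[, 2], regions[i, ]))
  }
  out
}

#' Kabsch-Sander hydrogen-bond energy between two residues
#'
#' E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol between
#' the acceptor residue's backbone C=O and the donor residue's backbone
#' N-H; a hydrogen bond is assigned when E < -0.5 kcal/mol. Identical or
#' sequence-adjacent residues never bond, by definition.
#'
#' @param coords atoms x 3 matrix.
#' @param top A [topology()] with backbone N, H, C, O atoms.
#' @param donor_res,acceptor_res 1-based residue indices (donor provides
#'   N-H, acceptor provides C=O).
#' @return Energy in kcal/mol (`Inf` when excluded by definition or atoms
#'   are missing).
#' @export
kabsch_sander_energy <- function(coords, top, donor_res, acceptor_res) {
  if (abs(donor_res - acceptor_res) <= 1L) return(Inf)
  i_n <- atom_index(top, donor_res, "N")
  i_h <- atom_index(top, donor_res, "H")
  i_c <- atom_index(top, acceptor_res, "C")
  i_o <- atom_index(top, acceptor_res, "O")
  if (anyNA(c(i_n, i_h, i_c, i_o))) return(Inf)
  r <- function(i, j) sqrt(sum((coords[i, ] - coords[j, ])^2))
  0.084 * 332 * (1 / r(i_o, i_n) + 1 / r(i_c, i_h) -
                   1 / r(i_o, i_h) - 1 / r(i_c, i_n))
}

## all Kabsch-Sander bonds of one frame: logical matrix bond[i, j] = TRUE
## when CO(i) ... HN(j) with E < -0.5 (i acceptor, j donor); vectorised
## over residue pairs
ks_bond_matrix <- function(coords, top, energy_cutoff = -0.5) {
  n_res <- n_residues(top)
  idx <- function(nm) vapply(seq_len(n_res),
                             function(r) atom_index(top, r, nm), integer(1))
  pos <- function(i) {
    m <- matrix(NA_real_, n_res, 3L)
    ok <- !is.na(i)
    m[ok, ] <- coords[i[ok], , drop = FALSE]
    m
  }
  p_n <- pos(idx("N")); p_h <- pos(idx("H"))
  p_c <- pos(idx("C")); p_o <- pos(idx("O"))
  pd <- function(a, b) {
    sqrt(pmax(outer(rowSums(a^2), rep(1, n_res)) +
                outer(rep(1, n_res), rowSums(b^2)) - 2 * a %*% t(b), 0))
  }
  e <- 0.084 * 332 * (1 / pd(p_o, p_n) + 1 / pd(p_c, p_h) -
                        1 / pd(p_o, p_h) - 1 / pd(p_c, p_n))
  bond <- !is.na(e) & is.finite(e) & e < energy_cutoff
  sep <- abs(outer(seq_len(n_res), seq_len(n_res), "-"))
  bond[sep <= 1L] <- FALSE
  bond
}

#' Simplified DSSP secondary-structure assignment
#'
#' Per-frame, per-residue labels from Kabsch-Sander bonds: an n-turn at i
#' when CO(i) bonds HN(i+n), n in 3..5; H (alpha-helix) for residues
#' covered by two consecutive 4-turns; E (sheet) for ladders of at least 2
#' consecutive bridge patterns; T for turn residues not in a helix; P for
#' runs of >= `ppii_min_run` residues inside the PPII Ramachandran window
#' with no H/E/T label; C otherwise. Priority H > E > T > P > C.
#'
#' @param ens A [ensemble()].
#' @param frame_indices Frames to assign (default all).
#' @param ppii_min_run Minimum PPII run length (default 2).
#' @return frames x residues character matrix with labels in
#'   {"H","E","T","P","C"}.
#' @export
dssp_assign <- function(ens, frame_indices = seq_len(n_frames(ens)),
                        ppii_min_run = 2) {
  stopifnot(inherits(ens, "coe_ensemble"))
  top <- ens$topology
  n_res <- n_residues(ens)
  dh <- backbone_dihedrals(subset_frames(ens, frame_indices))
  ppii_row <- ramachandran_regions()[ramachandran_regions()$name == "ppii", ]
  out <- matrix("C", length(frame_indices), n_res)
  for (f in seq_along(frame_indices)) {
    xyz <- frame_coords(ens, frame_indices[f])
    bond <- ks_bond_matrix(xyz, top)
    lab <- rep("C", n_res)

    ## turns: CO(i) ... HN(i+n)
    turn <- matrix(FALSE, n_res, 3L)        # columns: n = 3, 4, 5
    for (nt in 3:5) {
      i_ok <- seq_len(max(0L, n_res - nt))
      for (i in i_ok) turn[i, nt - 2L] <- bond[i, i + nt]
    }
    ## helix: two consecutive 4-turns at i-1 and i cover residues i..i+3
    helix <- rep(FALSE, n_res)
    for (i in 2:max(2L, n_res - 4L)) {
      if (n_res >= i + 4L && turn[i - 1L, 2L] && turn[i, 2L]) {
        helix[i:(i + 3L)] <- TRUE
      }
    }
    ## bridges (parallel or antiparallel), ladders of >= 2
    bridge <- matrix(FALSE, n_res, n_res)
    if (n_res >= 6L) for (i in 2:(n_res - 1L)) {
      for (j in 2:(n_res - 1L)) {
        if (abs(i - j) < 3L) next
        para <- (bond[i - 1L, j] && bond[j, i + 1L]) ||
          (bond[j - 1L, i] && bond[i, j + 1L])
        anti <- (bond[i, j] && bond[j, i]) ||
          (bond[i - 1L, j + 1L] && bond[j - 1L, i + 1L])
        if (para || anti) bridge[i, j] <- TRUE
      }
    }
    sheet <- rep(FALSE, n_res)
    for (i in seq_len(n_res - 1L)) {
      js <- which(bridge[i, ])
      for (j in js) {
        ladder <- (j + 1L <= n_res && bridge[i + 1L, j + 1L]) ||
          (j - 1L >= 1L && bridge[i + 1L, j - 1L])
        if (ladder) sheet[c(i, i + 1L)] <- TRUE
      }
    }
    ## turn label: residues strictly inside any n-turn
    turn_res <- rep(FALSE, n_res)
    for (nt in 3:5) {
      for (i in which(turn[, nt - 2L])) {
        turn_res[(i + 1L):(i + nt - 1L)] <- TRUE
      }
    }
    lab[turn_res] <- "T"
    lab[sheet] <- "E"
    lab[helix] <- "H"

    ## PPII: dihedral window, runs >= ppii_min_run, only over C residues
    in_ppii <- !is.na(dh$phi[f, ]) & !is.na(dh$psi[f, ]) &
      in_region(dh$phi[f, ], dh$psi[f, ], ppii_row) & lab == "C"
    r <- rle(in_ppii)
    pos <- cumsum(r$lengths) - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] && r$lengths[k] >= ppii_min_run) {
        lab[pos[k]:(pos[k] + r$lengths[k] - 1L)] <- "P"
      }
    }
    out[f, ] <- lab
  }
  dimnames(out) <- list(NULL, residue_labels(top))
  out
}

#' Secondary-structure label fractions per Rg group
#'
#' Fraction of residue-frames carrying each label within each group;
#' fractions per group sum to 1.
#'
#' @param ens A [ensemble()].
#' @param groups An [rg_group_set()].
#' @param labels Group labels to analyse (default all).
#' @param ... Passed to [dssp_assign()].
#' @return labels x groups matrix (rows H, E, T, P, C).
#' @export
group_ss_fractions <- function(ens, groups, labels = groups$labels, ...) {
  stopifnot(inherits(ens, "coe_ensemble"), inherits(groups, "rg_group_set"))
  ss_levels <- c("H", "E", "T", "P", "C")
  out <- matrix(NA_real_, length(ss_levels), length(labels),
                dimnames = list(ss_levels, as.character(labels)))
  for (g in seq_along(labels)) {
    frames <- group_frames(groups, labels[g])
    ss <- dssp_assign(ens, frames, ...)
    tab <- table(factor(ss, levels = ss_levels))
    out[, g] <- as.numeric(tab) / sum(tab)
  }
  out
}

#' Per-group Ramachandran region fractions
#'
#' The region-integration table: for each Rg group, the fraction of its
#' defined (phi, psi) pairs inside each region window.
#'
#' @param ens A [ensemble()].
#' @param groups An [rg_group_set()].
#' @param labels Group labels (default all).
#' @param regions Region table as from [ramachandran_regions()].
#' @return regions x groups matrix of fractions.
#' @export
group_region_fractions <- function(ens, groups, labels = groups$labels,
                                   regions = ramachandran_regions()) {
  dh <- backbone_dihedrals(ens)
  out <- matrix(NA_real_, nrow(regions), length(labels),
                dimnames = list(regions$name, as.character(labels)))
  for (g in seq_along(labels)) {
    frames <- group_frames(groups, labels[g])
    sub <- list(phi = dh$phi[frames, , drop = FALSE],
                psi = dh$psi[frames, , drop = FALSE])
    out[, g] <- region_fractions(sub, regions)
  }
  out
}
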