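## Geometric hydrogen-bond detection (GROMACS hbond convention) and
## residue-residue contact/distance maps.

## donors: N or O carrying a covalently attached H (within h_attach Ang);
## acceptors: every N or O
find_donors <- function(coords, top, h_attach = 1.25) {
  is_h <- top$elements == "H"
  cand <- which(top$elements %in% c("N", "O"))
  donors <- list()
  for (d in cand) {
    hs <- which(is_h)
    if (length(hs) == 0L) next
    dd <- sqrt(rowSums(sweep(coords[hs, , drop = FALSE], 2L,
                             coords[d, ])^2))
    att <- hs[dd <= h_attach]
    for (h in att) donors[[length(donors) + 1L]] <- c(donor = d, hydrogen = h)
  }
  donors
}

#' Detect hydrogen bonds in one frame (geometric criterion)
#'
#' A bond is recorded when the donor-acceptor distance is at most
#' `d_cutoff` and the hydrogen-donor-acceptor angle is at most
#' `angle_cutoff` (the `gmx hbond` convention; defaults 3.5 Angstrom, 30
#' degrees). Donors are N/O atoms with an attached hydrogen; acceptors are
#' all N/O atoms. Donor-acceptor pairs within the same residue are
#' excluded; adjacent residues are retained here and filtered only in
#' [hbond_map()] summaries.
#'
#' @param coords atoms x 3 matrix (Angstrom).
#' @param top A [topology()].
#' @param d_cutoff Donor-acceptor distance cutoff (Angstrom).
#' @param angle_cutoff Hydrogen-donor-acceptor angle cutoff (degrees).
#' @return data.frame with columns `donor_res`, `acceptor_res`,
#'   `donor_atom`, `acceptor_atom`, `distance`, `angle`.
#' @export
detect_hydrogen_bonds <- function(coords, top, d_cutoff = 3.5,
                                  angle_cutoff = 30) {
  coords <- as.matrix(coords)
  donors <- find_donors(coords, top)
  acceptors <- which(top$elements %in% c("N", "O"))
  out <- list()
  for (dn in donors) {
    d <- dn[["donor"]]; h <- dn[["hydrogen"]]
    da <- sqrt(rowSums(sweep(coords[acceptors, , drop = FALSE], 2L,
                             coords[d, ])^2))
    near <- acceptors[da <= d_cutoff & acceptors != d &
                        top$residue_index[acceptors] != top$residue_index[d]]
    for (a in near) {
      v_h <- coords[h, ] - coords[d, ]
      v_a <- coords[a, ] - coords[d, ]
      cosang <- sum(v_h * v_a) / (vnorm(v_h) * vnorm(v_a))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (ang <= angle_cutoff) {
        out[[length(out) + 1L]] <- data.frame(
          donor_res = top$residue_index[d],
          acceptor_res = top$residue_index[a],
          donor_atom = d, acceptor_atom = a,
          distance = sqrt(sum((coords[a, ] - coords[d, ])^2)),
          angle = ang)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(donor_res = integer(), acceptor_res = integer(),
                      donor_atom = integer(), acceptor_atom = integer(),
                      distance = numeric(), angle = numeric()))
  }
  do.call(rbind, out)
}

#' Per-group hydrogen-bond occupancy maps
#'
#' For each selected Rg group, the fraction of the group's frames in which
#' each residue pair is hydrogen bonded (in either direction). Pairs of
#' sequence separation < `min_separation` (default 2: self and adjacent
#' backbone pairs) are excluded from the maps. Also returns the ranked pair
#' list per group.
#'
#' @param ens A [ensemble()].
#' @param groups An [rg_group_set()].
#' @param labels Group labels to analyse (default all).
#' @param min_separation Minimum |i - j| retained in the maps.
#' @param ... Passed to [detect_hydrogen_bonds()].
#' @return List with `maps` (named list of symmetric residues x residues
#'   occupancy matrices) and `pairs` (data.frame: group, residue_i,
#'   residue_j, occupancy, ranked by occupancy within group).
#' @export
hbond_map <- function(ens, groups, labels = groups$labels,
                      min_separation = 2, ...) {
  stopifnot(inherits(ens, "coe_ensemble"), inherits(groups, "rg_group_set"))
  top <- ens$topology
  n_res <- n_residues(ens)
  rl <- residue_labels(top)
  maps <- list()
  pair_rows <- list()
  for (lab in labels) {
    frames <- group_frames(groups, lab)
    occ <- matrix(0, n_res, n_res, dimnames = list(rl, rl))
    for (fr in frames) {
      hb <- detect_hydrogen_bonds(frame_coords(ens, fr), top, ...)
      if (nrow(hb) == 0L) next
      hb <- hb[abs(hb$donor_res - hb$acceptor_res) >= min_separation, ,
               drop = FALSE]
      seen <- unique(cbind(pmin(hb$donor_res, hb$acceptor_res),
                           pmax(hb$donor_res, hb$acceptor_res)))
      if (is.null(dim(seen))) seen <- matrix(seen, ncol = 2)
      for (r in seq_len(nrow(seen))) {
        occ[seen[r, 1], seen[r, 2]] <- occ[seen[r, 1], seen[r, 2]] + 1
      }
    }
    ## counts live in the upper triangle; mirror to a symmetric map
    occ <- occ / length(frames)
    occ <- occ + t(occ); diag(occ) <- 0
    maps[[as.character(lab)]] <- occ
    ut <- which(upper.tri(occ) & occ > 0, arr.ind = TRUE)
    if (nrow(ut)) {
      pr <- data.frame(group = lab,
                       residue_i = rl[ut[, 1]], residue_j = rl[ut[, 2]],
                       occupancy = occ[ut])
      pair_rows[[as.character(lab)]] <- pr[order(-pr$occupancy), ]
    }
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows)
           else data.frame(group = integer(), residue_i = character(),
                           residue_j = character(), occupancy = numeric())
  rownames(pairs) <- NULL
  list(maps = maps, pairs = pairs)
}

#' Per-group residue-residue mean-distance maps
#'
#' Per-frame residue-pair distances (minimum heavy-atom distance or
#' CA-CA distance) averaged over each selected group's frames.
#'
#' @param ens A [ensemble()].
#' @param groups An [rg_group_set()].
#' @param labels Group labels to analyse (default all).
#' @param mode `"min-atom"` (minimum heavy-atom distance, default) or
#'   `"ca"` (CA-CA).
#' @return Named list of symmetric residues x residues matrices (Angstrom,
#'   zero diagonal), one per group.
#' @export
residue_distance_map <- function(ens, groups, labels = groups$labels,
                                 mode = c("min-atom", "ca")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ens, "coe_ensemble"), inherits(groups, "rg_group_set"))
  top <- ens$topology
  n_res <- n_residues(ens)
  rl <- residue_labels(top)
  if (mode == "ca") {
    sel <- vapply(seq_len(n_res), function(r) atom_index(top, r, "CA"),
                  integer(1))
    if (anyNA(sel)) stop("CA mode requires a CA atom in every residue")
  } else {
    heavy <- which(top$elements != "H")
  }
  out <- list()
  for (lab in labels) {
    frames <- group_frames(groups, lab)
    acc <- matrix(0, n_res, n_res, dimnames = list(rl, rl))
    for (fr in frames) {
      xyz <- frame_coords(ens, fr)
      if (mode == "ca") {
        dm <- as.matrix(stats::dist(xyz[sel, , drop = FALSE]))
      } else {
        dall <- as.matrix(stats::dist(xyz[heavy, , drop = FALSE]))
        res <- top$residue_index[heavy]
        dm <- matrix(Inf, n_res, n_res)
        for (i in seq_len(n_res)) {
          ri <- which(res == i)
          for (j in i:n_res) {
            dm[i, j] <- dm[j, i] <- min(dall[ri, res == j])
          }
        }
        diag(dm) <- 0
      }
      acc <- acc + dm
    }
    out[[as.character(lab)]] <- acc / length(frames)
  }
  out
}
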