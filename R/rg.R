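## Radius-of-gyration computation and the integer-Angstrom group
## decomposition that the whole workflow is organised around.

#' Construct an Rg-group partition
#'
#' @param labels Integer Angstrom labels, one per group.
#' @param members List of 1-based frame-index vectors, one per label.
#' @param rg_per_frame Optional per-frame Rg values (Angstrom).
#' @param validate_partition Check that members partition `1:F` (requires
#'   `rg_per_frame` or contiguous coverage); internal callers may disable.
#' @return An object of class `rg_group_set`.
#' @export
rg_group_set <- function(labels, members, rg_per_frame = NULL,
                         validate_partition = TRUE) {
  stopifnot(length(labels) == length(members), length(labels) >= 1)
  labels <- as.integer(labels)
  if (is.unsorted(labels, strictly = TRUE)) {
    o <- order(labels)
    labels <- labels[o]; members <- members[o]
  }
  if (anyDuplicated(labels)) stop("duplicate group labels")
  members <- lapply(members, function(m) sort(as.integer(m)))
  if (any(lengths(members) == 0L)) stop("empty groups are not allowed")
  all_idx <- unlist(members)
  if (anyDuplicated(all_idx)) stop("groups overlap: not a partition")
  if (validate_partition) {
    if (!setequal(all_idx, seq_len(max(all_idx)))) {
      stop("group members must partition 1:F with no gaps")
    }
    if (!is.null(rg_per_frame) && length(rg_per_frame) != max(all_idx)) {
      stop("rg_per_frame length must equal the number of frames")
    }
  }
  structure(list(labels = labels, members = members,
                 rg_per_frame = rg_per_frame),
            class = "rg_group_set")
}

#' @export
print.rg_group_set <- function(x, ...) {
  cat("Rg decomposition:", length(x$labels), "groups over",
      sum(lengths(x$members)), "frames\n")
  print(data.frame(label_A = x$labels, n_frames = lengths(x$members)),
        row.names = FALSE)
  invisible(x)
}

#' Mass-weighted radius of gyration of one frame
#'
#' Rg = sqrt( sum_i m_i |r_i - r_com|^2 / sum_i m_i ), the quantity
#' `gmx gyrate` reports, about the mass-weighted centre.
#'
#' @param coords atoms x 3 matrix (Angstrom).
#' @param masses Positive per-atom masses (amu); equal masses give the
#'   geometric Rg.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, nrow(coords) >= 1L)
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  stopifnot(length(masses) == nrow(coords))
  if (any(masses < 0) || sum(masses) <= 0) {
    stop("masses must be non-negative with positive total")
  }
  w <- masses / sum(masses)
  com <- colSums(coords * w)
  d2 <- rowSums(sweep(coords, 2L, com)^2)
  sqrt(sum(w * d2))
}

## round half away from zero (R's round() rounds half to even)
round_half_up <- function(x) trunc(x + sign(x) * 0.5)

#' Per-frame Rg of an ensemble
#'
#' @param ens A [ensemble()].
#' @return Numeric vector of length F (Angstrom).
#' @export
ensemble_rg <- function(ens) {
  stopifnot(inherits(ens, "coe_ensemble"))
  m <- ens$topology$masses
  vapply(seq_len(n_frames(ens)),
         function(i) radius_of_gyration(frame_coords(ens, i), m),
         numeric(1))
}

#' Partition an ensemble into integer-Angstrom Rg groups
#'
#' Each frame's mass-weighted Rg is rounded half-away-from-zero to the
#' nearest integer Angstrom; frames sharing a rounded value form a group.
#' Groups with zero members simply do not appear. Groups holding less than
#' `min_occupancy` of the frames are flagged `low_sampling` (never dropped).
#'
#' @param ens A [ensemble()].
#' @param min_occupancy Fraction of frames below which a group is flagged
#'   as sparsely sampled (default 0.001).
#' @return An [rg_group_set()] with `rg_per_frame` and a `low_sampling`
#'   logical attribute per group.
#' @export
assign_rg_groups <- function(ens, min_occupancy = 0.001) {
  rg <- ensemble_rg(ens)
  lab <- as.integer(round_half_up(rg))
  split_idx <- split(seq_along(lab), lab)
  labels <- as.integer(names(split_idx))
  gs <- rg_group_set(labels = labels, members = unname(split_idx),
                     rg_per_frame = rg)
  gs$low_sampling <- lengths(gs$members) < min_occupancy * length(rg)
  gs
}

#' Relative occupancy of each Rg group
#'
#' @param groups An [rg_group_set()].
#' @return data.frame with columns `label`, `count`, `fraction`
#'   (fractions sum to 1).
#' @export
group_histogram <- function(groups) {
  stopifnot(inherits(groups, "rg_group_set"))
  counts <- lengths(groups$members)
  data.frame(label = groups$labels,
             count = counts,
             fraction = counts / sum(counts))
}

## frames of one labelled group, with a helpful error
group_frames <- function(groups, label) {
  i <- match(label, groups$labels)
  if (is.na(i)) {
    stop("no Rg group labelled ", label, "; available: ",
         paste(groups$labels, collapse = ", "))
  }
  groups$members[[i]]
}
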