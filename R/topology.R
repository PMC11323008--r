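#' Construct an atom topology
#'
#' The static chain description every analysis consumes: atom names, chemical
#' elements, the residue each atom belongs to, per-residue names, and per-atom
#' masses and van der Waals radii. Masses and radii default to a built-in
#' element table (Bondi radii).
#'
#' @param atom_names Character vector of PDB atom names, one per atom.
#' @param residue_index Integer vector, 1-based residue ordinal per atom;
#'   must be non-decreasing and start at 1.
#' @param residue_name Character vector of 3-letter residue codes, one per
#'   residue.
#' @param elements Optional element symbol per atom; inferred from
#'   `atom_names` (with a warning) when missing.
#' @param masses,vdw_radius Optional per-atom overrides (amu, Angstrom).
#' @return An object of class `coe_topology`.
#' @export
topology <- function(atom_names, residue_index, residue_name,
                     elements = NULL, masses = NULL, vdw_radius = NULL) {
  n <- length(atom_names)
  stopifnot(n >= 1, length(residue_index) == n)
  residue_index <- as.integer(residue_index)
  if (residue_index[1] != 1L || any(diff(residue_index) < 0L)) {
    stop("residue_index must be non-decreasing and start at 1")
  }
  n_res <- max(residue_index)
  if (length(residue_name) != n_res) {
    stop("residue_name must have one entry per residue (", n_res, ")")
  }
  if (is.null(elements)) {
    warning("no elements supplied; inferring from atom names")
    elements <- infer_element(atom_names)
  }
  if (!all(elements %in% supported_elements())) {
    stop("unsupported element(s): ",
         paste(setdiff(unique(elements), supported_elements()), collapse = ", "))
  }
  if (is.null(masses)) masses <- element_mass(elements)
  if (is.null(vdw_radius)) vdw_radius <- element_vdw_radius(elements)
  stopifnot(length(masses) == n, length(vdw_radius) == n)
  if (any(!is.finite(masses)) || any(masses <= 0)) {
    stop("all atom masses must be positive and finite")
  }
  if (any(!is.finite(vdw_radius)) || any(vdw_radius <= 0)) {
    stop("all van der Waals radii must be positive and finite")
  }
  structure(
    list(atom_names = as.character(atom_names),
         elements = as.character(elements),
         residue_index = residue_index,
         residue_name = toupper(as.character(residue_name)),
         masses = as.numeric(masses),
         vdw_radius = as.numeric(vdw_radius)),
    class = "coe_topology"
  )
}

#' Number of atoms, frames and residues
#'
#' Accessors shared by topologies and ensembles.
#'
#' @param x A `coe_topology` or `coe_ensemble`.
#' @return Integer count.
#' @export
n_atoms <- function(x) UseMethod("n_atoms")
#' @export
n_atoms.coe_topology <- function(x) length(x$atom_names)
#' @export
n_atoms.coe_ensemble <- function(x) dim(x$coords)[2]

#' @rdname n_atoms
#' @export
n_residues <- function(x) UseMethod("n_residues")
#' @export
n_residues.coe_topology <- function(x) length(x$residue_name)
#' @export
n_residues.coe_ensemble <- function(x) n_residues(x$topology)

#' @export
print.coe_topology <- function(x, ...) {
  cat("Topology:", n_atoms(x), "atoms,", n_residues(x), "residues\n")
  cat("  elements:", paste(sort(unique(x$elements)), collapse = " "), "\n")
  invisible(x)
}

## residue label like "H3" (1-letter code + 1-based position)
residue_labels <- function(top) {
  paste0(aa_one(top$residue_name), seq_along(top$residue_name))
}

## index of the (first) atom with a given name in a residue, NA if absent
atom_index <- function(top, res, name) {
  hit <- which(top$residue_index == res & top$atom_names == name)
  if (length(hit) == 0L) NA_integer_ else hit[1]
}

#' Construct a conformer ensemble
#'
#' @param coords Numeric array of dimension frames x atoms x 3, in Angstrom.
#' @param topology A [topology()] object with matching atom count.
#' @param frame_stride Optional time between frames (arbitrary units), kept
#'   as metadata only.
#' @return An object of class `coe_ensemble`.
#' @export
ensemble <- function(coords, topology, frame_stride = NULL) {
  stopifnot(inherits(topology, "coe_topology"))
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    stop("coords must be a frames x atoms x 3 array")
  }
  if (dim(coords)[2] != n_atoms(topology)) {
    stop("coords atom count (", dim(coords)[2],
         ") does not match topology (", n_atoms(topology), ")")
  }
  if (dim(coords)[1] < 1L) stop("ensemble must contain at least one frame")
  if (any(!is.finite(coords))) stop("all coordinates must be finite")
  structure(
    list(coords = coords, topology = topology, frame_stride = frame_stride),
    class = "coe_ensemble"
  )
}

#' @rdname n_atoms
#' @export
n_frames <- function(x) UseMethod("n_frames")
#' @export
n_frames.coe_ensemble <- function(x) dim(x$coords)[1]

#' Extract one frame's coordinates
#'
#' @param ens A `coe_ensemble`.
#' @param i Frame index (1-based).
#' @return atoms x 3 numeric matrix (Angstrom).
#' @export
frame_coords <- function(ens, i) {
  stopifnot(inherits(ens, "coe_ensemble"),
            length(i) == 1L, i >= 1L, i <= n_frames(ens))
  matrix(ens$coords[i, , ], ncol = 3L,
         dimnames = list(ens$topology$atom_names, c("x", "y", "z")))
}

#' Keep a subset of frames
#'
#' @param ens A `coe_ensemble`.
#' @param frames Frame indices to keep (1-based, in order given).
#' @return A `coe_ensemble` with the selected frames.
#' @export
subset_frames <- function(ens, frames) {
  stopifnot(inherits(ens, "coe_ensemble"), length(frames) >= 1)
  frames <- as.integer(frames)
  if (any(frames < 1L | frames > n_frames(ens))) {
    stop("frame index out of range [1, ", n_frames(ens), "]")
  }
  ensemble(ens$coords[frames, , , drop = FALSE], ens$topology,
           frame_stride = ens$frame_stride)
}

#' @export
print.coe_ensemble <- function(x, ...) {
  cat("Conformer ensemble:", n_frames(x), "frames,",
      n_atoms(x), "atoms,", n_residues(x), "residues\n")
  invisible(x)
}

#' Construct a scattering profile
#'
#' @param q Strictly increasing scattering-vector grid (1/Angstrom), q >= 0.
#' @param intensity Intensities on `q` (arbitrary units).
#' @param sigma Optional positive uncertainties, same length.
#' @return An object of class `scattering_profile`.
#' @export
scattering_profile <- function(q, intensity, sigma = NULL) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  stopifnot(length(q) == length(intensity), length(q) >= 1)
  if (any(q < 0)) stop("q must be non-negative")
  if (any(diff(q) <= 0)) stop("q grid must be strictly increasing")
  if (any(!is.finite(intensity))) stop("intensities must be finite")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    stopifnot(length(sigma) == length(q))
    if (any(!is.finite(sigma)) || any(sigma <= 0)) {
      stop("sigma must be positive and finite")
    }
  }
  structure(list(q = q, intensity = intensity, sigma = sigma),
            class = "scattering_profile")
}

#' @export
print.scattering_profile <- function(x, ...) {
  cat("Scattering profile:", length(x$q), "points, q in [",
      format(min(x$q)), ",", format(max(x$q)), "] 1/Ang",
      if (is.null(x$sigma)) "(no uncertainties)" else "(with uncertainties)",
      "\n")
  invisible(x)
}
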