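## Ensemble, index-file and scattering-curve I/O.
## PDB parsing and writing are delegated to bio3d; the wrappers add the
## validation this workflow needs (identical atom lists across MODELs,
## element inference) and convert to the package containers.

#' Read a multi-MODEL PDB file as a conformer ensemble
#'
#' All MODELs must contain identical atom lists; a file without MODEL
#' records is read as a single-frame ensemble. Coordinates are kept in
#' Angstrom (PDB native). Missing element columns are inferred from atom
#' names with a warning.
#'
#' @param path Path to a PDB file.
#' @param frame_stride Optional time between frames, stored as metadata.
#' @return A [ensemble()] with frames ordered by MODEL number.
#' @export
read_pdb_ensemble <- function(path, frame_stride = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  .check_model_consistency(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type %in% c("ATOM", "HETATM")
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)

  elements <- at$elesy
  if (is.null(elements) || any(is.na(elements) | elements == "")) {
    warning("missing element column; inferring elements from atom names")
    elements <- infer_element(at$elety)
  }

  ## remap author residue numbering to a contiguous 1-based ordinal
  res_key <- paste(at$chain, at$resno, at$insert, sep = "|")
  residue_index <- match(res_key, unique(res_key))
  first_atom <- !duplicated(residue_index)
  top <- topology(atom_names = at$elety,
                  residue_index = residue_index,
                  residue_name = at$resid[first_atom],
                  elements = elements)

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n_f <- nrow(xyz)
  a <- ncol(xyz) / 3L
  coords <- array(NA_real_, dim = c(n_f, a, 3L))
  for (k in 1:3) coords[, , k] <- xyz[, seq(k, ncol(xyz), by = 3L), drop = FALSE]
  coords <- coords[, which(keep), , drop = FALSE]
  ensemble(coords, top, frame_stride = frame_stride)
}

## pre-scan the raw text so an inconsistent MODEL is reported by number
.check_model_consistency <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_no <- cumsum(rec == "MODEL ")
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM records in ", path)
  if (max(model_no) <= 1L) return(invisible(TRUE))
  ids <- substr(lines[is_atom], 13, 27)          # name+altloc+res+chain+resno
  per_model <- split(ids, model_no[is_atom])
  per_model <- per_model[names(per_model) != "0"]
  ref <- per_model[[1]]
  for (m in names(per_model)) {
    if (!identical(per_model[[m]], ref)) {
      stop("MODEL ", m, " atom list differs from MODEL ",
           names(per_model)[1], " (", length(per_model[[m]]), " vs ",
           length(ref), " atoms or different identities)")
    }
  }
  invisible(TRUE)
}

#' Write a conformer ensemble as a multi-MODEL PDB file
#'
#' @param ens A [ensemble()].
#' @param path Output path.
#' @param frame_indices Optional 1-based frame subset (order preserved);
#'   must be non-empty and within range.
#' @export
write_pdb_ensemble <- function(ens, path, frame_indices = NULL) {
  stopifnot(inherits(ens, "coe_ensemble"))
  if (is.null(frame_indices)) frame_indices <- seq_len(n_frames(ens))
  if (length(frame_indices) == 0L) stop("frame_indices must be non-empty")
  if (any(frame_indices < 1L | frame_indices > n_frames(ens))) {
    stop("frame index out of range [1, ", n_frames(ens), "]")
  }
  top <- ens$topology
  a <- n_atoms(ens)
  xyz <- matrix(NA_real_, nrow = length(frame_indices), ncol = 3L * a)
  for (k in 1:3) xyz[, seq(k, 3L * a, by = 3L)] <-
    ens$coords[frame_indices, , k, drop = FALSE]
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = top$residue_index,
                   resid = top$residue_name[top$residue_index],
                   eleno = seq_len(a),
                   elety = top$atom_names,
                   elesy = top$elements,
                   chain = rep("A", a))
  invisible(path)
}

#' Read an experimental small-angle scattering curve
#'
#' Whitespace-delimited numeric text with 2 (q, I) or 3 (q, I, sigma)
#' columns; lines starting with `#` are comments. q must be strictly
#' increasing.
#'
#' @param path Path to the curve file.
#' @return A [scattering_profile()]; `sigma` is `NULL` for 2-column input.
#' @export
read_saxs_curve <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no data rows in ", path)
  fields <- strsplit(lines, "[[:space:]]+")
  ncols <- unique(lengths(fields))
  if (length(ncols) != 1L) stop("inconsistent column count in ", path)
  if (ncols < 2L) stop("scattering curve needs at least 2 columns (q, I)")
  m <- matrix(as.numeric(unlist(fields)), ncol = ncols, byrow = TRUE)
  if (any(!is.finite(m[, 1:2]))) stop("non-numeric q or intensity in ", path)
  if (any(diff(m[, 1]) <= 0)) {
    stop("q values must be strictly increasing (duplicate or decreasing q)")
  }
  scattering_profile(q = m[, 1], intensity = m[, 2],
                     sigma = if (ncols >= 3L) m[, 3] else NULL)
}

#' Write a scattering profile (or P(r)) as 2/3-column text
#'
#' @param profile A [scattering_profile()].
#' @param path Output path.
#' @param header Optional comment line (written with a leading `#`).
#' @export
write_saxs_curve <- function(profile, path, header = NULL) {
  stopifnot(inherits(profile, "scattering_profile"))
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  m <- cbind(profile$q, profile$intensity)
  if (!is.null(profile$sigma)) m <- cbind(m, profile$sigma)
  writeLines(apply(m, 1L, function(r)
    paste(formatC(r, format = "g", digits = 10), collapse = " ")), con)
  invisible(path)
}

#' Write an Rg-group partition as a GROMACS-style index file
#'
#' One `[ Rg_<label> ]` section per group with whitespace-separated 1-based
#' frame numbers, at most 15 numbers per line.
#'
#' @param groups An [rg_group_set()].
#' @param path Output path.
#' @export
write_group_index <- function(groups, path) {
  stopifnot(inherits(groups, "rg_group_set"), length(groups$labels) >= 1)
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(groups$labels)) {
    writeLines(sprintf("[ Rg_%d ]", groups$labels[i]), con)
    idx <- groups$members[[i]]
    for (start in seq(1L, length(idx), by = 15L)) {
      writeLines(paste(idx[start:min(start + 14L, length(idx))],
                       collapse = " "), con)
    }
  }
  invisible(path)
}

#' Read a GROMACS-style frame index file as an Rg-group partition
#'
#' Sections must form a partition: a frame assigned to two sections is an
#' error. Section names of the form `Rg_<n>` (or bare integers) give the
#' integer-Angstrom group labels.
#'
#' @param path Path to the `.ndx`-style file.
#' @return An [rg_group_set()] (without per-frame Rg values).
#' @export
read_group_index <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != "" & !startsWith(lines, ";")]
  is_header <- grepl("^\\[.*\\]$", lines)
  if (!any(is_header)) stop("no [ section ] headers in ", path)
  section <- cumsum(is_header)
  if (any(section == 0L & !is_header)) stop("data before first section in ", path)
  headers <- trimws(gsub("^\\[|\\]$", "", lines[is_header]))
  labels <- suppressWarnings(as.integer(sub("^Rg_", "", headers)))
  if (anyNA(labels)) stop("section names must be 'Rg_<integer>' (got: ",
                          paste(headers[is.na(labels)], collapse = ", "), ")")
  members <- lapply(seq_along(headers), function(i) {
    body <- lines[section == i & !is_header]
    idx <- suppressWarnings(as.integer(unlist(strsplit(body, "[[:space:]]+"))))
    if (anyNA(idx)) stop("non-integer frame number in section ", headers[i])
    sort(idx)
  })
  all_idx <- unlist(members)
  if (anyDuplicated(all_idx)) {
    stop("frame(s) assigned to more than one section: ",
         paste(unique(all_idx[duplicated(all_idx)]), collapse = ", "),
         " (partition violated)")
  }
  o <- order(labels)
  rg_group_set(labels = labels[o], members = members[o], rg_per_frame = NULL,
               validate_partition = FALSE)
}
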