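## Element tables shared across the package.
## Masses in amu; van der Waals radii in Angstrom (Bondi).

.element_table <- data.frame(
  element = c("H", "C", "N", "O", "S"),
  mass    = c(1.008, 12.011, 14.007, 15.999, 32.06),
  vdw     = c(1.20, 1.70, 1.55, 1.52, 1.80),
  stringsAsFactors = FALSE
)

#' Supported chemical elements
#'
#' Protein input is restricted to the elements H, C, N, O and S; any other
#' element symbol is rejected at topology construction.
#'
#' @return Character vector of supported element symbols.
#' @export
supported_elements <- function() .element_table$element

element_mass <- function(element) {
  i <- match(element, .element_table$element)
  if (anyNA(i)) {
    stop("unsupported element(s): ",
         paste(unique(element[is.na(i)]), collapse = ", "))
  }
  .element_table$mass[i]
}

element_vdw_radius <- function(element) {
  i <- match(element, .element_table$element)
  if (anyNA(i)) {
    stop("unsupported element(s): ",
         paste(unique(element[is.na(i)]), collapse = ", "))
  }
  .element_table$vdw[i]
}

#' Infer the chemical element from a PDB atom name
#'
#' Uses the leading alphabetic character of the stripped atom name, after
#' discarding a leading digit (PDB hydrogen names such as "1HB"). Greek-letter
#' remoteness codes ("CA", "ND1", "OXT", ...) therefore map to their leading
#' element letter, which is correct for standard amino-acid atoms.
#'
#' @param atom_names Character vector of PDB atom names.
#' @return Character vector of element symbols.
#' @export
infer_element <- function(atom_names) {
  nm <- toupper(gsub("[^A-Z0-9]", "", toupper(atom_names)))
  nm <- sub("^[0-9]+", "", nm)
  el <- substr(nm, 1L, 1L)
  bad <- !(el %in% .element_table$element) | nm == ""
  if (any(bad)) {
    stop("cannot infer a supported element from atom name(s): ",
         paste(unique(atom_names[bad]), collapse = ", "))
  }
  el
}

## --- amino-acid tables ------------------------------------------------------

.aa1 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
          E = "GLU", Q = "GLN", G = "GLY", H = "HIS", I = "ILE",
          L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
          S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

aa_three <- function(one_letter) {
  out <- .aa1[toupper(one_letter)]
  if (anyNA(out)) {
    stop("unknown amino-acid letter(s): ",
         paste(unique(one_letter[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

aa_one <- function(three_letter) {
  m <- match(toupper(three_letter), .aa1)
  if (anyNA(m)) {
    stop("unknown residue name(s): ",
         paste(unique(three_letter[is.na(m)]), collapse = ", "))
  }
  names(.aa1)[m]
}

## Side-chain formal charges at neutral pH with histidine neutral -- the
## protonation convention used for histatin 5 throughout the package.
.side_chain_charge <- c(D = -1, E = -1, K = +1, R = +1)

#' Net formal charge of a peptide sequence
#'
#' Sums side-chain formal charges at neutral pH (Asp/Glu -1, Lys/Arg +1,
#' His neutral) plus the two charged termini (+1 amino, -1 carboxy), the
#' protonation convention used for histatin 5. For the Hst5 sequence this
#' yields +5e.
#'
#' @param sequence One-letter amino-acid string (or character vector of
#'   single letters).
#' @param charged_termini Include the +1/-1 terminal charges (default TRUE).
#' @return Integer net charge in units of e.
#' @examples
#' net_charge(hst5_sequence())  # +5
#' @export
net_charge <- function(sequence, charged_termini = TRUE) {
  aa <- split_sequence(sequence)
  ch <- .side_chain_charge[aa]
  ch[is.na(ch)] <- 0
  total <- sum(ch)
  if (charged_termini) total <- total + 1 - 1
  as.integer(total)
}

#' The histatin 5 sequence
#'
#' The 24-residue cationic salivary peptide histatin 5 (Hst5), the model
#' intrinsically disordered protein used by the synthetic generator defaults.
#'
#' @return One-letter amino-acid string of length 24.
#' @export
hst5_sequence <- function() "DSHAKRHHGYKRKFHEKHHSHRGY"

split_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) >= 1)
  if (length(sequence) == 1L && nchar(sequence) > 1L) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  aa <- toupper(sequence)
  if (!all(aa %in% names(.aa1))) {
    stop("unknown amino-acid letter(s): ",
         paste(unique(aa[!aa %in% names(.aa1)]), collapse = ", "))
  }
  aa
}

## --- maximum accessible surface areas --------------------------------------

## Theoretical maximum ASA per residue type (Angstrom^2), Tien et al. (2013).
## Used as the "expected" exposure baseline for SASA normalisation; can be
## overridden by the user in normalized_sasa().
.max_asa_tien <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLU = 223.0, GLN = 225.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0
)

#' Theoretical maximum accessible surface areas
#'
#' Per-residue theoretical maximum solvent-accessible surface areas
#' (Tien et al. 2013), in Angstrom^2, used as the expected-exposure baseline
#' when normalising observed SASA.
#'
#' @return Named numeric vector (3-letter residue codes).
#' @export
max_asa_table <- function() .max_asa_tien
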