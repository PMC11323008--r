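## Synthetic Hst5-like backbone ensembles.
##
## Frames are grown residue-by-residue with ideal peptide geometry from
## dihedrals sampled inside named Ramachandran windows, so downstream
## dihedral analysis recovers the sampling weights exactly by construction.
## A hidden two-state Markov chain (compact vs extended dihedral bias)
## gives the temporally correlated Rg needed to exercise tICA.

## ideal backbone internal coordinates (Angstrom, degrees)
.geom <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
  b_c_o = 1.231, b_n_h = 1.010, b_ca_cb = 1.530,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.8, a_c_n_h = 119.0, a_n_ca_cb = 110.6,
  omega = 180
)

#' Ramachandran region definitions
#'
#' The four secondary-structure windows used for region integration and for
#' dihedral sampling: beta-sheet (phi in [-170,-120], psi in [120,180]),
#' polyproline-II (phi [-90,-40], psi [100,180]), alpha-helix
#' (phi [-110,-40], psi [-50,10]) and left-handed helix (phi [30,70],
#' psi [10,50]). The windows are mutually disjoint; they do not tile the
#' Ramachandran plane.
#'
#' @return data.frame with columns `name`, `phi_lo`, `phi_hi`, `psi_lo`,
#'   `psi_hi` (degrees).
#' @export
ramachandran_regions <- function() {
  data.frame(
    name   = c("beta", "ppii", "alpha", "lh"),
    phi_lo = c(-170, -90, -110, 30),
    phi_hi = c(-120, -40, -40, 70),
    psi_lo = c(120, 100, -50, 10),
    psi_hi = c(180, 180, 10, 50),
    stringsAsFactors = FALSE
  )
}

.region_names <- c("beta", "ppii", "alpha", "lh", "coil")

normalize_weights <- function(w) {
  stopifnot(is.numeric(w), !is.null(names(w)))
  if (!all(names(w) %in% .region_names)) {
    stop("unknown region name(s): ",
         paste(setdiff(names(w), .region_names), collapse = ", "),
         "; valid: ", paste(.region_names, collapse = ", "))
  }
  full <- stats::setNames(numeric(length(.region_names)), .region_names)
  full[names(w)] <- w
  if (any(full < 0)) stop("region weights must be non-negative")
  s <- sum(full)
  if (abs(s - 1) > 1e-9) {
    if (s <= 0) stop("region weights must have positive sum")
    full <- full / s
  }
  full
}

#' Configuration for the synthetic ensemble generator
#'
#' Defaults emulate a histatin-5-like 24-residue disordered peptide: a
#' PPII-rich mix with enough helical/coil content to populate compact
#' states, giving a broad, smooth Rg distribution.
#'
#' @param sequence One-letter amino-acid string (default the Hst5 sequence).
#' @param n_frames Number of frames to generate.
#' @param region_weights Named probabilities over
#'   `c("beta","ppii","alpha","lh","coil")`; normalised to sum 1. Used
#'   directly when `switch_prob = 0`.
#' @param clash_cutoff Minimum allowed distance (Angstrom) between
#'   non-bonded heavy atoms more than 2 residues apart; clashing frames are
#'   resampled (up to 100 attempts).
#' @param switch_prob Per-frame probability of swapping the hidden
#'   compact/extended dihedral bias; 0 disables state switching.
#' @param seed Integer RNG seed.
#' @param compact_weights,extended_weights Region weights used by the two
#'   hidden states when `switch_prob > 0` (defaults: helix/turn-rich vs
#'   beta/PPII-rich).
#' @param with_cb Add CB pseudo-atoms to non-glycine residues.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(sequence = hst5_sequence(),
                             n_frames = 1000,
                             region_weights = c(beta = 0.20, ppii = 0.30,
                                                alpha = 0.15, lh = 0.05,
                                                coil = 0.30),
                             clash_cutoff = 2.0,
                             switch_prob = 0,
                             seed = 1L,
                             compact_weights = c(beta = 0.05, ppii = 0.10,
                                                 alpha = 0.55, lh = 0.10,
                                                 coil = 0.20),
                             extended_weights = c(beta = 0.30, ppii = 0.50,
                                                  alpha = 0.03, lh = 0.02,
                                                  coil = 0.15),
                             with_cb = FALSE) {
  aa <- split_sequence(sequence)
  stopifnot(n_frames >= 1, clash_cutoff > 0,
            switch_prob >= 0, switch_prob <= 1)
  structure(
    list(sequence = paste(aa, collapse = ""),
         n_frames = as.integer(n_frames),
         region_weights = normalize_weights(region_weights),
         clash_cutoff = clash_cutoff,
         switch_prob = switch_prob,
         seed = as.integer(seed),
         compact_weights = normalize_weights(compact_weights),
         extended_weights = normalize_weights(extended_weights),
         with_cb = isTRUE(with_cb)),
    class = "generator_config"
  )
}

#' Read a generator configuration from a flat key = value text file
#'
#' Recognised keys are exactly the [generator_config()] arguments; weights
#' are written as comma-separated `name:value` pairs. Unknown keys are an
#' error.
#'
#' @param path Path to the config file.
#' @return A `generator_config`.
#' @export
read_generator_config <- function(path) {
  kv <- read_keyval(path)
  known <- c("sequence", "n_frames", "region_weights", "clash_cutoff",
             "switch_prob", "seed", "compact_weights", "extended_weights",
             "with_cb")
  bad <- setdiff(names(kv), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  args <- list()
  for (k in names(kv)) {
    v <- kv[[k]]
    args[[k]] <- switch(k,
      sequence = v,
      n_frames = as.integer(v),
      clash_cutoff = as.numeric(v),
      switch_prob = as.numeric(v),
      seed = as.integer(v),
      with_cb = as.logical(v),
      parse_weights(v))
  }
  do.call(generator_config, args)
}

parse_weights <- function(s) {
  parts <- strsplit(strsplit(s, ",")[[1]], ":")
  stats::setNames(vapply(parts, function(p) as.numeric(trimws(p[2])),
                         numeric(1)),
                  vapply(parts, function(p) trimws(p[1]), character(1)))
}

read_keyval <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0)) stop("malformed line (no '='): ", lines[eq < 0][1])
  stats::setNames(as.list(trimws(substring(lines, eq + 1))),
                  trimws(substring(lines, 1, eq - 1)))
}

## draw one (phi, psi) uniformly inside a named region; coil = uniform over
## the complement of the four windows (rejection sampling)
draw_region_angles <- function(region) {
  reg <- ramachandran_regions()
  if (region == "coil") {
    repeat {
      phi <- stats::runif(1, -180, 180)
      psi <- stats::runif(1, -180, 180)
      inside <- any(phi >= reg$phi_lo & phi < reg$phi_hi &
                    psi >= reg$psi_lo & psi < reg$psi_hi)
      if (!inside) return(c(phi, psi))
    }
  }
  r <- reg[reg$name == region, ]
  c(stats::runif(1, r$phi_lo, r$phi_hi), stats::runif(1, r$psi_lo, r$psi_hi))
}

#' Sample one frame's backbone dihedrals
#'
#' Each residue independently draws a region label from `weights` (default
#' the config's `region_weights`) and a (phi, psi) pair uniformly inside
#' that region's Ramachandran window; coil draws uniformly over the
#' complement of the four windows. Uses R's current RNG stream.
#'
#' @param config A [generator_config()].
#' @param weights Optional named region weights overriding the config.
#' @return List with numeric vectors `phi`, `psi` (degrees, one per
#'   residue) and character vector `region`.
#' @export
sample_dihedrals <- function(config, weights = NULL) {
  stopifnot(inherits(config, "generator_config"))
  w <- if (is.null(weights)) config$region_weights else normalize_weights(weights)
  n <- nchar(config$sequence)
  region <- sample(.region_names, n, replace = TRUE, prob = w)
  ang <- vapply(region, draw_region_angles, numeric(2))
  list(phi = unname(ang[1, ]), psi = unname(ang[2, ]), region = region)
}

#' Build one backbone frame from dihedrals with ideal geometry
#'
#' Grows an N, CA, C, O, H (optionally CB) chain with ideal bond lengths
#' and angles, trans peptide bonds (omega = 180 deg), and the supplied
#' phi/psi. Recomputing dihedrals from the built frame reproduces the
#' inputs to numerical precision.
#'
#' @param sequence One-letter amino-acid string.
#' @param phi,psi Dihedrals in degrees, one per residue (`phi[1]` and the
#'   terminal-oxygen use of `psi[n]` follow the chain-growth convention;
#'   `phi[1]` is ignored).
#' @param with_cb Add CB pseudo-atoms to non-glycine residues.
#' @return List with `coords` (atoms x 3 matrix, Angstrom) and `topology`.
#' @export
build_backbone <- function(sequence, phi, psi, with_cb = FALSE) {
  aa <- split_sequence(sequence)
  n <- length(aa)
  stopifnot(length(phi) == n, length(psi) == n, n >= 2)
  g <- .geom
  N <- CA <- C <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  ## C1 sits in the xy-plane at the ideal N-CA-C angle
  a1 <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(a1), sin(a1), 0)
  for (i in 2:n) {
    N[i, ]  <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                          g$b_c_n, g$a_ca_c_n, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          g$b_n_ca, g$a_c_n_ca, g$omega)
    C[i, ]  <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                          g$b_ca_c, g$a_n_ca_c, phi[i])
  }
  O <- H <- matrix(NA_real_, n, 3)
  for (i in 1:n) {
    psi_eff <- if (i < n) psi[i] else if (is.finite(psi[n])) psi[n] else 180
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         g$b_c_o, g$a_ca_c_o, wrap_angle(psi_eff + 180))
    if (i == 1) {
      H[i, ] <- place_atom(C[1, ], CA[1, ], N[1, ], g$b_n_h, 118, 180)
    } else {
      H[i, ] <- place_atom(O[i - 1, ], C[i - 1, ], N[i, ],
                           g$b_n_h, g$a_c_n_h, 180)
    }
  }
  names_per_res <- list()
  coords <- list()
  for (i in 1:n) {
    nm <- c("N", "H", "CA", "C", "O")
    xyz <- rbind(N[i, ], H[i, ], CA[i, ], C[i, ], O[i, ])
    if (with_cb && aa[i] != "G") {
      cb <- place_atom(C[i, ], N[i, ], CA[i, ], g$b_ca_cb, g$a_n_ca_cb, -122)
      nm <- c(nm, "CB")
      xyz <- rbind(xyz, cb)
    }
    names_per_res[[i]] <- nm
    coords[[i]] <- xyz
  }
  atom_names <- unlist(names_per_res)
  residue_index <- rep(seq_len(n), lengths(names_per_res))
  elements <- substr(atom_names, 1, 1)
  top <- topology(atom_names = atom_names, residue_index = residue_index,
                  residue_name = aa_three(aa), elements = elements)
  list(coords = do.call(rbind, coords), topology = top)
}

wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  ifelse(a <= -180, a + 360, a)
}

## TRUE when some heavy-atom pair separated by > 2 residues is closer than
## cutoff
has_clash <- function(coords, top, cutoff) {
  heavy <- top$elements != "H"
  xyz <- coords[heavy, , drop = FALSE]
  res <- top$residue_index[heavy]
  d <- as.matrix(stats::dist(xyz))
  sep <- abs(outer(res, res, "-"))
  any(d[sep > 2] < cutoff)
}

#' Generate a synthetic conformer ensemble
#'
#' Frames are drawn by [sample_dihedrals()] + [build_backbone()]; frames
#' with a steric clash (non-bonded heavy atoms more than 2 residues apart
#' closer than `clash_cutoff`) are resampled up to 100 times, then accepted
#' with a warning. When `switch_prob > 0` a hidden two-state Markov chain
#' alternates between compact-biased and extended-biased region weights,
#' producing temporally correlated Rg; the realised state path is attached
#' as attribute `hidden_states` and the per-frame sampled region labels as
#' attribute `sampled_regions`.
#'
#' @param config A [generator_config()].
#' @return A [ensemble()] of `n_frames` frames.
#' @export
generate_ensemble <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_local_seed(config$seed, {
    n <- config$n_frames
    two_state <- config$switch_prob > 0
    states <- integer(n)
    if (two_state) {
      states[1] <- sample(1:2, 1)
      if (n > 1) {
        flips <- stats::runif(n - 1) < config$switch_prob
        for (t in 2:n) states[t] <- if (flips[t - 1]) 3L - states[t - 1] else states[t - 1]
      }
    } else {
      states[] <- 0L
    }
    proto <- build_backbone(config$sequence, rep(180, nchar(config$sequence)),
                            rep(180, nchar(config$sequence)),
                            with_cb = config$with_cb)
    top <- proto$topology
    coords <- array(NA_real_, dim = c(n, n_atoms(top), 3L))
    regions <- matrix(NA_character_, n, nchar(config$sequence))
    for (t in seq_len(n)) {
      w <- switch(states[t] + 1L,
                  config$region_weights,       # single-state
                  config$compact_weights,
                  config$extended_weights)
      ok <- FALSE
      for (attempt in 1:100) {
        dh <- sample_dihedrals(config, weights = w)
        fr <- build_backbone(config$sequence, dh$phi, dh$psi,
                             with_cb = config$with_cb)
        if (!has_clash(fr$coords, top, config$clash_cutoff)) { ok <- TRUE; break }
      }
      if (!ok) warning("frame ", t, ": no clash-free conformer in 100 ",
                       "attempts; accepting last sample")
      coords[t, , ] <- fr$coords
      regions[t, ] <- dh$region
    }
    ens <- ensemble(coords, top)
    attr(ens, "hidden_states") <- if (two_state) states else NULL
    attr(ens, "sampled_regions") <- regions
    ens
  })
}

## evaluate expr with a temporarily seeded RNG, restoring global state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
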