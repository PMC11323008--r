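# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# wrap a single built frame as a 1-frame ensemble
one_frame_ensemble <- function(frame) {
  ensemble(array(frame$coords, c(1, nrow(frame$coords), 3)), frame$topology)
}

helix_ensemble <- function(n = 12) {
  fr <- build_backbone(paste(rep("A", n), collapse = ""),
                       rep(-57, n), rep(-47, n))
  one_frame_ensemble(fr)
}

# small mixed-weight Hst5-like ensemble reused across tests
mixed_ensemble <- function() {
  cached("mixed60", function() {
    generate_ensemble(generator_config(n_frames = 60, seed = 101))
  })
}

compact_weights_fixture <- c(alpha = 0.55, lh = 0.10, coil = 0.35)
extended_weights_fixture <- c(beta = 0.30, ppii = 0.50, coil = 0.20)

compact_ensemble <- function() {
  cached("compact30", function() {
    generate_ensemble(generator_config(
      n_frames = 30, seed = 103, region_weights = compact_weights_fixture))
  })
}

extended_ensemble <- function() {
  cached("extended30", function() {
    generate_ensemble(generator_config(
      n_frames = 30, seed = 103, region_weights = extended_weights_fixture))
  })
}

# whole ensemble as a single Rg group (label = rounded mean Rg)
as_single_group <- function(ens) {
  rg <- ensemble_rg(ens)
  rg_group_set(labels = max(1L, round(mean(rg))),
               members = list(seq_len(n_frames(ens))), rg_per_frame = rg)
}

# minimal custom topology from element symbols only
element_topology <- function(elements, residue_index = NULL,
                             residue_name = NULL, vdw_radius = NULL) {
  n <- length(elements)
  if (is.null(residue_index)) residue_index <- rep(1L, n)
  if (is.null(residue_name)) {
    residue_name <- rep("ALA", max(residue_index))
  }
  topology(atom_names = elements, residue_index = residue_index,
           residue_name = residue_name, elements = elements,
           vdw_radius = vdw_radius)
}
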