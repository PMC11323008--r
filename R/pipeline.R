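## End-to-end orchestration: ensemble (or generator) -> Rg partition ->
## per-group analyses -> TSV outputs + checksummed manifest.

.all_analyses <- c("rg_histogram", "index", "profiles", "pr", "kratky",
                   "sasa", "hbond", "contact", "rmsf", "cluster", "tica",
                   "ramachandran", "dssp")

.default_params <- list(
  q_max = 0.5, n_q = 101, pr_bin_width = 1,
  sasa_probe = 1.4, sasa_points = 240,
  hbond_dist = 3.5, hbond_angle = 30,
  contact_mode = "min-atom",
  rmsd_cutoff = 7,
  tica_lag = 10, tica_components = 2, landscape_bins = 60,
  rama_bin_width = 2,
  min_group_size = 2
)

#' Configuration for a decomposition run
#'
#' @param input Path to a multi-MODEL PDB ensemble, or `NULL` when
#'   `generator` is given.
#' @param generator A [generator_config()] (used when `input` is `NULL`).
#' @param analyses Character vector of analyses to run (subset of
#'   `rg_histogram, index, profiles, pr, kratky, sasa, hbond, contact,
#'   rmsf, cluster, tica, ramachandran, dssp`), or `"all"`.
#' @param group_selection `"all"`, an integer vector of Rg labels, or
#'   `list(top_k = n)` for the n most occupied groups.
#' @param params Named list of per-analysis parameter overrides; unknown
#'   names are rejected.
#' @param seed Integer seed recorded in the manifest and used for any
#'   stochastic stage.
#' @param output_dir Directory for outputs (created if needed).
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL, generator = NULL,
                       analyses = "all", group_selection = "all",
                       params = list(), seed = 1L, output_dir) {
  if (is.null(input) && is.null(generator)) {
    stop("either an input ensemble path or a generator config is required")
  }
  if (identical(analyses, "all")) analyses <- .all_analyses
  bad <- setdiff(analyses, .all_analyses)
  if (length(bad)) {
    stop("unknown analysis key(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(.all_analyses, collapse = ", "))
  }
  badp <- setdiff(names(params), names(.default_params))
  if (length(badp)) {
    stop("unknown parameter(s): ", paste(badp, collapse = ", "),
         "; valid: ", paste(names(.default_params), collapse = ", "))
  }
  p <- utils::modifyList(.default_params, params)
  structure(list(input = input, generator = generator, analyses = analyses,
                 group_selection = group_selection, params = p,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

write_tsv <- function(df, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    df <- cbind(stats::setNames(data.frame(rownames(df),
                                           stringsAsFactors = FALSE),
                                rownames_as),
                as.data.frame(df, stringsAsFactors = FALSE))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_matrix_tsv <- function(m, path, rownames_as = "row") {
  write_tsv(as.data.frame(m), path, rownames_as = rownames_as)
}

select_groups <- function(groups, selection) {
  if (identical(selection, "all")) return(groups$labels)
  if (is.list(selection) && !is.null(selection$top_k)) {
    sizes <- lengths(groups$members)
    k <- min(selection$top_k, length(sizes))
    return(sort(groups$labels[order(-sizes)][seq_len(k)]))
  }
  labs <- as.integer(selection)
  missing <- setdiff(labs, groups$labels)
  if (length(missing)) {
    stop("requested Rg group(s) absent: ", paste(missing, collapse = ", "),
         "; available: ", paste(groups$labels, collapse = ", "))
  }
  labs
}

#' Run the full decomposition workflow
#'
#' Loads or generates the ensemble, partitions it into Rg groups, runs the
#' selected per-group analyses, writes every result as TSV/text under
#' `output_dir`, and returns (and writes) a manifest recording inputs,
#' parameters, seed and an md5 checksum per produced file. Identical
#' config and seed reproduce identical checksums. Analyses that need at
#' least 2 frames per group skip under-sized groups with a warning rather
#' than failing the run.
#'
#' @param config A [run_config()].
#' @param verbose Log per-stage progress to stderr.
#' @return The manifest, invisibly: list with `files` (data.frame of
#'   `file`, `md5`), `seed`, `params`, `group_labels`.
#' @export
run_decomposition <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  p <- config$params
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[coedecomp] ", ...)

  if (!is.null(config$input)) {
    say("reading ensemble from ", config$input)
    ens <- read_pdb_ensemble(config$input)
    input_desc <- config$input
  } else {
    gen <- config$generator
    gen$seed <- config$seed
    say("generating synthetic ensemble (", gen$n_frames, " frames)")
    ens <- generate_ensemble(gen)
    input_desc <- paste0("synthetic:", gen$sequence, ":n=", gen$n_frames)
  }

  say("assigning Rg groups")
  groups <- assign_rg_groups(ens)
  labels <- select_groups(groups, config$group_selection)
  big_enough <- labels[lengths(groups$members)[match(labels, groups$labels)] >=
                         p$min_group_size]
  q_grid <- seq(0, p$q_max, length.out = p$n_q)
  out <- character(0)
  path <- function(...) file.path(config$output_dir, paste0(...))
  an <- config$analyses

  if ("rg_histogram" %in% an) {
    out <- c(out, write_tsv(group_histogram(groups), path("rg_histogram.tsv")))
    out <- c(out, write_tsv(
      data.frame(frame = seq_along(groups$rg_per_frame),
                 rg = groups$rg_per_frame),
      path("rg_per_frame.tsv")))
  }
  if ("index" %in% an) {
    out <- c(out, write_group_index(groups, path("rg_groups.ndx")))
  }
  if ("profiles" %in% an) {
    say("scattering profiles (global + ", length(labels), " groups)")
    glob <- average_profile(ens, q_grid = q_grid)
    out <- c(out, write_saxs_curve(glob, path("profile_global.dat"),
                                   header = "q I(q)  global average"))
    for (lab in labels) {
      prof <- average_profile(ens, group_frames(groups, lab), q_grid = q_grid)
      out <- c(out, write_saxs_curve(prof, path("profile_rg", lab, ".dat"),
                                     header = paste("q I(q)  Rg group", lab)))
      if ("kratky" %in% an) {
        out <- c(out, write_tsv(kratky_transform(prof),
                                path("kratky_rg", lab, ".tsv")))
      }
    }
    if ("kratky" %in% an) {
      out <- c(out, write_tsv(kratky_transform(glob),
                              path("kratky_global.tsv")))
    }
  }
  if ("pr" %in% an) {
    say("pair-distance distributions")
    for (lab in labels) {
      pr <- pair_distance_distribution(ens, group_frames(groups, lab),
                                       bin_width = p$pr_bin_width)
      out <- c(out, write_tsv(
        data.frame(r = pr$r, p = pr$p),
        path("pr_rg", lab, ".tsv")))
    }
  }
  if ("sasa" %in% an) {
    say("SASA per residue and group")
    sasa <- sasa_by_group(ens, groups, labels,
                          probe_radius = p$sasa_probe,
                          n_sphere_points = p$sasa_points)
    out <- c(out, write_matrix_tsv(sasa$values, path("sasa_raw.tsv"),
                                   "residue"))
    norm <- normalized_sasa(sasa, ens$topology)
    out <- c(out, write_matrix_tsv(norm$values, path("sasa_normalized.tsv"),
                                   "residue"))
    out <- c(out, write_tsv(
      data.frame(residue = norm$residue_labels,
                 variance = norm$variance[, 1]),
      path("sasa_normalized_variance.tsv")))
  }
  if ("hbond" %in% an) {
    say("hydrogen-bond maps")
    hb <- hbond_map(ens, groups, labels,
                    d_cutoff = p$hbond_dist, angle_cutoff = p$hbond_angle)
    for (lab in names(hb$maps)) {
      out <- c(out, write_matrix_tsv(hb$maps[[lab]],
                                     path("hbond_map_rg", lab, ".tsv"),
                                     "residue"))
    }
    out <- c(out, write_tsv(hb$pairs, path("hbond_pairs.tsv")))
  }
  if ("contact" %in% an) {
    say("contact maps")
    cm <- residue_distance_map(ens, groups, labels, mode = p$contact_mode)
    for (lab in names(cm)) {
      out <- c(out, write_matrix_tsv(cm[[lab]],
                                     path("contact_map_rg", lab, ".tsv"),
                                     "residue"))
    }
  }
  if ("rmsf" %in% an) {
    rmsf_labels <- intersect(labels, big_enough)
    skipped <- setdiff(labels, rmsf_labels)
    if (length(skipped)) {
      warning("RMSF skipped for single-frame group(s): ",
              paste(skipped, collapse = ", "))
    }
    if (length(rmsf_labels)) {
      say("RMSF for ", length(rmsf_labels), " groups")
      rmsf <- rmsf_per_group(ens, groups, rmsf_labels)
      out <- c(out, write_matrix_tsv(rmsf$values, path("rmsf.tsv"),
                                     "residue"))
    }
  }
  if ("cluster" %in% an) {
    say("GROMOS clustering per group")
    rows <- list()
    for (lab in labels) {
      cl <- gromos_cluster(ens, group_frames(groups, lab),
                           rmsd_cutoff = p$rmsd_cutoff)
      cl$group <- lab
      rows[[as.character(lab)]] <- cl
    }
    out <- c(out, write_tsv(do.call(rbind, rows), path("clusters.tsv")))
  }
  if ("tica" %in% an) {
    tica_labels <- labels[lengths(groups$members)[match(labels, groups$labels)] >
                            p$tica_lag + p$tica_components]
    skipped <- setdiff(labels, tica_labels)
    if (length(skipped)) {
      warning("tICA skipped for group(s) with too few frames: ",
              paste(skipped, collapse = ", "))
    }
    feats <- featurize(ens)
    for (lab in tica_labels) {
      frames <- group_frames(groups, lab)
      model <- tica_fit(feats[frames, , drop = FALSE], lag = p$tica_lag,
                        n_components = p$tica_components)
      proj <- tica_transform(model, feats[frames, , drop = FALSE])
      fe <- tryCatch(
        free_energy_landscape(proj[, 1:2, drop = FALSE],
                              n_bins = p$landscape_bins),
        error = function(e) {
          warning("landscape skipped for group ", lab, ": ",
                  conditionMessage(e))
          NULL
        })
      if (!is.null(fe)) {
        grid <- expand.grid(x_bin = seq_len(p$landscape_bins),
                            y_bin = seq_len(p$landscape_bins))
        grid$free_energy_kT <- as.vector(fe$free_energy)
        grid$masked <- as.integer(is.na(grid$free_energy_kT))
        out <- c(out, write_tsv(grid, path("landscape_rg", lab, ".tsv")))
      }
      out <- c(out, write_tsv(
        data.frame(frame = frames, tic1 = proj[, 1],
                   tic2 = if (ncol(proj) > 1) proj[, 2] else NA_real_),
        path("tica_projection_rg", lab, ".tsv")))
      out <- c(out, write_tsv(
        data.frame(key = c("lag", "epsilon",
                           paste0("eigenvalue_", seq_along(model$eigenvalues))),
                   value = c(model$lag, model$epsilon, model$eigenvalues)),
        path("tica_model_rg", lab, ".txt")))
    }
  }
  if ("ramachandran" %in% an) {
    say("Ramachandran region integration")
    rf <- group_region_fractions(ens, groups, labels)
    out <- c(out, write_matrix_tsv(rf, path("region_fractions.tsv"),
                                   "region"))
    dh <- backbone_dihedrals(ens)
    hist2d <- ramachandran_histogram(dh, bin_width = p$rama_bin_width)
    out <- c(out, write_matrix_tsv(hist2d$counts,
                                   path("ramachandran_histogram.tsv"),
                                   "phi_bin"))
  }
  if ("dssp" %in% an) {
    say("secondary-structure fractions")
    ss <- group_ss_fractions(ens, groups, labels)
    out <- c(out, write_matrix_tsv(ss, path("ss_fractions.tsv"), "label"))
  }

  files <- data.frame(file = basename(out),
                      md5 = unname(tools::md5sum(out)),
                      stringsAsFactors = FALSE)
  files <- files[order(files$file), ]
  rownames(files) <- NULL
  manifest <- list(
    package = "coedecomp",
    version = as.character(utils::packageVersion("coedecomp")),
    input = input_desc,
    seed = config$seed,
    analyses = config$analyses,
    group_labels = labels,
    params = p,
    files = files
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("wrote ", nrow(files), " files + manifest")
  invisible(manifest)
}

#' Compare a run's average profiles with an experimental curve
#'
#' Reads the manifest of a finished [run_decomposition()] run, loads the
#' global and per-group average scattering profiles it lists, and reports
#' the reduced chi-squared of each against the experimental curve.
#'
#' @param manifest_path Path to a run's `manifest.json` (or its directory).
#' @param curve_path Experimental SAXS curve readable by
#'   [read_saxs_curve()].
#' @param fit_scale Fit the scale factor in [chi_squared()] (default TRUE).
#' @return data.frame with columns `profile`, `chi2`, `scale`, `n`.
#' @export
compare_to_experiment <- function(manifest_path, curve_path,
                                  fit_scale = TRUE) {
  if (dir.exists(manifest_path)) {
    manifest_path <- file.path(manifest_path, "manifest.json")
  }
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  run_dir <- dirname(manifest_path)
  prof_files <- man$files$file[grepl("^profile_.*\\.dat$", man$files$file)]
  if (!"profile_global.dat" %in% prof_files) {
    stop("manifest lists no global average profile; run the 'profiles' ",
         "analysis first")
  }
  exp_curve <- read_saxs_curve(curve_path)
  rows <- lapply(sort(prof_files), function(fn) {
    sim <- read_saxs_curve(file.path(run_dir, fn))
    cs <- chi_squared(exp_curve, sim, fit_scale = fit_scale)
    data.frame(profile = sub("^profile_(.*)\\.dat$", "\\1", fn),
               chi2 = cs$chi2, scale = cs$scale, n = cs$n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
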