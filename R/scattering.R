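## Debye-formula scattering, pair-distance distributions and chi-squared
## comparison against experimental curves. Vacuum form factors, hydration
## contrast 0, no excluded-volume correction.

## Cromer-Mann 4-Gaussian coefficients (International Tables for
## Crystallography, vol. C): f(q) = sum_k a_k exp(-b_k (q/4pi)^2) + c
.cromer_mann <- list(
  H = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
           b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305),
  C = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
           b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
           b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
           b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  S = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
           b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900)
)

#' X-ray atomic form factor
#'
#' Cromer-Mann 4-term Gaussian expansion; `form_factor(el, 0)` equals the
#' element's electron count to within 0.1.
#'
#' @param element Element symbol (H, C, N, O or S).
#' @param q Scattering vector values (1/Angstrom).
#' @return Dimensionless amplitude, same length as `q`.
#' @export
form_factor <- function(element, q) {
  cm <- .cromer_mann[[element]]
  if (is.null(cm)) stop("unsupported element: ", element)
  s2 <- (q / (4 * pi))^2
  out <- rep(cm$c, length(q))
  for (k in 1:4) out <- out + cm$a[k] * exp(-cm$b[k] * s2)
  out
}

sinc <- function(x) ifelse(x == 0, 1, sin(x) / x)

#' Default scattering-vector grid
#'
#' @param q_max Upper limit (1/Angstrom, default 0.5).
#' @param n Number of points (default 101, from 0).
#' @return Numeric grid.
#' @export
default_q_grid <- function(q_max = 0.5, n = 101) seq(0, q_max, length.out = n)

#' Debye-formula scattering profile of one frame
#'
#' I(q) = sum_i sum_j f_i(q) f_j(q) sinc(q r_ij), in vacuo (hydration-shell
#' contrast 0, no excluded-volume term). `method = "direct"` evaluates the
#' exact double sum; `method = "binned"` aggregates pair distances per
#' element pair on a fine grid (`bin_width`) before the sinc sum, which is
#' equivalent to within the binning resolution and much faster for large
#' atom counts.
#'
#' @param coords atoms x 3 matrix (Angstrom).
#' @param top A [topology()] (for elements), or `NULL` with
#'   `amplitudes` supplied.
#' @param q_grid Scattering-vector grid (1/Angstrom).
#' @param method "binned" (default) or "direct".
#' @param bin_width Distance resolution of the binned path (Angstrom).
#' @param amplitudes Optional per-atom constant amplitudes replacing the
#'   q-dependent form factors (e.g. all 1, or `f(0)` values for
#'   form-factor-at-zero weighting).
#' @return A [scattering_profile()].
#' @export
debye_profile <- function(coords, top = NULL, q_grid = default_q_grid(),
                          method = c("binned", "direct"), bin_width = 0.01,
                          amplitudes = NULL) {
  method <- match.arg(method)
  coords <- as.matrix(coords)
  a <- nrow(coords)
  stopifnot(a >= 1, ncol(coords) == 3)
  if (is.null(amplitudes)) {
    if (is.null(top)) stop("need a topology or explicit amplitudes")
    f <- vapply(supported_elements(), form_factor, numeric(length(q_grid)),
                q = q_grid)
    if (length(q_grid) == 1L) f <- matrix(f, nrow = 1)
    el_idx <- match(top$elements, supported_elements())
    fq <- f[, el_idx, drop = FALSE]              # q x atoms
  } else {
    stopifnot(length(amplitudes) == a)
    fq <- matrix(rep(amplitudes, each = length(q_grid)), nrow = length(q_grid))
  }
  self_term <- rowSums(fq^2)
  if (a == 1L) return(scattering_profile(q_grid, self_term))

  d <- stats::dist(coords)
  ij <- utils::combn(a, 2L)
  if (method == "direct") {
    cross <- numeric(length(q_grid))
    fpair <- fq[, ij[1, ], drop = FALSE] * fq[, ij[2, ], drop = FALSE]
    for (k in seq_along(q_grid)) {
      cross[k] <- 2 * sum(fpair[k, ] * sinc(q_grid[k] * d))
    }
  } else {
    ## aggregate pairs by (element-pair class, distance bin)
    pair_class <- if (is.null(amplitudes)) {
      e1 <- pmin(top$elements[ij[1, ]], top$elements[ij[2, ]])
      e2 <- pmax(top$elements[ij[1, ]], top$elements[ij[2, ]])
      paste(e1, e2)
    } else {
      sprintf("%.9g*%.9g",
              pmin(amplitudes[ij[1, ]], amplitudes[ij[2, ]]),
              pmax(amplitudes[ij[1, ]], amplitudes[ij[2, ]]))
    }
    uc <- unique(pair_class)
    cls_idx <- match(pair_class, uc)
    bin_idx <- as.integer(round(d / bin_width))
    stride <- max(bin_idx) + 1L
    key <- (cls_idx - 1L) * stride + bin_idx
    agg <- rowsum(rep(1, length(d)), key)
    ukey <- as.integer(rownames(agg))
    agg_cls <- ukey %/% stride + 1L
    agg_r <- (ukey %% stride) * bin_width
    ## amplitude product per class on each q
    first_pair <- match(uc, pair_class)
    fprod_class <- matrix(NA_real_, length(q_grid), length(uc))
    for (m in seq_along(uc)) {
      p <- first_pair[m]
      fprod_class[, m] <- fq[, ij[1, p]] * fq[, ij[2, p]]
    }
    cross <- numeric(length(q_grid))
    for (k in seq_along(q_grid)) {
      cross[k] <- 2 * sum(fprod_class[k, agg_cls] * agg[, 1] *
                            sinc(q_grid[k] * agg_r))
    }
  }
  scattering_profile(q_grid, self_term + cross)
}

#' Average scattering profile over frames
#'
#' Unweighted arithmetic mean of per-frame Debye profiles on a shared grid.
#'
#' @param ens A [ensemble()].
#' @param frame_indices Non-empty 1-based frame indices.
#' @param q_grid Scattering-vector grid.
#' @param ... Passed to [debye_profile()].
#' @return A [scattering_profile()].
#' @export
average_profile <- function(ens, frame_indices = seq_len(n_frames(ens)),
                            q_grid = default_q_grid(), ...) {
  stopifnot(inherits(ens, "coe_ensemble"))
  if (length(frame_indices) == 0L) stop("frame_indices must be non-empty")
  acc <- numeric(length(q_grid))
  for (i in frame_indices) {
    acc <- acc + debye_profile(frame_coords(ens, i), ens$topology,
                               q_grid, ...)$intensity
  }
  scattering_profile(q_grid, acc / length(frame_indices))
}

#' Kratky transform of a scattering profile
#'
#' @param profile A [scattering_profile()].
#' @param normalize Divide by I(0) (profile must include q = 0 or an
#'   extrapolatable low-q point; the first intensity is used).
#' @return data.frame with columns `q` and `qsq_I` (q^2 I(q)).
#' @export
kratky_transform <- function(profile, normalize = FALSE) {
  stopifnot(inherits(profile, "scattering_profile"))
  v <- profile$q^2 * profile$intensity
  if (normalize) v <- v / profile$intensity[1]
  data.frame(q = profile$q, qsq_I = v)
}

#' Guinier Rg estimate from the low-q region
#'
#' Fits ln I(q) vs q^2 over points with q * rg_guess < `q_rg_max` and
#' returns sqrt(-3 * slope).
#'
#' @param profile A [scattering_profile()].
#' @param rg_guess Initial Rg used to delimit the Guinier window (Angstrom).
#' @param q_rg_max Window limit (default 1.0).
#' @return Estimated Rg (Angstrom).
#' @export
guinier_rg <- function(profile, rg_guess, q_rg_max = 1.0) {
  keep <- profile$q > 0 & profile$q * rg_guess < q_rg_max
  if (sum(keep) < 3) stop("fewer than 3 points in the Guinier window")
  fit <- stats::lm(log(profile$intensity[keep]) ~ I(profile$q[keep]^2))
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) stop("non-decreasing low-q intensity: no Guinier regime")
  sqrt(-3 * slope)
}

#' Intraparticle pair-distance distribution P(r)
#'
#' Direct histogram of all intra-frame atom-pair distances, weighted by the
#' product of the atoms' form factors at q = 0, averaged over the selected
#' frames, and normalised to unit area (sum p * dr = 1). `r_max` is the
#' largest observed pair distance.
#'
#' @param ens A [ensemble()].
#' @param frame_indices Non-empty frame subset (default all frames).
#' @param bin_width Histogram bin width (Angstrom, default 1).
#' @return An object of class `pr_distribution`: list with `r` (bin
#'   centres), `p` (density), `r_max`, `bin_width`.
#' @export
pair_distance_distribution <- function(ens,
                                       frame_indices = seq_len(n_frames(ens)),
                                       bin_width = 1) {
  stopifnot(inherits(ens, "coe_ensemble"), bin_width > 0)
  if (length(frame_indices) == 0L) stop("frame_indices must be non-empty")
  top <- ens$topology
  f0 <- form_factor_at_zero(top$elements)
  a <- n_atoms(ens)
  ij <- utils::combn(a, 2L)
  w_pair <- f0[ij[1, ]] * f0[ij[2, ]]
  r_max <- 0
  acc <- NULL
  for (i in frame_indices) {
    d <- as.vector(stats::dist(frame_coords(ens, i)))
    r_max <- max(r_max, max(d))
    bins <- floor(d / bin_width)
    h <- tapply(w_pair, bins, sum)
    hv <- numeric(max(as.integer(names(h))) + 1L)
    hv[as.integer(names(h)) + 1L] <- h
    if (is.null(acc)) acc <- hv
    else {
      n_max <- max(length(acc), length(hv))
      acc <- c(acc, numeric(n_max - length(acc))) +
        c(hv, numeric(n_max - length(hv)))
    }
  }
  p <- acc / (sum(acc) * bin_width)
  structure(list(r = (seq_along(p) - 0.5) * bin_width, p = p,
                 r_max = r_max, bin_width = bin_width),
            class = "pr_distribution")
}

form_factor_at_zero <- function(elements) {
  vapply(elements, function(e) form_factor(e, 0), numeric(1))
}

#' @export
print.pr_distribution <- function(x, ...) {
  cat("P(r):", length(x$r), "bins of", x$bin_width,
      "Ang; r_max =", format(x$r_max, digits = 4), "Ang\n")
  invisible(x)
}

#' Reconstruct I(q) from a P(r) histogram
#'
#' I(q)/I(0) = sum_r P(r) sinc(q r) dr plus the self-term share; used for
#' Fourier-consistency checks against [debye_profile()] computed with
#' q-independent amplitudes.
#'
#' @param pr A `pr_distribution`.
#' @param q_grid Scattering-vector grid.
#' @return data.frame with `q` and the normalised cross-pair intensity
#'   `I_over_I0_pairs`.
#' @export
profile_from_pr <- function(pr, q_grid = default_q_grid()) {
  stopifnot(inherits(pr, "pr_distribution"))
  v <- vapply(q_grid, function(q) sum(pr$p * sinc(q * pr$r)) * pr$bin_width,
              numeric(1))
  data.frame(q = q_grid, I_over_I0_pairs = v)
}

#' Reduced chi-squared between experimental and simulated profiles
#'
#' chi^2 = (1/N) sum_i ((E_i - c S_i) / sigma_i)^2 with the simulated curve
#' linearly interpolated onto the experimental grid. The scale factor c is
#' fitted by uncertainty-weighted least squares unless `fit_scale = FALSE`
#' (then c = 1). Missing experimental uncertainties count as sigma = 1.
#'
#' @param experimental,simulated [scattering_profile()] objects.
#' @param fit_scale Fit the multiplicative scale factor (default TRUE).
#' @return List with `chi2`, `scale`, `n`.
#' @export
chi_squared <- function(experimental, simulated, fit_scale = TRUE) {
  stopifnot(inherits(experimental, "scattering_profile"),
            inherits(simulated, "scattering_profile"))
  qe <- experimental$q
  keep <- qe >= min(simulated$q) & qe <= max(simulated$q)
  if (sum(keep) < 2L) {
    stop("experimental and simulated q ranges do not overlap (need >= 2 ",
         "common points)")
  }
  e <- experimental$intensity[keep]
  s <- stats::approx(simulated$q, simulated$intensity, xout = qe[keep])$y
  sig <- if (is.null(experimental$sigma)) rep(1, sum(keep))
         else experimental$sigma[keep]
  cfit <- if (fit_scale) sum(e * s / sig^2) / sum(s^2 / sig^2) else 1
  chi2 <- mean(((e - cfit * s) / sig)^2)
  list(chi2 = chi2, scale = cfit, n = sum(keep))
}
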