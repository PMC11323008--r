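---
title: "Methods: Rg-group decomposition of disordered-protein ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Rg-group decomposition of disordered-protein ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The decomposition model

An intrinsically disordered protein (IDP) in solution is a conformational
ensemble: a distribution over structures rather than one fold. Ensemble
observables (a SAXS curve, an average SASA, a mean contact map) are
averages over that distribution and hide its structure. `coedecomp`
decomposes the ensemble along a single, physically interpretable
coordinate — the mass-weighted radius of gyration

$$R_g = \sqrt{\frac{\sum_i m_i \lVert r_i - r_{\mathrm{com}} \rVert^2}
{\sum_i m_i}}$$

— by rounding each frame's $R_g$ (in Å) to the nearest integer and
treating each integer label as a group. Every analysis in the package is
then computed per group, so compact, coil-like and extended subpopulations
can be compared directly.

Assumptions worth stating explicitly:

* The decomposition coordinate is global size only. Two structurally
  different conformers with the same $R_g$ land in the same group; the
  per-group clustering and tICA stages exist precisely to expose such
  residual heterogeneity.
* Groups are defined by rounding half-away-from-zero. The bin *width* (1 Å)
  and the rule for ties are conventions; the package fixes them once for
  reproducibility rather than inferring intent from any particular data
  set. Groups are never dropped: sparsely occupied ones (below
  `min_occupancy`, default 0.1 % of frames) are flagged `low_sampling`
  because statistics computed from a handful of frames deserve suspicion,
  not deletion.
* $R_g$ uses all atoms, mass-weighted — the convention of standard MD
  tooling — not a Cα-only variant.

Frame indices are 1-based throughout, matching both R and the GROMACS
`.ndx` index-file dialect the package writes, so the in-memory and on-disk
numbering coincide.

## Scattering

Per-frame profiles use the Debye formula over atoms,
$I(q) = \sum_{ij} f_i(q) f_j(q)\,\mathrm{sinc}(q r_{ij})$, with 4-term
Cromer–Mann form factors for H, C, N, O, S. Profiles are in vacuo: no
hydration-shell term and no excluded-volume correction (the
hydration-contrast-zero convention). Two evaluation paths exist: an exact
$O(A^2)$ double sum, and a binned path that aggregates pair distances per
element pair on a 0.01 Å grid before the sinc sum. The binned path is the
default; it agrees with the exact sum to well under 0.1 % over the default
grid (q ∈ [0, 0.5] Å⁻¹, 101 points) and is what makes averaging over
hundreds of frames cheap. Rotation invariance is exact for the direct path
and holds to the binning resolution for the fast path.

$P(r)$ is computed directly from coordinates: a histogram of all
intra-frame atom-pair distances, weighted by the product of the atoms'
form factors at $q = 0$, averaged over the selected frames and normalised
to unit area. This is a deliberate deviation from the indirect-Fourier
route used by experimental pipelines (e.g. PRIMUS): when model coordinates
are available the distance distribution is exact, and regularised
inversion would only add machinery that cannot be validated from within.
`r_max` is reported as the largest observed pair distance, not a bin
edge. Consistency of the two representations is property-tested through
$I(q)/I(0) = \int P(r)\,\mathrm{sinc}(qr)\,dr$ (with $q$-independent
amplitudes, so only binning error enters).

The reduced discrepancy statistic is
$\chi^2 = \frac{1}{N} \sum_i \left[ (E_i - c\,S_i)/\sigma_i \right]^2$
with the simulated curve linearly interpolated onto the experimental grid.
The scale factor $c$ is fitted by uncertainty-weighted least squares by
default, because absolute SAXS intensities are rarely on a common scale;
`fit_scale = FALSE` pins $c = 1$. Missing uncertainties count as
$\sigma = 1$, which turns the statistic into a plain mean squared
residual — fine for self-comparisons, meaningless across instruments, so
supply real uncertainties when you have them.

## Surface area and contacts

SASA is Shrake–Rupley: test points on each atom's expanded sphere
($r_{vdw}$ + probe, Bondi radii, probe 1.4 Å), a point accessible iff
outside every other expanded sphere. The test points are a deterministic
golden-spiral layout, so results are exactly reproducible; the flip side
is that the point grid lives in the lab frame, and rotating a structure
changes which points are buried. Rotation invariance therefore holds to
the sampling resolution: at the default 960 points per atom, total SASA
moves by well under 1 %. Doubling the point count changes totals by less
than 1 % on a 24-residue chain, which is the convergence criterion used in
the tests; per-group summaries in the pipeline default to 240 points as a
speed/accuracy compromise you can override (`sasa_points`).

Normalised SASA subtracts a per-residue-type expected exposure (the
Tien et al. 2013 theoretical maximum-ASA table, user-overridable) from the
observed per-residue value, giving signed deviations comparable across
residue types; the variance reported with it is the across-group variance
of those deviations, which highlights residues whose exposure tracks
compaction.

Hydrogen bonds use the standard geometric criterion (donor–acceptor
distance ≤ 3.5 Å and H–donor–acceptor angle ≤ 30°), donors being N/O with
a covalently attached hydrogen (≤ 1.25 Å). Detection keeps all
inter-residue bonds; occupancy *maps* drop pairs closer than 2 in
sequence, because backbone-adjacent bonds are trivially frequent and
drown the long-range signal. Contact maps default to minimum
heavy-atom distances, with a Cα mode for backbone-only input.
The Rg–SASA kernel density uses a Gaussian product kernel with Scott's
rule bandwidths ($h_j = \hat\sigma_j n^{-1/6}$), overridable; zero
variance in either coordinate is an error rather than a silent delta
function.

## Flexibility and slow modes

RMSF superposes each group's frames onto the group mean (Cα selection),
re-averages, and iterates until the mean moves < 10⁻⁴ Å RMS (≤ 10
iterations) — the usual fixed point that removes the arbitrariness of a
single reference frame. Superposition is Kabsch via SVD with the
determinant correction, so reflections are never used; collinear
selections are rejected. Note one consequence checked in the tests: a
perturbation on one residue is partially absorbed by the fitted
translation/rotation, so its RMSF reads slightly below the injected
amplitude and its neighbours slightly above zero.

GROMOS clustering is the Daura neighbour-counting algorithm on the
pairwise superposed Cα RMSD matrix with a 7 Å (0.7 nm) default cutoff.
Ties in neighbour count break toward the lowest frame index, and final
cluster ids sort by decreasing size with ties in discovery order, making
the output deterministic and invariant (up to equal-size relabeling) under
frame reordering.

tICA estimates the symmetrised instantaneous and lagged covariances of
mean-centred features and solves
$C_\tau v = \lambda (C_0 + \varepsilon I) v$ by Cholesky whitening plus a
symmetric eigenproblem, so eigenvalues are real and components orthonormal
in the $C_0$ metric. Defaults: features are all Cα–Cα distances with
sequence separation ≥ 2 (rigid-motion invariant and well-defined for
backbone-only chains; a sin/cos dihedral mode is available), lag 10
frames, $\varepsilon = 10^{-6}\,\mathrm{tr}(C_0)/d$. The regularisation
exists for collinear features (duplicated distances in near-rigid
substructures); it leaves the leading subspace essentially untouched.
Free-energy landscapes are $-\ln$ of the 2D bin occupancy in kT, shifted
to zero at the occupied minimum, on a 60 × 60 grid spanning the 1st–99th
percentile of each component; empty bins are masked NA rather than given
a fake finite energy.

## Secondary structure

Dihedrals follow the IUPAC sign convention
(φ = C(i−1)–N–Cα–C, ψ = N–Cα–C–N(i+1)), validated against an independent
structural-bioinformatics implementation. Region integration uses four
Ramachandran windows — β-sheet φ[−170,−120] ψ[120,180], PPII φ[−90,−40]
ψ[100,180], α φ[−110,−40] ψ[−50,10], left-handed helix φ[30,70]
ψ[10,50] — with closed-low/open-high membership on each axis, so shared
printed boundaries can never double-count; the windows are checked to be
mutually disjoint and do not tile the plane, so fractions need not sum
to 1. Fractions are counted over raw (φ, ψ) points rather than histogram
bins (a histogram-based count would inherit the bin width; the raw count
is the limit of that procedure as bins shrink).

The simplified DSSP uses the Kabsch–Sander electrostatic energy
$E = 0.084 \cdot 332\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$
kcal/mol with a bond iff $E < -0.5$, identical/adjacent residues
excluded. Labels: H for residues covered by two consecutive 4-turns, E
for bridge ladders of length ≥ 2, T for turn residues not in a helix, P
for runs of ≥ 2 residues inside the PPII window with no other label, C
otherwise (priority H > E > T > P > C). The PPII class is dihedral-based
because the classic H-bond pattern logic has no PPII notion; a 2-residue
minimum run keeps isolated dihedral excursions out of the class. The full
8-class assignment (G, I, B, S) is out of scope.

## The synthetic generator

The generator emulates the statistical signatures of a short IDP ensemble
that the analyses consume, not its physics. Frames are grown
residue-by-residue with ideal peptide geometry (N–Cα 1.458 Å, Cα–C
1.525 Å, C–N 1.329 Å, C=O 1.231 Å, N–H 1.010 Å; angles 111.2°/116.2°/
121.7°; ω = 180°) from dihedrals sampled inside the named Ramachandran
windows according to `region_weights` (coil = uniform over the complement
of the four windows). Frames with non-bonded heavy atoms closer than
`clash_cutoff` (default 2.0 Å, roughly the sum of covalent radii — tight
enough to forbid overlap, loose enough that helix-rich weights still
terminate) at sequence separation > 2 are resampled up to 100 times, then
accepted with a warning so pathological weight sets cannot hang a run.
`switch_prob` turns on a hidden two-state Markov chain alternating between
helix/turn-rich ("compact") and β/PPII-rich ("extended") weights, giving
the temporally correlated size fluctuations that tICA is meant to find;
the realised state path is attached for validation. All sampling runs
under a locally seeded RNG, so the same seed yields bit-identical
coordinates without touching the caller's RNG state.

Defaults model a histatin 5-like peptide: the Hst5 sequence, a PPII-rich
mixed weight set (β 0.20, PPII 0.30, α 0.15, LH 0.05, coil 0.30) chosen so
a few hundred frames span roughly 8–17 Å in $R_g$ with a smooth unimodal
occupancy — the qualitative shape expected for a 24-residue disordered
peptide.

What the generator does *not* emulate, and hence what passing tests do
not show about real data: residues are independent given the hidden state
(no cooperative folding, no persistence length beyond the fixed geometry),
there are no side chains beyond optional Cβ pseudo-atoms (so SASA
normalisation exercises the bookkeeping, not rotamer physics), no solvent,
and clash rejection is the only interaction. Tests against it validate
algorithmic correctness and parameter recovery, not force-field-level
realism.

## Test and pipeline problem sizes

The suite runs analytic closed forms at machine precision and stochastic
checks at sizes chosen to keep the full run comfortably on one CPU: shared
60-frame mixed ensembles for invariance checks, a 460-frame ensemble
(≈ 10⁴ dihedral pairs) for region-weight recovery within 3σ binomial
error, 5 000 frames at `switch_prob` 0.01 for hidden-state recovery from
the leading tIC (> 80 % agreement), AR(1) theory at n = 20 000
(λ₁ ≈ ρ^τ = 0.729), 100 random ≤ 12-frame instances against an
independently coded clustering oracle, and a 20-seed battery of one-sided
Wilcoxon tests (α = 0.01) for the compact-vs-extended trends in r_max,
hydrogen-bond occupancy, normalised SASA vs group Rg, and turn/PPII
fractions. `scripts/acceptance.R` re-runs the headline quantities at
similar sizes from the installed package.

## Known limitations

* Scattering is in vacuo; comparisons with real SAXS curves absorb the
  missing hydration layer into the fitted scale only approximately.
* `chi_squared` with absent uncertainties weights all points equally, so
  its absolute value is not a goodness-of-fit in the statistical sense.
* The O(A²)/O(F²) algorithms (Debye, pairwise RMSD for clustering) are
  pure R and sized for peptide-scale systems (tens of residues, 10²–10⁴
  frames per call), not for hundreds of thousands of frames of a large
  protein.
* Backbone-only DSSP on synthetic chains sees few sheets (isolated chains
  rarely form ladders), so the E class is exercised mainly through its
  bridge-pattern unit logic.
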