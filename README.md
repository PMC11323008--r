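# coedecomp

Decomposition of the conformational ensemble (CoE) of an intrinsically
disordered protein (IDP) into radius-of-gyration groups, with per-group
structural characterisation.

IDPs such as the 24-residue salivary peptide histatin 5 (Hst5) do not fold
into a single structure: in solution they interconvert between compact,
coil-like and extended conformers. Solution scattering (SAXS) sees only the
ensemble average, so the individual conformer classes are hidden. This
package implements the decomposition approach: sort the frames of a
conformer ensemble by their mass-weighted radius of gyration,

&nbsp;&nbsp;&nbsp;&nbsp;*R*g = sqrt( Σᵢ mᵢ ‖rᵢ − r꜀ₒₘ‖² / Σᵢ mᵢ ),

bin them into integer-Ångström *R*g groups, and compute every observable
per group instead of per ensemble:

* **Scattering** — Debye-formula profiles *I(q) = Σᵢⱼ fᵢ(q) fⱼ(q)
  sin(qrᵢⱼ)/(qrᵢⱼ)* with Cromer–Mann atomic form factors (in vacuo,
  hydration contrast 0), Kratky transforms, Guinier *R*g, direct
  pair-distance distributions *P(r)* with *r*max, and reduced
  χ² = (1/N) Σᵢ [(Eᵢ − cSᵢ)/σᵢ]² against an experimental curve with a
  fitted scale factor *c*.
* **Surface & contacts** — Shrake–Rupley SASA per atom/residue, normalised
  SASA (observed − expected maximum exposure per residue type),
  *R*g–SASA kernel density, geometric hydrogen-bond maps (3.5 Å / 30°
  criterion) and residue–residue distance maps.
* **Flexibility** — per-group RMSF after iterative Kabsch superposition,
  GROMOS (Daura) RMSD clustering at a 7 Å cutoff, time-lagged independent
  component analysis (tICA) on sequence-separated Cα distances, and
  free-energy landscapes *F = −ln ρ* in kT over the leading tICs.
* **Secondary structure** — backbone φ/ψ dihedrals, Ramachandran 2D
  histograms and region integration (β-sheet, PPII, α-helix, left-handed
  helix windows), Kabsch–Sander hydrogen-bond energies and a simplified
  DSSP assignment {H, E, T, P, C} including a polyproline-II class.

Because public MD trajectories of this kind are not deposited, the package
ships a first-class synthetic generator: Hst5-like backbone ensembles grown
with ideal peptide geometry from dihedrals sampled inside named
Ramachandran windows, with steric-clash rejection and an optional hidden
two-state Markov chain (compact vs extended bias) that gives the temporally
correlated dynamics tICA needs. Every analysis stage is validated against
analytic closed forms, brute-force oracles, and parameter-recovery tests on
this generator.

## Worked example

```r
library(coedecomp)

cfg    <- generator_config(n_frames = 300, seed = 7)   # Hst5 defaults
ens    <- generate_ensemble(cfg)
groups <- assign_rg_groups(ens)
print(groups)
```

```
Rg decomposition: 10 groups over 300 frames
 label_A n_frames
       8       11
       9       26
      10       41
      11       51
      12       40
      13       44
      14       35
      15       27
      16       20
      17        5
```

The ensemble spans compact (8 Å) to extended (17 Å) conformers with a
smooth occupancy maximum near 11–13 Å, the shape expected for a short
disordered peptide. Per-group observables then read, for example:

```r
pr <- pair_distance_distribution(ens, groups$members[[3]])  # Rg group 10
pr
#> P(r): 38 bins of 1 Ang; r_max = 37.55 Ang

round(100 * group_region_fractions(ens, groups, labels = c(10, 14)), 1)
#>         10   14
#> beta  17.0 22.3
#> ppii  29.9 33.0
#> alpha 15.2 11.4
#> lh     6.0  4.8
```

`r_max` is the largest intramolecular distance in the group (37.6 Å for
the compact group 10 here, versus > 60 Å for extended groups), and the
region table gives the percentage of backbone (φ, ψ) pairs inside each
Ramachandran window — extended groups are richer in β/PPII, compact groups
in α, mirroring how local structure trades off with global compaction.

The whole workflow — Rg histogram, GROMACS-style `.ndx` group files,
per-group profiles, P(r), SASA, H-bond and contact maps, RMSF, clusters,
tICA landscapes, Ramachandran and DSSP tables, plus a checksummed
manifest — runs as one call:

```r
man <- run_decomposition(run_config(
  generator = generator_config(n_frames = 500, seed = 7),
  output_dir = "run1", seed = 7))
compare_to_experiment("run1", "experimental_curve.dat")  # chi^2 per profile
```

or from a shell via `inst/scripts/coe-decompose.R`
(`decompose <run.cfg>`, `generate <gen.cfg> <out.pdb>`,
`compare <run-dir> <curve.dat>`).

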