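# ubikin

Kinetics of ubiquitin discharge from E2~Ub thioester conjugates, and
geometric analysis of E2–ubiquitin coordinate ensembles.

## The problem

J2-family ubiquitin-conjugating enzymes (yeast Ubc6, human Ube2J2)
preferentially attach ubiquitin to serine and threonine hydroxyl groups
rather than lysines, forming alkali-labile oxyester linkages. Two
quantitative workflows underpin the characterization of this
chemoselectivity:

1. **Discharge (chase) kinetics.** After the E1 enzyme loads the E2 with
   ubiquitin, EDTA quenches reloading and the decay of the thioester-loaded
   species E2~Ub is followed by gel densitometry or fluorescence
   anisotropy. The loaded state decays through three competing pathways —
   hydrolysis (rate constant *k*₁, min⁻¹), bimolecular attack by an added
   nucleophile at concentration \[Nu\] (*k*₂, mM⁻¹ min⁻¹), and
   intramolecular autoubiquitination (*k*₃, min⁻¹):

   E2L(t) = E2L₀ · e^(−(k₁ + k₂\[Nu\] + k₃) t)

   E2Ub(t) = (k₃ E2L₀ / (k₁ + k₂\[Nu\] + k₃)) · (1 − e^(−(k₁ + k₂\[Nu\] + k₃) t))

   Because the autoubiquitinated E2 co-migrates with the loaded state on
   non-reducing gels, the observable mono-Ub band is E2L(t) + E2Ub(t).
   Fitting that sum globally to paired time courses (no nucleophile vs.
   one or more nucleophile concentrations, parameters shared, \[Nu\]
   fixed) separates *k*₁, *k*₂ and *k*₃.

2. **Ensemble geometry.** For coordinate ensembles of the E2–Ub
   conjugate, the attack geometry of the catalytic histidine is
   quantified by the signed distance of its unprotonated ε-nitrogen from
   the thioester plane (through Cys-Sγ, Gly76-C, Gly76-O; positive toward
   the solvent cavity) and the orientation angle of the imidazole ring,
   alongside hydrogen bonds (D–A ≤ 3.0 Å, D–H–A ≥ 150°), salt bridges
   (ion-pair COM ≤ 5 Å), χ₁/χ₂ side-chain dihedrals, per-residue RMSF
   after Cα superposition, and active-site pocket volume by grid flooding
   (12 Å sphere, 0.5 Å spacing, 1.09 Å heavy-atom exclusion, convex-hull
   pruning).

The package implements both workflows, the densitometry arithmetic that
feeds the kinetics (background subtraction, NaOH-resistant/-sensitive
partition distinguishing oxyester from isopeptide linkages), auxiliary
fits (mono- and double-exponential, linear rate-vs-concentration, pH
dose–response, fold-change error propagation, kinetic solvent isotope
ratios), and synthetic-data generators with exactly known ground truth
for every analysis path.

## Worked example

A packaged example dataset holds a simulated chase pair (no nucleophile
vs. 250 mM glycerol, Gaussian densitometry noise σ = 0.02) generated at
*k*₁ = 0.015 min⁻¹, *k*₂ = 3.8×10⁻⁴ mM⁻¹ min⁻¹, *k*₃ = 0.002 min⁻¹:

```r
library(ubikin)
courses <- read_timecourse_csv(
  system.file("extdata", "example_chase.csv", package = "ubikin"))
fit <- fit_discharge(chase_design(courses))
summary(fit)
#> Competing-pathway discharge fit summary
#>          estimate    std_error fixed
#> k1   0.0152184165 5.234905e-04 FALSE
#> k2   0.0003645879 1.567926e-05 FALSE
#> k3   0.0017449107 4.340914e-04 FALSE
#> E2L0 0.9915762186 1.019898e-02 FALSE
#> residual RMS 0.01527 on 26 points (df 22); k1 half-life 45.5 min
```

All four shared parameters are recovered within ~2 standard errors of
the generating values; the hydrolysis half-life ln 2 / *k*₁ ≈ 45.5 min.
`plot(fit)` overlays the data and fitted curves; `predict`, `residuals`
and `simulate` behave as for other R model objects.

Rate comparisons between enzyme variants propagate the standard
deviations of averaged rate constants into the fold difference:

```r
fold_change_with_error(rate_with_error(3.9e-4, 0.6e-4),
                       rate_with_error(0.9e-4, 0.3e-4))
#> rate 4.333 +/- 1.59
```

On the structural side, `gen_thioester_frame()` builds toy active-site
frames with prescribed geometry, and `signed_plane_offset()`,
`orientation_angle()`, `detect_hbonds()`, `detect_salt_bridges()`,
`per_residue_rmsf()`, `sidechain_dihedrals()` and `pocket_volume()`
measure real (multi-model PDB) or generated ensembles;
`geometry_report()` collects the per-frame observables into a table.

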