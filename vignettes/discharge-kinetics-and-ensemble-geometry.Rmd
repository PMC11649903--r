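---
title: "Competing-pathway discharge kinetics and ensemble geometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competing-pathway discharge kinetics and ensemble geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubikin)
```

## The kinetic model

A thioester-loaded E2~Ub conjugate (`E2L`) disappears through three
competing reactions: pseudo-first-order hydrolysis ($k_1$, min$^{-1}$),
second-order discharge onto an added nucleophile at fixed concentration
$[\mathrm{Nu}]$ ($k_2$, mM$^{-1}$min$^{-1}$), and first-order
intramolecular autoubiquitination ($k_3$, min$^{-1}$) producing `E2Ub`.
With $k_\mathrm{obs} = k_1 + k_2[\mathrm{Nu}] + k_3$ the rate laws
integrate in closed form:

$$[\mathrm{E2_L}](t) = [\mathrm{E2_L}]_0\, e^{-k_\mathrm{obs} t},
\qquad
[\mathrm{E2_{Ub}}](t) = \frac{k_3 [\mathrm{E2_L}]_0}{k_\mathrm{obs}}
\left(1 - e^{-k_\mathrm{obs} t}\right).$$

Because autoubiquitinated E2 co-migrates with the loaded species on
non-reducing gels, the quantifiable observable is the *sum*
$[\mathrm{E2_L}](t) + [\mathrm{E2_{Ub}}](t)$, which decays from
$[\mathrm{E2_L}]_0$ to the plateau $k_3[\mathrm{E2_L}]_0/k_\mathrm{obs}$.
The discharged apo fraction follows by mass balance; the package checks
conservation to $10^{-10}$ and validates the closed form against an
independent stiff ODE integration (`ode_species`, tolerances
$10^{-12}$) to $10^{-8}$.

Assumptions worth stating explicitly:

* The chase starts at $t = 0$ with E1 reloading fully quenched; the
  EDTA quench is treated as instantaneous and no mixing dead time is
  modeled. $t = 0$ is the first chase sample.
* State variables are densitometric *fractions*, not concentrations;
  $[\mathrm{E2_L}]_0$ defaults to 1 and is a free fit parameter.
* Autoubiquitination is intramolecular (first order); nucleophile
  attack never saturates (no Michaelis–Menten term), matching the
  concentration regimes of the assays.
* Units are fixed package-wide to minutes and millimolar. $k_2$ is
  per-mM per-min: nucleophile concentrations in these assays are stated
  in mM, so the per-millimolar reading of "mmol$^{-1}$ min$^{-1}$" is
  the dimensionally consistent one.

## Global fitting

`fit_discharge()` minimizes the summed squared residuals of the
observed-sum model over *all* courses of a `chase_design`
simultaneously, with $\{[\mathrm{E2_L}]_0, k_1, k_2, k_3\}$ shared and
each course's $[\mathrm{Nu}]$ held at its recorded value. The optimizer
is Levenberg–Marquardt least squares (`minpack.lm::nls.lm`).

Numerical choices:

* **Positivity by log-scale rates.** Rates span orders of magnitude and
  must be non-negative, so the free rates are optimized as $\log k$
  with a floor of $\log 10^{-12}$. A data set that genuinely contains
  no signal for a pathway drives that rate to the floor, i.e. to zero
  for all practical purposes (the tests treat $\le 10^{-6}$ as zero).
  $[\mathrm{E2_L}]_0$ is fitted on the natural scale, bounded to
  $(10^{-6}, 2)$: noisy densitometry can push the first sample above 1,
  and hard-capping at 1 would bias the estimate, so the simulation-side
  invariant $0 < [\mathrm{E2_L}]_0 \le 1$ is not imposed on estimates.
* **Deterministic initialization.** $[\mathrm{E2_L}]_0$ from the first
  sample; $k_1$ from a half-amplitude-crossing estimate of the
  nucleophile-free course (robust to plateau noise); $k_2$ from the
  excess decay rate of the highest-$[\mathrm{Nu}]$ course divided by
  $[\mathrm{Nu}]$; $k_3$ from the late-time plateau. Degenerate inputs
  (flat courses) start the unidentifiable rates at the floor, where the
  zero-gradient flat solution keeps them.
* **Uncertainties.** Standard errors come from the Jacobian-based
  covariance at the optimum, scaled by the residual variance, with the
  delta method mapping $\log k$ errors back to the natural scale. No
  bootstrap is performed by default; `simulate()` provides seeded
  parametric resamples if one is wanted.
* **Weighting.** All points of all courses are weighted equally. How
  the original paired fits weighted their courses is not documented;
  equal per-point weighting is the neutral choice and is what the
  recovery experiments below validate.
* **Replicates.** Replicate experiments are fitted separately and the
  rate constants averaged afterwards (fit-then-average), mirroring
  practice for the averaged constants entering fold-change comparisons;
  the package does not pool replicates into one fit.
* **Apparent constants.** Fits of courses recorded in the presence of a
  RING-domain E3 use the same machinery but the result carries an
  `apparent` flag: discharge then occurs from a mixture of RING-bound
  and free conjugate, so the constants are meaningful only at that RING
  concentration. No attempt is made to deconvolve the two populations.

Auxiliary fits follow the same pattern: `fit_mono_exponential`
($A e^{-kt} + C$; non-decaying input is flagged rather than failed),
`fit_double_exponential` (components reordered so $k_a \ge k_b$;
$k_a/k_b < 1.2$ flagged as collapsed), `fit_linear_rate_vs_conc`
(ordinary least squares; the intercept is the E3-free rate), and
`fit_ph_dose_response`. For the pH profile the functional form is not
prescribed anywhere, so a 4-parameter logistic *in pH* is used —
$k(\mathrm{pH}) = \mathrm{floor} + (\mathrm{ceiling} -
\mathrm{floor})/(1 + 10^{\,s(\mathrm{pH}_{1/2} - \mathrm{pH})})$ — with
the midpoint reported as the apparent p$K_a$; flat data flag the
midpoint as unidentifiable. Fold differences between wild-type and
mutant rates propagate errors as
$\partial(r) = r\sqrt{(\partial k_{WT}/k_{WT})^2 +
(\partial k_{Mut}/k_{Mut})^2}$, which the tests verify against Monte
Carlo sampling to 5% for relative errors up to 10%.

## Densitometry

`fraction_loaded` is the loaded/(loaded+apo) band ratio. For substrate
modification, `fraction_modified` subtracts a background intensity from
the **modified** signal before forming modified/(modified+unmodified).
Whether the background band should be subtracted from the modified or
the total signal is ambiguous in the source protocol; subtraction from
the modified signal is the package's choice and is applied uniformly.
Values are clamped at zero (never negative) and clamping is reported via
a warning and a `clamped` attribute rather than silently absorbed. The
no-ATP baseline is a single condition-level scalar (one value per
condition, not per lane): the protocol does not state a per-time-point
baseline, and a per-lane baseline would double-count lane noise.

The NaOH partition divides the background-corrected modified fraction
with alkali treatment by the one without: the ratio is the
NaOH-*resistant* (isopeptide) proportion, its complement the
NaOH-*sensitive* (oxyester) proportion; they sum to 1 exactly, ratios
slightly above 1 (noise) are capped with a warning.

## Ensemble geometry

All geometric operators work on `md_frame` objects (multi-model PDB via
`bio3d`, model order = frame order, coordinates in Å, residues keyed by
chain and author numbering).

* **Thioester plane.** Coordinates are centered on Cys-Sγ; the plane
  normal is the cross product of the Sγ→C and Sγ→O vectors, oriented so
  a caller-named cavity reference atom scores positive; the signed
  offset is the dot product with the centered His-Nε position. The
  orientation angle is measured at Nε between the mass-weighted center
  of the five imidazole ring atoms and the carbonyl carbon.
* **Base-catalysis compatibility.** A frame is compatible when
  $|$offset$| \le 3.5$ Å (a catalytically competent nitrogen sits
  roughly 3 Å off the plane) and the orientation angle falls in a
  caller-chosen window (default $[90°, 180°]$). No specific angular
  window is canonical, so both thresholds are exposed and the default
  window is deliberately permissive.
* **Hydrogen bonds.** The source criteria as written ("at most 0.12 nm
  between acceptor and donor hydrogen", angle "at most 150°") are
  geometrically inconsistent with standard hydrogen-bond definitions —
  taken literally they would reject ideal linear bonds and accept
  near-right-angle contacts. The package therefore interprets 1.2 Å as
  the donor–hydrogen *covalent identification* cutoff, 3.0 Å as the
  donor–acceptor cutoff, and the angle threshold as a *minimum* of
  150°. The literal reading of the angle criterion remains available
  via `contact_criteria(angle_mode = "literal_maximum")`. Donors
  without a covalently attached hydrogen are skipped with a warning.
* **Salt bridges.** Mass-weighted centers of charged groups (Arg
  guanidinium, Lys ammonium, Asp/Glu carboxylates) within 5 Å.
* **Dihedrals.** $\chi_1$ = N–Cα–Cβ–Cγ, $\chi_2$ = Cα–Cβ–Cγ–Nδ1 for
  histidine, signed per IUPAC in $(-180°, 180°]$.
* **RMSF.** Frames are superposed onto the first frame by Kabsch
  least-squares over a fit selection (default: all Cα), then per-atom
  fluctuations about the ensemble mean are averaged within residues
  over the measure selection. For isotropic Gaussian jitter of SD
  $\sigma$ the expected per-atom RMSF is $\sigma\sqrt{3}$, which the
  tests verify distributionally.
* **Pocket volume.** The inclusion sphere (radius 12 Å) is centered on
  the midpoint of the segment connecting the midpoints of two
  caller-named atom pairs — the natural reading of "centered on the
  axis between" two residue pairs; the pairs are configurable. The
  grid is anchored at that center with points at
  $\mathrm{center} + s\,(i,j,k)$, $s = 0.5$ Å, which makes the volume
  exactly invariant under translation of an aligned frame (frames are
  expected to be superposed first; the grid axes stay global, so
  arbitrary rotations re-discretize within one grid shell). Points
  strictly closer than 1.09 Å to any heavy atom (element ≠ H, from PDB
  columns 77–78 with an atom-name fallback) are deleted — ties at
  exactly the cutoff are retained, a convention that only matters on
  constructed inputs. Points outside the convex hull of the heavy atoms
  are removed; the hull is computed by an in-package incremental
  quickhull (no suitable hull routine ships with the declared
  dependencies) and is validated in the tests against constructed cube
  and tetrahedron geometries with known membership. The volume is the
  surviving point count times $s^3$. Volumes are computed per frame;
  how per-frame volumes should be summarized (median vs mean) is left
  to the caller.
* **His tautomers.** Residue-name dialects (HID/HSD, HIE/HSE, HIP/HSP)
  are normalized to HIS on input with the protonation recorded; the
  "unprotonated nitrogen" is NE2 for δ-protonated and ND1 for
  ε-protonated histidine. The PDB writer re-emits the dialect so round
  trips preserve the state.

## Synthetic data: what it emulates, and what it does not

The generators produce every input class with exactly known truth:

* `gen_chase` draws time courses from the closed-form observed signal
  plus i.i.d. additive Gaussian noise on the fraction scale. The
  default study conditions mirror the reference experiment: paired
  courses at 0 and 250 mM nucleophile, 13 samples over 0–120 min,
  $k_1 = 0.015$ min$^{-1}$, $k_2 = 3.8\times10^{-4}$
  mM$^{-1}$min$^{-1}$, $[\mathrm{E2_L}]_0 = 1$, noise
  $\sigma = 0.02$. No value is printed for the minor autoubiquitination
  rate; $k_3 = 0.002$ min$^{-1}$ (a small fraction of $k_1$) is the
  package's choice of a realistic "minimal but visible" pathway.
  Densitometry error is not characterized in the source; Gaussian is an
  assumption, stated as such, and noise is *unclipped* by default so
  fits must tolerate slight excursions outside $[0,1]$ as real
  densitometry produces.
* `gen_lane_table` converts known modified fractions into band
  intensities with an arbitrary scale, additive background and optional
  NaOH twin lanes at a prescribed resistant proportion; with zero noise
  the densitometry pipeline returns the inputs exactly.
* `gen_thioester_frame` builds a toy active site whose measured plane
  offset and orientation angle equal the targets *exactly*, including
  the mass-weighting of the ring center (the pentagon is placed by
  solving the two-parameter ring-center position in closed form).
  Decoy atoms are seeded and kept 3 Å clear of the site.
* `gen_fluctuating_ensemble` jitters a base frame with per-atom
  Gaussian displacements and can script a donor–acceptor contact on a
  per-frame schedule; scheduled atoms are exempt from jitter so
  interaction frequencies are known exactly.

One master integer seed fans out to per-generator substreams, so adding
a generator never perturbs existing streams and equal seeds reproduce
byte-identical data.

What the generators deliberately do **not** emulate: correlated
densitometry errors (lane-to-lane gain drift), saturating film
response, force-field-realistic conformational sampling, solvent, or
image-level gel artifacts. Passing the recovery tests therefore shows
that the estimators are correct and well-calibrated *under the stated
noise model*, not that any particular wet-lab dataset would yield those
constants. Quantities that require the raw gels or deposited structures
(e.g. the measured NaOH-resistant percentage of a real substrate, RING
titration slopes, crystallographic statistics) are exercised only
through synthetic analogues.

## Problem sizes and runtime

The test-suite experiments are sized for a single CPU: 100 seeded
parameter draws for the closed-form/ODE equivalence, 51 synthetic
designs (noise $\sigma \in \{0.01, 0.02, 0.05\}$) for the bias and
coverage checks, $10^5$ Monte-Carlo samples for the fold-change error
formula, 2000 frames for the RMSF distributional check, and a 12 Å /
0.5 Å pocket grid (~58 000 candidate points). The full suite runs in
well under a minute.

## Known limitations

* The mono-band model cannot separate $k_3$ from zero on data with no
  visible plateau; the estimate then sits at the positivity floor with
  a large standard error, which is the honest answer.
* On a *constant* signal, any $k_3$ with $k_1 = k_2 = 0$ reproduces the
  data (loaded and autoubiquitinated species co-migrate), so $k_3$ is
  structurally unidentifiable there; the floor initialization resolves
  the degeneracy toward zero.
* Pocket volumes depend on the alignment convention: frames must be
  superposed onto a common reference before calling `pocket_volume`,
  and rotations of unaligned frames change the volume within one
  grid-shell of discretization.
* E1 loading kinetics, ubiquitin chain elongation, RING binding
  equilibria and membrane-phase geometry are out of scope by design.
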