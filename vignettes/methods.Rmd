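---
title: "Models and methods: equilibrium binding, AFM volumetry and stoichiometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: equilibrium binding, AFM volumetry and stoichiometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(titravol)
```

titravol quantifies the interaction between a DNA-bound transcription factor
(Cra, the E. coli catabolite repressor activator) and an enzyme partner
(FruK, fructose-1-kinase) from three kinds of bench data: equilibrium
biolayer-interferometry (BLI) titrations, atomic-force-microscopy (AFM)
particle measurements, and plate-reader assays (luciferase-coupled enzyme
activity and OD600 growth curves). This vignette explains the models, the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## Equilibrium binding with ligand depletion

A BLI titration reports the equilibrium plateau signal $Y$ as a function of
titrant (FruK) concentration $L$. In the non-depleting limit the isotherm is
hyperbolic,

$$Y = c + Y_{max} \frac{L}{K_d + L},$$

with baseline $c$, amplitude $Y_{max}$ and dissociation constant $K_d$
(molar). This form is valid only in the *equilibrium* binding regime, when
the fixed component of the reaction — here the effective concentration
$D_T$ of DNA-bound Cra on the sensor tip — is at least 10-fold below
$K_d$. When $D_T$ approaches or exceeds $K_d$ a non-negligible fraction of
added titrant is consumed by complex formation, and the quadratic
(Morrison) depletion model is required:

$$Y = c + Y_{max}\,\frac{a - \sqrt{a^2 - 4 n L / D_T}}{2n},
\qquad a = n + \frac{L}{D_T} + \frac{K_d}{D_T},$$

with stoichiometry $n$ (fixed at 1 throughout; `binding_regime()` encodes
the 10-fold rule, with ratios exactly 0.1 and 10 assigned to the outer
regimes). The discriminant is mathematically non-negative; floating-point
round-off can push it slightly below zero, so it is clamped at 0.

For the Cra–FruK assay $D_T \approx K_d \approx 2\times10^{-9}$ M — the
*intermediate* regime — and a single curve cannot separate affinity from
depletion: $K_d$, $D_T$ and $Y_{max}$ trade off almost freely. The remedy
is a global fit across many independent titrations with deliberately varied
amounts of immobilized DNA: one shared $K_d$, and per-curve $c$, $Y_{max}$
and $D_T$. `fit_titration()` implements this as a single optimization
rather than the manual vary-and-refit iteration sometimes used at the
bench; the objective is the same and the result is reproducible.

Numerical choices:

* $K_d$ and each $D_T$ are optimized as log10 values, which enforces
  positivity and makes step sizes concentration-scale-free. The default
  $D_T$ start is 1 nM, the typical effective concentration of immobilized
  DNA on a streptavidin BLI tip; a per-curve `DT_hint_M` column overrides it.
* For fixed nonlinear parameters the model is linear in $(c, Y_{max})$, so
  these are profiled out exactly by weighted linear least squares (variable
  projection). The nonlinear search therefore runs over $1 + m$ parameters
  for $m$ curves instead of $1 + 3m$, which makes the fit fast and robust.
* The optimizer is Levenberg–Marquardt (minpack.lm), multistarted from 7
  log-spaced $K_d$ values spanning $10^{-12}$–$10^{-5}$ M so that no
  reasonable affinity is missed. Unit weights by default; a `signal_sd`
  column switches to inverse-variance weights.
* Standard errors come from the Jacobian of the full parameter vector at
  the optimum; the SE of $K_d$ is transported from the log scale by the
  delta method.
* A curve whose data span less than 20% of its fitted amplitude (or whose
  fitted amplitude collapses to zero) is flagged non-identifiable.
* Preparations of the fixed component are typically 70–90% binding-active;
  fitted $D_T$ values are *effective* concentrations and are not corrected.
  An `active_fraction` argument reports the rescaled values alongside when
  set.

`confint(fit, method = "bootstrap")` gives a parametric bootstrap interval:
noise is resimulated on the fitted curves at each curve's own residual
scale (curves of different amplitude are differently noisy, and a pooled
scale would understate the variance of the shared-$K_d$ estimator), the
global fit is re-run warm-started from the fitted parameters, and the
percentile interval is reported. Warm starts were checked against full
multistarts on resampled data and agree to a few percent in spread.

## AFM volumetry and the mass ladder

Deposited particles are measured as a peak height $h$ and two widths at
half-height, $w_{long}$ and $w_{orth}$. The particle volume is that of an
elliptic cylinder,

$$V = \pi\, h\, \frac{w_{long}}{2} \frac{w_{orth}}{2},$$

the geometry that brackets correctly between a spherical segment (which
under-estimates) and a rectangular box (which over-estimates) for globular
complexes. DNA lying next to a bound complex is modelled as a cylindrical
segment, $V_{DNA} = \tfrac{2}{3} h_{DNA} w_{DNA}^2$, and subtracted so only
protein volume remains. The segment formula is implemented exactly in this
$w^2$ form; a parabolic cross-section times an independent segment length
would read $\tfrac{2}{3} h\, w\, \ell$, but no separate length is measured,
and the $w^2$ convention is retained deliberately. A negative net volume
indicates a measurement problem; such rows are flagged and excluded rather
than clamped at zero, because silent clamping would bias the mass
distribution upward-looking tails away.

Volumes convert to molecular weights through a protein specific volume
$\bar v$:

$$M[\mathrm{Da}] = \frac{V[\mathrm{nm^3}] \times 10^{-21}}{\bar v\,[\mathrm{ml/g}]}
  \times N_A, \qquad N_A = 6.02214076\times10^{23}.$$

The default $\bar v = 0.67$ ml/g is derived from crystal structures of the
relevant protein families as solvent-excluded volume over the mass of the
modelled atoms. `specific_volume_from_structure()` reproduces that
derivation for any structure: voxels within $r_{vdW} + r_{probe}$ of an
atom are marked using exact distances (Bondi radii; water probe 1.4 Å), a
thin shell of solvent-side voxels carrying their exact clearances acts as
probe sources, and a voxel is solvent-excluded when
$\min_z(|x - z| - \mathrm{clearance}(z)) > r_{probe}$ — the morphological
closing of the van der Waals region, accurate to second order in the grid
spacing because the enlarged region's boundary consists of spherical
patches. A one-voxel linear ramp on the signed distance removes
lattice-alignment bias; the default spacing is 0.5 Å and the estimate
refines monotonically as the spacing decreases. Crystal structures usually
omit hydrogens; the heavy-atom radii absorb them implicitly, and the mass
is that of the atoms present, so residues missing from the model contribute
neither volume nor mass.

Expected masses come from a reference ladder built from the monomer masses
(Cra 37,999 Da; FruK 33,756 Da): the two homodimers (the "(dimer)$_1$"
tier, only 12% apart in mass and not separable by volumetry), the
(dimer)$_2$ heterocomplex Cra$_2$:FruK$_2$, and the (dimer)$_3$ complex
Cra$_2$:FruK$_2$:Cra$_2$ — the composition that follows from requiring a
Cra dimer on DNA and from the observation that single-protein samples
contain only homodimers. `protein_mass()` recomputes monomer masses from
sequence (average isotopic residue masses, unmodified chain).

## Model-free 1-D clustering of mass estimates

Mass distributions are partitioned with `cluster1d()`, an exact dynamic
program over contiguous groups of the sorted values minimizing the
within-cluster sum of squares. In one dimension the WCSS-optimal partition
is always contiguous in sorted order, so this is the global optimum — no
iterative k-means, no dependence on starting values or input order. The
`fixed_top_class_size` constraint pins the top class to exactly the given
number of largest observations (used when a small, visually distinct heavy
population is known) and re-optimizes the remaining classes; it is read as
a member count, the natural interpretation of fixing a class at $n = 7$.

`choose_k()` scores partitions by BIC under a hard-assignment,
equal-variance Gaussian mixture (pooled variance $WCSS/(n-k)$, $2k$
parameters); it is a diagnostic and never overrides an explicitly requested
$k$. `assign_stoichiometry()` maps each class mean to the nearest ladder
mass, breaking ties toward the smaller complex; when more than one ladder
entry lies within 10% of the class mean the call is reported as ambiguous
with all candidate labels — chosen because the two homodimers differ by
about 12%, so both are candidates for an intermediate (dimer)$_1$ mean
while the higher tiers remain unambiguous.

## Enzyme assay and growth metrics

Luciferase fold changes are ratios of replicate means to buffer-only
control means, with first-order error propagation
$\sigma_{fold} = fold\sqrt{(\sigma_c/\bar y_c)^2 + (\sigma_0/\bar y_0)^2}$;
replicate counts of three are too small for a within-plate bootstrap, so
propagation is the default, and with multiple independent experiments the
reported spread is the SD of per-experiment folds. ATP standards
(0.03–4 mM) are calibrated log–log linearly, the form that covers both
linear and mildly saturating luminescence responses; inverse predictions
outside the calibrated range are flagged as extrapolations. Concentration
dependence is assessed by Spearman rank correlation with a seeded
permutation test (default 10,000 permutations), because monotonicity — not
a specific dose–response form — is the claim being tested.

Growth curves are summarized by the time to half-maximal OD600: the
maximum of a 3-point median-smoothed series (resistant to single-point
spikes), with the first crossing of half that maximum located by linear
interpolation between flanking samples. Against a known plateau capacity
the crossing can be unreachable, in which case it is marked rather than
extrapolated. Strain delays are differences of half-max times; the sign is
preserved, and an unreachable crossing propagates.

## Synthetic data: what it emulates and what it does not

No raw study data are redistributed, so every stage is exercised against
seeded generators whose defaults are the study conditions:

* `simulate_titration()` — quadratic-model plateaus: $K_d = 2$ nM shared by
  ten curves, per-curve $D_T$ log-uniform over 0.5–5 nM (the deliberately
  varied immobilized-DNA loading), baselines and amplitudes uniform over
  realistic signal ranges, additive Gaussian noise of 2% of each curve's
  amplitude on a 12-point grid spanning $10^{-10.5}$–$10^{-7.5}$ M. The 2%
  noise level is a configurable judgement call (plateau noise is not a
  published number); the fractional-of-amplitude parameterization keeps
  curves of different amplitude comparably noisy.
* `simulate_afm_peaks()` — mixtures at the ladder masses (default 45/40/15%
  across the three tiers, 60 particles), decomposed into $(h, w_{long},
  w_{orth})$ under lognormal height (median 2 nm) and aspect (median 1.3)
  models typical of dried protein complexes on mica, with adjacent-DNA
  geometry (median height 0.5 nm, width 6 nm) added to the deposited volume
  of DNA-bound particles; fractional Gaussian noise per measured dimension.
* `simulate_growth()` — a symmetric logistic sampled every 30 min for 22 h
  with 0.01 OD additive noise.
* `simulate_plate()` — triplicate luminescence across the physiological
  substrate range 0.1–15 mM with a saturating true fold response, 10%-CV
  buffer controls, and power-law ATP standards over 0.03–4 mM.

One top-level seed drives per-generator substreams at fixed offsets, so
adding a generator never reshuffles another's draws. What the generators do
*not* emulate: BLI sensorgram kinetics (only equilibrium plateaus are
modelled), tip-convolution and image-processing artefacts upstream of the
AFM measurement table, correlated plate effects, diauxic or asymmetric
growth. Passing round-trip tests therefore demonstrates the correctness of
the estimators under the stated noise models, not robustness to every
artefact of real instruments.

## Problem sizes and verification

The test-suite and acceptance-script simulations use the study-scale
configurations: ten 12-point curves per global fit, three Kd scenarios
(2.0, 2.1, 1.6 nM) recovered within the uncertainties reported for them,
200-replicate coverage simulations with 100 bootstrap refits each,
60-particle AFM samples, 100 random instances for the
clustering-vs-enumeration oracle, and Monte-Carlo integration with $10^6$
points for the solvent-excluded-volume check. The dynamic program is
validated against exhaustive enumeration of contiguous partitions
($n \le 15$, $k \le 4$), the global fitter against an independent
profile-RSS grid scan at 0.001-decade resolution, the volume chain by exact
noiseless round trips, and sequence masses against an external
average-mass implementation.

## Known limitations

* The global fit assumes independent Gaussian plateau noise; correlated
  drift within a titration series is not modelled.
* Bootstrap intervals inherit the parametric noise model; with per-curve
  residual scales estimated from ~9 degrees of freedom each, realized
  coverage sits near the lower edge of the nominal band in simulation.
* The DNA segment volume uses the printed $w^2$ convention (see above);
  absolute DNA volumes are therefore convention-dependent, though they are
  small relative to protein volumes.
* Volumetry cannot distinguish the two homodimers; ambiguity is reported,
  not resolved.
* The specific-volume routine assumes Bondi radii and a 1.4 Å water probe;
  structures with exotic ligands whose elements are outside the radius
  table are rejected explicitly rather than guessed at.
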