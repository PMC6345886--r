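---
title: "Models and methods in mitoamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mitoamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoamp)
```

# Overview

`mitoamp` packages three computational procedures used to study how
LC3/GABARAP (Atg8) proteins amplify PINK1/Parkin mitophagy through
ubiquitin-independent, LIR-motif-mediated recruitment of the autophagy
receptor NDP52:

1. a 21-state kinetic model of PINK1/Parkin activation and NDP52-driven
   autophagosome initiation, with simulation, bounded least-squares
   calibration and rate-constant robustness analysis;
2. an automated 3D image quantification workflow for mitochondria and
   autophagy-initiation foci in multi-channel confocal stacks;
3. a ratiometric mtKeima cytometry gating rule.

Each stage has a seed-deterministic synthetic-data generator with recorded
ground truth, so the full pipeline is exercisable — and testable — without
any external data.

# The kinetic model

## Structure

The model is a well-mixed deterministic system of 21 ordinary differential
equations over the species returned by `mito_species()`. It couples two
positive feedback loops:

* **PINK1/Parkin loop.** Mitochondrial depolarization (the `Stim` input,
  reaction 4) switches PINK1 dimerization on; the active dimer
  phosphorylates ubiquitin on Ser65 (reaction 7) and recruited Parkin
  (reaction 11), and phospho-Parkin feeds back by making more ubiquitin
  available for phosphorylation (reaction 5).
* **Atg8/LIR loop.** pS65-Ub recruits NDP52 through its ubiquitin-binding
  domain (reaction 12). Recruited NDP52 — through any of its bound forms —
  activates ULK1 (reaction 14), which drives PtdIns(3)P production
  (reaction 16) and thereby Atg8 lipidation (reaction 18). Lipidated Atg8
  (Atg8PE) recruits further NDP52 through its LIR motif independently of
  ubiquitin (reaction 20), closing the second loop. The LIR-mutant variant
  (`LIR_V136S`) severs exactly this loop by zeroing the association
  constants of reactions 13 and 20.

Protein-protein binding follows mass-action kinetics; every
(de)phosphorylation or conversion follows Michaelis-Menten kinetics in the
`kc * [E]` form with an explicit enzyme species, and every conversion has an
opposing reaction so the unstimulated system can equilibrate. Three species
are constant inputs: the stimulus switch, Atg4 (deconjugation of Atg8PE,
reaction 19) and a generic phosphatase that catalyses the opposing
dephosphorylation/inactivation reactions (6, 8, 10, 15, 17). The readout is
*total lipidated Atg8*: free Atg8PE plus every Atg8PE-containing complex
(`atg8pe_readout()`), since receptor binding does not de-lipidate Atg8.

Six moieties are conserved (NDP52, Parkin, ubiquitin, Atg8, ULK1,
PtdIns); PINK1 alone is synthesized and degraded (reactions 1-3), with the
dimer degrading more slowly than the monomer because dimerization
stabilizes it. Conservation is checked symbolically (the moiety vectors
annihilate the stoichiometry matrix) and numerically (relative drift of
simulated totals below 1e-6).

## Reference parameters

Only class ranges are biophysically fixed: association constants are
diffusion-limited (0.1–10 /nM/s), Michaelis constants span 1–1000 nM,
catalytic constants 1e-4–1 /s and synthesis velocities 0.001–10 nM/s. The
shipped reference set (`default_parameters()`) was calibrated once, within
those ranges, against the qualitative behaviours the system is known to
show, and is not adjusted thereafter:

* an unstimulated steady state with lipidated Atg8 below 1% of the Atg8
  pool;
* a lagged, switch-like lipidation response within a 2 h horizon after
  stimulation;
* pointwise-diminished output when the LIR feedback is removed;
* baseline output under PI3K inhibition;
* limited dispersion (coefficient of variation below 0.5 in the
  2 h readout) under independent 2-fold log-uniform perturbation of all
  rate constants.

Two structural choices matter for reconciling these requirements and are
worth recording. First, the NDP52 binding steps use weak,
micromolar-range dissociation constants (Kd of 600 nM for UBD/pS65-Ub,
200 nM for LIR/Atg8PE). Strong affinities make the resting state
self-igniting: with nanomolar Kd the feedback gain of the Atg8PE/NDP52/ULK1
loop exceeds one even without stimulus and the "off" state runs away.
Second, the plateau of the response is pinned by pool depletion (PtdIns
and Atg8 totals), which is what keeps the stimulated endpoint insensitive
to rate-constant perturbation: most perturbed systems still saturate the
same pools by 2 h.

Concentrations are nM, time is seconds. The default horizon is 7200 s,
matching an hours-scale stimulation experiment; it is a configuration
value, not a claim about the biological time base.

## Simulation protocol

`equilibrate()` relaxes the system with the stimulus off (the returned
state has max |dx/dt| < 1e-8 nM/s); `simulate_mitophagy()` starts from that
state, sets the stimulus at t = 0 and integrates with `deSolve::lsoda`
(relative tolerance 1e-8, absolute tolerance 1e-10 nM) — a stiff-capable
method, since the feedback system mixes second-scale binding with
hour-scale accumulation. The right-hand side is evaluated in compiled code;
the data-driven R evaluation (`derivatives()`) is kept as the reference
implementation and a test asserts their agreement on random states.

`perturb_robustness()` multiplies every kinetic constant by an independent
log-uniform factor in [1/fold, fold], re-equilibrates, re-simulates and
reports the coefficient of variation of the endpoint readout and of the
area under the curve. The "limited effect" claim is operationalized as
CV < 0.5 at fold 2 with 200 samples. A perturbed set occasionally has no
stable resting state; such samples are started from the initial pools
instead of aborting the report.

## Fitting

`fit_parameters()` runs bounded Levenberg-Marquardt least squares
(`minpack.lm::nls.lm`) in log10 parameter space, with the printed class
ranges as box bounds. Residuals are normalized per observable to each
observed series' maximum so PINK1-dimer, pS65-Ub and Atg8PE series
contribute comparably. The default free set — the PINK1 synthesis velocity
(reaction 1) and the catalytic constants of ubiquitin phosphorylation
(reaction 7) and PI3K conversion (reaction 16) — was chosen from a
sensitivity screen as the parameters the three observables actually
constrain: on noiseless synthetic data a 2-fold-perturbed start recovers
all three essentially exactly, and with 5% multiplicative noise the median
worst-case error over ten seeds stays within 20%. Most other velocity
constants sit in deep substrate or enzyme excess in the reference regime;
that excess is precisely what makes the output robust to rate-constant
perturbation, and its flip side is that those constants are only weakly
identifiable from a single wild-type time course (association constants of
the two NDP52 recruitment routes are additionally mutually collinear).
Degradation constants stay fixed; the free set is an argument.

# The 3D image quantification workflow

Mitochondria are segmented with a local-threshold strategy: per-plane
sliding-paraboloid background subtraction (50 px radius), contrast
enhancement (0.2% saturation), a 2D median with a 1.25 px circular
footprint (the 5-pixel cross), seed detection as (8, 8, 4) px local
maxima, a 2-voxel 3D median, per-plane Bernsen local thresholding (4 px
radius) and a seed-based 3D watershed (5 px radius), discarding objects of
2 voxels or fewer (<= 0.02072 µm³). Foci are segmented with a global
strategy: montage histogram normalization (bounds at the lowest/highest
intensities exceeding 0.01% of montage pixels), a 1.5-voxel 3D median,
global threshold 96 and a 300-voxel maximum component size. All constants
live in `segmentation_config()` and every one is overridable.

Implementation notes, where the method name alone does not fix the
algorithm:

* *Sliding paraboloid* is implemented as grayscale opening with the
  additively separable paraboloid structuring function z = d²/(2·radius);
  linear ramps are reproduced exactly away from the border, so smooth
  illumination gradients are removed while objects narrower than the
  paraboloid are preserved.
* *Fractional median radii* use the circular footprint of all pixels whose
  centre lies within the radius (1.25 px → 5-pixel cross; 1.5 voxels → 19-
  voxel ball; 2 voxels → 33-voxel ball).
* *Seed window* (8, 8, 4) is read as full window edge lengths; the box
  half-widths used are floor(w/2). Equal-valued plateaus collapse to one
  seed at the voxel nearest the plateau centroid.
* *Bernsen low-contrast rule*: where local contrast is below 15, the pixel
  class is decided by comparing the local mid-gray with half the bit-depth
  range (128 on 8-bit). An alternative rule — comparison with the global
  plane mean — misbehaves on mostly-background planes, where the global
  mean sits at the background level and half the background flips to
  foreground; the fixed mid-level reference avoids this and matches the
  common ImageJ implementation. Both the limit and the reference are
  configuration values.
* *Watershed radius* is interpreted as the seed-merge radius: seeds closer
  than 5 px label one object; regions then grow from seeds through the
  Bernsen mask by priority flooding, brightest voxels first,
  26-connected, with deterministic FIFO tie-breaking.
* Voxels are indexed (z, y, x); volumes are always µm³ from the stack's
  voxel-size metadata (0.18² × 0.32 µm³ per voxel at the reference
  sampling). Missing voxel metadata is an error, since volume thresholds
  could not be applied.

Positivity of a mitochondrial object for a marker requires mean intensity
strictly above 5 *and* intensity standard deviation strictly above an
experiment-specific threshold; the shipped table covers the receptor /
cell-background combinations with values 10, 15, 20, 25 and 30, and unknown
experiment keys require an explicit threshold rather than a silent default.
Translocation is the volume-weighted percentage of positive mitochondrial
objects. Receptor intensities are mapped to [0, 1] with fixed anchors
(OPTN: 4.88 → 0, 64.28 → 1; NDP52: 15.05 → 0, 193.21 → 1). Whether
positivity runs on raw or montage-normalized intensities is selectable;
the default is raw for the mitochondria workflow and normalized for foci
experiments, matching the order of operations in the two strategies.

# mtKeima gating

`build_mtkeima_gate()` operationalizes a manual gating action: in the
log10 (488-excited × 561-excited) plane, the gate's long edge is set
parallel to the principal axis of the untreated population and translated
along the outward normal — oriented toward the acidified, higher-561 /
lower-488 side — by the minimal amount that encloses at least 99.8% of the
untreated events. The minimal translation is found exactly from the order
statistics of the normal projections (equivalent to a step-plus-bisection
search with one-event tolerance). `percent_positive()` reports the
percentage of events beyond the edge on the acidified side. Compensation
is assumed done upstream; pre-gating on GFP/Keima (optionally iRFP670)
expression is provided by `pregate_double_positive()`.

# Synthetic data and what passing tests mean

The image generator paints swept-cylinder tubes (random-walk axis, flat
axial faces — matching how optically sectioned tubes appear at a 320 nm
axial pitch), Gaussian foci centred on section planes, a receptor channel
painted per ground-truth positivity, a low-order polynomial background and
Poisson shot noise plus Gaussian read noise, quantized to 8-bit at 180/320
nm voxels. Scene defaults (a dozen tubes of ~1.4 µm diameter, two dozen
foci of ~0.6 µm FWHM, 30% positive mitochondrial volume) were chosen once
as a realistic stimulated field. The generator does not model a point
spread function, cell boundaries, or object contact — so passing the
recovery tests demonstrates that the workflow implements its stated rules
faithfully on well-separated objects, not that it resolves touching
mitochondria in real images. Cell counts are external inputs, as manual
counts are in practice.

The cytometry generator mixes two correlated bivariate log-normal
populations (neutral vs acidified mtKeima signatures) with a requested
mixing fraction; 20,000 events is the default acquisition size. The
time-course generator samples the simulated trajectories and applies
multiplicative Gaussian noise.

All generators restore the caller's RNG state and record seed and
parameters beside the data.

# Problem sizes used in the checks

The packaged tests run the full pipelines at desk scale: 96×96×12 stacks,
20,000-event cytometry samples, 200-sample robustness runs at 2-fold
perturbation, and ten-seed noisy-fit replicates on 13-point time courses.

# Known limitations

* The model is well-mixed and deterministic; no spatial gradients, no
  stochastic (Gillespie) dynamics.
* The reference parameter set reproduces reported phenomenology; it is not
  a fit to measured rate constants, and absolute concentrations are
  nominal.
* The fit is local bounded least squares; no global optimization or
  posterior uncertainty.
* The gating edge uses the principal axis of the log-intensity cloud;
  other alignment rules (e.g. quantile regression of the bulk edge) would
  need to be plugged in for strongly curved populations.
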