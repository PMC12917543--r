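---
title: "Methods: channel density, head models and parcellations for EEG source metrics"
author: "eegdens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: channel density, head models and parcellations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eegdens)
```

## The question the package addresses

High-density EEG (128-256 channels) combined with individual MRI-based head
models is the research-grade setup for source-space analyses of brain
activity, but clinical practice mostly records 19-25 channels without an
individual MRI. `eegdens` provides a complete, seeded simulation-and-analysis
pipeline to quantify how three practical choices shape group-level results:

* the **montage density** (256 channels iteratively thinned to 19),
* the **head model** (each subject's own geometry versus one canonical
  template), and
* the **spatial resolution of reporting** (cortical vertices, anatomical-style
  regions, or large functional networks).

The motivating phenotype is idiopathic generalized epilepsy (IGE), whose
signature in resting-state EEG is globally raised theta-band power and raised
lagged theta synchronization relative to controls. Because clinical
recordings of this kind are not publicly available, the package ships a
synthetic-cohort generator with a known ground truth; every analysis stage is
the same code that would run on real sensor data.

## Forward model

Real studies use boundary-element head models. Here the volume conductor is
the analytic three-shell concentric sphere (brain, skull, scalp; default
radii 0.087/0.092/0.100 m and conductivities 0.33/0.0066/0.33 S/m, the
standard 1:50 skull contrast). For each spherical-harmonic order `n` the
package solves the five-coefficient boundary-value problem (potential and
radial current continuous at both interfaces, zero current through the
scalp) with layer-edge scaling of the unknowns, so the series is numerically
stable to arbitrary truncation order; the default keeps 60 terms, for which
the neglected tail is below 1e-6 of the leadfield at the deepest default
source. With equal conductivities the solution collapses to the classical
homogeneous-sphere closed form, which the test suite exploits as an
independent oracle (the closed form is derived by Legendre
generating-function summation, a route fully independent of the linear
solves).

The electrode layout is a mirror-symmetric Fibonacci-style lattice on the
upper scalp cap (120 degrees polar coverage): a midline arc plus
golden-angle points on the right half mirrored to the left. The 19 classical
10-20 directions are snapped to their nearest lattice points, renamed, and
protected. `reduceLayout()` then removes channels from the densest regions:
the non-protected channel with the smallest nearest-neighbour distance goes
first, immediately followed by its contralateral mirror partner. Because the
whole reduction is one deterministic removal sequence and a target count is
simply a prefix of it, montages are nested (reducing to 64 then 32 equals
reducing to 32 directly), including across odd targets such as 25 -- this
prefix reading is the package's resolution of the underspecified "iterative
distance-based" rule, chosen because it is the only reading that makes
nestedness exact.

## Source space and parcellations

Each hemisphere is a geodesic icosphere with `10 k^2 + 2` vertices (162 for
`k = 4`; `k = 10` gives the 1002-vertices-per-hemisphere resolution of
standard surface registration). That unit "registration sphere" carries the
parcellations and the spin test. Anatomically, each hemisphere sphere is
compressed into its half of the head and radiates at a constant cortical
depth of 0.85 x the brain radius. The constant depth is deliberate: with
sources at strongly varying depth, a large fraction of the cortex is
unresolvable from the scalp and no montage comparison is informative. Region
labels (default 68) are grown as contiguous mesh patches from seeded
vertices, mirror-symmetrically across hemispheres; network labels (default
14) are grown the same way and span both hemispheres symmetrically.

## Spectral estimation and beamforming

Trials are conditioned the standard way: first-order Butterworth band-pass
1-70 Hz applied forward-backward (zero phase; the direction convention is
the package's choice, as single-pass filtering would shift spike-wave marks
across trial boundaries), least-squares DFT removal of 50/100/150 Hz line
components over the whole recording before decimation (the harmonics exceed
the post-decimation Nyquist), decimation to 150 Hz behind a zero-phase
order-4 Butterworth guard at 0.8 x the new Nyquist (8th-order effective
magnitude; the first-order 70 Hz rolloff alone is too shallow), segmentation
into 10 s trials, per-trial demeaning and common average referencing.
Spike-wave-like marked trials are removed together with both neighbours, and
the requested number of clean trials is drawn uniformly, seeded.

Band cross-spectra use DPSS multitapers with the standard taper-count rule
`K = floor(2 T W) - 1` (39 tapers for 10 s trials at +-2 Hz smoothing),
computed from Slepian's tridiagonal commuting matrix and evaluated at the
single FFT bin nearest the band centre -- the multitaper already integrates
over +-W, so band-averaging would smooth twice. The six-band registry is
delta 2+-2, theta 6+-2, alpha 10+-2, beta1 16+-4, beta2 25+-4 and low gamma
40+-8 Hz.

DICS beamforming regularizes with `C_r = Re(C) + lambda tr(Re(C))/N I` at
`lambda = 0.05`; the "5 percent" is read as a fraction of the mean sensor
power (trace/N) rather than of the largest eigenvalue, the more common
convention in beamformer implementations. Orientations are fixed per vertex
at the dominant eigenvector of the real part of the 3x3 source CSD, with the
sign convention that the first nonzero component is positive. Because the
inverse uses the real CSD, the scalar unit-gain filters are real, which the
implementation exploits: power, and the real and imaginary parts of the full
vertex-by-vertex cross-spectrum, are plain real matrix products. Connectivity
is the absolute imaginary part of coherency -- insensitive to instantaneous
(volume-conducted) mixing -- summarized per vertex as the mean over all other
vertices, and globally as the vertex mean.

A practical identity keeps the multi-montage pipeline tractable: common
average re-referencing is linear, so the CSD of a re-referenced channel
subset is `P C[s,s] P` with `P` the subset centering matrix. One full-montage
CSD per subject and band therefore serves every reduced montage exactly.

## Group statistics

Group contrasts (patients > controls, one-sided) use permutation analysis of
a linear model with age (centred), sex and site as nuisance covariates under
the Freedman-Lane scheme: nuisance-only residuals are permuted, the full
model refit, and the group t statistic recomputed. When the number of
requested permutations reaches `n!` the test enumerates all permutations
exactly. Vertex-wise maps are enhanced with TFCE (`E = 1`, `H = 2`,
`dh = max/100`, the standard surface recommendation) over the mesh adjacency
of both hemispheres jointly, and family-wise error is controlled by the
max-statistic distribution. p-values use the plus-one convention and are
reported alongside `-log10(p)` with the conventional 1.3 threshold. Cohen d
is derived from the group t as `d = t sqrt(1/n1 + 1/n2)`. Global metrics per
band are compared across channel sets with Benjamini-Hochberg FDR control
within each band. Site blocks are not imposed on the permutations (the
design treats site as a covariate only).

TFCE is implemented as an incremental union-find over descending thresholds
with vectorized pointer-jumping, so it is cheap enough to run inside every
permutation; the test suite checks it against a literal brute-force
threshold-sum double loop.

## Spatial comparisons

Similarity between effect-size (Cohen d) maps is Spearman's rank
correlation. At the vertex level its significance uses the spin test: a
uniform random rotation of the left registration sphere, its sagittal mirror
image applied to the right sphere, nearest-vertex remapping of one map and
re-correlation over all vertices jointly, 1000 rotations by default,
two-sided plus-one p. The joint-correlation combination of the two
hemispheres is the package's reading of "each hemisphere separately";
parcel-level maps have no sphere embedding and are compared without a spin
p. Correlations are standardized with Fisher's z, and resolutions are
compared with the independent-samples z-difference statistic using the
spatial-unit counts as effective sample sizes -- an approximation, since all
correlations share the reference map, and flagged as such in reports. FDR is
controlled across channel-set comparisons (7 against the full montage; 8 in
the head-model family).

## The synthetic cohort

Every cortical vertex carries an independent source: `1/f`-amplitude
background (unit slope, amplitude 2) plus one narrowband stochastic
oscillator per band (complex Gaussian envelope of 1 Hz bandwidth carried at
the band centre, unit variance). The stochastic envelope matters: pure
sinusoids at a shared centre frequency are mutually coherent within a trial,
and an adaptive beamformer then partially cancels the very sources whose
power it should estimate. Patients' oscillator amplitudes are scaled by the
band effect (default: theta x 1.4) at the vertices of the active regions
(default: five mirror-symmetric region pairs), and every vertex of a coupled
target region receives the exact 90-degree-lagged copy of a matched
source-region vertex's oscillator scaled by the coupling increment (default:
theta +0.3 between all left-right pairs of the active set, emulating raised
interhemispheric synchrony). The lag makes the injected coupling visible to
imaginary coherency while instantaneous leakage is not.

Sources project through the subject's own three-shell leadfield: per-subject
geometry is a common head-scale factor (s.d. 2 percent) plus tangential
electrode jitter. A common scale -- rather than independent per-shell
perturbations -- keeps the thin skull layer physically plausible; letting it
fluctuate independently would vary sensor power by tens of percent between
subjects and swamp any group effect. Sensor noise is white with an amplitude
set by the control generative law at the configured SNR (default 3), the
same for both groups: recording noise does not grow with a subject's source
power, and group-dependent noise would confound the contrast. About 37
percent of patients get 1-3 randomly placed high-amplitude 3 Hz burst
trials, recorded as 0-based marks, exercising the trial-exclusion rule
without claiming to model epileptiform morphology. Ages are Gaussian
(31 +- 12 years), sexes balanced within group, sites round-robin.

Ground truth is the region-indicator map of the injected effects, which the
per-vertex source model makes literally true: power effects live exactly on
the active-region vertices, coupling effects on the coupled-region vertices.

What the generator does not emulate: real cortical folding (sources sit on a
smooth shell at constant depth, so depth-related montage effects are
understated), spatially correlated background dynamics, realistic artefact
waveforms (ocular, muscle), alpha-blocking/vigilance structure, and
MRI-segmentation error beyond the global scale factor. Passing tests
therefore demonstrate internal consistency of the estimation chain and
qualitative reproduction of density/head-model phenomena, not clinical
performance on real EEG.

## Scaled-down study sizes

The full reference design (89 subjects, 256 channels, 1002 vertices per
hemisphere, 30 clean trials) runs with `runPipeline()` but takes hours on
one core and tens of gigabytes of transient source time series at the
default recording length; memory scales as vertices x samples per subject.
The package's own validation uses scaled-down conditions, chosen once and
documented here:

* *Null calibration*: 200 cohorts of 6 vs 6, 19 channels, 162
  vertices/hemisphere, 16 regions, 30 s recordings, canonical head model,
  199 permutations; the generator runs in its coarse "region" source mode
  (one independent source per region), since type-I error concerns the
  statistics pipeline and not the generator's spatial grain.
* *Effect recovery*: one 20 vs 20 cohort, 64 channels, 162
  vertices/hemisphere, 160 s recordings, 7 clean trials (multitaper dof
  546), individual head models, 500 permutations, 499 spin rotations.
* *Density ladder*: ten 8 vs 8 cohorts, montages 256/128/64/32/19, 42
  vertices/hemisphere, 60 s recordings, canonical head model, effect-size
  maps from the covariate-adjusted linear model (no permutations needed).
* *Localization*: 20 noiseless tangential unit dipoles on the 162-vertex
  mesh with a 64-channel montage.

## Numerical conventions and degenerate inputs

* Random draws all derive from user seeds through a fixed linear hash;
  subject records depend only on (cohort seed, subject index).
* The greedy reduction breaks distance ties by lexicographically smallest
  label; mirror-symmetric ties therefore resolve to the left channel first.
* TFCE thresholds step in fractions of the map maximum; the transform of an
  all-zero (or all-negative-side) map is zero, and raising a non-maximal
  vertex never decreases any output.
* Perfectly fitted responses (zero residual variance) get a group t of
  exactly 0 rather than roundoff ratios.
* Coherency magnitudes are clipped to 1 against roundoff; zero source
  auto-power raises an error rather than producing NaN coherency.
* Spearman correlations of parcel maps can reach |r| = 1 on coarse
  parcellations; report tables clamp at 1 - 1e-12 before the Fisher
  transform (the bare `fisherZ()` refuses |r| >= 1).
* Recordings shorter than one trial yield an empty TrialSet with a warning;
  requesting more clean trials than exist raises an error naming the
  subject.

## Known limitations

* The spherical geometry cannot represent skull-thickness variation or
  anisotropy; "individual vs canonical" differences are milder than with
  real anatomy, and the package's head-model comparisons should be read as
  lower bounds on real-data discrepancies.
* The z-difference test between resolutions treats the two correlations as
  independent although they share the reference map; dependent-correlation
  tests are deliberately out of scope.
* Spin-test nearest-vertex remapping duplicates some values at coarse mesh
  resolutions, slightly discretizing the null.
* The generator's effect topography is binary at region granularity; graded
  or focal effects can be configured but are not part of the default study
  conditions.
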