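# eegdens

How much EEG do you need to see a brain-wide group difference? `eegdens` is
an R package for evaluating how **montage density** (256 down to 19
channels), **head-model type** (individual vs canonical geometry) and
**cortical parcellation** (vertices, anatomical-style regions, functional
networks) shape group-level differences in source-space EEG metrics. The
motivating application is resting-state idiopathic generalized epilepsy
(IGE), whose electrophysiological signature is globally raised theta-band
power and lagged theta synchronization; the package simulates such cohorts
with a known ground truth and runs the complete analysis chain on them.

The pipeline implements, in S4 classes with tested numerics:

* mirror-symmetric spherical-cap electrode layouts with protected 10–20
  anchors and nested, distance-based channel reduction;
* the analytic three-shell concentric-sphere EEG forward model
  (per-harmonic boundary-value solution, V = Σₙ kₙ τⁿ⁻¹ Tₙ / (4πσ₁R²p₁²));
* DPSS multitaper band cross-spectral densities (K = ⌊2TW⌋ − 1 tapers at
  the band's centre bin);
* DICS beamforming (regularized real-CSD inverse, unit-gain filters at the
  dominant power orientation), source power and absolute imaginary
  coherency c_ij = S_ij/√(S_ii S_jj) as the connectivity measure;
* Freedman–Lane permutation GLMs with nuisance covariates, TFCE
  (E = 1, H = 2, dh = max/100) and max-statistic FWE control, with Cohen
  d = t·√(1/n₁ + 1/n₂);
* spin-test spatial correlations of effect-size maps (mirrored random
  rotations of the registration spheres), Fisher z and z-difference
  comparisons with BH-FDR control;
* a seeded synthetic-cohort generator: per-vertex narrowband stochastic
  sources, patient theta amplitude ratio 1.4 in active regions,
  90°-lagged interhemispheric theta coupling +0.3, head-scale jitter,
  spike-wave-like marked trials, age/sex/site covariates.

## A worked example

Simulate a small cohort, analyse the theta band at two montage densities
under both head models, and print the report:

```r
library(eegdens)

spec <- cohortSpec(nPatients = 4, nControls = 4, nChannels = 32,
                   verticesPerHemisphere = 42, nRegions = 8, nNetworks = 4,
                   samplingRate = 150, recordingLength = 100, seed = 3)
cfg <- runConfig(cohort = spec, channelSets = c(32, 19),
                 bands = defaultBands()["theta"],
                 nTrialsSelect = 3, nPerm = 99, nRotations = 99, seed = 5)
res <- runPipeline(cfg)
cat(writeReport(res), sep = "\n")
```

The report this prints (about 9 s on one core):

```
Group contrast (patients > controls), global source metrics
===========================================================

Band theta:
  connectivity  individual   32 ch: d =   2.30, p = 0.0700, q = 0.1400
  connectivity  individual   19 ch: d =   0.37, p = 0.3700, q = 0.3700
  power         individual   32 ch: d =  11.58, p = 0.0400, q = 0.0400 *
  power         individual   19 ch: d =   6.83, p = 0.0400, q = 0.0400 *
  connectivity  canonical    32 ch: d =   3.26, p = 0.0500, q = 0.1000
  connectivity  canonical    19 ch: d =   0.41, p = 0.3400, q = 0.3400
  power         canonical    32 ch: d =   6.70, p = 0.0400, q = 0.0500 *
  power         canonical    19 ch: d =   5.14, p = 0.0500, q = 0.0500 *

Spatial correlation with the full-montage effect-size map
(z-difference tests against parcel resolutions are approximate:
 all correlations share the reference map)

  connectivity  individual   19 ch: r =  0.04 (z =  0.04), p_spin = 0.8400
  power         individual   19 ch: r =  0.35 (z =  0.36), p_spin = 0.0800
  connectivity  canonical    19 ch: r =  0.12 (z =  0.12), p_spin = 0.4700
  power         canonical    19 ch: r =  0.27 (z =  0.28), p_spin = 0.0500 *

Individual vs canonical head model (effect-size maps)

  connectivity    32 ch: r =  0.91 (z =  1.52), p_spin = 0.0100 *
  connectivity    19 ch: r =  0.98 (z =  2.29), p_spin = 0.0100 *
  power           32 ch: r =  0.53 (z =  0.59), p_spin = 0.0100 *
  power           19 ch: r =  0.72 (z =  0.90), p_spin = 0.0100 *

Cohort balance: chi2(sex) = 0.00 (p = 1.00), F(age) = 0.00 (p = 1.00)
```

In the first block each line is one analysis cell: Cohen `d` for the
patient-minus-control contrast of the global source metric, its one-sided
permutation `p`, the BH-FDR-adjusted `q` across channel sets within the
band, and a `*` where `q <= 0.05`. Even in this toy cohort the injected
theta power effect is large and detected at both densities, while
connectivity — estimated from all vertex pairs — is noisier and loses its
contrast at 19 channels. The second block shows the same asymmetry
spatially: the 19-channel power effect-size map still correlates with the
full-montage map (r ≈ 0.3) while the connectivity map does not, and the
third block shows individual and canonical head models agreeing on the
effect topography — the package's central qualitative phenomena, visible
even at toy scale.

Lower-level entry points (`buildLayout`, `reduceLayout`,
`buildSourceSpace`, `computeLeadfield`, `computeBandCsd`,
`computeDicsFilters`, `computeSourcePower`, `computeSourceConnectivity`,
`permutationGlm`, `tfceTransform`, `spinTest`, `compareCorrelations`, ...)
are documented individually; the methods vignette
(`vignettes/channel-density-methods.Rmd`) explains the models, defaults and
design decisions.

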