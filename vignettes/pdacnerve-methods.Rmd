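---
title: "Quantifying sympathetic innervation in pancreatic cancer models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sympathetic innervation in pancreatic cancer models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdacnerve)
```

# Scope

`pdacnerve` implements the quantitative core of a light-sheet-microscopy
study of sympathetic nerve remodelling during pancreatic ductal
adenocarcinoma (PDAC) progression in mouse models: whole-organ nerve
volumetrics, axon--blood-vessel morphometry with multivariate staging of
tissue samples, a hierarchical Bayesian Gompertz model for longitudinal
tumor growth curves, and the survival endpoints used to compare treatment
arms and patient expression groups. Because the original animal and patient
data are not deposited, every stage is validated against synthetic data
with planted ground truth; the generators are first-class, tested code.

# Volumetrics

All volumes use voxel-centre membership: a voxel belongs to a structure iff
its binary mask value is set, and volume is voxel count times voxel volume.
There is no partial-volume weighting and no mesh reconstruction -- inputs
are binary segmentation masks (multi-page TIFF, voxel size in micrometres
in a JSON sidecar), and every estimator is checkable against a per-voxel
loop.

`nerveVolumePartition()` splits the total nerve volume `V_TH_TOTAL` against
a tumor mask contained in the organ mask, reporting the intratumoral
density `V_TH_INTRA / V_PDAC`, the extratumoral density
`(V_TH_TOTAL - V_TH_INTRA) / (V_Panc - V_PDAC)` and the percentage of nerve
volume inside the tumor. Ratios with zero denominators are `NA` (flagged
undefined), never errors; a tumor voxel outside the organ is an error that
reports the offending voxel count. The nerve mask is assumed to be already
restricted to the organ, matching the upstream editing step that removes
extra-pancreatic nerve trunks.

`sectionalNerveFraction()` profiles nerve density along the head-to-tail
axis on `nLevels` (default 10) equidistant slabs of the organ's occupied
extent. Slabs are half-open index intervals with the last slab closed, so
they partition the organ exactly once; per slab the statistic is
`100 * (nerve voxels) / (organ voxels)`. A fixed physical slab thickness is
not enforced: equidistant index slabs reproduce the equidistant optical
levels used for the published profiles whatever the acquired extent.

# Skeletonization and morphometry

Tubular masks are reduced to centreline graphs by topology-preserving
thinning implemented in C++: iterative removal of *simple points*
(points whose deletion provably preserves both foreground 26-connectivity
and background 6-connectivity, tested by direct flood fill over the
3x3x3 neighbourhood) in six directional sub-iterations, keeping curve
endpoints. The resulting voxel chains become a graph: 26-connected
clusters of junction voxels collapse to single nodes, terminal spurs
shorter than the pruning length (default 3 voxel edges -- the scale of
thinning artifacts on rasterized tubes) are removed, short
junction-junction edges are contracted (one anatomical branch point can
thin to two nearby junction voxels), and pass-through nodes are merged so
that one edge corresponds to one anatomical branch. Edge length is the sum
of inter-voxel Euclidean steps in physical units.

The 12-variable profile of a tissue sample covers axon density and
branching (variables 1--4), vessel density and calibre (5--6), and the
axon--vessel contact architecture (7--12). Two conventions matter:

* **Surface area** is exposed-face counting: each mask voxel contributes
  its number of face-adjacent background voxels (the image border counts
  as background) times the voxel face area. This overestimates the area of
  a smooth surface by the lattice factor 3/2; ratios of areas (the contact
  percentages) are unaffected.
* **Contact** at distance `d` (default 2 um, about one voxel at the
  generator resolution; the mesh tool used for the published analysis has
  no stated distance, so an explicit voxel-native threshold is required):
  a surface voxel is in contact when its centre lies within `d` of a
  surface-voxel centre of the other structure, computed by an exact
  Euclidean distance transform. Contact zones are 26-connected components
  of the axon-side contact voxels. The "total contact area" (variable 11)
  averages the axon-side and vessel-side contact areas, which makes it
  exactly symmetric under swapping the two masks.

Vessel calibre is the mean distance transform at centreline voxels: the
EDT to the nearest background centre overshoots the continuous radius by
about half a voxel while the thinned centreline sits off-axis by about the
same amount, so the raw EDT is reported without correction. The median
axon-to-vessel distance (variable 12) samples the vessel-surface distance
transform at axon skeleton voxels.

# The synthetic tissue phantom

`generateTissuePhantom()` draws continuous geometry first and rasterizes
it second, so the ground truth is computed before voxelization. Vessels
and free axon trunks are correlated random walks inside a margin box;
*aligned* axon trunks (the periacinar pattern of healthy tissue) follow a
vessel's centreline at a fixed surface gap (default 0: touching). Branch
points are Poisson-placed along trunks with a class-dependent rate,
hotspot sprouting multiplies that rate. Tubes are rasterized as capsules
(voxel centres within the radius of any centreline segment).

Several generator-side constraints keep the planted truth recoverable by
construction rather than by luck:

* one aligned axon per vessel, and rejection sampling keeps any two axon
  tubes (and any two vessels) at least one tube diameter plus one voxel
  apart -- fused tubes would create junctions the truth record cannot
  know;
* branch points stay 6 um clear of trunk ends and of each other, above the
  spur-pruning and junction-contraction scales;
* vessels shorter than 40 um are redrawn (a blob is not a vessel).

The truth record emulates what the voxel estimators measure, not the
idealized continuum: tube volumes include the capsule end caps; absolute
areas carry the 3/2 lattice factor; contact is scored softly, with
`P(contact | gap g) = P(S <= d - g)` where `S`, the sum of the two
surface-voxel centre insets, is triangular on `[0, 2s]` (each inset is
roughly uniform over a voxel); and zones are connected components of the
3D contact point cloud merged at a two-voxel cell, mirroring how
26-connected voxel zones join patches that meet anywhere in space.

Per-variable tolerances reflect these discretization arguments: 25% on
densities and radius, 30--40% on branch statistics, 15 percentage points
on the contact percentages, 75% on zone counts/areas, and
`max(3 um, 35%)` on the median axon-to-vessel distance -- the last is a
median of a bimodal (aligned versus free axon) distribution and is
intrinsically unstable at single-phantom scale. Across 3 tissue classes
and 16 seeds, 575 of 576 truth cells pass these tolerances; the residual
failures are zone-count flips on single phantoms.

The class presets (`tissueClassSpec()`) encode the study's qualitative
contrasts: control/asymptomatic tissue has vessel-aligned axons with few
long branches; noninvasive neoplastic lesions (NF/ADM/PanIN) have denser
axons with more, shorter branches (sprouting hotspots), reduced
axon-vessel alignment and enlarged vessels; invasive tumor regions have
intermediate density with lesion-like contact changes. What the phantoms
do *not* emulate: image noise and segmentation errors, curvature-dependent
axon calibre, lumenized epithelial structures, and real periacinar
micro-anatomy -- passing round-trip tests therefore demonstrates estimator
correctness on clean geometry, not robustness to segmentation quality.

# Staging statistics

Z-scores follow the control-referenced definition
`z = (xbar - xbar_c) / sigma_c` per variable, with the class mean in the
numerator and the control mean and sample standard deviation (n - 1
denominator, hence at least two control samples) in the reference. The
control row is identically zero; a zero control standard deviation flags
the variable `NA`.

PCA centres (and by default unit-variance scales) the variables; the sign
of each component is fixed by making its largest-magnitude loading
positive. Clustering is Ward (`ward.D2`) on Euclidean distances of
standardized variables, cut at `k = 3` -- the published analysis names
neither linkage nor metric, so the choice is stated here and in the
configuration rather than hidden. Variables containing undefined cells are
excluded from PCA and clustering with a message (an explicit policy in
place of silent imputation; dropping whole variables keeps the geometry of
the remaining space exact, which pairwise deletion would not). Cluster
recovery is scored by the adjusted Rand index against reference labels.

# The hierarchical Gompertz growth model

The log bioluminescence of mouse $i$ at day $t$ is modelled as

$$\log y_i(t) = \log b_i + e^{-a_i t}\,(z_{0i} - \log b_i) + \varepsilon,$$

with plateau $\log b_i$ (the log signal as $t \to \infty$), rate $a_i$
(how fast the log curve reaches its plateau, 1/day) and nuisance initial
level $z_{0i}$. Group structure enters through
$\log b_i = \overline{\log b}_{g(i)} + \eta^b_i$ and
$a_i = \overline{a}_{g(i)} + \eta^a_i$ with normal mouse effects whose
variances are shared across groups and estimated. The code computes the
mean as $z_0 + (1 - e^{-at})(\log b - z_0)$, algebraically identical but
exact at $t = 0$ in floating point.

A plain normal mouse effect on $a_i$ puts non-negligible mass on negative
rates under realistic settings (mean 0.35, sd 0.3 gives about 12%), and a
negative rate makes the log curve diverge. Both the generator and the
model therefore truncate the mouse-level (and group-level) rate at zero --
one mechanism on both sides, so the generator and the fitter share one
likelihood and the planted truth always has finite density.

Priors are weakly informative and scale-aware, recorded in the fit object:
group plateau means are normal around the data maximum with sd 5; group
rate means are half-normal(1); $z_{0i}$ is normal around the mean first
observation with sd 5; all standard deviations are half-normal(1). Raw
(non-logged) input is floored at a configurable detection limit before the
log transform, with a message.

The posterior is sampled by MCMC through JAGS (4 chains, 2000 warmup and
2000 kept draws per chain by default; every chain's RNG is derived from
the mandatory seed, so fits are exactly reproducible). Convergence is
summarized by split-R̂ (each chain halved) and effective sample size, and
the fit fails loudly -- configurably an error, warning, or silent -- when
split-R̂ exceeds 1.01. At the default layout the study-condition cohorts
(2 groups x 10 mice x 8 days) fit in a few seconds on one CPU.

Group comparison reports the draw-wise posterior probability that the
second group's parameter exceeds the first's (ties count one half); both
the plateau and the rate marginals are reported, since the published
analysis is ambiguous about which one-sided contrast its probability
refers to. Bivariate highest-posterior-density regions of
(plateau mean, rate mean) are computed from a kernel density estimate:
grid cells are ranked by density and the level absorbing the requested
mass defines the region, so higher-probability regions contain
lower-probability ones by construction; marginal summaries follow the
boxplot convention with 1.5 IQR whiskers shortened to the most extreme
draw. Posterior predictive bands report central 0.5 and 0.95 intervals of
the mouse-level mean curve, optionally widened by the residual noise
(flagged in the output).

Calibration under the null (identical group specifications) was checked by
simulation: across replicate cohorts the median group-difference
probability sits near 0.5 and 90% credible intervals cover the planted
plateau mean at nominal-compatible rates; the acceptance script recomputes
a scaled-down version of this check.

# Survival endpoints

The Kaplan-Meier estimator, the Mantel-Cox (log-rank) test and the O/E
hazard ratio are computed from first principles -- their conventions are
part of the interface -- with the survival package as an independent
cross-check in the test suite. Conventions: censored records tied with an
event time remain at risk for that event; the median is the smallest time
at which survival drops to 0.5 or below (undefined when the curve never
does); the hazard-ratio pair is `HR(B/A) = (O_B/E_B)/(O_A/E_A)` and its
exact reciprocal, matching the paired reporting of the published legends.
The O/E estimator shrinks ratios away from unity (a Cox model would not,
but Cox regression is out of scope), which is why simulation recovery of a
true ratio of 2.7 at 30 mice per arm is asserted within 30%, not tighter.

The expression cutpoint search scans every observed marker value between
the 10th and 90th percentiles, splits the cohort at each candidate and
returns the threshold maximizing the log-rank statistic (smallest value on
ties). The maximum of many correlated statistics is biased; the output
carries an explicit selection-bias warning and no corrected p-value is
offered. Threshold recovery converges at the cube-root rate typical of
maximally-selected statistics, so the planted-threshold test asserts
recovery within 0.15 at n = 60 rather than at observation-gap resolution.

# Pipeline and reproducibility

`runPipeline()` chains the stages (simulate tissue/organ/growth/survival,
morphometry, staging, growth fit, survival analysis) from a YAML or JSON
configuration with one global seed; each stage derives its own seed from a
hash of its name, so adding a stage does not shift the randomness of the
others. Every produced file is listed in a manifest with its MD5 hash and
the resolved configuration; rerunning with the same configuration and seed
reproduces identical hashes, which the test suite asserts byte-for-byte.

Problem sizes used by the tests and the acceptance script -- 96-voxel
phantom grids, 64-voxel pipeline demos, 10 mice per group, 10-20 replicate
cohorts at 2 chains x 800 draws, 2000 null replicates for the log-rank
type-I check -- were chosen so the whole validation runs in minutes on one
CPU while keeping every Monte-Carlo criterion comfortably inside its
sampling error.

# Known limitations

* Generators produce isotropic voxels only; readers accept anisotropic
  voxel sizes, but contact statistics and profiles require isotropy.
* Exposed-face surface areas are lattice-metric quantities; compare them
  only with other face-counted areas (the 3/2 factor cancels in ratios).
* The skeleton is a curve skeleton: sheet-like structures would thin to
  curves, so the morphometry applies to tubular networks only.
* The truth model for contact-zone counts is an emulation; on single
  phantoms a zone-count flip against its 75% tolerance occurs at the
  percent level.
* NRRD input, mesh-based surface reconstruction, intensity-based
  segmentation, Cox regression and growth-law model selection are out of
  scope.
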