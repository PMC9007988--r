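# pdacnerve

Quantitative analysis of sympathetic innervation in mouse models of
pancreatic ductal adenocarcinoma (PDAC), for labs doing whole-organ
light-sheet imaging of cleared pancreata and longitudinal tumor monitoring.
The package covers the four quantitative stages of such a study:

1. **Whole-organ nerve volumetrics** — partition of the segmented
   sympathetic (TH+) nerve volume against the tumor surface
   (`V_TH_INTRA / V_PDAC` intratumoral density,
   `(V_TH_TOTAL − V_TH_INTRA) / (V_Panc − V_PDAC)` extratumoral density)
   and sectional density profiles along the head-to-tail axis.
2. **Axon–vessel morphometry** — topology-preserving 3D skeletonization of
   axon and vessel masks and a 12-variable profile per tissue sample: axon
   density and branching, vessel density and calibre, and the axon/vessel
   surface-contact architecture (`% Contact axon/BV`, `% Contact BV/axon`,
   contact-zone count and size, interface area, axon-to-vessel distance).
3. **Multivariate staging** — control-referenced Z-scores
   (`z = (x̄ − x̄_c) / σ_c`), PCA and Ward hierarchical clustering that
   stage tissue samples into innervation groups
   (control/asymptomatic → noninvasive lesions → invasive tumor).
4. **Growth and survival** — a hierarchical Bayesian Gompertz model for
   log-bioluminescence curves,
   `log y_i(t) = log b_i + e^{−a_i t}(z_{0i} − log b_i) + ε`, with group
   means on the plateau `log b` and rate `a`, mouse-level random effects,
   MCMC inference (JAGS), posterior group-difference probabilities and
   HPD credible regions; plus Kaplan–Meier / log-rank / O-over-E
   hazard-ratio endpoints and a maximally-selected expression cutpoint.

A synthetic-data module generates tubular axon/vessel phantoms, organ
volumes, growth cohorts and survival cohorts with planted ground truth, so
the whole pipeline is testable end to end without animal data. See the
methods vignette (`vignettes/pdacnerve-methods.Rmd`) for the models,
conventions and design decisions.

## Worked example

Generate a noninvasive-lesion phantom, profile it, and inspect the skeleton:

```r
library(pdacnerve)

ph <- generateTissuePhantom(tissueClassSpec("PanIN", seed = 1))
ph$axon
#> VolumeMask: 96 x 96 x 96 voxels, 1 x 1 x 1 um/voxel
#>   foreground: 10570 voxels ( 10570 um^3 )

skeletonize(ph$axon)
#> NetworkSkeleton: 67 nodes, 58 edges
#>   total length: 874.54 um; branch points (degree >= 3): 24

pr <- morphometricProfile(ph$axon, ph$vessel,
                          sampleId = "PanIN_1", class = "PanIN")
round(t(pr[, -(1:2)]), 2)
#> axon_volume_density_pct              1.19
#> axon_branch_count_per_mm3        65556.28
#> axon_mean_branch_length_um          15.08
#> axon_branchpoint_count_per_mm3   27126.74
#> vessel_volume_density_pct            2.57
#> vessel_mean_radius_um                4.70
#> contact_axon_bv_pct                 19.25
#> contact_bv_axon_pct                 17.73
#> contact_zone_count_per_mm2         505.50
#> contact_zone_mean_area_um2         380.75
#> contact_area_per_mm3           3185130.93
#> axon_vessel_median_distance_um       6.56
```

The profile reads as: axons fill 1.19% of the tissue, fragmented into many
short branches (about 66,000 branches/mm³ of mean length 15 µm with 27,000
branch points/mm³ — the sprouting signature of neoplastic lesions), while
only 19% of the axon surface remains in contact with blood vessels. Each
phantom also returns `ph$truth`, the planted value and tolerance for all
12 variables, which the estimators recover (the test suite asserts this
round trip per tissue class).

Survival endpoints print the paired hazard ratios used in two-group
comparisons:

```r
lr <- logrankHazardRatio(c(1, 3), c(1, 1), c(2, 4, 5), c(1, 0, 1))
#> chisq = 1.591, p = 0.207, HR(B/A) = 0.326, HR(A/B) = 3.068
```

Pipelines chain the stages from one YAML/JSON configuration with a single
seed (`runPipeline()`); every output file is hashed into a manifest and
reruns are byte-identical.

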