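# fibermorph

Instance morphometry of myelinated white-matter fibers in two-dimensional
electron-microscopy sections.

A myelinated fiber appears in section as an axon cross-section wrapped in a
myelin sheath. Three numbers summarise it: the axon diameter *d*, the outer
fiber diameter *D*, and the g-ratio *g = d/D*. fibermorph implements the
quantitative chain that turns a semantic background/axon/myelin probability
map into those numbers, fiber by fiber, and then into population statements:

1. **Instance segmentation** — per-pixel argmax thresholding, binary
   clean-up, then a distance-transform watershed that separates touching
   ("kissing") sheaths, followed by a plausibility filter with
   machine-readable rejection reasons.
2. **Ellipse morphometry** — each region is summarised by the ellipse with
   the same normalized second moments. The minor axis of an oblique
   elliptical cut of a tube equals the true tube diameter at any cut angle,
   so minor axes are the diameter estimates and
   *g* = minor(axon) / minor(outer fiber) is cut-angle invariant.
   Alternative estimators (equivalent-circle diameter, skeleton-based
   myelin thickness) are computed alongside.
3. **Population modeling** — Bayesian fits of the generalized extreme value
   (GEV) distribution *G(x) = σ⁻¹ t^{ξ+1} e^{−t}*,
   *t = (1 + ξ(x−µ)/σ)^{−1/ξ}*, to diameter samples, with 99% HPD
   intervals, split-R̂/ESS diagnostics and predictive checks.
4. **Conduction velocity** — the generalized Rushton relation
   *v = s·gD·(−ln g)^α* with *s* = 7.5 µs⁻¹ and *α* = 0.68 (or the
   data-derived *α* = −ln g), plus internode-length and travel-time
   helpers.
5. **Validation** — IoU/Dice/95th-percentile Hausdorff distance, one-to-one
   instance matching with a 40% overlap rule and FP/FN accounting, and
   Bland–Altman agreement with size-stratified error.
6. **Phantom generator** — synthetic populations of obliquely cut tubular
   fibers with GEV diameters, configurable g-ratio and cut-angle laws, and
   degradation artifacts (myelin gaps, kissing pairs, boundary noise,
   blur), with exact ground truth for every stage above.

It is aimed at quantitative neuroanatomy groups measuring axon and myelin
geometry at scale, and at method developers who need a ground-truthed
harness for segmentation-derived morphometry.

## Worked example

```r
library(fibermorph)

# a 60-fiber phantom with known ground truth
cfg <- phantom_config(fiber_count = 60, canvas = c(1024, 1024), seed = 7,
                      g_ratio_law = c(mean = 0.54, sd = 0.04))
ph <- generate_phantom(cfg)

# segment: threshold -> binary clean-up -> distance-transform watershed
masks <- threshold_semantic(ph$semantic)
inst <- separate_instances(masks$axon, masks$myelin,
                           pixel_size_nm = cfg$pixel_size_nm)
length(instance_ids(inst))
#> [1] 60

# measure and filter
records <- filter_instances(measure_instances(inst))$kept
summary(records[, c("axon_minor_um", "outer_minor_um", "g_ratio")])
#>  axon_minor_um    outer_minor_um      g_ratio
#>  Min.   :0.2835   Min.   :0.5310   Min.   :0.4445
#>  Median :0.5376   Median :1.0250   Median :0.5405
#>  Mean   :0.6410   Mean   :1.1964   Mean   :0.5399
#>  Max.   :1.6551   Max.   :3.2342   Max.   :0.6081

# fit the diameter distribution
fit <- fit_gev(records$axon_minor_um, seed = 1)
fit
#> Bayesian GEV fit (4 chains x 1000 draws, sampler: independence)
#>   n = 60 observations
#>         mean      sd hpd99_lower hpd99_upper  rhat  ess
#> mu    0.5066 0.02344     0.44741      0.5689 1.001 1936
#> sigma 0.1638 0.02096     0.11944      0.2240 1.000 1892
#> xi    0.2330 0.09786    -0.02133      0.4859 1.003 2068

# conduction velocities (m/s) from each fiber's D and g
records <- fiber_velocities(records)
median(records$v_mps)
#> [1] 2.973359

# validate against the phantom's ground truth
mt <- match_instances(inst, ph$instances)
mt
#> match_result: 60 matched pairs, 0 FP, 0 FN
paired_agreement(records, measure_instances(ph$instances),
                 mt$pairs, "g_ratio")
#> agreement [g_ratio]: n = 60, bias = 5.794e-05,
#>   LoA = [-0.0004502, 0.0005661], MAE = 7.128e-05
```

All 60 fibers are recovered as distinct instances, the population mean
g-ratio lands on the configured 0.54, the GEV posterior covers the
generator's (µ = 0.5, σ = 0.15, ξ = 0.1) law, and the per-fiber g-ratio
agreement against ground truth is at the 10⁻⁴ level — the measurement chain
itself adds essentially no error on clean input.

Closed-form helpers work standalone:

```r
derive_alpha(0.54)             # 0.616 -> alpha = 0.62 at the observed mean g
conduction_velocity(0.94, 0.54) # 2.74 m/s for a median SWM fiber
travel_time(0.04, 2.7)          # 14.8 ms across a 4-cm association fiber
```

A thin command-line wrapper with `phantom`, `segment`, `measure`,
`fit-gev`, `velocity`, `validate` and `run` subcommands is installed at
`inst/cli/fibermorph`.

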