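# nvumorph

Morphometry of the retinal neurovascular unit (NVU) from segmented 3D
electron-microscopy stacks.

Serial block-face scanning electron microscopy (SBF-SEM) images retinal
capillaries at ~6 nm/pixel in-plane with 100 nm serial sections, and
segmentation assigns each voxel an NVU role: lumen, endothelium, vascular
basement membrane (BM), pericyte, macroglia, endothelial tubule, or
electron-lucent background. `nvumorph` turns such label volumes into the
quantities used to compare non-diabetic and diabetic capillaries:

* **BM thickness** — per-section 2D local thickness of the BM shell. Local
  thickness at a point is the diameter of the largest disc fully inside the
  shape covering that point; it is computed from the Euclidean distance
  transform with the fixed convention *diameter = 2·EDT − 1* pixels,
  sampled on the distance ridge (discrete medial axis), and aggregated to a
  per-stack mean and maximum.
* **Peg-and-socket formations** — pericyte protrusions crossing the BM into
  endothelial invaginations, found as 3D connected components
  (26-connectivity on the anisotropic grid) of pericyte voxels inside the
  capillary-wall envelope, with attached vs partially-detached state read
  from the electron-lucent space in the socket.
* **Cell–BM detachments** — lucent clefts adjacent to both a cell
  (endothelium, pericyte or macroglia) and the BM, with width and
  persistence thresholds.
* **Endothelial tubules** — tubule components classified as closed,
  luminal, abluminal or transendothelial by surface adjacency.
* **Normalisation and statistics** — counts per 10 µm capillary depth
  (depth = sections × 100 nm); mean ± SEM; unpaired two-tailed pooled t
  test or Mann–Whitney U (exact by enumeration for small tie-free samples).

Because raw EM stacks are large external data, the package includes a
**synthetic phantom generator**: capillary cross-section stacks with an
analytically known BM thickness field
w(θ, z) = base + amplitude·sin(k·θ + 2πz/z_period) and a planted-feature
inventory that serves as exact ground truth. All detectors and the
thickness estimator are validated against phantoms, and simulated cohorts
(Poisson per-capillary counts, 9 capillaries per group) validate the
statistical layer.

## Worked example

```r
library(nvumorph)

sp <- phantomSpec(nSlices = 30,
  pegs = rbind(pegFeature(8, 0.6),
               pegFeature(15, 1.6, state = "partially_detached")),
  detachments = detachmentFeature("endothelium", 22, 4.0, gap_nm = 24),
  tubules = rbind(tubuleFeature(6, 5.5, opening = "closed"),
                  tubuleFeature(25, 3.0, opening = "luminal")))
ph <- generatePhantom(sp)

summarizeCapillary(ph$volume, ph$roleMap)
#> CapillaryMetrics: depth 3.00 um (30 slices), 5 events
#>  feature_type            subtype count freq_per_10um
#>    peg_socket                all     2      6.666667
#>    peg_socket           attached     1      3.333333
#>    peg_socket partially_detached     1      3.333333
#>    detachment                all     1      3.333333
#>    detachment        endothelium     1      3.333333
#>    detachment           pericyte     0      0.000000
#>    detachment          macroglia     0      0.000000
#>        tubule                all     2      6.666667
#>        tubule             closed     1      3.333333
#>        tubule            luminal     1      3.333333
#>        tubule          abluminal     0      0.000000
#>        tubule   transendothelial     0      0.000000

stackThickness(ph$volume, ph$roleMap)
#> ThicknessProfile: 19599 samples over 30 slices (0 skipped)
#>   aggregate mean 97.8 nm, max 102.0 nm
```

Every planted feature is recovered with its state and opening class; the
102 nm BM shell (17 pixels at 6 nm/pixel) measures a maximum of exactly
102 nm and a mean within one voxel of truth. Group comparison on a
simulated 9-vs-9 cohort (control vs a diabetic-like effect — pegs ×0.4,
detachments ×6, tubules ×2.5):

```r
ctl <- makeCohort(cohortTemplate(), 9, rngSeed = 1, metricsOnly = TRUE)
dia <- makeCohort(cohortTemplate(), 9, effect = diabeticEffect(),
                  rngSeed = 2, metricsOnly = TRUE)
mt <- rbind(cohortMetricsTable(ctl, "non_diabetic"),
            cohortMetricsTable(dia, "diabetic"))
compareMetricTable(mt, "peg_per_10um")
#> student_t_unpaired (pooled_variance): non_diabetic vs diabetic
#>   non_diabetic: mean 3.481 +/- 0.3731 SEM (n=9)
#>   diabetic: mean 1 +/- 0.1571 SEM (n=9)
#>   statistic 6.129, two-tailed p = 1.453e-05 ***
```

The end-to-end pipeline (cohort simulation → detection → thickness →
comparisons → JSON/CSV report) is `runPipeline()`, also exposed as a thin
command line in `inst/scripts/nvumorph.R` with subcommands `phantom`,
`thickness`, `features`, `compare` and `run`.

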