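---
title: "Quantifying the retinal neurovascular unit in segmented 3D EM: methods and design"
author: "nvumorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the retinal neurovascular unit in segmented 3D EM: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nvumorph)
```

## The measurement problem

Serial block-face scanning electron microscopy (SBF-SEM) of retinal
capillaries yields aligned stacks of 130–300 sections at roughly 6 nm/pixel
in-plane and a 100 nm z-step. After segmentation, each voxel carries a label
for its neurovascular-unit (NVU) role: capillary lumen, endothelium,
basement membrane (BM), pericyte, macroglia, intracytoplasmic endothelial
tubule, or electron-lucent background. `nvumorph` quantifies such label
volumes:

1. **BM thickness** — mean and maximum local thickness of the BM shell,
   measured per 2D section;
2. **Peg-and-socket formations** — pericyte protrusions crossing the BM
   into endothelial invaginations, classified as attached or partially
   detached by the lucent space in the socket;
3. **Cell–BM detachments** — electron-lucent clefts between the BM and the
   endothelium, pericytes or macroglia;
4. **Endothelial tubules** — tubule-labeled components classified by
   opening topology (closed, luminal, abluminal, transendothelial);
5. **Group statistics** — per-capillary metrics normalised per 10 µm of
   capillary depth, compared between groups as mean ± SEM with unpaired
   two-tailed tests.

Because the biological stacks are external data, the package ships a
synthetic phantom generator with analytic ground truth; every detector and
the thickness estimator are validated against phantoms whose true answer is
known by construction.

## Data model and coordinate conventions

A `LabelVolume` is an integer array with dimensions `(y, x, z)`; slice `k`
is page `k` of the corresponding multi-page TIFF. Voxel sizes are carried as
`(dz, dy, dx)` in nanometres, default `(100, 6, 6)`, and the axial
anisotropy is preserved throughout — nothing is ever resampled to isotropy.
Voxel sizes live in the YAML/JSON role-map sidecar rather than in TIFF
tags: TIFF resolution dialects are ambiguous enough across writers that we
treat any tags as untrustworthy and ignore them. TIFF plus sidecar is the
package's one canonical interchange format.

Label 0 is always `background`: electron-lucent or unsegmented space. The
lucent gaps that constitute detachment events are therefore simply
background voxels in the right place, exactly as an annotator would leave
them unlabeled.

## BM thickness: 2D local thickness with a fixed disc convention

Local thickness at a point of a shape is the diameter of the largest disc
fully inside the shape that covers the point. We measure it per section,
not with 3D spheres: at 100 nm z-step versus 6 nm pixels a 3D sphere is
dominated by the axial direction and systematically underestimates a shell
~100 nm thick. "Thickness" here is consequently the in-plane thickness of
the BM ring in each cross-section.

The implementation uses the Euclidean distance transform (EDT; distance
from a foreground pixel centre to the nearest background pixel centre) and
the fixed odd-diameter convention

> diameter = 2·EDT − 1 pixels,

so a one-pixel-wide ring measures exactly one voxel (6 nm) and a 17-pixel
shell measures 102 nm. The full local-thickness map is built by sweeping
the distinct EDT values in decreasing order and painting each maximal disc
with one morphological dilation; this is exactly equivalent to the
exhaustive disc search, which the package also ships
(`bruteForceLocalThickness`) as an independent O(n²) oracle and which the
test suite compares against on random masks. The image frame is treated as
surrounded by background in both paths.

**Sampling.** Thickness samples are taken at the EDT ridge — pixels whose
EDT is a local maximum over the 8-neighbourhood — rather than at all mask
pixels. Ridge sampling weights the shell by its length instead of its
area, so thick sectors are not over-represented in the mean; and unlike an
iterative thinning skeleton it is exactly invariant under 90° rotations,
flips and translations, which the tests assert on random masks. Slices with
a fragmented BM are measured in a single EDT pass, which is equivalent to
per-component measurement with pooling because discs cannot cross
background.

**Aggregation.** The per-stack mean is the pooled (sample-count-weighted)
mean over sections; the maximum is the global per-stack maximum sample.
Sections with an empty BM mask are skipped with a warning and listed in the
profile; only a stack with no BM at all is an error.

**Accuracy.** On rasterised phantoms the convention recovers uniform shells
of 60, 102 and 160 nm to within one in-plane voxel (6 nm) for both mean and
maximum, and a sinusoidally modulated shell (base 120 nm, amplitude 40 nm)
to within one voxel of its quadrature mean and maximum. Two systematic
effects are worth knowing: boundary discretisation costs up to ±1 pixel,
and the odd-diameter convention reads an even-width band one pixel low, so
phantom thicknesses that are odd pixel multiples (e.g. 102 nm = 17 px)
measure exactly.

## Feature detection

Features are 3D connected components in voxel space with 26-connectivity.
z-neighbouring voxels are 100 nm apart, which we accept deliberately: real
formations persist across sections, and 6-connectivity fragments thin pegs.
All surface-adjacency tests (opening classes, gap contacts) are in-plane
face adjacency only; z-only contact never counts, again because of the
anisotropy. One component = one event, regardless of z-extent: we count
formations, not sections.

**Peg-and-socket formations.** The capillary-wall interior is defined as
the hole-filled in-plane morphological closing of
(endothelium ∪ lumen ∪ BM) with a 5-pixel-radius disc. The closing seals
the narrow channel a peg bores through the BM, so hole-filling captures
the socket, its lucent space and the BM-crossing part of the peg without
bridging to unrelated structures. A peg event is a pericyte component
inside this envelope that touches the BM in-plane. Its attachment state is
decided by the lucent (background) space in contact with it inside the
envelope: if that space has in-plane width ≥ `lucent_gap_threshold_nm`
(default 12 nm, two pixels), the peg is partially detached. Lucent widths
use the same 2·EDT−1 convention as thickness.

**Detachments.** A detachment is a background component that is in-plane
adjacent to both the target cell and the BM, at least
`min_gap_width_nm` (12 nm) wide, at most `max_gap_width_nm` (90 nm) wide,
and persistent over ≥ `min_z_slices` (2) sections. The upper width bound
distinguishes a thin detachment cleft from open extracellular space, which
can also touch both a cell and the BM near the edge of a pericyte arc.
Socket-interior lucent voxels already claimed by a peg event are excluded
before component analysis, so no lucent voxel is ever counted twice.

**Tubules.** Tubule components are classified by surface adjacency:
`luminal` if touching the lumen, `abluminal` if touching the BM,
`transendothelial` if both — a complete through-channel — and `closed`
otherwise. The transendothelial count is reported as an explicit field so
that "no complete channels" is a single-number check at pipeline level.

**Thresholds.** `min_voxels = 20`, `min_z_slices = 2`,
`lucent_gap_threshold_nm = 12`, `min_gap_width_nm = 12`,
`max_gap_width_nm = 90`, `closing_radius_px = 5`. These are declared
defaults of this implementation, all exposed in configuration; they are not
taken from any published criterion list. Events touching the first or last
section are counted and flagged `boundary = TRUE` so downstream analyses
can censor them if desired.

**Normalisation.** Capillary depth is `nSlices × dz`, and every frequency
is `count × 10 µm / depth`. A stack that meanders obliquely through the
block would be longer than `nSlices × dz`; the package equates depth with
the axial extent, consistent with phantoms whose capillary axis is aligned
with z.

## The phantom generator

Phantoms are capillary cross-section stacks built in physical nanometres
and rasterised by centre sampling (a voxel belongs to a structure iff its
centre lies in the structure's analytic region), which keeps
analytic-versus-measured comparisons predictable to ±1 voxel. Geometry:
lumen disc, endothelial annulus, BM shell with thickness field

$$w(\theta, z) = \mathrm{base} + \mathrm{amplitude}\cdot
\sin(k_\theta \theta + 2\pi z / z_{\mathrm{period}}),$$

a pericyte arc seated on the BM, and optionally a macroglial wrap over the
remaining surface. `analyticThicknessSummary()` integrates \(w\) by
quadrature independently of any rasterisation and is the thickness oracle.

Planted features mirror the real structures: pegs are pericyte rods from
the pericyte body through the BM into the endothelial band (shaft radius at
least two pixels so detection is never voxel-limited); partially detached
pegs get a background shell of the requested gap width inside the socket;
detachments are background bands carved between the target cell and the
BM over a (z, arc) window; tubules are rods inside the endothelium whose
radial extent reaches neither, one, or both surfaces according to the
opening class. The spec validates that features are pairwise
non-overlapping in (z, arc) and that every feature geometrically fits; the
ground truth inventory equals what was actually planted, exactly.
Generation is deterministic — regeneration is bit-identical — and an
optional Gaussian boundary-jitter flag (default off) roughens the
interfaces for robustness exercises.

The default cross-section (lumen radius 700 nm, endothelium 250 nm,
BM 102 nm, pericyte/macroglia 150 nm) is a scaled-down but anatomically
shaped capillary chosen to fit a 512² field at 6 nm/pixel; scaling the
cross-section down does not change what is being validated (ring topology,
shell widths in voxels, feature contact relations), and it keeps every
validation run tractable on one CPU.

**What the phantoms do not emulate:** grayscale EM texture, segmentation
errors, oblique or meandering capillary axes, and features that straddle
the stack boundary. Passing the phantom suite therefore demonstrates that
the measurement and detection chain is correct on clean label volumes with
z-aligned geometry; it does not certify robustness to segmentation noise.
That is the appropriate scope for validating the quantification step, which
consumes finished segmentations.

## Simulated cohorts and their statistics

`makeCohort()` mirrors the study design: n capillaries per group, one stack
each, per-stack feature counts Poisson-distributed around group means, and
a diabetic-like group defined by effect multipliers on the control means.
The frozen study conditions are: 300-section stacks (30 µm, the upper end
of the 130–300 range, which maximises per-capillary information), control
means of 9 pegs (3.0 per 10 µm, one in ten partially detached), 0.6/0.6/0.3
endothelial/pericyte/macroglial detachments, and 9 tubules (7 closed, 1
luminal, 1 abluminal, 0 transendothelial) per stack; the diabetic-like
multipliers are 0.4 for pegs, 6 for detachments and 2.5 for tubules, with
half the diabetic pegs partially detached. The BM base thickness varies
between capillaries with an 8 nm SD (~8% biological variability) and is
identical in law between groups, so the thickness comparison has a
realistic, non-degenerate null. These values were fixed once by a
design-stage power analysis targeting >95% power at 9 vs 9 capillaries and
were not adjusted afterwards.

Large simulation studies (type-I error over 1000 replicates, power over
200) run in `metricsOnly` mode: per-capillary metrics are taken from the
generative ground truth without rasterising volumes. This is a deliberate
separation of concerns — the detectors are shown to recover rasterised
manifests *exactly* in their own validation, after which the group-level
operating characteristics depend only on the generative count model, and
simulating them at rasterised scale would add hours of compute and no
information.

Statistics follow the reporting conventions of the field: mean ± SEM
(sd/√n, n−1 standard deviation; SEM undefined at n = 1), unpaired
two-tailed pooled-variance t test or Mann–Whitney U. The Mann–Whitney p is
exact — full enumeration of rank assignments — for tie-free samples with
n\_a + n\_b ≤ 14, and otherwise uses mid-ranks with the tie-corrected,
continuity-corrected normal approximation; the method used is recorded in
every result. Because the source studies say "t test or Mann–Whitney"
without a per-panel rule, the package's default is explicit and
reproducible: Mann–Whitney when either group has n < 5 or fails a
Shapiro–Wilk screen at p < 0.05 (degenerate groups count as failing),
otherwise the t test; the choice is configurable and always logged. The
capillary is the statistical unit, matching the "nine capillaries per
group" design; mouse-level clustering is deliberately not modelled and the
report says so.

```{r stats-example}
r <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
pValue(r)          # exact: 2 of 20 rank assignments
testUsed(r)
```

## Numerical choices and degenerate inputs

* EDT and disc painting use strict inequalities with a 1e-9 guard so that
  sqrt-valued distances never flip membership by rounding.
* Zero-variance t tests: p = 1 for equal means, 0 otherwise, by convention.
* Empty BM sections are skipped (warn); an all-empty stack errors.
* Roles mapped in the sidecar but absent from a stack are a warning (a
  feature-free capillary is not an error); labels present in the stack but
  missing from the role map are an error, because they break the role
  partition.
* Labels above 255 are written as 16-bit TIFF; above 65535 the writer
  refuses rather than clips.
* All randomness is seeded: phantom jitter from the spec seed, cohorts from
  a master seed via per-stack derived seeds, so every pipeline artifact is
  reproducible bit-for-bit from config + seed.

## Problem sizes used in validation

The shipped validation suite uses 512²-pixel, 50-section phantoms for
thickness recovery, ≤128² masks for the exhaustive oracle comparison,
40-section phantoms for the detector sweep, and metricsOnly cohorts of
9 vs 9 capillaries × 300 sections for 1000 null and 200 effect replicates.
These sizes were chosen so that a complete validation runs in minutes on a
single CPU while still exercising every code path at realistic voxel
dimensions.

## Known limitations

* Thickness is in-plane 2D by design; a BM sheet strongly oblique to the
  sectioning plane would read thick. The same limitation applies to any
  per-section measurement at this anisotropy.
* Depth equals `nSlices × dz`; oblique capillary segments are not
  re-measured along their true axis.
* Detachment detection assumes lucent clefts thinner than
  `max_gap_width_nm`; a detachment wider than the open-space cutoff would
  be discarded.
* The exact inclusion/exclusion criteria of any particular study are not
  reproduced; the detector thresholds here are declared, documented
  defaults.
* Phantom validation certifies the quantification chain on clean labels,
  not robustness to segmentation error.
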