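---
title: "Methods: quantifying axonal vulnerability traits from fluorescence microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying axonal vulnerability traits from fluorescence microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Neuronal populations that degenerate early in Parkinson's disease (nigral
dopamine neurons, locus coeruleus, raphe, dorsal vagal motor neurons) share a
cellular phenotype: very large, heavily branched axonal arbors dense with
transmitter release sites, and a correspondingly high energetic and redox
burden on their mitochondria. `axovuln` implements, as a reusable and tested
pipeline, the quantitative-microscopy measurements used to compare such
"vulnerable" populations with more resilient ones (ventral tegmental area,
hypoglossal nucleus, striatal cholinergic interneurons) in primary culture:

1. **Soma census and survival** — count marker-positive cell bodies per well
   and normalize counts across a hydrogen-peroxide dose series (0, 100, 150,
   200 µM) by each population's dose-0 mean.
2. **Neurite morphometry** — trace thin neurites, reduce them to a skeleton
   graph and report total length, number of sections and mean section length
   per neuron, per well.
3. **Varicosity analysis** — detect enlargements along thin neurites, apply
   the morphological size gate (width 0.2–1 µm), classify synaptotagmin-1
   positivity against a cutoff estimated from gate-excluded segmentations,
   and report positive fraction, nearest-neighbor spacing and density per
   axon length.
4. **Redox dynamics** — quality-control mitochondrially targeted roGFP
   traces and quantify relative oxidation from the DTT/ALD calibration.
5. **Estimation statistics** — BCa bootstrap mean differences (shared-control
   and two-group designs) next to the usual omnibus/post hoc tests.

The raw images behind the original study are not publicly deposited, so the
package ships a synthetic-data generator that emulates their statistical
structure and provides exact ground truth; every pipeline stage is validated
against it.

# The synthetic generator as the study conditions

`field_spec()` defines one simulated well. Its defaults are the conditions
all recovery tests run under, chosen once to be realistic for a sparse
primary culture imaged at high magnification:

* **Raster**: 448 × 448 px at 0.3 µm/px (a 134 µm field, a cropped
  high-magnification confocal field of view). At 0.3 µm/px a varicosity of
  0.2–1 µm spans roughly 1–3 px, so the size gate operates near the
  resolution limit, as it does in the real assay. The acquisition scale is
  an assumption, not a reported value; it is configurable.
* **Somata**: 10 marker-positive cell bodies of 8–15 µm diameter, placed
  with a clearance that relaxes only if the field is crowded; 30 additional
  marker-negative nuclei.
* **Neurites**: smoothed random walks (1 µm steps, heading noise 0.22 rad,
  curvature clamped) from each soma edge, branching as a Poisson process
  (0.02 events/µm), steering away from field borders and around somata —
  axons skirt cell bodies rather than crossing them. The summed centerline
  length tracks a 1200 µm target to within one step per neuron. Lines are
  rendered with a 0.25 µm FWHM Gaussian profile (sub-resolution, < 1 px).
* **Varicosities**: planted along the centerline with gamma-distributed gaps
  (mean 6 µm, CV 1/3), oriented Gaussian enlargements whose transverse FWHM
  is drawn U(0.35, 0.8) µm; 15% are oversize swellings (U(1.5, 2) µm) that
  fall outside the morphological gate and always carry the negative Syt-1
  component — these are what the cutoff estimator feeds on. Syt-1
  intensities form a two-component mixture (means 200/30, SD 12).
* **Camera**: constant background 100 with additive Gaussian read noise
  (SD 5), giving neurites an SNR of about 8. Poisson shot noise and channel
  bleed-through are deliberately not simulated: detection only assumes
  SNR > ~3, and the original acquisition scanned channels sequentially.

Rendering is supersampled 3× and averaged down, with sub-resolution
structure (lines, varicosity blobs) drawn on the fine grid and disk-scale
structure (somata, nuclei) drawn directly at the output scale. Identical
seeds give bit-identical images, truths and traces.

**What the generator does not emulate** — and therefore what passing tests
do not establish about real data: astrocyte background texture, uneven
illumination, fasciculation (axons bundling so tightly that 2-D tracing is
degenerate), photobleaching kinetics, and 3-D structure. In particular, the
default neurite density is chosen so that individual neurites are resolvable;
at several-fold higher densities the skeleton of overlapping arbors merges
and any 2-D tracer undercounts length. That is a genuine limitation of the
measurement, not of the simulation.

# Module notes and numerical choices

## Soma census

Median filter → Otsu threshold (floored at the image median to guard
near-empty fields) → morphological opening of radius 1.5 µm (removes
neurite-thickness structure) → hole filling → labeling → area gate at
30 µm² (somata are ≥ 8 µm across; varicosities and debris are far smaller).
Census accuracy against ground truth uses greedy closest-first one-to-one
matching within 5 µm and the symmetric denominator
`matches / max(n_true, n_predicted)`; the original study reports ~90%
validation accuracy without defining its formula, so the matching rule here
is a declared convention.

Survival normalization divides each well's count by the mean dose-0 count of
the same population on the same plate. Cross-plate pooling is out of scope; a
zero dose-0 mean flags the population as undefined rather than erroring.

## Neurite morphometry

Neurites are enhanced with a single-scale Hessian ridge filter (σ = 1 px) and
thresholded at 4 × the MAD of the ridge response — the response is
essentially zero on flat background, so its MAD tracks the noise floor, and
isolated supra-threshold specks fall to a 2 µm minimum component size. The
soma mask, dilated by 1.5 µm, is excluded.

The skeletonizer is a vectorized Zhang–Suen thinning. Skeleton pixels become
graph vertices; 8-neighbor links become edges weighted `pixel_size` (lateral)
or `sqrt(2) * pixel_size` (diagonal, stated explicitly for
bit-reproducibility), with diagonals bridged by a shared lateral neighbor
removed so length is not double-counted. Terminal spurs shorter than 1 µm
(skeletonization artifacts, well below varicosity scale) are pruned. A
"section" is a maximal path between nodes of degree ≠ 2; the decomposition
covers each edge exactly once, so section lengths sum to the graph total
*exactly*, and per-well metrics follow by arithmetic. All traced length is
treated as axonal: in these cultures most neurites are MAP2-negative, so the
tracer reads the neurochemical marker channel only.

## Varicosity analysis

Candidates are local maxima of the marker profile sampled at 0.15 µm steps
along every skeleton section, required to exceed
`max(2 × baseline, baseline + 5 × MAD)` where the baseline is the section's
25th-percentile signal — a low quantile, so the estimate stays on the bare
neurite even when enlargements cover half the branch, as they do at the
2–5 µm spacings typical of real axons. Maxima closer than 1.2 µm merge.
Geometry is measured from the image itself: transverse width as
2 × min(half-widths at half maximum) on either side of the peak — the `min`
makes the estimate robust to a crossing neurite contaminating one flank —
and length as the along-section extent at half maximum over background (the
local ridge baseline is too noisy a reference at crossings). Candidates
within 1 µm of a junction node are flagged `near_junction`: they count for
detection and density, but a crossing branch corrupts their transverse and
intensity profiles, so positivity classification and the cutoff estimate
leave them aside — an unbiased subsample, since varicosity placement is
independent of branch points. The size gate keeps widths in [0.2, 1] µm. The
printed length range of 0.3–0.5 µm would exclude most elongated boutons
(length < width); the package defaults to [0.3, 5] µm and offers the literal
range via `strict_length_gate`, recording the applied gate in every output
row.

The Syt-1 positivity cutoff is estimated from the gate-*excluded*
candidates, whose Syt-1 signal represents nonspecific staining. The default
statistic is a robust upper envelope of that pool, median + 3 MAD: a small
minority of excluded candidates are genuine varicosities mis-measured across
a gate boundary, and raw order statistics (the 95th percentile, offered as
an alternative along with mean + 2 SD) chase exactly that contamination when
the pool is small. The fall-back with fewer than five excluded candidates is
background mean + 2 SD, flagged.
Positivity is `mean intensity > cutoff` among gate-passing varicosities.
Nearest-neighbor spacing is 2-D Euclidean between centroids (not
along-skeleton path length), and density is passing varicosities per mm of
skeleton.

## Redox dynamics

Traces carry three epochs: baseline, a DTT plateau at the fluorescence
maximum (full reduction) and an ALD plateau at the minimum (full oxidation).
F, FDTT and FALD are medians of the last half of each epoch (the plateau,
once the calibrant has equilibrated — the summary statistic is a package
convention). QC excludes traces whose baseline drifts by more than 10%
(|least-squares slope × duration| relative to the fitted start level) and
non-responders, which must fail to rise under DTT or fall under ALD by at
least 3 baseline SDs in the expected directions. Relative oxidation is
`1 − (F − FALD)/(FDTT − FALD)`, clipped to [0, 1] with a flag. Stack
registration is translation-only by FFT cross-correlation against frame 1 —
sufficient for stage drift in fixed-stage recordings; rotation is a
documented non-goal. Somatodendritic inter-mitochondrial distances are not
computed (puncta density too high to resolve); axonal gaps are consecutive
ordered center-to-center differences, simulated by default at the reported
moments (mean ≈ 13 µm, SD 5.4 µm) via a gamma model.

## Estimation statistics

The unpaired mean difference `mean(b) − mean(a)` gets a 95% BCa interval:
bias correction `z0 = qnorm(P(boot < observed))`, acceleration from the
delete-one jackknife skewness over both groups, endpoints read from the
type-7 quantiles of the bootstrap distribution. 5000 resamples by default
(reduced in some tests for runtime; coverage is validated at 1000).
Zero-variance inputs yield a degenerate flagged interval. The resampling
unit is whatever the caller passes — in this pipeline always the well,
never the pixel or varicosity. Shared-control designs derive each pair's
seed from the master seed and the group label by a rolling polynomial hash
and sort within groups first, making results invariant to row order.

Omnibus testing routes on a per-group Shapiro–Wilk screen at α = 0.05
(the routing rule is a declared convention): ANOVA + Tukey HSD when all
groups pass, Kruskal–Wallis + pairwise Mann–Whitney with Bonferroni
otherwise; both routes can be forced. The vulnerable-vs-resilient contrast
(SNc, LC, R, DMV vs VTA, XII, STR) uses an exact Mann–Whitney U for
combined n ≤ 20 without ties and the tie-corrected normal approximation
otherwise, with a Gardner–Altman-style two-group estimation result
alongside. Box statistics follow Tukey: type-7 interpolated hinges, whiskers
at the most extreme values within 1.5 IQR. The original study's a-priori
power computation is not implemented: its variance assumption is not
recoverable from the text, so the reported n = 22 cannot be verified.

# The demo plate

`make_demo_dataset()` writes a 7-population × 4-dose plate (3 wells at dose
0, 2 per nonzero dose, 256 × 256 px fields) plus per-population roGFP traces
(12 ROIs each, one planted drifter and one non-responder among them) and a
ready config. Vulnerable populations are planted with longer axons (180 vs
110 µm per neuron), higher Syt-1-positive fractions (0.75 vs 0.45), steeper
dose-response and higher relative oxidation, so `run_pipeline()` exercises
every stage and the class comparisons detect the planted differences in the
direction the biology predicts. The demo runs end to end in a few minutes on
one CPU.

```{r, eval = FALSE}
library(axovuln)
make_demo_dataset("demo", seed = 1)
record <- run_pipeline("demo/config.yaml")
read.csv("demo/results/stats_tests.csv")
```

# Known limitations

* 2-D skeleton tracing merges overlapping strands; length recovery is
  validated at resolvable densities and will undercount dense fascicles.
* Transverse FWHM reads ~20% low for structures much wider than the line
  profile; the oversize swellings planted by the generator are placed well
  clear of the gate boundary so this bias cannot move them across it.
* The Syt-1 cutoff convention (p95 of excluded) assumes excluded
  segmentations are predominantly background-like; a contaminated excluded
  pool (for example, at extreme varicosity densities) shifts the cutoff up.
* Translation-only registration does not correct rotation or scaling.
* The generator's camera model omits shot noise; detection thresholds are
  calibrated in MAD units and tolerate moderate deviations, but
  quantitatively different noise regimes deserve re-validation.
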