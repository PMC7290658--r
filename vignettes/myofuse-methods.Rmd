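---
title: "Methods: quantifying myotube fusion and opposing gene regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying myotube fusion and opposing gene regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myofuse)
```

## Overview

`myofuse` quantifies myogenic differentiation and fusion from two-channel
fluorescence images — DAPI marking nuclei, embryonic myosin heavy chain
(eMHC) marking differentiated cytoplasm — and classifies genes regulated in
opposing directions across two differential-expression contrasts. Because
the pipeline's claims are about *recovery* (counting the nuclei that are
there, reproducing a phenotype that was planted), the package carries its
own simulator: ground-truth scenes of myotubes and mononucleated cells,
rendered images with controlled blur and noise, and two-contrast DE tables
with planted opposing regulation. Every downstream stage is tested against
that truth.

## The imaging model and its parameters

A *scene* is a field of capsule-shaped myotubes (a line segment dilated by
a half-width, polygonized with 12 segments per semicircular cap) and
scattered mononucleated cells. Myotubes are placed by rejection sampling
under pairwise non-overlap (axis-to-axis distance exceeding the summed
half-widths); nuclei are placed inside each capsule's rectangular core, and
mono-cell nuclei outside every tube, under a *global* minimum
centre-to-centre separation. Key parameters of `scene_params()`:

* `field_width_px`, `field_height_px` (default 400 x 400 px) and
  `pixel_size_um` (default 0.25 µm/px, i.e. a 100 µm field at high
  magnification). No magnification metadata accompanies the assay this
  emulates, so pixel size is a free parameter: metrics that depend on it
  (density) are always reported with explicit unit conversion.
* `nuclei_per_myotube_sampler`: fixed list, shifted geometric (default,
  mean 8) or shifted negative binomial — all guaranteed $\ge 2$, matching
  the operational definition of a myotube. Capsule length scales with the
  drawn count at twice the close-packing area per nucleus, so rejection
  sampling stays cheap; tubes that would outgrow the field widen instead.
* `nucleus_radius_px` (default 5) and `min_nucleus_separation_px`. The
  separation default is $2r + 3$: disks whose centres sit exactly $2r$
  apart can still touch after pixelation under 8-connectivity, and a 3 px
  gap keeps noiseless particles disjoint so counts are exactly
  recoverable. That exactness is the point of the noiseless fixtures.
* `fraction_mono_emhc_positive` (default 0.2): differentiated but unfused
  cells, which count toward the differentiation index but not the fusion
  distribution.

Rendering (`render_params()`) stamps constant-intensity disks (DAPI) and
filled polygons (eMHC) onto a constant background — overlaps set, not add —
then applies a separable Gaussian blur (`psf_sigma_px`, default 1) and
noise (default Gaussian with sd = 5% of the DAPI peak: visible, but far
from the Otsu separation limit at the default 16-bit intensities). Values
that would exceed the bit depth raise an error rather than clip silently;
clipping is opt-in. What the simulator deliberately does *not* model:
chromatin texture, uneven illumination, out-of-focus light, touching
nuclei inside one cell, 3-D structure. Passing the recovery tests therefore
demonstrates correctness of the measurement chain, not robustness to every
real-world artefact.

## Nuclei detection

`segment_nuclei()` composes four primitives, each implemented from its
definition:

1. **Rolling-ball background subtraction** — the background is the
   grayscale opening of the image by a spherical-cap structuring element of
   radius `rolling_ball_radius_px` (default 50 px); the subtracted result
   is clamped to $[0, \mathrm{input}]$. This is the mathematical "ball
   rolling under the intensity surface"; the classic ImageJ implementation
   approximates the ball with a paraboloid and shrinks large images, so
   bit-compatibility with it is a non-goal. One consequence worth knowing:
   an isolated impulse keeps $v - (r - \sqrt{r^2-1})$, not exactly $v$ —
   the ball cap intrudes a height $r - \sqrt{r^2-1}$ (0.01 grey levels at
   the default radius) into any feature narrower than itself.
2. **Otsu threshold** over a 256-bin histogram spanning the observed value
   range (so 8- and 16-bit data are treated uniformly), maximizing
   between-class variance; ties resolve to the lowest cut, and the mask is
   `value > threshold`. A constant image yields an empty mask with a
   warning rather than an arbitrary split.
3. **Cleanup**: fill enclosed background holes (components not touching
   the border, 4-connected background), then binary opening with a disk of
   `opening_radius_px` (default 1) to remove specks.
4. **Particle analysis**: connected components (default 8-connectivity,
   the particle-analyzer convention), area filter
   `[min_area_px, max_area_px]` (default [20, Inf); a default-radius
   nucleus covers ~80 px), centroids as the arithmetic mean of pixel
   centres. Coordinates are continuous, origin top-left, the pixel in
   0-based column $c$, row $r$ centred at $(c+0.5,\ r+0.5)$.

Touching nuclei are **not** split — no watershed/declumping — matching the
measurement recipe this reproduces; the simulator's separation default
makes that a non-issue on synthetic data, and it is a documented limitation
on real clusters. The threshold method and size bounds are package choices
(the recipe specifies only "automatic" thresholding); the configuration
enum leaves room for alternatives.

## Fusion metrics

Nuclei are assigned to ROI polygons by an even-odd centroid-in-polygon test
with *boundary counts as inside* (no silent loss of on-edge centroids). A
centroid inside several ROIs goes to the nearest polygon centroid, ties to
the lowest ROI id — overlap should not occur with hand-drawn myotube
outlines, but the rule makes the assignment total and deterministic.

* differentiation index = nuclei in *all* eMHC-positive ROIs (mono- or
  multinucleated) / total nuclei — the literal "nuclei in eMHC-positive
  cells" reading;
* density = count / (width x height x pixel size²), reported per mm²;
* fusion distribution over eMHC-positive ROIs with $\ge 2$ nuclei: median,
  log2 median, and fractions in the size classes $[2,14]$, $[15,49]$,
  $[50,\infty)$. The upper class is closed at 50 so the three classes
  partition $[2,\infty)$ — the verbal convention ("between 15 and 49",
  "more than 50") leaves exactly-50 unmapped, and an exhaustive partition
  was preferred.

`compare_groups()` provides the two tests used on these metrics: a
pooled-variance Student *t* (Welch behind a flag) and a two-sided Wilcoxon
rank-sum. "Wilcoxon" is interpreted as the two-*sample* rank-sum test since
the compared groups are independent conditions; the signed-rank variant is
not implemented. The rank-sum p-value is exact by full enumeration of the
$\binom{n}{n_a}$ rank splits (midranks for ties) when $n_a+n_b \le 12$,
and otherwise uses the normal approximation with continuity and tie
correction — the exact path is the contract, the cutoff keeps enumeration
below $\binom{12}{6} = 924$ splits.

## Opposing-regulation classification

The DE arm consumes per-gene `(gene_id, log2fc, pvalue)` tables — the
fitted outputs of a count-model package; the fit itself is out of scope.
`bh_adjust()` applies Benjamini–Hochberg step-up correction (via
`stats::p.adjust`; an independent step-up implementation backs the tests).
Correction is per contrast; when `padj` is absent it is computed over the
*full* table, never a filtered subset, because the adjustment depends on
the number of tests. `filter_deg()` keeps $|\log_2\mathrm{FC}| \ge 0.8$
and $p_{\mathrm{adj}} \le 0.05$ by default, both boundaries inclusive
("at least" / "equal or less"); direction is `up` iff $\log_2\mathrm{FC} >
0$ (an exact 0 cannot pass a positive cutoff, so the labeling convention
there is inert). A known ambiguity in the source material — a figure legend
citing a raw p < 0.01 cutoff where the methods text says adjusted p ≤ 0.05
— is resolved by exposing both knobs with the methods-text default rather
than adjudicating. `classify_opposing()` intersects the two significant
sets and labels each shared gene's quadrant; `down_a_up_b` is the
opposing-regulation candidate set.

The DE simulator plants `n_shared_planted` genes (default 98) significant
in both contrasts, `n_opposing_planted` of them (default 46) down-in-A /
up-in-B; the remaining planted genes are concordant, split up/down evenly.
Planted $|\log_2\mathrm{FC}|$ is uniform on $[0.8, 2.8]$; planted p-values
are log-uniform on $[10^{-12}, 10^{-3}]$ — the upper end chosen so that
after BH at $m = 1000$ every planted gene stays below 0.05
($10^{-3} \cdot 1000/98 \approx 0.0102$), which the exact-recovery
contract requires; log-uniform spans realistic significance without ties.
Null genes draw $\log_2\mathrm{FC} \sim N(0, 0.3)$ and $p \sim U(0,1)$; the
chance that a null gene passes both filters in both contrasts is of order
$10^{-9}$ per gene, so planted-truth recovery is exact except with
negligible probability (and the tests treat any such event as a failure,
not a tolerance).

## Numerical and design choices

* **Determinism**: every stochastic stage takes an explicit seed in its
  parameter object and is byte-reproducible; the pipeline writes a
  provenance record (seed, configuration hash, versions).
* **Degenerate inputs**: constant rasters (empty mask + warning), zero
  detected nuclei (differentiation index 0 + warning), no qualifying
  myotube (NA summaries + warning, NaN fractions), zero imaged area
  (error), crowded fields (error naming the parameter to relax).
* **Morphology at borders**: structuring elements are restricted to the
  image domain (no padding), the same convention the brute-force test
  oracles use.
* **Problem sizes**: validation runs use 10 simulated fields of 400 x 400
  px per condition for recovery, 20 seeds of 100-vs-100 myotube counts for
  the power study, and a 1,000-gene universe for DE recovery — sizes at
  which every statistical check is stable yet the whole suite runs in
  minutes on a single core.
* The two-condition power study compares samples drawn directly from the
  nuclei-per-myotube sampler (geometric mean 5 vs 15) rather than
  re-rendering hundreds of tubes: the compared quantity *is* the count
  distribution, and the imaging chain's fidelity is established separately
  by the recovery tests.

## Known limitations

No watershed splitting of touching nuclei; no illumination-field
correction beyond rolling ball; ROIs are inputs (no automatic myotube
segmentation from the eMHC channel); the simulator's realism is
deliberately limited as listed above; figure rendering is basic
(`autoplot`, `plot_fusion_distribution`, `plot_volcano`).
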