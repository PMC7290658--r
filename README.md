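# myofuse

Quantification of myoblast fusion and myogenic differentiation from
two-channel fluorescence microscopy, plus the downstream classification of
genes regulated in opposing directions across two knockdown contrasts.

## The problem

Skeletal muscle forms when mononucleated myoblasts differentiate and fuse
into multinucleated myotubes. In culture, the phenotype is scored from
images with a nuclear stain (DAPI) and a cytoplasmic marker of
differentiation (embryonic myosin heavy chain, eMHC): myotubes are drawn as
polygonal regions of interest (ROIs) on the eMHC channel, and every metric
reduces to counting nuclei and locating them relative to those regions.
`myofuse` implements that analysis as a tested, scriptable pipeline, and —
because the interesting claims are about recovering a known phenotype — a
synthetic-data module that simulates fields with exact ground truth so each
stage can be validated end to end.

The core quantities, for a field with $N$ detected nuclei of which
$N_{\mathrm{eMHC^+}}$ lie in eMHC-positive cells:

- **nuclei density** $= N / A$, with $A$ the imaged surface in mm²;
- **differentiation index** $= N_{\mathrm{eMHC^+}} / N$;
- **fusion distribution**: the multiset $\{n_i\}$ of nucleus counts over
  eMHC-positive ROIs with $n_i \ge 2$ (the operational definition of a
  myotube), summarized by its median, $\log_2$ median and the size-class
  fractions $[2,14]$, $[15,49]$, $[50,\infty)$;
- group comparisons: pooled-variance Student *t* for density and
  differentiation index, two-sided Wilcoxon rank-sum (exact by enumeration
  for $n_a+n_b \le 12$, midrank ties) for the fusion distribution.

Nuclei are detected from the DAPI channel exactly as the classic ImageJ
recipe does, implemented from first principles: rolling-ball background
subtraction (grayscale opening by a spherical-cap structuring element),
Otsu thresholding over a 256-bin histogram, hole filling and binary
opening, then connected-component particle analysis with area filtering and
centroid extraction.

The expression arm consumes per-gene tables (`gene_id, log2fc, pvalue`)
from two contrasts, applies Benjamini–Hochberg correction and the inclusive
cutoffs $|\log_2 \mathrm{FC}| \ge 0.8$ (linear fold-change $1.74$) and
$p_{\mathrm{adj}} \le 0.05$, intersects the significant sets, and assigns
each shared gene to a direction quadrant — `down_a_up_b` being the
candidate set for opposing isoform control.

## Worked example

```r
library(myofuse)

sc  <- generate_scene(scene_params(seed = 3))
img <- render_scene(sc, render_params(psf_sigma_px = 0, noise = "none",
                                      background_level = 0))
nuc <- segment_nuclei(img)
rep <- build_fusion_report(nuc, scene_rois(sc))
rep
#> <fusion_report> 68 nuclei over 0.01 mm^2 (6800 /mm^2)
#>   differentiation index 0.647; 6 myotubes (median 5.5 nuclei, log2 2.46)
#> # A tibble: 3 x 3
#>   bin       n fraction
#>   <fct> <int>    <dbl>
#> 1 2-14      5    0.833
#> 2 15-49     1    0.167
#> 3 >=50      0    0
```

The 68 detected nuclei equal the simulated ground truth exactly (noiseless
render), the differentiation index 0.647 is the planted fraction of nuclei
in eMHC-positive cells, and the six per-myotube counts match the counts the
scene was built with. `tidy(rep)` gives the per-ROI table, `glance(rep)` a
one-row summary, `autoplot(rep)` the size-class bar chart.

For the expression arm:

```r
deg <- generate_deg_tables(deg_sim_params(seed = 1))  # 98 shared, 46 opposing planted
cl  <- classify_opposing(filter_deg(deg$contrast_a), filter_deg(deg$contrast_b))
glance(cl)
#> # A tibble: 1 x 5
#>   overlap down_a_up_b up_a_down_b up_both down_both
#>     <int>       <int>       <int>   <int>     <int>
#> 1      98          46           0      28        24
```

`run_fusion_pipeline(fusion_run_config(), "out/")` chains
simulate → segment → quantify → classify for a two-condition experiment and
writes per-field reports, a per-myotube table, comparison statistics, the
DE classification and a provenance record.

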