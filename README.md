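# rimfluct

Quantifies how *punctate* a fluorescent lamin signal is along the nuclear
envelope. Mature lamins (lamin A/C, lamin B) line the nuclear periphery
continuously; the unprocessed precursor prelamin A accumulates in discrete
foci. `rimfluct` turns that qualitative contrast into a per-nucleus number
by:

1. **Segmenting** each nucleus from a multi-channel fluorescence image —
   Otsu thresholding of the counterstain (DAPI) projection for an initial
   boundary, refined by a gradient-vector-field (GVF) parametric active
   contour (75 iterations);
2. **Sampling** a reference envelope channel (lamin B) and a test channel
   (lamin A/C or prelamin A) along the refined contour;
3. **Scoring** the pair with the **fluctuation index**: circular first
   derivatives of both profiles, normalized; bidirectional per-position
   ratios of the derivative magnitudes with divide-by-zero correction,
   min-max normalized to [0, 1]; the percentage of positions above 0.15 in
   each direction, summed,

   `index = 100·P(r̂_ref/test > 0.15) + 100·P(r̂_test/ref > 0.15)  ∈ [0, 200]`.

A test channel distributed identically to the reference scores **exactly
0**; the index grows as the test signal concentrates into foci. The package
also ships a synthetic rim-image generator with exact ground truth (so the
whole pipeline is testable without microscopy data), linescan profiling,
immunoblot densitometry ratios (`prelamin A / (lamin A + prelamin A)` with
Welch tests), and a batch pipeline with CSV reports and QC overlays.

## Worked example

```r
library(rimfluct)

# a synthetic nucleus with 6 bright foci over a near-black rim baseline
img <- generate_nucleus_image(
  synthetic_spec(n_foci = 6L, focus_contrast = 5, baseline_fraction = 0.05))

contour <- segment_nuclei(img$stack)[[1]]
contour_distance(contour, img$truth$contour)$mean
#> [1] 0.234184        # mean boundary error vs ground truth, pixels

ref  <- sample_contour_intensity(max_intensity_projection(img$stack, "reference"), contour)
test <- sample_contour_intensity(max_intensity_projection(img$stack, "test"), contour)
fluctuation_index(ref, test)
#> fluctuation_result: index 38.00 (ref/test 35.00% + test/ref 3.00%), 200 points, threshold 0.15
```

The index of 38 is dominated by the ref/test direction: along the dim, flat
gaps between foci the test derivative is exactly zero while the reference
still fluctuates, and those positions are what the metric counts. A
two-group experiment (punctate vs uniform rims, 44 nuclei each, jittered
geometry):

```r
report <- run_analysis(generate_cohort(n_per_group = 44, seed = 1))
summarize_groups(report, alternative = "greater")
#>      group  n      mean       sd median    iqr
#> 1 punctate 44 37.784091 9.060775  35.75 13.625
#> 2  uniform 44  9.931818 4.370343   8.75  6.125
#> rank-sum p = 3.3e-16
```

The punctate group's index distribution sits far above the uniform
group's — the quantitative version of calling a stain "punctate" by eye.

A thin CLI covers the same flow from a shell
(`inst/scripts/rimfluct simulate|run|blot-ratio|summarize`); see the
vignette `vignettes/rim-fluctuation-methods.Rmd` for the model, parameter
and design details.

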