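# precisionmap

Individual-specific ("precision") functional brain network mapping from dense
grayordinate BOLD time series, in R.

Group-average atlases hide the fact that the topography of large-scale brain
networks — where the default mode, frontoparietal or attention networks sit
on the cortex — differs from person to person. `precisionmap` builds network
maps for *individuals* from their resting-state functional connectivity and
aggregates them into population probabilistic atlases. It is aimed at
researchers analysing dense (surface + subcortical, CIFTI-style) resting-state
data who need per-participant network assignments, data-driven overlapping
networks, and reliability analysis, and at methodologists who want a tested,
synthetic-cohort-validated reference implementation of this workflow.

## What it implements

* **Motion preprocessing** — framewise displacement
  `FD_i = |Δp_x| + |Δp_y| + |Δp_z| + r(|Δα| + |Δβ| + |Δγ|)` with rotations
  converted on a 50 mm sphere; censoring at FD > 0.2 mm with a 5-contiguous-
  frame rule and a median-absolute-deviation BOLD-outlier rule; nuisance
  regression (tissue means, motion parameters, derivatives, squares);
  zero-phase first-order Butterworth band-pass (0.009–0.080 Hz);
  exact-duration random frame sampling.
* **Template matching (TM)** — per-network templates thresholded at z ≥ 1
  (the top ~15.9% of connections); each grayordinate's binarized connectivity
  compared with each template by the η² image-similarity coefficient

      η² = 1 − Σ[(a−m)² + (b−m)²] / Σ[(a−M̄)² + (b−M̄)²],  m = (a+b)/2

  and assigned winner-take-all.
* **OMNI mapping** — overlapping multi-network assignment by per-network
  data-driven thresholds: the η² distribution in 10,000 bins, Savitzky–Golay
  smoothed (2,000-point window), thresholded at the local minimum of its
  bimodal shape between bins 4,000 and 7,000.
* **Community-detection consensus** — 30 mm distance exclusion, edge-density
  ladder (0.3–3%), a pluggable community-detection backend
  (`igraph::cluster_infomap` adapter included), Jaccard relabeling to a
  reference parcellation (0.1 floor, large networks claimed first), consensus
  at the sparsest successful density, and < 30-grayordinate cluster cleanup.
* **Probabilistic atlases** — per-network assignment frequencies across a
  cohort; ROI sets by thresholding at 0.8 (or the 0.75 preset) with a
  30-grayordinate minimum cluster; integration zones where the cohort-mean
  network overlap count exceeds 2.2.
* **Reliability** — split-half NMI versus a cross-participant null (one-tailed
  Welch t-test), edge-wise brain–behavior correlations, subset reliability
  curves with exponential rise-to-maximum fits `y = y0 + a(1 − e^(−bx))`.
* **Synthetic cohorts** — planted network topographies with per-participant
  jitter, multi-network hub zones, configurable SNR, spiky motion traces and
  behavioral scores; the ground-truth oracle for the entire test suite.

I/O covers CIFTI-2 (`.dtseries.nii` / `.dscalar.nii` / `.dlabel.nii`) and a
plain-text dialect (tab-delimited matrix + JSON sidecar). Analysis results
are tibbles or carry `tidy()` / `glance()` methods, and the main result types
have `autoplot()` methods.

## Worked example

Simulate a small cohort, censor one participant's frames, build templates
from three participants, and map a held-out participant:

```r
library(precisionmap)

cohort <- generate_cohort(cohort_spec(n_participants = 8, n_gray = 500,
                                      K = 5, n_frames = 300, master_seed = 1))
pt <- cohort$participants[[8]]

mask <- censor_frames(compute_fd(pt$motion), censor_config(),
                      bold_sd = apply(pt$ts$values, 1, sd))
mask
#> <frame_mask> 294/300 frames retained

seed_maps <- lapply(cohort$participants[1:3], function(p)
  participant_seed_maps(p$ts, cohort$truth$labels))
templates <- build_templates(seed_maps, palette = cohort$palette)
templates
#> <template_set> 5 networks x 500 grayordinates (z >= 1; built from 3 participants)

map <- template_match(pt$ts, templates, mask)
mean(map$labels == pt$truth$labels$labels)
#> [1] 0.934
```

294/300 frames survive censoring (the simulated trace has occasional 0.5 mm
spikes), and the held-out participant's map recovers 93% of the planted
labels — the disagreements sit on jittered network borders and in the planted
hub zones, where single assignment is ambiguous by design. Split-half
reliability over five participants:

```r
sh <- split_half(lapply(cohort$participants[4:8], `[[`, "ts"),
                 function(ts, m) template_match(ts, templates, m), seed = 1)
glance(sh)
#> # A tibble: 1 × 6
#>   mean_intra_nmi mean_null_nmi t_statistic   dof  p_value n_participants
#>            <dbl>         <dbl>       <dbl> <dbl>    <dbl>          <int>
#> 1          0.994         0.851        20.0  29.3 6.16e-19              5
```

Maps built from two halves of the same participant's data agree far better
(NMI 0.99) than maps from different participants (0.85), i.e., the maps are
individual-specific.

A command-line front end over the same functions is installed at
`inst/cli/precisionmap.R` (`simulate`, `run`, `censor`, `tm`, `omni`
subcommands).

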