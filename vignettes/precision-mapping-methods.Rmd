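---
title: "Precision functional network mapping: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Precision functional network mapping: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(precisionmap)
```

# The problem

Group-average functional atlases blur over person-to-person variation in
where large-scale brain networks sit on the cortex. Precision functional
mapping assigns every grayordinate (cortical surface vertex or subcortical
voxel) of an *individual* to a network, using that individual's resting-state
connectivity, and then aggregates individual maps into population
probabilistic atlases. This package implements that workflow end to end:
motion preprocessing, dense connectivity, template matching (TM), overlapping
multi-network (OMNI) mapping, multi-density community-detection consensus,
probabilistic atlases with derived ROI sets and integration zones, and
split-half / subset reliability analysis — together with a synthetic cohort
generator that serves as the ground-truth oracle for all of it.

# Motion preprocessing

Framewise displacement for frame $i$ is

$$\mathrm{FD}_i = |\Delta p_{ix}| + |\Delta p_{iy}| + |\Delta p_{iz}|
  + r\,(|\Delta\alpha_i| + |\Delta\beta_i| + |\Delta\gamma_i|),$$

with rotations converted from degrees to arc length on a sphere of radius
$r = 50$ mm, the approximate mean distance from cortex to the head centre.
The first frame has no predecessor; we set $\mathrm{FD}_1 = 0$, the common
convention. Censoring proceeds in three stages: frames with
$\mathrm{FD} > 0.2$ mm are removed; then any surviving run of retained frames
shorter than 5 is removed (short islands of "clean" data between spikes are
unreliable); finally, frames whose spatial BOLD standard deviation deviates
from the median of the retained frames by more than $3 \times 1.4826 \times
\mathrm{MAD}$ are removed. The MAD multiplier and consistency constant are
the conventional choices for the named method. We run the BOLD-outlier stage
last; the ordering between it and the short-segment rule is a free choice
with little practical consequence, since both stages are conservative.

Nuisance regression removes, per grayordinate, an intercept, the three
tissue mean signals (whole brain, ventricle, white matter), the six
rigid-body parameters, the first differences of those nine regressors, and
the squares of all eighteen columns (37 columns total). Band-pass filtering
is a first-order Butterworth between 0.009 and 0.080 Hz applied once forward
and once backward (zero phase, squared magnitude response). Both operations
run on the full frame series — zero-phase filtering needs contiguous samples
— and censoring masks are applied afterwards, when correlations are formed.
Exact-duration sampling (e.g., exactly 10 minutes of retained frames, drawn
uniformly at random under a caller-supplied seed) equalizes scan duration
across participants before correlation.

# Connectivity and templates

Dense connectivity is the Pearson correlation of every grayordinate pair
over retained frames. Because subcortical SNR differs from cortical SNR, the
matrix is z-scored separately within five structural blocks: left and right
within-hemisphere cortex, inter-hemispheric cortex, subcortex, and
cortex–subcortex. The source method names hemispheres, subcortex, and
cortex–subcortex; a separate inter-hemispheric block keeps each named block
pure. Block statistics are computed over off-diagonal entries and the
diagonal is zeroed in the normalized matrix.

Network templates come from a template cohort and an initializing group
parcellation: each network's mean time series is correlated against all
grayordinates per participant, the seed maps are averaged across the
template cohort, each averaged map is z-scored **across grayordinates**, and
the support is thresholded at $z \ge 1$ — which keeps the top
$1 - \Phi(1) \approx 15.9\%$ of connections. Standardizing within each map is
what makes that fraction hold; it also makes supports invariant to
location-scale changes of the input maps.

# Template matching with eta-squared

Each grayordinate's connectivity row is binarized at $z \ge 1$ and compared
with each template's binary support using the image-similarity coefficient

$$\eta^2 = 1 - \frac{\sum_i \big[(a_i - m_i)^2 + (b_i - m_i)^2\big]}
  {\sum_i \big[(a_i - \bar M)^2 + (b_i - \bar M)^2\big]},
  \qquad m_i = \tfrac{a_i + b_i}{2},\; \bar M = \mathrm{mean}(m).$$

The coefficient is 1 for identical patterns and symmetric in its arguments.
Three choices here were genuinely open and are worth recording:

* **Binarized, full-length comparison.** The comparison uses binary vectors
  over *all* grayordinates, shared zeros included. We prototyped the
  alternative of comparing over the union of the two supports and rejected
  it: with union support the similarity of unrelated patterns collapses to
  ~0 and of matching patterns to ~1, so the empirical distributions sit at
  the extremes and the bimodal-threshold machinery below (whose search
  window is fixed at $\eta^2 \in [0.4, 0.7]$) never sees the valley.
  Full-length comparison places unrelated pairs near ~0.45 and matching
  pairs near 1 — the regime the fixed window presumes. A side effect worth
  knowing: two *disjoint* equal-size supports in a large space score about
  0.5, not 0, because the shared zero background is concordant; what matters
  for assignment is the ordering (disjoint < partial < identical), which
  holds throughout.
* **Winner-take-all tie-break** is the lowest palette index, with ties
  counted and reported. All-zero profiles stay unassigned.
* **Binary fast path.** For binary vectors $\eta^2$ reduces to a closed form
  in the four concordance counts, which lets the K × n_gray profile be
  computed with two matrix products; a test pins the fast path to the scalar
  formula.

# OMNI mapping

Instead of the argmax, OMNI assigns every network whose $\eta^2$ exceeds a
per-network, per-participant data-driven threshold. The threshold is found
from the distribution of that network's $\eta^2$ values across
grayordinates: 10,000 fixed-width bins on $[0, 1]$ (so bins 4,000–7,000 mean
$\eta^2 \in [0.4, 0.7]$), a cubic-spline fit of the counts at bin centres,
Savitzky–Golay smoothing with a 2,000-point window and polynomial order 3,
and the local minimum of the smoothed curve located by the first
negative-to-positive sign change of its central-difference derivative inside
the window. Numerical guards added around that rule, all visible in
`find_bimodal_threshold()`:

* The filter needs an odd window, so 2,000 is widened to 2,001 bins.
* A candidate minimum counts only if the curve rises by more than 1% of its
  peak on **both** sides over the full support (the modes themselves may sit
  outside the window) *and* the candidate sits below half the peak height.
  Without these guards, filter ripple on the flank of a narrow mode — the
  typical situation when a few thousand values occupy 10,000 bins — produces
  spurious minima, and flat tails of unimodal distributions produce
  micro-minima.
* If no candidate qualifies the fallback is the argmin of the smoothed curve
  in the window, flagged `fallback_used`, as happens for genuinely unimodal
  distributions.

Assignment is strict (`>` the threshold). Overlap counts are column sums of
the membership matrix; cohort-mean counts thresholded at 2.2 networks, with
30-grayordinate minimum cluster size, give the integration-zone region set.

# Community-detection consensus

The map-equation optimizer itself is prior art and pluggable: any function
from a weighted edge list to a membership vector can serve as the backend
(`igraph::cluster_infomap` ships as the optional adapter; the deterministic
reference backend is connected components plus seeded label propagation).
The package's own contribution is the layer around it: connections closer
than 30 mm are zeroed (to avoid spatial-smoothing bias), the matrix is
thresholded at a ladder of edge densities (0.3–3%, extendable to 4–5% for
combined cortical+subcortical runs), each density's communities are
relabeled against a reference parcellation by Jaccard index, and a consensus
map takes each grayordinate's label at the *sparsest* density where it was
assigned.

Relabeling follows a greedy claiming pass in priority order — large,
well-known networks first — where each network is claimed by the unlabeled
community with the highest Jaccard index (minimum 0.1); communities left
over after the pass take their best-matching network irrespective of claims,
so several communities may share one network name, and communities below the
0.1 floor stay unassigned. The intra-tier order of the priority list is the
order in which the networks are conventionally listed. Contiguous clusters
smaller than 30 grayordinates are merged into the adjacent network with the
largest total size, iterating to a fixed point; group-level networks of 400
or fewer grayordinates are dropped to unassigned in group-average runs.

# Reliability

Split-half reliability splits each participant's frames (interleaved by
default), maps each half, and compares the two maps with normalized mutual
information, normalized by the arithmetic mean of the two entropies —
a convention choice; the source codebase's normalization is not printed.
Unassigned grayordinates are excluded pairwise: absence of evidence is not a
community. The intra-participant NMI distribution is tested against the
null of cross-participant half pairs with a one-tailed Welch t-test
(fractional degrees of freedom via Satterthwaite), matching the unequal
variance assumption reported for this design.

Subset reliability samples participants without replacement at a ladder of
sizes, correlates each subsample's edge-wise brain–behavior vector with a
reference vector from an independent group, and fits

$$y = y_0 + a\,(1 - e^{-bx})$$

by Levenberg–Marquardt nonlinear least squares with $b \ge 0$, starting from
$y_0 = \min y$, $a = \max y - \min y$, $b = 1/\mathrm{median}(x)$. A constant
response is detected up front and returned as a degenerate fit with $a = 0$
rather than passed to the optimizer.

# The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` plants $K$ networks as the nearest-centre partition of a
synthetic grayordinate geometry: two mirrored hemispheric caps of a 70 mm
sphere plus an interior subcortical ball, with a symmetrized 6-nearest-
neighbour adjacency. Network centres are seeded by farthest-point sampling
and refined by Lloyd iterations so planted territories are comparable in
size — without that refinement the smallest member network of a hub zone has
systematically depressed $\eta^2$ (similarity scales with territory size)
and overlap recovery degrades for reasons unrelated to the method. Each
participant jitters the centres by isotropic Gaussian noise (3 mm default),
hub zones mix three networks at equal weight 1/3, BOLD arises as the
membership-weighted mixture of band-limited (0.009–0.080 Hz) unit-variance
latent network signals plus white noise at $1/\mathrm{SNR}$, and motion
traces are random walks with ~0.02 mm baseline FD plus isolated 0.5 mm
spikes at a configurable rate.

Default study conditions (chosen once): 20 participants per test group,
1,500 grayordinates (40/40/20% left cortex / right cortex / subcortex),
$K = 8$, SNR 4, 3 mm jitter, 750 frames at TR 0.8 s (10 minutes), 2% spike
probability. Hub geometry requires a calibration of its own, prescribed by
the generator's overlap-count contract (group-mean count well above 2.2
inside zones, near 1 outside):

* Zones mix **three** networks — a two-network zone can never exceed the 2.2
  mean-count threshold.
* A zone must hold at least 30 grayordinates (the minimum detectable cluster)
  yet remain a small fraction of a network's territory, because the
  $\eta^2$ crosstalk a zone induces in its partner networks' profiles scales
  with the zone's share of a territory. At 1,500 grayordinates those two
  requirements collide (a 30-grayordinate zone is ~25% of a territory), so
  overlap validation uses a denser preset, `omni_cohort_spec()`: 4,000
  grayordinates with 15 mm zones (~7% of a territory).

What the generator does *not* emulate: hemodynamics, physiological noise,
scanner drift, spatial autocorrelation of noise, multi-site effects, real
cortical geometry, or continuous (graded) network membership outside the
designated zones. Tests passing on this cohort demonstrate that the
implementations recover *planted* structure under controlled noise; they do
not certify performance on real fMRI, where preprocessing residuals and
topographic variability are richer.

One consequence of the equal-weight zones: winner-take-all assignment inside
a zone is undefined by construction (three exactly tied memberships), so
single-assignment accuracy and probability-map replication are evaluated
outside zones; the zones are the business of the OMNI pathway.

# Problem sizes and runtime

Validation runs use 50-participant cohorts (10 template participants plus
two 20-participant test halves) at 1,500 grayordinates for template
matching, probabilistic atlases and split-half reliability, and at 4,000
grayordinates for overlap and integration-zone recovery; these sizes give
stable estimates of every validated quantity while keeping a full validation
run in the tens of minutes on one CPU. Dense matrices are held in double
precision in memory; CIFTI-2 files store float32.

# File formats

Two dialects are supported everywhere: CIFTI-2 (`.dtseries.nii`,
`.dscalar.nii`, `.dlabel.nii`; NIfTI-2 container with the CIFTI XML header
extension, float32 payload) and a plain-text dialect — UTF-8, tab-delimited,
one frame per row, with a JSON sidecar carrying the repetition time,
structure tags, coordinates and (for label files) the palette. Grayordinate
indices are 0-based in files and 1-based in R. Standard CIFTI-2 does not
carry surface coordinates; the writer stores them in the CIFTI Matrix
metadata so spaces survive a roundtrip, and files from other tools that lack
them are read with placeholder geometry and a warning.

# Known limitations

* The subcortex is a single structure tag; the source pipelines distinguish
  thalamus, cerebellum, and other structures, and whether block z-scoring
  should split them further is unresolved.
* The map-equation optimizer is not re-implemented; the reference backend is
  a deterministic stand-in adequate for planted-partition graphs.
* Surface smoothing before seed extraction is out of scope (no surface
  meshes), and volumetric registration is not supported.
* The eta-squared formula follows the image-similarity lineage of the
  template-matching literature; the source work does not print its exact
  form, so small numerical differences from other implementations are
  possible.
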