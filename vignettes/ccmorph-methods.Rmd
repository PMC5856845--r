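---
title: "Nerve fiber morphometry from corneal confocal microscopy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nerve fiber morphometry from corneal confocal microscopy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccmorph)
```

# The measurement problem

The corneal sub-basal plexus is a quasi-two-dimensional mat of
unmyelinated nerve fiber bundles imaged in vivo by corneal confocal
microscopy (CCM). Individual axons (0.2–2 µm) are below the resolution of
the instrument; the bright curvilinear structures in a frame are bundles
whose width grows with the number of axons they carry. Small fiber
neuropathy thins this plexus, and — more subtly — reshapes the
*distribution of bundle widths*: bundles near the healthy modal caliber
(~3.2 µm) drop out preferentially, while very thin and thick bundles are
relatively preserved.

One-dimensional endpoints (fiber count, branch count, total length) ignore
caliber. `ccmorph` therefore computes, alongside NFD/NBD/NFL, two
*area* endpoints that carry width information: a width-integrated skeleton
area (NFA WxL) and a direct pixel-counting mask area (NFA FIJI), plus the
width-frequency histogram itself. All endpoints are normalized by the
imaged corneal area in mm², so they are comparable across devices once the
pixel pitch is known (`calibration()`; the HRT III default is 384 px over
400 µm, i.e. 1.0417 µm/px and a 0.16 mm² field).

# Segmentation: adaptive threshold with a tubularity gate

`segment_nerves()` builds the binary nerve mask in four steps.

1. **Contrast enhancement.** A Gaussian blur at `enhance_sigma_px`
   (default 0.9 px) suppresses pixel noise. Small values matter: blurring
   at scale $\sigma_e$ widens a bundle of intrinsic profile scale
   $\sigma$ to $\sqrt{\sigma^2+\sigma_e^2}$, biasing every downstream
   width estimate, so the default is as small as noise suppression
   allows.
2. **Adaptive background threshold.** The local background is a
   large-scale blur (`bg_sigma_px = 32`), which tracks illumination
   gradients. The threshold margin above background is
   `threshold_k` × the *local contrast spread*, defined as the local peak
   of (enhanced − background) over a disc (`spread_radius_px = 6`),
   floored at `noise_floor_k = 6` MADs of the contrast image. Because the
   spread tracks each bundle's own peak amplitude, `threshold_k = 0.43`
   cuts every bundle at a near-constant fraction of its peak brightness
   regardless of how bright it is — so the mask width approximates the
   full width at half maximum of the bundle profile, and dim bundles are
   not swallowed by bright neighbours. In fiber-free regions the MAD
   floor keeps noise out.
3. **Tubularity gate.** A Frangi-type ridge measure from the eigenvalues
   of the scale-normalized Hessian (`tubularity_map()`, scales 1–3 px,
   blobness β = 0.5, structure scale c = half the maximal Hessian norm)
   suppresses blob- and edge-like false positives. Eigenvalue ridge
   filters respond weakly *exactly at crossings and branch points* (both
   principal curvatures are strongly negative, which the blobness term
   penalizes), so the response is smoothed at 1.5 px before gating: the
   strong response on the adjoining arms then carries the junction
   pixels, and bundles are not disconnected where they branch or cross.
4. **Component filter.** Connected components below
   `min_component_px = 30` are discarded.

The defaults were calibrated once on seeded phantoms (straight bars of
2–6 px width, then full plexus phantoms) so that mask area, skeleton
length and distance-transform widths recover the generator's ground
truth; they are all exposed in `seg_params()` for other devices or
imaging conditions.

`compute_nfa_fiji()` is deliberately computed on the *raw* mask — no gap
bridging, no hole filling, no smoothing — because the pixel-counting area
is meant to preserve fine structure (beading, caliber variation) that
heavier processing chains erase.

# Skeleton morphometry

`skeletonize_mask()` thins the mask to a one-pixel medial axis
(Zhang–Suen, followed by removal of redundant staircase pixels), then
builds a graph. Digital skeletons need care in several places, each
handled explicitly:

* **Node classification** uses the number of 8-connected components of a
  pixel's neighbours (1 = endpoint, 2 = path, ≥3 = junction), which is
  robust where the raw neighbour count over-triggers on staircase
  corners. Adjacent junction pixels merge into a single node.
* **Edge length** is measured on a lightly smoothed sub-pixel polyline
  (moving average, endpoints pinned). The raw 8-connected chain metric
  (1 / √2 steps) overestimates smooth curve length by up to ~8% at 22.5°;
  smoothing removes this digitization bias. The classic chain rule is
  available as `length_method = "chain"`.
* **Small interior holes** (sub-threshold noise pixels inside a bundle)
  are filled *before thinning only*, so the medial axis does not wrap
  around them; the mask and NFA are untouched.
* **Shallow junctions** often trace as a smooth pass-through plus a
  dangling stub; dangling ends adjacent to another edge's interior are
  snapped onto it, creating the junction the geometry implies.
* **Terminal spurs** shorter than `prune_um = 5` µm hanging off junctions
  are pruned as thinning artefacts.

`classify_fibers()` reconstructs main bundles by straightest-continuation
chaining: at each junction, incident edges are paired greedily by
smallest turning angle (directions estimated over path pixels 3–16, past
the 1–3 px jog that digital junctions produce) up to `max_turn_deg = 75`.
Chains of at least `main_min_length_um = 50` are main fibers; remaining
edges ≥ 10 µm touching a main fiber are branches; the rest are orphans
that count toward NFL only. Chains whose free ends face each other across
a gap ≤ 15 µm, aligned within 40°, are counted as a single fiber — a
counting-level repair for the rare dim stretch the threshold drops; no
pixels are invented and the gap adds no length. These thresholds mirror
common automated CCM analysis conventions and are all configurable.

`measure_widths()` reads the bundle width at each skeleton pixel as
`2d − 1` px, where `d` is the Euclidean distance transform value (distance
to the nearest background pixel centre); `2d − 1` is twice the distance to
the mask *boundary*. Distances are averaged over a 5-pixel window along
each edge before rounding, which removes an odd/even parity artefact of
the discrete transform on oblique fibers. Widths clamp to the 1–8 px
band. A perpendicular ray-casting estimator is kept internally as a
cross-check; the two agree within 1 px on straight bars.

`compute_variables()` then assembles, per mm² of field:
NFD = main fibers, NBD = branches, NFL = total skeleton length (all
edges), NFA WxL = Σ width·dl along the skeleton, and the length-weighted
mean width, which satisfies `nfa_wxl = 1000 · nfl · mean_width_um` by
construction. A literal "sum of width pixels × number of length pixels"
product is available behind `literal = TRUE` for comparison; its
magnitude is not an area density, which is why the integrated reading is
the default.

# Width distributions

`width_histogram()` counts skeleton pixels per integer pixel-width bin
(1–8), normalized per image; group curves are unweighted means of
per-image distributions (`average_width_distributions()`), so every image
contributes equally and normalization is preserved. `fit_width_model()`
fits a three-parameter bell on the width axis (gaussian) or log-width
axis (lognormal) by least squares (Levenberg–Marquardt); healthy-like
distributions are near-symmetric and both families fit comparably.
`midwidth_dropout()` summarizes the diagnostic band: the ratio of
2.8–4.0 µm mass (inclusive left, exclusive right edge on bin centres)
between a distribution and a reference.

# Statistical toolkit

* `roc_analysis()` — AUC as the Mann–Whitney concordance probability
  (ties half-weight), Hanley–McNeil closed-form SE with
  $Q_1 = A/(2-A)$, $Q_2 = 2A^2/(1+A)$, the empirical curve, and the cut
  point maximizing TP+TN (ties to higher sensitivity; the Youden point is
  also reported).
* `compare_auc()` — z-test
  $z = (A_1-A_2)/\sqrt{SE_1^2+SE_2^2-2r\,SE_1 SE_2}$. For paired designs
  the AUC–AUC correlation $r$ is estimated from the empirical covariance
  of the Mann–Whitney structural components (the quantity the classic
  lookup-table recipe approximates); the average within-class score
  correlation is available as `r_method = "score"`, and
  `compare_auc_boot()` provides a stratified-bootstrap cross-check.
* `passing_bablok()` — method-comparison regression: the slope is the
  shifted median over pairwise slopes (slopes of −1 excluded, median
  index offset by the count of slopes < −1), CIs from binomial rank
  bounds. Exact affine equivariance holds when no pairwise slopes cross
  −1, the usual situation when two methods measure the same quantity.
* `fit_quadratic()` — ordinary least squares for the curvilinear
  length–area relation (method-comparison regression is kept for paired
  same-quantity measurements; a curved mean relation is a model fit, so
  OLS is the right tool).
* `normalize_variable()` — square-root transform for right-skewed
  area-like endpoints with Shapiro–Wilk W before/after
  (`stats::shapiro.test`).
* `ancova_change()` — `lm(followup ~ baseline + arm)`; the arm
  coefficient is the baseline-adjusted net change.
* `mdc()` — SEM · 1.96 · √2, the 95% smallest detectable change for a
  test–retest design. Both the distributional SEM (sd/√n) and any
  reliability-based SEM the user supplies are accepted; the function
  takes the SEM itself.
* `summarize_groups()` — descriptives, percent-of-control, within-group
  Pearson correlation matrices, and Tukey HSD group comparisons
  (`aov` + `TukeyHSD`).

# The synthetic test bed

`random_plexus_spec()` emulates healthy plexus morphology: roughly
horizontal, near-parallel bundles spanning the field (vertical slots with
±6 px jitter and 6 px/control-point wander — sub-basal bundles are
notably parallel), log-normal widths with median ~3.1 µm and log-sd 0.25
clamped to the measurable 1–8 px band, 0–2 branches per bundle of
25–45 px, periodic beading (amplitude 0.10, period 25 px), rendered with
a Gaussian cross-section whose FWHM equals the nominal width
(σ = width/2.355) so that "width" is well defined for a half-maximum-type
estimator, on a background of 40 grey levels with Gaussian noise
(sd 15, i.e. SNR 8 at the default amplitude 120). `generate_plexus()`
records truth (counts, lengths, widths, analytic width×length area)
before degradation; the same seed always reproduces the same image
bit-for-bit.

`apply_neuropathy()` models severity as width-selective dropout — removal
probability `severity · exp(−(w − 3.2)²/(2·0.4²))`, i.e. centered on the
healthy modal caliber with the preferentially lost band ≈ 2.8–4.0 µm —
plus mild swelling of survivors (8% at full severity). The swelling
default is deliberately non-zero: with the removal kernel centered on the
distribution mean, pure dropout leaves the surviving mean width nearly
unchanged, whereas neuropathic plexi shift toward thicker bundles;
individual fiber swelling is the standard proposed mechanism. Together
these reproduce the qualitative severity structure: mid-band mass falls
monotonically (to ~65–70% of normal at full severity in the default
cohort) and mean surviving width rises monotonically.

`generate_cohort()` draws per-subject endpoint vectors from correlated
multivariate normals truncated at zero; `ccm_reference_groups()` bundles
representative group means/SDs for healthy controls, four diabetic
severity bands and sarcoidosis at typical clinical sample sizes, with a
default inter-endpoint correlation of 0.85 (healthy-cohort endpoint
correlations run ~0.83–0.91).

What passing phantom tests does *not* show: the generator has no optical
speckle, no depth-of-focus variation, no mosaicking seams, no
image-quality spread, and its "truth" widths are nominal rather than
anatomical. Recovery on phantoms validates the algorithmic chain, not
clinical accuracy on real images.

# Numerical choices and problem sizes

Convolutions are FFT-based with replicate borders (EBImage). The Frangi
structure scale c re-derives per image as half the maximal Hessian norm;
a constant image returns an all-zero tubularity map rather than an error.
Degenerate statistical inputs fail loudly (empty classes, identical x in
regression, single-arm ANCOVA) or are flagged (Shapiro–Wilk on constant
data, non-converged width-model fits). Validation suites use 50-phantom
batches at 384×384 (about a minute end to end on one CPU), 100–200
replicate simulations for the statistical oracles, and a bootstrap with
800 resamples for the correlated-AUC cross-check; these sizes give
Monte-Carlo noise comfortably below each property's acceptance margin.

# Known limitations

* Two bundles sharing a ridge for a stretch (near-tangent courses) are
  intrinsically ambiguous in a medial-axis representation; counts there
  can be off by one. This is the dominant residual error mode in phantom
  NFD recovery (~90% exact at realistic densities).
* Width saturates at 8 px by design, so very thick bundles are reported
  at the cap, and widths below ~1.5 px are dominated by the enhancement
  blur.
* The straightest-continuation and branch rules are conventions; other
  automated CCM packages use unpublished variants, so absolute NFD/NBD
  values are comparable only within a fixed rule set (endpoint
  *definitions* here match the field's standard meanings, but are not
  bit-compatible clones of any proprietary tool).
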