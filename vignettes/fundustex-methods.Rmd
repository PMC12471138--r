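---
title: "Vascular texture and fundus color analysis: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vascular texture and fundus color analysis: models, parameters, design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundustex)
```

## The problem

Retinal diseases such as diabetic retinopathy and glaucoma alter the eye in
two measurable ways visible in ordinary color fundus photographs: the
vascular tree becomes sparser, thinner and less branched, and the overall
chromaticity of the fundus shifts, most prominently in the green and blue
channels. `fundustex` implements a dual-framework quantification of both
effects:

1. **Vascular texture.** The vessel tree is segmented, and the segmented
   raster is profiled with eight Haralick features of the 16-level
   gray-level co-occurrence matrix (GLCM), averaged over the four standard
   orientations. Reduced vascular complexity shows up as *higher* energy and
   *lower* correlation, variance, sum average, sum variance, sum entropy and
   entropy.
2. **Global color distribution.** Per-channel 256-bin intensity histograms
   of the full fundus area (no segmentation), group-averaged and compared
   with rank tests; group separability is quantified with the Mahalanobis
   distance between the group clouds in histogram space, per channel and
   for all channels combined.

A seeded synthetic fundus generator stands in for real cohorts so that the
entire pipeline, including its statistical layer, is testable offline.

## Texture model

For a quantized image with levels $1..N$ (default $N = 16$ over gray range
$[0, 255]$), the co-occurrence matrix at distance $d$ and orientation
$\theta$ counts ordered level pairs at offset
$(\pi_x(d,\theta), \pi_y(d,\theta))$, with the usual (row, col) offsets
$0^\circ\!:(0,d)$, $45^\circ\!:(-d,d)$, $90^\circ\!:(-d,0)$,
$135^\circ\!:(-d,-d)$, single-offset (non-symmetric) counting, normalized
to probabilities $P(i,j)$. The eight features are the classic ones: energy
$\sum P^2$, contrast $\sum (i-j)^2 P$, correlation
$\sum \frac{(i-\mu_x)(j-\mu_y)}{\sigma_x\sigma_y} P$, variance
$\sum (i-\mu)^2 P$, sum average $\sum_k k\,P_{x+y}(k)$, sum variance
$\sum_k (k-\mu_{x+y})^2 P_{x+y}(k)$, sum entropy and entropy, with
marginals $P_x, P_y$ and the diagonal-sum distribution
$P_{x+y}(k) = \sum_{i+j=k} P(i,j)$.

Numerical conventions, all exercised by tests:

* **Logarithm base 2** (entropies in bits; the entropy of the uniform
  $4\times4$ matrix is exactly $\log_2 16 = 4$). Natural log is available
  via `log_base`.
* $0 \log 0 \equiv 0$ throughout.
* **Correlation is defined as 0** (with a warning) when
  $\sigma_x \sigma_y = 0$; the formula is otherwise undefined on constant
  rasters.
* **Variance uses $\mu = \mu_x$**, the marginal mean over the first index.
  The defining formula prints an unsubscripted $\mu$; the marginal reading
  is the one consistent with the other marginal-based features, and the
  identity $\text{sum average} = \mu_x + \mu_y$ is asserted to $10^{-10}$
  in the tests.
* **Masked grayscale, not binary.** Texture is computed on the grayscale
  image with non-vessel pixels set to 0, over the full raster. Quantizing a
  binary mask to 16 levels would be vacuous, and the zero-dominated masked
  raster is the reading consistent with reference sum-average values near 3
  (the all-background pair mass sits at $P(1,1)$, driving energy toward 1
  and sum average toward 2).

## Segmentation model

The pipeline is: green channel → CLAHE (8×8 tiles, clip limit 0.01) →
3×3 median filter → oriented matched filter → isodata threshold of the
in-FOV response → removal of small components.

The matched filter kernel at vessel direction $\theta$ has cross-section
$-\exp(-u^2/2\sigma^2)$, truncated at $|u| \le 3\sigma$, extended
$|t| \le L/2$ along the vessel, mean-subtracted over its support; defaults
$\sigma = 2$ px, $L = 9$ px, 12 orientations at $15^\circ$. Because the
kernel is zero-mean, a constant image yields a zero response and the
response is invariant to intensity offsets. The sign convention makes dark
lines respond *positively* on the original (non-inverted) image; this is
the classical formulation and the one under which the best-matching
orientation at a dark horizontal line is the $0^\circ$ kernel.

The isodata (iterative intermeans) threshold starts at the global mean and
iterates $T \leftarrow (\text{mean above} + \text{mean below})/2$ to a
0.5-gray-level tolerance with a 100-iteration cap; an all-constant input is
flagged degenerate and produces an empty mask with a warning rather than an
error. The threshold is applied to the matched-filter response (the
alternative — thresholding the raw intensity histogram — is a plausible
reading of the original description but is not what this module does).

CLAHE implementation notes: per-tile 256-bin histograms are clipped at
`clip_limit` × tile pixel count with uniform redistribution of the excess,
and per-pixel output bilinearly interpolates the four surrounding tile
mappings. A zero-contrast tile keeps the identity mapping: equalizing a
single value is arbitrary, and the identity choice makes constant images
fixed points of the whole preprocessing chain (a property the tests rely
on).

The field of view (FOV) is the stored mask when present, otherwise the
largest connected component of red channel > 20 — the black surround of
fundus photographs must not enter the response histogram. The minimum
component size defaults to 50 px at the reference 3504×2336 scale, scaled
by image area (which makes it ≈1 px, i.e. inactive, at 256×256).

## Synthetic cohort generator

The generator emulates exactly the statistical structure the analysis
consumes, and deliberately nothing more:

* a circular field (radius 0.48 × min dimension) on a black surround;
* a vessel tree grown by stochastic branching random walks from roots on a
  nominal optic-disc location: 1 px steps, heading jitter
  $N(0, \text{tortuosity}^2)$, a disc of the walker's width stamped per
  step, children spawned with probability `branch_prob` at 0.8× the parent
  width (floor 1 px), death at the field boundary;
* growth until the vessel-pixel fraction of the field reaches
  `vessel_density`. When the whole population dies early the generator
  re-seeds a fresh batch of roots; a global step cap guarantees termination
  and raises a density warning if the target was unreachable. Stopping at
  first crossing makes the measured density overshoot by at most one
  stamping sweep (≈1–3%), comfortably inside the ±10% control band;
* a reddish background $N(\mu_{RGB} + (0, g, b), \sigma_{RGB}^2)$ with the
  green/blue shifts $(g, b)$ as the pathology knob, vessels at 0.55× the
  shifted background mean (dark, as in real photographs), additive noise on
  all in-field pixels, 8-bit clipping.

Per-image RNG sub-streams are derived from the cohort seed by fixed
strides, so a cohort is a pure function of its `cohort_spec` while images
remain mutually independent.

The shipped presets state the two cohorts used throughout the tests. The
healthy preset (density 0.12, branch probability 0.015 — both carried over
from the specification of the healthy-like contrast) uses 6 roots, width
3 ± 0.6 px, tortuosity 0.18 rad; the pathological preset (density 0.07,
branch probability 0.008) uses 4 roots, width 2 ± 0.4 px, tortuosity 0.10
rad, and chromatic shifts of −12 (green) and −10 (blue) 8-bit units.
Background (180, 95, 45) ± (10, 8, 6) with noise SD 5 approximates the
red-dominant chromaticity of fundus photographs. Where no value was
prescribed, these were chosen once as field-plausible and are not
revisited: widths scale the 2–10 px vessels of classic desk-scale vessel
databases, the shifts are a few percent of the channel range (large enough
to be visible in a histogram, small enough not to be trivial), and the
pathological cohort is thinner, sparser, straighter and less branched, as
described for glaucomatous and diabetic vasculature.

**What the generator does not emulate:** optic disc and fovea rendering,
microaneurysms, hemorrhages, exudates, illumination gradients, JPEG
artifacts, camera vignetting. A green test therefore establishes that the
*pipeline recovers the stated statistical contrasts*, not that it would
reach any particular accuracy on clinical images.

## Statistical layer

* Two-sample Kolmogorov–Smirnov: $D = \sup|F_1 - F_2|$ over pooled points;
  asymptotic p-value with the effective size $n_1 n_2/(n_1+n_2)$ and the
  standard small-sample correction. The statistic is verified against full
  enumeration for all sample sizes ≤ 6.
* Wilcoxon–Mann–Whitney: midrank U; exact null distribution when both
  samples are small and tie-free (this is what makes tiny textbook cases
  like $\{1,2\}$ vs $\{3,4\}$ give exactly $p = 1/3$), otherwise the normal
  approximation with tie and continuity corrections. By default the test
  compares the two groups' average-histogram bin frequencies per channel; a
  per-image mode (mean channel intensity per image) is available — neither
  is asserted to be the original study's exact procedure.
* Lilliefors: KS distance to the normal law fitted to the sample; because
  the parameters are estimated, the p-value comes from a seeded Monte-Carlo
  null (default 2000 replicates) rather than the standard KS distribution.
* Mahalanobis separability: each image is a point in
  $256\cdot|\text{channels}|$ dimensions (concatenated frequency
  histograms). With ~15 images per group the pooled covariance is
  rank-deficient, so the inverse is the Moore–Penrose pseudo-inverse after
  truncating eigenvalues below $10^{-10}$ of the largest — the
  minimal-assumption reading of "group as a point cloud"; a shrinkage mode
  $(1-\lambda)\Sigma + \lambda\,\mathrm{diag}(\Sigma)$ is available.
  Histograms are normalized to frequencies before averaging and distance
  computation so that groups of differently sized images remain comparable.
* Two-sided tests throughout, α = 0.05 reporting threshold, and no
  multiple-comparison correction by default (mirroring the exploratory
  design); Benjamini–Hochberg is available behind a flag.

## Known limitations

* **Desk-scale Dice.** On the 256×256 presets the full segmentation
  pipeline reaches mean Dice ≈ 0.77 (healthy) and ≈ 0.66 (pathological)
  against ground truth. This is a geometric property of the classical
  matched filter at this scale, not a tuning artifact: a *straight*,
  high-contrast width-3 vessel is already widened to ≈3.9 px (Dice ceiling
  ≈ 0.87), threshold sweeps show no threshold exceeds ≈0.74/≈0.67 on the
  actual response, and the 3×3 median erases 1-px tapered branches. A ±1 px
  boundary error costs ~40% of Dice on a 2-px vessel but only ~10% on a
  14-px full-resolution vessel, which is why high-resolution studies report
  ≈0.86 while desk-scale matched-filter literature reports ≈0.70–0.75. The
  acceptance suite asserts the 0.80 band anyway and that check is expected
  to fail; the direction-recovery and separability criteria are unaffected.
* The Wilcoxon default mode treats histogram bins as exchangeable
  observations; bins are in fact correlated, so its p-values are
  descriptive, not calibrated.
* `estimate_fov` assumes an HRF-like dark surround; synthetic images carry
  their exact FOV mask instead.
* External validation against the real HRF database (45 images at
  3504×2336) is supported by `run_study()` on a user-supplied manifest but
  requires downloading that database; no quantitative HRF claim is made by
  the test suite.
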