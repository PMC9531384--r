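---
title: "Methods: segmental T1, map texture, and fibrosis quantification for allograft surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmental T1, map texture, and fibrosis quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Surveillance of pediatric heart-transplant recipients rests on endomyocardial
biopsy, which samples the right ventricle at random and misses focal disease.
Native T1 mapping offers a whole-heart alternative: myocardial edema and
fibrosis prolong T1, so rejection should raise segmental T1 values and — because
rejection is patchy — also make T1 maps more spatially heterogeneous. This
package implements the full quantitative chain needed to study that idea:

1. **Segmental T1** — 16-segment mean native T1, global mean and peak, with a
   900–1050 ms normal range and a strict `> 1050 ms` abnormality rule.
2. **Map texture** — gray-level co-occurrence matrix (GLCM) features of a
   single mid-ventricular slice after Otsu-based myocardial segmentation.
3. **Fibrosis** — percentage collagen on trichrome-stained biopsy images by
   colorimetric blue-pixel counting.
4. **Statistics** — group comparisons (no rejection vs rejection), three-group
   ANOVA, ROC/AUC, sensitivity at the abnormality cutoff, and Pearson
   correlations against graft-dysfunction markers.

No public imaging data accompany this problem, so the package ships a synthetic
phantom/cohort generator with known ground truth; every stage is validated
against that truth or against independent brute-force oracles in the test
suite.

## Segmental native T1

A study is an ordered base→apex stack of short-axis maps (eight by default).
The middle six slices are analyzed (2 basal, 2 mid, 2 apical); the most basal
and most apical slices are excluded as motion-prone. On basal and mid slices,
ROIs cover two septal segments and one combined lateral region (AHA segments
2, 3, 5+6 basally; 8, 9, 11+12 at mid-ventricle); apical slices contribute the
septal and lateral segments (14, 16). Anterior and inferior walls are never
analyzed — in small patients they suffer partial-volume contamination from
lungs, fat, diaphragm and stomach. That yields 16 ROIs per study.

Each ROI is restricted to the **radial middle third** of the wall
(`endo + w/3 ≤ r < endo + 2w/3`, `w = epi − endo`), avoiding blood pool at the
endocardium and partial volume at the epicardium. Note that the middle third
of the radius holds exactly one third of an annulus sector's area, a fact the
tests exploit.

Summary metrics are deliberately simple: the **global mean** is the unweighted
mean of the 16 segmental means (not pixel-weighted), and **peak T1** is their
maximum. A segment is abnormal when its mean is *strictly* above the upper
normal bound; values exactly at 1050 ms are normal.

Interobserver agreement uses the two-way random-effects, absolute-agreement,
single-measure ICC (ICC(A,1)); "intraclass correlation" alone is ambiguous, so
the form is recorded in the output. On phantoms the second reader is emulated
by rotating the segment layout a few degrees; because synthetic maps are
smooth and the layout is exact, phantom ICCs are near 1 — far above clinical
interobserver values, which absorb hand-tracing variability the phantom does
not model.

## Texture of the T1 map

Texture is computed on one mid-ventricular slice (the lower-indexed of the two
mid-tagged slices, configurable). The myocardium is segmented in two Otsu
steps: background vs signal, then myocardium vs the higher-T1 blood pool; the
largest connected component is kept and one pixel is eroded from the outer
boundary. A focal elevation can occasionally pull the second threshold below
bright myocardium and break the annulus; in that case the upper class is
re-split (hierarchical Otsu) so that only blood is excluded. The Otsu
implementation itself is exact: every distinct value is a histogram bin and
the between-class variance is maximized over all cuts, ties towards the lowest
cut.

In-mask values are min–max quantized to 256 levels
(`floor(255·(v − min)/(max − min))`, maximum mapping to 255), which makes all
downstream features invariant to positive affine transforms of T1 — texture
sees *relative*, not absolute, values. A `1e-7` guard inside the floor keeps
exact integer ratios stable against floating-point jitter.

The co-occurrence matrix accumulates, over the four distance-1 offsets
(0°, 45°, 90°, 135°), the pairs of in-mask neighbors; pairs with either pixel
outside the mask are skipped (no padding), and in symmetric mode each pair
counts in both orders. With `p(i, j)` the normalized entries, marginal
moments `μx, μy, σx, σy` and `μ = (μx + μy)/2`, the nine features are

| feature | formula |
|---|---|
| energy | Σ p² |
| contrast | Σ p (i − j)² |
| entropy | −Σ p log₂ p |
| homogeneity | Σ p / (1 + \|i − j\|) |
| correlation | Σ (i − μx)(j − μy) p / (σx σy) |
| sum average | Σₖ k p₍ₓ₊ᵧ₎(k) |
| variance | Σ (i − μ)² p |
| dissimilarity | Σ p \|i − j\| |
| autocorrelation | Σ i j p |

Conventions that shift feature values and are therefore recorded in the
output: levels are indexed from 0 (so sum average ranges over 0…510), entropy
uses base 2, and homogeneity uses the `1/(1 + |i−j|)` form (the
`1/(1 + (i−j)²)` variant is available behind a flag). All nine features are
checked against an independent double-loop implementation to 1e-10.

## Fibrosis quantification

Tissue pixels are those whose mean channel value falls below a background
luminance cutoff (default 240) and that are not manually excluded; collagen
pixels additionally satisfy the colorimetric rule `blue ≥ 100`,
`blue − red ≥ 20`, `blue − green ≥ 20` (an HSV hue-window rule is available).
Fibrosis percent is `100 · collagen / tissue`, exclusions removed from both
counts. The thresholds are recorded conventions, not clinical constants: the
synthetic slide generator draws palettes strictly inside (collagen) and
outside (cytoplasm) the rule, so recovery of the generated fraction is exact,
and the tests assert exactly that.

## Statistics

Two-group comparisons use the pooled-variance Student t-test (Welch behind a
flag); the three-group comparison is a classical one-way ANOVA (with two
groups, F = t², which the tests verify to 1e-9). ROC curves are empirical;
the AUC is the Mann–Whitney concordance probability computed from midranks,
so ties get half credit and the AUC equals the trapezoidal area under the
tie-grouped curve to 1e-12. The AUC p-value uses the tie-corrected normal
approximation of the Mann–Whitney statistic — the method is a recorded choice.
Features on which the rejection class scores *lower* (energy, typically) are
negated before curve construction so reported AUCs are ≥ 0.5, with the
direction recorded; sensitivity at a cutoff uses the same strict inequality
as the abnormality rule. Raw p-values are reported without multiple-testing
correction, and cases are treated as independent even though surveillance
cohorts contain repeat encounters — both caveats are stamped into every
report.

## The synthetic generator: what it emulates, and what it does not

A phantom slice is a disc-in-annulus: blood pool (1600 ms) inside an annular
myocardium (baseline ≈ 1000 ms) on zero background, at 1.4 mm/pixel. A
cohort draws per-case baselines from N(975, 25) ms — centered in the 900–1050
ms normal range — and assigns groups A/B/C with probabilities 0.74/0.12/0.14.
Rejection is emulated by two mechanisms:

* a global additive shift (defaults A/B/C = 0/40/80 ms), standing in for
  diffuse edema; these shift values are calibration knobs — the source
  material reports only group summaries on clinical data, not an effect size;
* wedge-shaped focal **hotspots** (Δ ~ U(120, 250) ms over 50–90° of arc),
  standing in for patchy inflammation. B/C cases draw `max(1, Poisson(rate))`
  hotspots (a rejection case with no heterogeneity would contradict the
  scenario being emulated), and the first hotspot always lands on the texture
  slice so the texture channel sees the pathology.

Markers are generated as `mean + sign·r·sd·z(peakT1) + sd·√(1−r²)·ε` with the
target correlation `r` (default 0.45) and signs fixed per marker (pressures
and BNP positive, ejection fraction and volumes negative). Fibrosis percent is
drawn independently of group, N(7.6, 4.5) truncated at 0.2% — the scenario in
which biopsy fibrosis carries no rejection signal.

**Noise model.** Map noise is a Gaussian field smoothed with a Gaussian
kernel (σ = 1.5 px) and scaled by `noise_sd` (20 ms), and pixel values are
rounded to integer milliseconds as scanner-exported maps are. Both choices
are load-bearing for texture. Fitted parametric maps are spatially smooth;
with truly independent per-pixel continuous noise, a few hundred mask pixels
quantized to 256 levels make nearly every co-occurrence pair unique, GLCM
entropy saturates at log₂(n_pairs) for *any* clean map, and focal lesions can
only lower it — the opposite of the heterogeneity effect the texture channel
exists to detect. Correlated integer-valued noise gives clean maps a
diagonally concentrated GLCM with headroom for lesions to add off-diagonal
mass. Setting `noise_smooth_sigma = 0` recovers the independent-noise model.

Not emulated: realistic cardiac shape and partial-volume mixtures, motion and
banding artifacts, inversion-recovery physics, antibody-mediated rejection
phenotypes, and hand-traced ROI variability. Consequently, passing tests
show the *measurement chain* is correct and the *statistical layer* behaves
as designed under known truth; they do not certify clinical effect sizes —
synthetic group separations (AUCs near 1) are deliberately stronger than
clinical ones.

## Numerical choices and degenerate inputs

* Otsu: exact over distinct values; constant input errors ("no separable
  classes"); ties to the lowest cut.
* Quantization: constant in-mask region → all-zero levels plus a recorded
  degenerate flag; GLCM correlation is then NA with a warning.
* GLCM: zero valid pairs is an error, never a silent empty matrix.
* Abnormality, sensitivity cutoffs: strict `>` throughout.
* All generator functions take explicit seeds, derive per-slice/per-case
  sub-seeds from them, and restore the caller's RNG state.

## Problem sizes used by the test suite

Simulation-heavy checks run at reduced image sizes chosen so the suite
completes quickly on one CPU: null-calibration cohorts use 48-px six-slice
stacks with 20 cases × 2000 replicates (the headline A vs B+C t-test holds
its 5% level); directional-effect checks use 64-px stacks at the study's own
cohort size, 50 cases × 200 replicates. The pipeline default (128-px,
8-slice, 50-case cohort) is what `scripts/acceptance.R` and the `analysis/`
drivers run.

## Known limitations

* Whether the "middle third" should be radial (implemented) or area-based is
  unspecified in the field; for an annulus the two happen to coincide in
  area fraction but not in shape.
* The GLCM conventions (offset set, symmetry, log base, homogeneity form,
  index origin) vary across texture toolboxes; results are only comparable
  when these recorded parameters match.
* Phantom ICC is near 1 and should not be read as a claim about human
  interobserver agreement.
* The colorimetric fibrosis thresholds are conventions; real slides need
  stain-specific tuning and manual exclusion masks.
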