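# t1tex

Quantitative analysis of cardiac MRI native T1 maps and biopsy histology for
heart-transplant surveillance, with a fully synthetic validation cohort.

## The problem

In pediatric heart-transplant recipients, allograft rejection is patchy and
the diagnostic gold standard — random endomyocardial biopsy of the right
ventricle — misses it. Native T1 mapping images the whole myocardium:
rejection-related edema and fibrosis prolong T1, raising segmental values,
and because the process is focal it also increases the *spatial
heterogeneity* of the map. `t1tex` implements the complete measurement and
analysis chain for studying this:

* **Segmental T1** — 16 septal/lateral ROIs over the middle six of eight
  short-axis slices (AHA segments 2, 3, 5+6; 8, 9, 11+12; 14, 16), each
  restricted to the radial middle third of the wall. Global mean T1 is the
  unweighted mean of the 16 segmental means; peak T1 is their maximum;
  segments are abnormal when strictly above the 900–1050 ms normal range.
* **Map texture** — Otsu-based myocardial segmentation of one
  mid-ventricular slice, min–max quantization to 256 levels, a symmetric
  256×256 gray-level co-occurrence matrix (GLCM) over the four distance-1
  offsets, and the nine classical features: energy, contrast, entropy,
  homogeneity, correlation, sum average, variance, dissimilarity,
  autocorrelation (e.g. energy = Σ p², entropy = −Σ p log₂ p,
  variance = Σ (i−μ)² p).
* **Fibrosis** — percentage collagen on Masson-trichrome slide images by a
  recorded colorimetric rule (blue ≥ 100, blue−red ≥ 20, blue−green ≥ 20)
  over a tissue mask with manual exclusions.
* **Statistics** — pooled t-tests of no-rejection (group A) vs rejection
  (groups B+C) and of biopsy grade 0R vs >0R; three-group ANOVA with a
  monotone-trend check; Mann–Whitney ROC/AUC (ties at half credit) for T1
  and texture metrics; sensitivity at the strict peak T1 > 1050 ms cutoff;
  Pearson correlations against graft-dysfunction markers (BNP, pressures,
  ejection fraction, volumes); ICC(A,1) for interobserver agreement.

No imaging data are public for this problem, so the package includes a
synthetic generator — annular LV phantoms with blood pool, spatially
correlated integer-ms map noise, group-wise T1 shifts, focal high-T1
hotspots for rejection cases, calibrated marker correlations, and trichrome
slides with exact ground truth — and every stage is tested against that
truth or an independent brute-force oracle.

## Worked example

The `analysis/` directory holds the study workflow as numbered drivers
(`01_simulate_cohort.R` … `05_group_stats.R`), writing tables under
`results/`. Step 3, texture analysis of the 50-case default cohort, prints:

```
Nine texture features per case written for 50 cases
Entropy:  A 6.95 bits, B+C 7.63 bits
Variance: A 1632,     B+C 6349
Energy:   A 0.0111,   B+C 0.0083
```

Rejection cases (B+C) are more heterogeneous: higher entropy and variance,
lower energy. Step 5 assembles the full report:

```
Group summary (T1, ms):
 group  n mean_t1_mean mean_t1_sd peak_t1_mean peak_t1_sd
     A 36       977.13     21.576       979.25     21.648
     B  3      1055.93     22.616      1227.06    147.998
     C 11      1062.71     19.021      1181.22     49.307

A vs B+C t-tests:
 measure mean_neg sd_neg mean_pos sd_pos         p
 mean_t1    977.1  21.58     1061  19.11 4.926e-17
 peak_t1    979.3  21.65     1191  74.97 2.132e-20

Peak T1 > 1050 ms: sensitivity 100%, specificity 100%
```

Group means rise with rejection severity, the A vs B+C separation is strong,
and in this cohort every rejection case peaks above the 1050 ms abnormality
cutoff. (Synthetic effect sizes are deliberately clean; clinical separations
are weaker.) The same computation is available in one call:

```r
library(t1tex)
cfg <- pipeline_config(cohort = cohort_spec(n_cases = 50, seed = 2022))
res <- run_pipeline(cfg, out_dir = "results")  # cohort.csv, report.{json,md}
res$report
```

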