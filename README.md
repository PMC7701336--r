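# cardioclust

Unsupervised discovery of rare pathological subpopulations in cardiac
cohorts described by nine image-derived shape and motion features.

Population cine-MRI cohorts are overwhelmingly healthy; the occasional
dilated cardiomyopathy (DCM) or right-ventricular abnormality (RVA) hides
as a handful of cases among thousands. `cardioclust` implements the full
analysis chain that finds them:

1. **Redundancy screening** of all feature pairs with Pearson's r and the
   maximal information coefficient (MIC, characteristic-matrix
   dynamic-programming approximation, `alpha = 0.6`, `c = 15`); a pair is
   flagged when |r| > 0.8 or MIC > 0.5 and one member is dropped.
2. **Gaussian mixture modeling** by EM (compiled core) with `tied`,
   `diag` and `full` covariance structures, Ward-partition plus
   k-means++ initialization, and BIC = −2 logL + p log n.
3. **Prevalence-gated model selection**: fix the covariance structure by
   minimal BIC, take every k within 0.5% of the minimum as a candidate,
   and choose the smallest candidate maximizing the number of *small*
   clusters — at most `floor(0.02 n)` cases, the size a genuine disease
   cluster can have in a screened cohort of prevalence below 2%.
4. **Threshold-rule labeling** (ACDC-style, strict inequalities):
   RVA ⇔ RV EDV > 110 mL/m² ∨ RV EF < 0.40;
   DCM ⇔ LV EDV > 100 mL/m² ∧ LV EF < 0.40 (LV EDV reconstructed via
   `V_LV_ED = V_LV_ES / (1 − EF_LV)`); a surrogate HCM rule
   (thickness > 15 mm with preserved EF). A small cluster is labeled
   when ≥ 90% of members satisfy a rule.
5. **Validation battery**: PCA projection of cases and cluster centers,
   pairwise Welch and Mann-Whitney tests over all (large-cluster pair,
   feature) cells, and Huber robust regression (IRLS, MAD scale,
   k = 1.345) of an outlier-contaminated reference measurement channel
   on the pipeline values.

A first-class synthetic-cohort simulator (`simulateCohort()`) generates
feature tables with the statistical structure this analysis assumes —
seven separable normal subgroups, planted 11-case RVA and 4-case DCM
subgroups across real density gaps, the exact `EF = 1 − ESV/EDV`
redundancy, pooled LV calibration (EDV ≈ 70.6 mL/m², EF ≈ 0.664), and a
noisy reference channel with known generative coefficients — so every
stage is testable end-to-end with ground truth.

## Worked example

```r
library(cardioclust)
run <- runPipeline(cohortSimConfig(), seed = 42)
run
#> PipelineRun on 3822 cases (seed 42 )
#> selected features: V_RV_ED, V_LV_ES, EF_RV, R_RVLV_ED, R_LVMLV_ED, MT_LVM_ED, RMD, TMD
#> ModelSelection: covType=tied, k=10
#> candidate k: 10, 11, 12
#> small-cluster threshold: 76 cases
#> small clusters per candidate: 10:2 11:2 12:2
#> ClusterLabeling: 3822 cases in 10 clusters (small threshold 76 )
#> cluster 9: 11 cases -> RVA (fraction 1.00)
#> cluster 10: 4 cases -> DCM (fraction 1.00)
```

Reading: screening dropped `EF_LV` (its |r| = 0.85 with `V_LV_ES` is the
one flagged redundancy), the BIC sweep over k = 2..12 and three
covariance structures kept k = 10..12 as candidates, and k = 10 is the
smallest candidate producing two clusters under the 76-case prevalence
gate. Those two clusters are exactly the planted pathological subgroups:
11 cases whose members all satisfy the RVA rule and 4 cases that all
satisfy the DCM rule. `run$gtComparison` additionally recovers the
reference channel's generative slope/intercept (1.002, 3.373 for EDV) by
Huber regression despite 2% gross outliers.

Classify any feature table directly:

```r
rva <- referenceClusterCases("rva")   # bundled 11-case reference table
sum(ruleRVA(rva$V_RV_ED, rva$EF_RV))
#> [1] 11
```

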