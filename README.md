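# mdsshift

Germline-control-free stratification of targeted-panel sequencing cohorts
by VAF frequency shifts, with survival inference — built for
myelodysplastic syndrome (MDS) panels that include immune-checkpoint
(PD-1, PD-L1, B7-H3, LAG3) and micro-RNA-processing (DICER1, DROSHA)
genes alongside the common myeloid drivers.

## The problem

Tumor-only panel sequencing of bone-marrow aspirates cannot separate
somatic mutations from inherited polymorphisms: there is no matched
germline sample. Yet both kinds of variation are informative — somatic
clones mark the malignant compartment, and unusual polymorphism patterns
can mark the patient. `mdsshift` implements a joint treatment:

1. **Filter cascade.** Variant calls are filtered by consequence class
   (synonymous / intronic / intergenic removed; UTR variants of checkpoint
   and miRNA-processing genes retained), population allele frequency
   (gnomAD-style AF > 1% removed), detection threshold (VAF ≥ 1% for the
   general analysis, ≥ 5% for common-driver reporting, always with ≥ 10
   supporting reads), and cohort prevalence (variants in > 50% of patients
   are displayed but not tallied). Variants seen in a single patient are
   excluded before clustering.
2. **Frequency-shift matrix.** For each variant *v*, the cohort median VAF
   (zeros included for non-detections) is rounded to the nearest **anchor**
   `a(v) ∈ {0, 50, 100}%` — the three values a germline genotype can take.
   Each patient's shift is `s(v, p) = VAF(v, p) − a(v)`, bounded in
   [−100, +100]. Germline-consistent genotypes give shifts near 0 or ±50/100
   (abnormal polymorphisms), somatic clones give intermediate positive
   shifts above an anchor of 0.
3. **Stratification.** Patients are clustered on the shift-matrix columns
   (Euclidean distance, Ward linkage) and the tree is cut into the top two
   clusters. Variants are ranked by Mann-Whitney tests of their shifts
   between clusters with Benjamini-Hochberg correction.
4. **Clinical and survival inference.** Cluster-wise Kaplan-Meier curves
   with Greenwood / complementary-log-log 95% bands, the two-group
   log-rank test, and multivariate Cox proportional hazards
   (cluster + IPSS-R ordinal score), all implemented natively
   (Newton-Raphson on the partial likelihood; Breslow or Efron ties) and
   cross-checked against the `survival` package in the test suite.

A seeded synthetic-cohort generator (`generate_cohort()`) emulates the
data-generating assumptions — Hardy-Weinberg germline layers with binomial
sequencing noise at 1000×, cluster-dependent somatic clones with
right-skewed Beta VAFs, exponential survival with a cluster hazard ratio —
so every stage is testable without any sequencing data.

## Worked example

```r
library(mdsshift)

co  <- generate_cohort(synthetic_config(seed = 42))   # 35 patients, 18 genes
fit <- mds_fit(co$records, clinical = co$clinical, panel = co$panel)
fit
#> Frequency-shift cohort stratification
#>   35 patients, 25 clustering variants (ward.D2 linkage)
#>   cluster sizes: 1: 22, 2: 13
#>   log-rank chi^2 = 7.255, p = 0.007072
#>   Cox cluster-2 HR = 0.17 (95% CI 0.05-0.61), p = 0.00668
```

The two clusters differ in survival: five-year overall survival is 26% in
cluster 1 versus 73% in cluster 2 (the generator assigned the higher
hazard to the latent group that happened to be labelled 1 here — labels
are ordered by patient id, not by risk), and the Cox hazard ratio between
them, adjusted for IPSS-R, is 0.17 (equivalently 5.9 for the high-risk
cluster). `summary(fit)` adds the most cluster-discriminant variants and
per-gene prevalence:

```r
head(summary(fit)$top_discriminant, 3)
#>             variant statistic            p   p_adjusted
#> 1 chr16:1001011:T:A        11 1.132553e-07 5.678878e-07
#> 2 chr13:1001048:A:C        11 1.135776e-07 5.678878e-07
#> 3 chr13:1001344:A:C        11 1.135776e-07 5.678878e-07
```

`labels(fit)`, `coef(fit)`, `predict(fit, newdata)` and `plot(fit)` give
the cluster labels, Cox coefficients, nearest-centroid assignment of new
VAF profiles, and the dendrogram/heatmap. `run_pipeline()` executes the
same analysis from a YAML/JSON config and writes a results bundle (shift
matrix, anchors, labels, Newick tree, discriminant ranking, prevalence,
burden, KM/log-rank/Cox tables, manifest); a thin command-line wrapper
with `run` / `simulate` / `validate` verbs is installed at
`inst/scripts/mdsshift.R`.

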