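---
title: "Frequency-shift stratification of tumor-only panel cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-shift stratification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdsshift)
```

## The model

`mdsshift` analyses small-variant calls from targeted panel sequencing of
cohorts without matched germline controls. The central object is the
**frequency-shift matrix**. For every variant that survives the filter
cascade, the cohort median VAF — computed over *all* patients, with 0 for
patients in whom the variant was not detected — is rounded to the nearest
member of \{0, 50, 100\}\%, the three values a diploid germline genotype
produces (hom-ref, het, hom-alt). This **anchor** is the cohort's typical
allele state for that locus. Subtracting it from each patient's VAF gives
a shift bounded in $[-100, +100]$ that exposes two signals at once:

* **Abnormal polymorphisms** — a patient whose genotype differs from the
  cohort's typical genotype shows a shift near $\pm 50$ or $\pm 100$;
* **Somatic clones** — variants rare in the cohort anchor at 0, so a
  clone's shift equals its VAF, an intermediate positive value that scales
  with clone size.

Because the median is taken over all patients including non-detections, a
variant must be common in the cohort before its anchor leaves 0 — rare
somatic variation can never be mistaken for a shared genotype. This is
the device that substitutes for a germline control: no per-patient
somatic/germline call is ever made, the cohort geometry absorbs both.

Patients (columns) are then clustered agglomeratively under Euclidean
distance and the tree is cut into the top two clusters, which become the
strata for clinical comparison and survival analysis.

## Filter cascade and its two regimes

All filters act per record and are contractions (idempotent, and the three
record-wise filters commute):

| filter | rule | default |
|---|---|---|
| functional | drop synonymous / intronic / intergenic; keep UTRs of checkpoint + miRNA-processing genes | see `checkpoint_mirna_genes()` |
| population | drop population AF > `pop_af_max`; missing AF kept | 0.01 |
| detection | keep VAF ≥ threshold **and** alt reads ≥ `min_alt_reads` | 1\%, 10 reads |
| prevalence | variants in > `prevalence_cap` of patients excluded from tallies, kept for display | 0.5 |
| singletons | variants in exactly one patient dropped before clustering | on |

Two threshold regimes coexist. Common myeloid drivers are reported at a
5\% VAF threshold restricted to exonic pathogenic classes, the
conventional presentation. The general analysis — including clustering —
uses 1\%, because checkpoint and miRNA-processing variants may live in
minor cell subpopulations (e.g. bone-marrow niche cells); at panel depths
of ~1000× a 1\% VAF still guarantees roughly ten supporting reads, and the
explicit `min_alt_reads = 10` guard enforces that when depth is lower.
Missing population AF is treated as rare (kept): absence from a population
database is evidence the variant is below any filterable frequency.

The cascade order (functional → population → detection → singletons) is a
package decision; the first three commute, and prevalence capping is
applied to reporting tallies only, not to the clustering matrix — the
clustering input excludes only singletons, so that shared abnormal
polymorphisms remain available as stratification signal.

## Numerical and procedural choices

* **Anchor ties.** A median exactly equidistant from two anchors (25 or
  75) rounds to the lower anchor. This is deterministic and biases ties
  toward treating the variant as rarer, the conservative direction for
  somatic interpretation.
* **Linkage.** The distance is fixed (Euclidean); the linkage is a free
  choice and `ward.D2` — Ward's minimum-variance criterion in its form
  consistent with raw Euclidean distances — is the default because it
  produces compact, balanced two-cluster cuts and is robust to the
  mixed germline/somatic scale of the shift matrix. `complete` and
  `average` are available through the configuration.
* **Label determinism.** `stats::hclust` is deterministic; cluster labels
  are additionally canonicalised so that label 1 contains the
  lexicographically smallest patient id (radix/C ordering, independent of
  locale). Reruns and column permutations yield identical partitions.
* **Discriminant ranking.** Per-variant two-sided Mann-Whitney tests of
  shifts between the clusters, Benjamini-Hochberg adjusted, sorted by raw
  p with ties broken by variant key. When the combined sample size is at
  most 20 the p-value comes from full enumeration of the permutation null
  using midranks (exact also under ties); above that, the normal
  approximation with continuity correction.
* **Fisher tests** (binary clinical contrasts) report the exact
  conditional p-value; the odds ratio is the sample cross-product ratio
  with the Haldane half-count correction when a cell is zero.
* **Kaplan-Meier.** Product-limit over distinct event times, Greenwood
  variance, 95\% bands on the complementary log-log scale (bounds stay in
  $[0,1]$, appropriate for small cohorts). Five-year overall survival is
  read at $t = 60$ months from the right-continuous step function.
* **Cox regression.** Newton-Raphson on the partial likelihood with
  step-halving; Breslow tie handling by default (Efron available) —
  at 1000× panel depth follow-up times are effectively continuous, so the
  tie method rarely matters. Convergence at relative log-likelihood change
  $< 10^{-9}$ or 100 iterations; a diverging coefficient path (monotone
  likelihood under perfect separation) is flagged as non-converged rather
  than reported as an estimate. IPSS-R enters as a single ordinal
  covariate (1–4), matching the pooled one-coefficient adjustment that a
  four-level score with a monotone risk gradient supports at n ≈ 35;
  category dummies would cost three degrees of freedom the cohort size
  cannot fund.
* **Degenerate inputs.** Zero-depth calls are rejected with a warning;
  an all-singleton cohort empties the clustering input with a warning and
  the fit refuses; no events ⇒ survival ≡ 1 with empty bands; a zero
  margin in a 2×2 table ⇒ p = 1 with a warning.

## The synthetic cohort generator

`generate_cohort()` draws cohorts with the statistical structure the
analysis assumes, so that recovery of known truth can be tested end to
end. Defaults describe the study conditions the package targets: 35
patients on an 18-gene myeloid panel at 1000× depth.

* **Germline layer** — 12 polymorphic sites, per-site alternate allele
  frequency 5\%, genotypes drawn from Hardy-Weinberg, true allele
  fraction ∈ \{0, 50, 100\}\%, observed depths Binomial(1000, AF). The
  sites carry no population-database annotation (missing `pop_af`),
  emulating cohort-specific polymorphisms that survive the gnomAD-style
  filter; setting `germline_pop_af` above 1\% instead routes them into the
  population filter.
* **Somatic layer** — 16 sites split 8/8 between the two latent clusters
  with disjoint gene preferences; a patient carries an own-cluster site
  with probability 0.85; clone VAFs are $1 + 59\,\mathrm{Beta}(2,3)$
  percent — right-skewed, as clonal hierarchies produce — plus binomial
  sequencing noise. Equal gene weights across clusters remove all
  genomic cluster signal (the null configuration).
* **Survival** — exponential, baseline hazard 0.0055/month (≈ 72\%
  five-year survival in the reference cluster), hazard ratio 4.2 for the
  second cluster, censoring Uniform(6, 120) months.
* **Clinical covariates** — sampled independently of cluster (age centred
  at 49, IPSS-R categories weighted toward high/very-high as in a
  transplant-centre population, log-normal blood counts), so that any
  survival association flows only through the cluster structure.

What the generator does **not** model: mapping and FFPE artifacts,
copy-number-driven VAF distortion, clonal phylogenies beyond independent
per-site carriage, and cell-population substructure (all low-VAF variants
are generic subclones — attributing them to niche cells or other
compartments is biology outside the data). Passing recovery tests on these
cohorts therefore demonstrates the statistical machinery, not robustness
to every artifact of real panel data.

## Simulation studies and their sizes

The test suite and `scripts/acceptance.R` run the following studies, sized
to give stable Monte-Carlo estimates while keeping the default run fast:

* cluster recovery: 50 replicates of 200-patient cohorts with the default
  (disjoint-weight) somatic layer; adjusted Rand index ≥ 0.9 expected in
  ≥ 90\% of replicates;
* Cox recovery: 200 replicates at n = 1000, true HR 2, ~20–25\% uniform
  censoring (mean estimate and CI coverage), and 100 replicates at
  n = 1000 where HR 4.2 is re-estimated through the *recovered* cluster
  label after aligning it to truth by majority agreement;
* null calibration: 200 replicates at unit hazard ratio (log-rank
  rejection rate at the 5\% level), and 25 replicates with equal somatic
  weights in which discriminant tests against the true latent labels are
  checked for Benjamini-Hochberg false-discovery control.

On the last point, a caveat worth stating plainly: ranking variants
between clusters that were themselves derived from the same shift matrix
is selection inference. Even with no cluster-dependent signal, a data-driven
partition separates patients who genuinely differ at individual sites, so
adjusted p-values between *recovered* clusters are anti-conservative and
the ranking should be read as exploratory ordering, not hypothesis
testing. The calibration study above therefore uses the true latent
labels, which is the well-posed null for the test machinery itself.

## Known limitations

* Two clusters are assumed primary (`k` is configurable but the
  survival stage models a single binary contrast).
* The anchor set \{0, 50, 100\} presumes diploid loci; copy-number
  alterations shift germline VAFs off these anchors and will read as
  signal.
* Prevalence percentages use the full enrolled cohort as denominator and
  integer rounding for display; raw fractions are always retained.
* The Cox implementation covers right-censored data with fixed
  covariates; no time-varying covariates, competing risks or
  proportionality diagnostics.
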