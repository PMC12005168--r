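# agetraj

Trajectory-based differential expression for aging time-course RNA-seq.

Most aging expression studies compare one "young" and one "old" timepoint and
can only conclude that a gene goes up or down with age. `agetraj` implements
the alternative: a multitimepoint design that samples an aging cohort
repeatedly across its whole lifespan — indexed both by chronological age
(days) and by physiological age (the fraction of the cohort that has died) —
and then asks not just *whether* each gene changes but *what shape* its
expression trajectory takes. The package is aimed at R users analyzing bulk
RNA-seq time courses over aging (or any process with a monotone
"progression" covariate), and at methodologists who want a fully seeded
synthetic cohort to study the behaviour of such designs.

## What it computes

**Differential expression.** Counts for gene *g* in sample *j* are modelled
as negative binomial, `K_gj ~ NB(mu_gj, alpha_g)` with
`Var = mu + alpha mu^2` and `log mu_gj = x_j' beta_g + log s_j`, where `s_j`
are median-of-ratios size factors. The same in-package GLM engine (IRLS,
profile-ML dispersion, Wald and likelihood-ratio tests, Benjamini–Hochberg
step-up) runs three analyses per gene:

* **Day** — age in days as a continuous covariate (Wald test on the slope);
* **Survival** — cohort mortality fraction as a continuous covariate (Wald);
* **Sampling Point** — the sampling points as a categorical factor, tested
  jointly by LRT against the intercept-only model, which catches genes whose
  trajectory neither continuous covariate describes.

A gene is age-related if any analysis reports adjusted *p* < 0.05; the union
feeds the trajectory stage.

**Trajectories.** Each significant gene's per-sampling-point mean of
normalized expression is standardized by the gene's overall mean and SD
(a Z-score trajectory), genes are clustered hierarchically on the Pearson
dissimilarity `d = 1 - r`, and each cluster's mean trajectory is classified
by ordinary regression on day: **LinearUp** / **LinearDown** if the slope's
*p*-value beats the Bonferroni threshold `0.05 / k` (0.002 at k = 28),
**Complex** otherwise.

**Two-timepoint reanalysis.** The same counts are re-analyzed as a classic
young-versus-old contrast (plus sliding "old" windows), and a concordance
table reports, per trajectory class, how many genes the 2-timepoint design
recovers and whether the inferred direction matches.

**Enrichment.** Clusters are tested for gene-set over-representation with a
one-sided hypergeometric test against a user-supplied background, BH-scoped
within each (cluster, collection) analysis; collections are read from GMT.

**Synthetic cohorts.** A seeded generator reproduces the study conditions
end-to-end: 15 sampling days from day 3 (99.9% alive) to day 59 (1.92%
alive) on a survivorship curve through those anchors, 3 replicates at 14
points and 6 at the last (48 samples), and NB counts from per-gene
trajectory templates (null, linear up/down, midlife peak, wave).

## Worked example

```r
library(agetraj)

design <- make_design()                       # 48 samples, SP1..SP15
truth  <- make_truth(1000, seed = 101)        # 50% null, 20%+20% linear, 5%+5% peak/wave
counts <- simulate_counts(truth, design, seed = 102)

de <- run_three_analyses(counts, design)
de
#> de_result_set: 1000 expressed genes, alpha = 0.05
#>   significant: Day = 432, Survival = 438, SamplingPoint = 646
#>   union: 664 genes

norm <- normalize_counts(counts[de$background_genes, ], de$size_factors)
traj <- zscore_trajectories(norm, design, genes = de$union_genes)
hc   <- hierarchical_cluster(pearson_dissimilarity(traj), linkage = "complete")
cl   <- cut_clusters(hc, 8)
prof <- characterize_clusters(traj, cl, unique(design$day))
prof$profiles[, c("cluster", "name", "slope", "p_value", "n_genes")]
#>   cluster         name         slope      p_value n_genes
#> 1       1 LinearDown-1 -0.0330097580 1.957802e-12     225
#> 2       2    Complex-1 -0.0002211252 9.820255e-01      60
#> 3       3    Complex-2 -0.0001793266 9.660100e-01      20
#> 4       4   LinearUp-1  0.0342947115 6.013415e-16     213
#> 5       5    Complex-3  0.0003427174 9.667450e-01      74
#> 6       6    Complex-4 -0.0055442519 1.505719e-01      42
#> 7       7    Complex-5 -0.0009191459 8.717360e-01      13
#> 8       8    Complex-6  0.0017493845 7.491304e-01      17

cr <- two_group_de(counts, design, young_days = c(3, 6), old_days = 59)
cc <- concordance(cl, prof, cr)
cc[cc$level == "class", ]
#>   level       name n_genes n_recovered fraction_up fraction_down fraction_missed direction_match
#> 1 class   LinearUp     213         201      0.9437        0.0000          0.0563               1
#> 2 class LinearDown     225         194      0.0000        0.8622          0.1378               1
#> 3 class    Complex     226          26      0.0354        0.0796          0.8850              NA
```

Reading the output: the Sampling-Point LRT finds the most genes (646 vs
~435 for each continuous analysis) because only it can see the
endpoint-symmetric peak and wave trajectories. After clustering the
664-gene union at k = 8, the two monotone clusters are classified Linear
with the expected signs and the peak/wave/noise clusters are Complex. The
2-timepoint reanalysis recovers ~86–94% of the Linear-class genes — every
one with the correct direction — but misses ~89% of the Complex-class
genes, whose start and end points are indistinguishable by construction.

The same flow is available as one call: `run_pipeline(pipeline_config(...))`
writes every stage table as TSV plus a YAML manifest with parameters and
checksums, from either a simulated cohort or user TSV/GMT inputs.

## Package layout

* `R/design.R` — survivorship curves (Weibull default, Gompertz available) and the sampling design
* `R/simulate.R` — trajectory truth tables and NB count simulation
* `R/nbglm.R` — size factors, NB GLM (IRLS), dispersion, Wald/LRT, BH
* `R/de.R` — the three-analysis engine and result sets
* `R/trajectory.R` — Z-score trajectories, Pearson dissimilarity, clustering
* `R/characterize.R` — cluster curves, spline smoothing, Linear/Complex calls
* `R/contrast.R` — young-vs-old contrasts, sliding windows, concordance
* `R/enrichment.R` — GMT I/O and hypergeometric over-representation
* `R/pipeline.R` — config, validation, end-to-end orchestration
* `vignettes/aging-trajectories.Rmd` — the methods vignette
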