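# mirmeta

Random-effects meta-analysis of miRNA expression with downstream target
integration, for two-group drug-resistance studies.

## The problem

Individual microRNA microarray studies of therapy resistance — for example
HER2-positive breast cancer cell lines or sera compared between
treatment-resistant and control groups — are typically small, run on
different platforms, and agree poorly on which miRNAs matter. `mirmeta`
implements the standard remedy as one tested pipeline: per-study
differential expression with empirical-Bayes moderated t-statistics,
study-level combination of log2 fold changes under a random-effects model,
and integration of the significant miRNAs with validated target genes,
functional enrichment, protein-interaction hubs, and survival.

Because such pipelines are usually assembled ad hoc around external
databases, every stage here is also exercisable offline: a synthetic-data
module generates multi-study inputs with planted signal (shared effects,
between-study heterogeneity, missing values, decoy species ids, decoy
interactions), so recovery, calibration and error control are all testable.

## The statistics

For each study, feature-wise two-group fits give the log2 fold change
(resistant − control), pooled variance s², and a moderated t in which s² is
shrunk toward a scaled inverse-chi-square prior estimated by the method of
moments on log s² (prior df d₀ and prior variance s₀²):

    s²_post = (d₀·s₀² + df·s²) / (d₀ + df),   t = logFC / (s_post·√(1/n₁+1/n₂))

Per-study standard errors are recovered from the identity SE = |logFC / t|,
giving inverse-variance weights wᵢ = 1/SEᵢ². Heterogeneity per miRNA is
assessed with Cochran's Q = Σ wᵢ(ESᵢ − ES_fixed)², chi-square on k−1 df
under homogeneity, and the between-study variance by the
DerSimonian–Laird moment estimator

    τ² = max(0, (Q − (k−1)) / (Σw − Σw²/Σw))

with combined effect ES = Σ w*ᵢ ESᵢ / Σ w*ᵢ, w*ᵢ = 1/(SEᵢ² + τ²),
z = ES·√(Σw*), and Benjamini–Hochberg control across all miRNAs. By default
the model is chosen per feature by the Q test (random effects when
heterogeneity is significant, fixed otherwise); always-random and
always-fixed policies are available.

Downstream: significant human ("hsa"-prefixed) miRNAs are mapped to
validated target genes, intersected with BH-significant |log2FC| > 1 DEGs
from validation mRNA studies, and the overlap genes are tested for term
over-representation (hypergeometric upper tail, Bonferroni/BH/Holm) with
Cohen-kappa grouping of redundant terms, ranked for PPI hubs by degree,
and evaluated by Kaplan–Meier curves with the log-rank test and an
observed/expected hazard ratio with 95% CI.

## Worked example

```r
library(mirmeta)

run <- run_pipeline(run_config(seed = 1))
run
#> <mirmeta_run>
#>   DEMs: 21 (9 up / 12 down) | DEGs per study: 177 / 176 / 172
#>   overlap genes: 104 | top term: TERM_PLANTED (adj p = 3.37e-103)
#>   top hub: GENE1688 (degree 10) | survival HR = 1.95 (log-rank p = 1.36e-05)
```

Twenty true miRNAs were planted; 21 pass the meta-analytic adjusted-p <
0.05 cut (all 20 planted ones plus one false positive), split into 9 up-
and 12 down-regulated. Each mRNA study calls ~170 DEGs (adjusted p < 0.05
and |log2FC| > 1); intersecting the union of DEGs with the validated
targets of the significant miRNAs leaves 104 candidate resistance genes.
The planted enrichment term tops the over-representation ranking, the
planted hub is the highest-degree network node, and the survival split of
the synthetic cohort recovers a hazard ratio near its generating value of
2.

Individual stages compose with pipes on tibbles:

```r
gen     <- synth_mirna_studies(synth_config(seed = 1))
studies <- lapply(gen$studies, function(st)
  if (any(st$missing_mask)) impute_missing(st, seed = 1) else st)
de   <- lapply(studies, de_analysis)
eff  <- purrr::imap_dfr(de, ~ study_effects(.x, study_id = paste0("study", .y)))
meta <- run_meta(eff)
glance(meta)
#> # A tibble: 1 × 6
#>   n_features n_sig  n_up n_down median_tau2 n_het
#>        <int> <int> <int>  <int>       <dbl> <int>
#> 1        300    21     9     12           0    37
autoplot(meta)   # volcano plot
```

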