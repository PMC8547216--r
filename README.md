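# comorbidnet

Disease–disease association discovery from longitudinal diagnosis records.

`comorbidnet` is an R package for epidemiologists and clinical informaticians
who have a longitudinal outpatient diagnosis stream — one row per patient,
date, and ICD-9/ICD-10 (or pre-grouped CCS) code — and want to know **which
diseases travel together, how strongly, and in what temporal order**. It
implements the full analysis as composable, pipe-friendly functions plus a
one-call pipeline, and ships a seeded synthetic-cohort generator with planted
ground truth so every stage is verifiable without access to protected
clinical data.

## The method

1. **ICD → CCS grouping.** Diagnosis codes are normalized (dots stripped,
   upper-cased) and mapped many-to-one into single-level Clinical
   Classifications Software categories.
2. **Cohort selection.** Keep patients with ≥ 1 of the top-*k* (default 50)
   most prevalent categories *and* strictly more than 5 distinct categories.
   Prevalence counts distinct patients, never repeat events.
3. **Medical-concept embedding.** Each patient's categories, in
   chronological order, form a sentence. A from-scratch CBOW word2vec with
   negative sampling (single-threaded, bitwise deterministic per seed) learns
   a vector `v_c ∈ R^32` per category by minimising, per target `w_t` with
   mean context vector `h`,

   `L = −log σ(h·v′_{w_t}) − Σ_{j=1..5} log σ(−h·v′_{n_j})`,

   noise tokens drawn from the unigram^0.75 distribution (defaults: dim 32,
   window 5, min_count 1, 5 epochs).
4. **Comorbidity network.** Association between categories *i*, *j* is the
   Pearson correlation `r(v_i, v_j)` across the 32 dimensions. Pairs with
   `r ≥ 0.5` (CCS level) or `r ≥ 0.8` (ICD level, inclusive thresholds) form
   the network; Ward/Euclidean hierarchical clustering on the full vectors
   groups diseases; a sign-stabilised 2-D PCA provides the disease map.
5. **Time delays.** Per strongly associated pair, `Δt = first(b) − first(a)`
   in days per patient carrying both; reported as % a-earlier / b-earlier /
   same-day with per-direction median day gaps, and as two one-sided
   Gaussian-KDE curves (Silverman bandwidth, exact direct summation).

## Worked example

```r
library(comorbidnet)

cfg <- generator_config(
  n_patients = 2000, n_ccs_codes = 30, n_clusters = 5,
  within_cluster_co_prob = 0.8,
  lag_specs = data.frame(code_a = "C01", code_b = "C02",
                         mean_lag_days = 300, sd_lag_days = 50,
                         direction_prob = 0.8),
  seed = 42)
cohort <- generate_cohort(cfg)
cohort
#> <ehr_cohort> 2000 patients, 15928 events, 30 codes, 5 planted clusters

prevalence <- top_k_prevalence(cohort$events, k = 50)
head(prevalence, 3)
#> # A tibble: 3 × 3
#>   code  n_patients pct_patients
#> 1 C21          526         26.3
#> 2 C09          520         26
#> 3 C04          519         26.0

selection <- filter_cohort(cohort$events, prevalence$code, min_unique = 5)
model <- build_sentences(selection) |> train_cbow(seed = 42)

assoc <- analyze_associations(model, threshold = 0.5, k = 5)
glance(assoc)
#> # A tibble: 1 × 5
#>   n_codes n_edges threshold k_clusters mean_abs_corr
#> 1      30      75       0.5          5         0.392
head(tidy(assoc), 3)
#> # A tibble: 3 × 5
#>   code_a code_b     r cluster_a cluster_b
#> 1 C01    C05    0.997         3         3
#> 2 C02    C03    0.997         3         3
#> 3 C04    C05    0.996         3         3

delay_summary(pair_delays(cohort$events, "C01", "C02"))
#> # A tibble: 1 × 8
#>   code_a code_b n_patients pct_a_earlier pct_b_earlier pct_same_day …
#> 1 C01    C02           273          75.5          19.0         5.49
```

Reading the output: the 75 network edges at `r ≥ 0.5` connect codes within
the five planted comorbidity clusters (`cluster_a == cluster_b` in the tidy
edge list), and the planted 300-day directional lag between `C01` and `C02`
(direction probability 0.8, same-day atom 0.05) is recovered from the 273
patients carrying both: `C01` came first in 75.5% of them. `autoplot(assoc)`
draws the clustered disease map; `delay_kde()` + `autoplot()` the Δt density
curves; `run_pipeline(pipeline_config(...), out_dir)` runs all stages and
writes every artifact (CSV/SIF/GraphML/manifest) for network viewers such as
Cytoscape.

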