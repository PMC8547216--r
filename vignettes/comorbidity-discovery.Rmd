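---
title: "Discovering disease–disease associations from diagnosis sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering disease–disease associations from diagnosis sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbidnet)
```

## The problem

Certain diseases co-occur far more often than chance within the same
patients, and one member of such a pair frequently precedes the other by a
characteristic interval. Longitudinal outpatient EHR data — a stream of
dated diagnosis codes per patient — carries both signals, but raw ICD-9 and
ICD-10 codes are too granular (tens of thousands of codes) and categorical,
so neither co-occurrence strength nor temporal order is directly computable
at a useful resolution.

`comorbidnet` implements a complete pipeline for this problem:

1. **Grouping.** ICD-9/ICD-10 codes are mapped to single-level Clinical
   Classifications Software (CCS) categories, reducing thousands of codes to
   a few hundred clinically meaningful diagnosis groups.
2. **Cohort selection.** Patients are kept when they carry at least one of
   the top-*k* most prevalent categories (*k* = 50 by default) and strictly
   more than five distinct categories — the second filter guarantees each
   retained patient contributes co-occurrence information.
3. **Embedding.** Each patient's categories, ordered chronologically, form a
   "sentence"; a continuous-bag-of-words (CBOW) word2vec model with negative
   sampling maps every category to a 32-dimensional vector from these
   sentences.
4. **Association.** The Pearson correlation between two categories' vectors
   across the 32 dimensions scores their comorbidity; pairs with *r* ≥ 0.5
   (CCS level) or *r* ≥ 0.8 (ICD level) form the comorbidity network, Ward
   hierarchical clustering on the full vectors groups related diseases, and
   a 2-D PCA projection is produced for display only.
5. **Time delay.** For each strongly associated pair, the signed day
   difference Δt between the two diseases' *first* diagnoses per patient is
   summarised (percent earlier / later / same day, median day gaps) and its
   distribution estimated by kernel density estimation, one one-sided curve
   per direction.

## The embedding model

For a target token at position $t$ with context set $C_t$ (up to `window`
tokens each side, truncated at sentence edges — no random window shrinking,
so training is fully determined by the seed), the hidden vector is the mean
of the context input vectors, $h = \frac{1}{|C_t|}\sum_{c \in C_t} v_c$, and
the per-example negative-sampling loss is

$$
L = -\log\sigma(h \cdot v'_{w_t}) \;-\; \sum_{j=1}^{n_{neg}}
    \log\sigma(-h \cdot v'_{n_j}),
$$

with noise tokens $n_j$ drawn from the unigram distribution raised to the
0.75 power. Optimisation is plain SGD with a linear learning-rate decay.
The trainer is written from scratch (in C++ via Rcpp), single-threaded, and
bitwise reproducible from one integer seed; its own RNG (splitmix64) makes
results independent of R's RNG state. Analytic gradients are verified
against central differences by a standing test.

Two subtleties worth knowing:

* **Input vectors are the representation.** Downstream correlation and
  clustering use the input (context) vectors. Input–input similarity
  reflects *shared contexts*, not raw adjacency: two diseases embed close
  when they occur amid the same neighbouring diagnoses. In a comorbidity
  cluster every member serves as context for every other, which is exactly
  the signal the pipeline exploits.
* **Negative draws colliding with the target are redrawn**, keeping the
  number of noise terms per example fixed so the per-update loss is
  well-defined for gradient checking.

### Hyperparameters

| parameter | default | role |
|---|---|---|
| `dim` | 32 | embedding dimension; the resolution of the similarity space |
| `window` | 5 | max token distance between target and context |
| `min_count` | 1 | minimum corpus frequency to enter the vocabulary |
| `negative` | 5 | noise tokens per positive example |
| `epochs` | 5 | corpus passes |
| `initial_lr`, `final_lr` | 0.025, 1e-4 | linear SGD schedule endpoints |
| `noise_exponent` | 0.75 | unigram flattening for the noise distribution |

`dim`, `window`, `min_count` and the CBOW algorithm are the analysis'
published settings; `negative`, `epochs`, the learning-rate schedule and
`noise_exponent` are unreported there, so the package adopts the canonical
word2vec defaults. Whether recurrent diagnoses should be collapsed before
embedding is genuinely open; repeats are kept by default (repetition is
co-occurrence information) with `build_sentences(dedupe_per_day = TRUE)` as
the alternative.

## Association analysis choices

* **Correlation across dimensions.** The only computable reading of
  "correlation of the numerical vectors": each code's 32 coordinates are the
  paired samples. The matrix is exactly symmetrised and the diagonal set
  to 1; zero-variance vectors raise an error naming the code.
* **Thresholds are inclusive** (≥), so a pair sitting exactly at 0.5 (or 0.8
  in ICD mode) is retained.
* **Ward linkage on Euclidean distances** over the original 32-d vectors;
  the linkage and metric are not pinned down by the source analysis, and
  Ward/Euclidean is the common default for embedding vectors. The cluster
  count `k` is a user parameter (documented default 9, matching the
  published category-level analysis); there is no principled internal way to
  choose it.
* **PCA is display-only**; clustering and correlation always use the
  full-dimensional vectors. Component signs are fixed by making each
  component's largest-magnitude loading positive, so projections are
  deterministic.

## Time-delay analysis choices

* Δt is anchored at the **first** occurrence of each code per patient:
  repeat diagnoses of a chronic condition say nothing about onset order, so
  first-vs-first is the defensible estimate of the inter-disease delay.
* "Same day" means Δt exactly 0 — dates carry day resolution and no
  tolerance window is applied.
* The two directions are summarised and density-estimated **separately as
  magnitude distributions** (a-earlier uses Δt > 0; b-earlier uses |Δt| for
  Δt < 0), matching the two-curve convention for visualising delay
  distributions. Empty direction subsets yield `NA` medians, never zeros.
* KDE uses a Gaussian kernel with Silverman's rule-of-thumb bandwidth
  (`stats::bw.nrd0`) per direction, evaluated by *direct summation* — exact
  to machine precision, unlike FFT-binned estimators — on a uniform grid
  spanning the observed magnitudes padded by 4 bandwidths on each side.
  The padding guarantees each curve integrates to 1 within 10⁻³ by the
  trapezoid rule even when delays sit close to zero; a grid clipped at 0
  would cut kernel mass and break that contract.

## The synthetic cohort generator

Protected clinical registries cannot ship with a package, so every stage is
validated against `generate_cohort()`, a seeded simulator with *planted
ground truth*:

* **Follow-up** lengths are drawn per patient from a normal law
  (median 3 years, sd 0.5 years, truncated at 0.5 years), emulating a
  multi-year outpatient registry.
* **Comorbidity clusters.** Categories are partitioned into contiguous
  blocks; each patient seeds one uniformly chosen disease and acquires each
  other disease of that cluster with probability `within_cluster_co_prob`.
  Cross-cluster co-occurrence arises only through background noise.
* **Background noise**: a Poisson number of uniformly-dated, uniformly-coded
  extra diagnoses per patient. Noise never uses codes named in `lag_specs`,
  so planted first-occurrence lags remain exact.
* **Directional lags.** For each configured pair, carriers of both codes
  receive first-diagnosis dates separated by a signed draw from
  N(mean, sd) days — positive (code *a* first) with probability
  `direction_prob` — plus an atom of mass `same_day_prob` at exactly 0.
* **ICD granularity.** Each category owns `icd_per_ccs` synthetic child
  codes (`"C07.2"` style); the ICD stream picks a child per event, and the
  emitted code map groups it back, exercising the many-to-one mapping
  machinery without bundling the licensed CCS tables.
* **Reproducibility.** One root seed; per-patient substreams are derived by
  a counter, so patient-level draws survive reordering.

The generator deliberately does **not** emulate miscoding, ICD-9→ICD-10
transition artifacts, correlated demographics, realistic visit cadence, or
informative censoring. Passing tests therefore demonstrate that the
*pipeline machinery* recovers known structure from data of this form — not
that any particular clinical finding generalises.

## Problem sizes used by the test suite

The package's verification experiments use cohorts of 2,000 patients
(30 categories, 5 planted clusters, within-cluster co-occurrence 0.8,
10 replicate seeds) for cluster recovery, and 4,000 patients (≈550 carriers
of both lag codes, chosen so the binomial standard error of the direction
percentage is well inside the ±5-point acceptance band) for directional-lag
recovery. At these sizes hierarchical clustering of the embeddings recovers
the planted partition essentially perfectly and the recovered direction
percentages and median lags sit within sampling error of the planted values;
the exact figures are computed — never hard-coded — by
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`.

## Degenerate inputs and tie-breaks

* Same-day events are ordered by code string within a patient-day when
  building sentences; prevalence ties break lexicographically by code — both
  make top-*k* boundaries and training corpora deterministic.
* The uniqueness filter is strict ("more than five"): a patient with exactly
  five distinct categories is excluded. Uniqueness is counted over *all* of
  a patient's categories by default (the filter order is: top-code
  membership first, uniqueness second); `unique_within_top = TRUE` exposes
  the narrower reading.
* Empty cohorts flow through `run_pipeline()` and `report()` as zero counts,
  not errors; training demands at least one sentence with two in-vocabulary
  tokens and a non-empty vocabulary after `min_count` pruning.
* Conflicting duplicate rows in a code map (same normalized ICD key, two
  CCS targets) are rejected outright rather than resolved silently.

## Limitations

Correlation of embeddings is a co-occurrence measure, not a causal or even
incidence-ordered relationship: recurrent diagnoses, delayed recording of
chronic conditions, and follow-up censoring all bias observed Δt. The
pipeline reports direction *tendencies* (percentages and medians), and the
KDE curves describe recorded diagnosis gaps, not disease onset gaps. The
"medically relevant" subset for ICD-level analysis is inherently
analysis-specific; the pipeline takes an explicit allowlist
(`icd_allowlist`) and defaults to all mapped codes.
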