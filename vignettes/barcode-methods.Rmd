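---
title: "Mutational-barcode detection of clonal hematopoiesis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutational-barcode detection of clonal hematopoiesis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chbarcode)
library(dplyr)
```

## The statistical model

Blood is renewed by a pool of hematopoietic stem cells. When one clone
expands disproportionately (clonal hematopoiesis, CH), the somatic
mutations private to its founder cell — its *mutational barcode* —
surface in bulk whole-genome sequencing as low-VAF variants. For a clone
occupying cell fraction $f$ of the sample, a heterozygous clone mutation
is covered by fraction $f/2$ of reads, so its alt-read count at depth
$d$ is $\mathrm{Binomial}(d, f/2)$. A germline heterozygote is
$\mathrm{Binomial}(d, 1/2)$.

The caller counts, per sample, *indicator mutations*: cohort singletons
passing quality filters whose VAF lies in the closed window
$[0.10, 0.25]$. Three windows partition the analysis:

| window | VAF range | dominant content |
|--------|-----------|------------------|
| LOW  | [0.10, 0.25] | clone barcode + germline binomial tail + artifacts |
| MID  | [0.35, 0.65] | germline heterozygotes |
| HIGH | [0.75, 0.90] | germline heterozygotes (upper tail) |

Because the binomial germline law is symmetric about $1/2$, and because
the integer alt-read bounds of LOW and HIGH are exact mirror images at
every depth ($\lceil 0.75d \rceil = d - \lfloor 0.25d \rfloor$,
$\lfloor 0.9d \rfloor = d - \lceil 0.1d \rceil$), the expected germline
count in LOW equals that in HIGH. The contamination of LOW is therefore
estimated from HIGH via the cohort-level ratio

$$ r(c, d) = \frac{\sum_i \mathrm{HIGH}_i(d)}{\sum_i \mathrm{MID}_i(d)} $$

fitted separately per sequencing center $c$ and integer depth
$d \in [21, 60]$, giving for each sample

$$ E_i = \sum_{d \ge 21} r(c_i, d)\,\mathrm{MID}_i(d), \qquad
   S_i = \sum_{d \ge 21} \mathrm{LOW}_i(d) - E_i . $$

A sample is called CH when $S_i \ge T$, where $T$ is 20 plus a signed
center adjustment (+1 Vanguard, −2.2 Sanger) or an absolute platform
override (46 WGS NoPCR Nova, 32 NEB WGS). These constants are consumed
as given calibration values — the base of 20 corresponds to an expected
CH fraction of about 1% at age 40 — and `threshold_config()` exposes
them for re-calibration on other cohorts.

The assumptions, stated explicitly:

* germline alt reads are binomial and symmetric about VAF 0.5;
* MID and HIGH are overwhelmingly germline (a large clone, $f > 0.7$,
  would leak into MID — such samples look germline-inflated, not
  clonal);
* $r(c, d)$ is constant across samples given center and depth;
* the artifact bump is confined to 1–2 alt reads (hence `alt_min = 3`).

## Tunable parameters

All bounds reproduce the published method's constants and are
configurable with those defaults:

* `filter_config()`: `gq_min = 90` (phred-like genotype quality),
  `filters_keep = c("PASS", "Low_QD")`, `depth_min/max = 15/60` reads
  (inclusive), `alt_min = 3` reads, `snv_only = TRUE`.
* `fit_germline_ratio()`: `min_depth = 21`, `max_depth = 60`,
  `pool_window = 2` depth units for the zero-denominator fallback.
* `threshold_config()`: `base = 20` indicator mutations, the center
  adjustments and platform overrides above, `default_adjustment = 0`
  for unlisted centers (set `NULL` to make unknown centers an error).
* CPLD cascade: depth > 10 (strict), FILTER = PASS,
  $0.01 \le \mathrm{VAF} \le 0.99$, germline classification at exact
  binomial $p > 0.05$ (strict, as printed), key removal at > 5 carriers
  and > 75% germline-like, HIGH-impact rescue excluded for
  GNAS/JAK2/SRSF2/SF3B1 (genes whose truncating calls are
  artifact-prone in this assay), published-list rescue for
  moderate-impact hotspots.
* CHIP cascade: depth ≥ 20, alt reads ("minAD") ≥ 3, recurrence
  regression at ≥ 15 carriers with removal when *both* covariates have
  $p > 0.1$ or a negative estimate, aggregate binomial removal at
  $p > 0.01$ with the three TET2 exemptions (H1904R, I1873T, T1884A).
* Exclusions: ICD10 blocks C81–C96 and D45–D47 up to
  `window_days = 183` after draw; WBC outside [1.5, 35] ×10⁹/l,
  HGB < 8 g/dl, PLT < 50 ×10⁹/l, all strict, missing values never
  exclude.

## The synthetic cohort generator

`simulate_cohort()` is the package's test bench: it generates exactly
the structure the model assumes, with known truth.

* **Depth law.** Per-variant depth is Poisson with a center-specific
  mean, truncated to ≥ 1 (`depth_dispersion = Inf`); a finite
  dispersion switches to negative binomial, and 0 fixes depth — used
  when a test needs a single depth stratum. The real assays publish no
  depth law; Poisson is the minimal choice that exercises the model's
  depth stratification.
* **Sites.** Private germline heterozygous sites (Poisson around
  `n_germline_het = 30000`, the scale at which a 30–40× genome yields
  indicator-window counts of a few dozen), drawn without replacement
  from a 22-chromosome coordinate space so privacy is guaranteed by
  construction; `shared_pool_size` cohort-shared sites with population
  frequencies uniform on [0.05, 0.5], which singleton extraction must
  remove; clone sites at $\mathrm{Binomial}(d, f/2)$; an artifact bump
  of `error_bump_rate` records with 1–2 alt reads, the population the
  `alt_min = 3` filter exists to remove.
* **Clones.** Prevalence follows a logistic in age anchored at 1% at
  age 40 and 50% at age 80 (`clone_prevalence_logistic()`), multiplied
  on the odds scale by smoking status, pack-years and years-since-quit
  factors. Clone fractions default to uniform [0.2, 0.6] (site VAF
  0.10–0.30, straddling the indicator window) and mutation counts to
  Poisson(300) — a founder cell of a late-life clone carries hundreds
  of genome-wide passengers, of which the depth-dependent binomial
  places a subset in the window.
* **Quality fields.** Fractions of records fail GQ (2%), carry Low_QD
  (2%) or a disqualifying FILTER (1%); calibration experiments set
  these to zero to isolate the estimator from filter attrition.

What the generator does **not** emulate: read-level errors and mapping
artifacts (beyond the 1–2-read bump), mosaic chromosomal alterations,
sex-chromosome loss, relatedness between participants, and any
clustering of germline sites along the genome. Passing tests therefore
demonstrate correctness of the estimator under its stated model, not
robustness to every failure mode of real sequencing.

## Numerical choices

* **Window membership** compares VAF to bounds with a $10^{-9}$
  tolerance so two-decimal bounds act as exact closed bounds despite
  binary floating point (alt 10 of depth 40 is VAF 0.25 and belongs to
  LOW).
* **Zero-denominator ratio cells** fall back to the ratio pooled over
  ±2 depth neighbours, then to the center-wide pooled ratio; this keeps
  $E$ finite and smooth where a depth stratum is sparse.
* **Negative $S$ is retained.** Clamping at zero would bias the null
  upward and break the calibration tests.
* **No rounding** anywhere on the decision path: `is_ch` is exactly
  `S >= T`.
* **Null mean and its standard error.** Because all samples share the
  fitted ratio, the cohort mean of $S$ collapses algebraically to
  $(L_{tot} - H_{tot})/n$, whose exact standard error is
  $\sqrt{L_{tot} + H_{tot}}/n$. The per-sample estimates are positively
  correlated through the shared fit, so the naive
  $\mathrm{sd}(S_i)/\sqrt{n}$ *understates* the sampling error of the
  mean; calibration tests use the exact form.
* **Singleton extraction precedes quality filtering** (the singleton
  definition is a cohort property of the raw call set), and the
  singleton key is allele-level `(chrom, pos, alt)` — a barcode
  mutation is an allele event; position-level keying is available as an
  option.
* **Problem sizes.** The null-calibration experiment uses 500 samples
  × ~30k sites at depth ~35 (about 15M records); ratio-oracle checks
  use 360k sites per depth; spike-in recovery uses 200 samples × 10k
  sites with 40 conditioned in-window singletons spiked into half. At
  these sizes the pipeline runs in roughly a minute on one CPU, with
  Monte-Carlo errors small enough for the stated 2-s.e. checks.

## Open design decisions

Where the method description leaves latitude, the package fixes a
choice and documents it:

* **"Within 6 months"** of blood draw is 183 days, configurable; day
  counts and calendar months differ by at most two days.
* **ICD10 matching** is at the three-character block with subcode
  inheritance (C91 matches C91.1), matching how block ranges are
  written.
* **Fisher's two-sided rule** sums hypergeometric probabilities no
  larger than the observed table's (the convention of R's
  `fisher.test`, which computes the p-value); the reported OR is the
  sample OR $ad/bc$, with the conditional-MLE OR alongside.
* **The CHIP recurrence test** ("association with age and rs7705526")
  names covariates but no model family; the package fits a logistic
  regression of carrier status on age and dosage and applies the
  removal rule to the Wald p-values and signs. The fit is isolated in
  one function and swappable.
* **Smoking dose terms** enter linearly (pack-years, years quit). The
  original analysis used transformations derived from a generalized
  additive model that it does not specify; this divergence is flagged
  here deliberately.
* **Strict inequalities** are implemented exactly as printed:
  germline classification at $p > 0.05$, CHIP removal at $p > 0.01$,
  depth > 10 in the CPLD cascade, recurrence at > 5 and > 75%.

## Worked miniature

```{r example}
cfg <- sim_config(n_samples = 40, seed = 7, n_germline_het = 4000)
sim <- simulate_cohort(cfg)
calls <- run_barcode_pipeline(sim$variants, sim$manifest)
cmp <- inner_join(as_tibble(calls), sim$truth, by = "sample_id")
table(called = cmp$is_ch, clone = cmp$has_clone)
```

At 4k sites per sample the germline noise floor is lower than at
genome scale, so even modest clones separate cleanly; the acceptance
script runs the same machinery at full scale.

```{r plots, fig.width = 6, fig.height = 3.5}
autoplot(attr(calls, "model"))
```

## Limitations

* Thresholds and center adjustments are consumed as published
  constants; the package exposes the knobs but does not re-derive the
  original calibration procedure, which is not fully specified.
* The caller estimates a *count* of somatic singletons, not the clone
  fraction or clone age; samples with several co-existing clones are
  indistinguishable from one larger clone.
* Very large clones ($f > 0.7$) violate the "MID is germline"
  assumption and can partially mask themselves by inflating $E$.
* The association layer covers case-control logistic models, Fisher
  per-variant tests and IVW slopes; time-to-event analyses and burden
  tests are out of scope.
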