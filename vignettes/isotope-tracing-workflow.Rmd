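---
title: "Scoring metabolic pathway activity from steady-state isotope tracing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring metabolic pathway activity from steady-state isotope tracing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracescore)
```

## The problem

Steady-state stable isotope tracing feeds cultured cells or tissue explants a
nutrient carrying heavy isotopes — here ¹⁵N₂-glutamine, labeled at both the
amine and amide nitrogen — and measures, after a fixed tracing window, how much
of each downstream metabolite pool carries tracer-derived heavy atoms. LC-MS
reports, for each metabolite, the intensities of its isotopologues M+0 … M+n
(n = the number of nitrogen positions that can receive label). Comparing how
strongly different model systems (e.g. heterocellular tumor explants versus
stem-like cell monocultures) label a pathway's products reveals which
metabolic activities are cell-intrinsic and which depend on the tissue
microenvironment.

Raw isotopologue intensities cannot be compared directly:

1. Natural heavy-isotope abundance (¹³C ≈ 1.07%, ¹⁵N ≈ 0.364%, …) inflates
   measured M+i signals and must be deconvolved.
2. Absolute enrichment depends on how much tracer each culture actually took
   up, on proliferation, and on de novo synthesis of the tracer nutrient
   itself, so enrichments must be normalized before cross-model comparison.

This package implements the full chain: correction → fractional enrichment →
Metabolite Labeling Score → differential (volcano) analysis → quantitative
metabolite set enrichment, plus a simulator that generates raw datasets with
known ground truth.

## Natural-abundance correction

For a metabolite with `n` labelable tracer atoms, the measured intensity
vector satisfies (up to noise and truncation) `raw = M %*% true`, where column
`j` of the lower-triangular matrix `M` is the probability distribution of
*extra* mass shifts acquired by a molecule that already carries `j`
tracer-derived labels:

* **tracer-only mode** (default): shifts come only from the `n − j` unlabeled
  tracer-element atoms — a binomial `Binom(n − j, a)` with `a` the
  heavy-isotope probability of the tracer element. This is the right model
  for high-resolution orbitrap data, where isotopologues caused by other
  elements (e.g. ¹³C) are mass-resolved away from the ¹⁵N series.
* **all-elements mode**: that binomial convolved with the mass-shift
  distributions of every non-tracer atom in the formula, truncated at shift
  `n`. This is the right model for unit-resolution data where all heavy
  isotopes collapse onto nominal mass shifts.

`correct_vector()` solves `M x = raw` for `x ≥ 0` by non-negative least
squares (Lawson–Hanson, with an exact triangular-solve fast path when the
unconstrained solution is already non-negative). NNLS guarantees the corrected
fractions are never negative on noisy data; on noiseless data the inverse is
exact, which the tests verify through the solver residual. After solving,
fractions are renormalized to the simplex; the relative L2 residual is
reported per vector. All-zero vectors are flagged `undetected` and flow
through the pipeline rather than erroring, because real datasets contain
"not detected" metabolites that downstream comparisons must handle.

Isotopic compositions default to IUPAC representative values (¹⁵N = 0.00364)
in one overridable table (`natural_abundance()`, YAML override via
`read_abundance_table()`).

## Fractional enrichment, total labeling and the score

After correction, fractional enrichment (FE) of isotopologue `i` is the
simplex entry `f_i`; **total labeling** is `1 − f₀`, the fraction of molecules
carrying at least one tracer-derived atom. The **Metabolite Labeling Score**
for metabolite m in sample s is

```
score(m, s) = total_labeling(m, s) / total_labeling(reference, s)
```

with glutamate as the default reference: glutamate receives nitrogen directly
from glutamine in essentially every system, so its labeling acts as an
internal gauge of tracer availability. Scores are computed per sample (each
sample's own glutamate), which keeps replicate variance honest; a group-mean
normalization mode exists for sensitivity analyses. The reference statistic
can also be switched from total labeling to a specific isotopologue's FE.

Before scoring, metabolites are filtered for (a) total labeling strictly
greater than zero and (b) adequate pool size. "Adequate" is deliberately
scale-free by default: the pool must reach at least 1% of that sample's
median detected-metabolite pool (`filter_policy(min_pool = 0.01)`), which
transfers across instruments without retuning; an absolute intensity
threshold is available. Tracer-free samples are never scored — dividing by a
near-zero reference labeling is meaningless — and are instead checked by
`qc_report()` (reference labeling floor 0.05 in traced samples, median
background ceiling 0.01 in tracer-free samples).

## Differential analysis

`compare_models()` runs an unpaired two-sample t-test per metabolite on the
scores of two groups and gates significance on both raw `p < 0.05` and fold
change `> 1.25` (either direction), the conventional volcano thresholds for
this assay. The classic pooled-variance Student test is the default — it is
what mainstream GUI statistics packages run for a plain "unpaired t-test",
and at n = 3 replicates it holds its nominal level on null simulations
(measured type-I ≈ 0.038) where Welch's unequal-variance test is conservative
(≈ 0.026) and underpowered through its tiny degrees of freedom. Welch is one
flag away (`test = "welch"`) and is preferable when group variances differ
strongly and replication exceeds the typical n = 3. No
multiple-testing correction is applied to the volcano flags — matching the
assay's convention — but Benjamini–Hochberg q-values are emitted as an extra
column.

Structural absences are kept categorical: a metabolite with at least two
scored replicates in one group and fewer than two in the other is reported as
`exclusive_to_A`/`exclusive_to_B` with no p-value, never as a pseudo-infinite
fold change. This matters because a pool that is absent or unlabeled in one
model yields zero *or one* noise-positive replicate at random; both outcomes
mean "quantifiable in one model only".

`concordance()` (OLS of one condition's per-metabolite labeling on another's,
with Pearson r) quantifies agreement between preconditioning regimes, and
`paired_metabolite_test()` provides the figure-panel style per-metabolite
one-way ANOVA (≥ 3 groups, classic equal-variance F) or two-group t-test.

## Quantitative set enrichment by permutation

`run_qea()` tests each metabolite set for association between member scores
and group membership. The set statistic is the mean over tested members of
the squared two-sample t statistic — a quadratic association measure in the
globaltest family. The null distribution permutes the sample group labels
jointly across all metabolites, preserving inter-metabolite correlation; when
`choose(n_A + n_B, n_A) ≤ 10000` every assignment is enumerated and p-values
are exact multiples of `1/n_assignments`, otherwise 9999 random permutations
are drawn with the add-one estimator `p = (1 + #{perm ≥ obs}) / (1 + N)`.
Scores enter the test as-is — no renormalization, filtering or scaling beyond
the score's own quality filters. Set members are matched case-insensitively
with an optional synonym map; members lacking a complete score profile across
both groups are excluded from the statistic (the joint permutation must stay
exchangeable) and reported in the output, never silently dropped.

One discreteness caveat: the squared-t statistic is invariant to swapping the
group labels, so with 3 vs 3 samples the 20 assignments collapse to 10
distinct partitions and the smallest attainable p-value is 2/20 = 0.1. A 5%
decision level is therefore structurally unattainable at 3 vs 3 under
exhaustive permutation; the package's type-I calibration checks use 5
replicates per group (252 assignments), where rejection at `p ≤ 0.05` is
attainable and measured rejection rates for both the per-metabolite t-test
and the QEA fall in the 3–7% band.

## The simulator

`simulate_dataset()` generates raw three-table datasets from a nitrogen-
transfer network with exact ground truth, so every stage is testable without
instrument data. Design choices:

* **Steady-state "fraction-new" mixing, not kinetics.** A single-timepoint
  tracing experiment observes a snapshot: each pool is a mixture of a
  fraction `f` synthesized during the window (labeled per its precursors) and
  `1 − f` pre-existing unlabeled material. Pathway activity differences are
  multipliers on `f` (a multiplier of 0 switches a route off); ODE machinery
  would add unverifiable scope for no observable gain.
* **Exact positional propagation.** Each metabolite's pool is represented as
  a joint distribution over its 2ⁿ position-label configurations, built in
  topological order; a product molecule draws one molecule per precursor rule
  (within-rule positions stay correlated, e.g. both nitrogens of one
  glutamine; draws across rules are independent, e.g. the two separate
  glutamine amide donations into the purine ring). Tests verify the engine
  against a Monte Carlo oracle that literally replays this generative story.
* **The tracer is pure M+2 by default** (both nitrogens labeled jointly),
  matching a ¹⁵N₂-glutamine tracer; an independent-position mode exists for
  testing.
* **Measurement model.** True distributions are forward-convolved with
  natural abundance in all-elements mode (the full measured spectrum), scaled
  by pool size, and hit with multiplicative lognormal noise applied
  independently to every isotopologue intensity — fraction-level noise then
  emerges from the ratio structure rather than being imposed. Because the
  simulator's forward model is the all-elements convolution, simulated data
  are analyzed with `correct_dataset(mode = "all-elements")`; the
  tracer-only default applies to real mass-resolved data.
* **Ground truth is always emitted** (true total labeling, true score,
  per-metabolite differential flags); tests never re-derive truth from the
  simulator's internals.

### The built-in scenario

`preset_scenario("sxo_vs_gsc")` encodes a 20-metabolite network — glutamine →
glutamate → amino acids; two separate glutamine amide donations into the
purine ring (IMP → AMP/GMP → adenosine, hypoxanthine, GDP-mannose); carbamoyl
phosphate + aspartate into UMP → uridine → uracil → dihydrouracil; a small
urea-cycle arm — with two groups of 3 traced + 2 tracer-free replicates. The
explant-like group has baseline purine degradation, measurable GDP-mannose
and active pyrimidine degradation; the monoculture-like group has 4× purine
degradation, GDP-mannose below detection and pyrimidine degradation off.
Atom mappings are textbook-level pedagogy, not mechanistic stoichiometry.

Parameter defaults and why:

* tracer enrichment `e = 0.40` — a realistic intracellular glutamine M+2
  fractional enrichment after 24 h of ¹⁵N₂-glutamine tracing in
  physiological medium;
* `noise_cv = 0.10` — typical replicate-level LC-MS intensity variability;
* fraction-new values: ~0.25–0.5 for amino acid pools, 0.5–0.6 for nucleotide
  pools (nucleotides turn over quickly on a 24 h window), 0.2 baseline for
  purine degradation products and 0.7 for active pyrimidine degradation.
  These magnitudes put degradation-product labeling scores in the 0.2–1.2
  range relative to glutamate, the regime the assay actually operates in; an
  earlier draft that cascaded small fractions gave ~1% total labeling, an
  order of magnitude below anything measurable against the deconvolution
  noise of carbon-rich molecules.

`preset_scenario("null")` runs identical groups (every differential flag
false); `preset_scenario("preconditioning_concordance")` runs two conditions
with identical truth and independent noise for concordance analysis.

### What the simulator does and does not emulate

It emulates label propagation at steady state, natural-abundance
contamination, heterogeneous pool sizes, below-detection metabolites,
tracer-free controls and multiplicative replicate noise. It does **not**
emulate chromatographic or peak-shape artifacts, ion suppression,
resolution-dependent partial overlap of isotopologue peaks, missing-at-random
dropout, or kinetic (multi-timepoint) labeling dynamics. Passing tests
therefore demonstrate the *analysis* is correct and well-calibrated under the
stated measurement model — not that any particular biological conclusion
transfers to real instruments.

## Numerical choices and degenerate inputs

* NNLS with triangular fast path; solver residual reported per vector;
  simplex renormalization after truncation.
* Zero-variance t-test inputs: t = 0, p = 1 when means agree (Inf, minimal p
  otherwise) rather than an error, so degenerate metabolites flow through.
* All-zero intensity vectors → `undetected`, excluded from scoring by the
  filters, reported in every accounting table.
* Isotopologue cap `n + 1 ≤ 64` guards pathological annotations.
* Missing isotopologue rows are zero-filled with a warning; duplicated rows
  are an error (they indicate corrupt peak integration).
* Metabolite ids match case-sensitively after whitespace trimming in the data
  model; set membership matches case-insensitively with an optional synonym
  map, because set libraries and LC-MS naming conventions differ.
* Problem sizes used by the test suite and acceptance script: 200 random
  molecules for the matrix oracle, 1000 round-trip trials, 100 simulation
  seeds for differential recovery, 1000 null datasets (5 replicates/group)
  for type-I calibration — sizes chosen so the whole suite runs comfortably
  on a laptop while keeping Monte Carlo error well below the decision bands.

## Known limitations

* No resolution-aware correction (partial isotopologue overlap at finite
  resolving power); only the two discrete modes.
* Exact numerical agreement with any particular commercial or web QEA
  implementation is a non-goal; the permutation QEA here is a documented,
  reproducible re-implementation of the idea, not a clone.
* Single-timepoint scores are not fluxes; the package deliberately offers no
  kinetic flux estimation.
* The preset network's atom mappings are pedagogical. Real positional
  stoichiometries (how many glutamine nitrogens reach GMP vs AMP in vivo) are
  not quantified by the assay this package supports.

## A worked run

```{r, eval = FALSE}
ps  <- preset_scenario("sxo_vs_gsc", seed = 7)
sim <- simulate_dataset(ps$network, ps$scenario)
corrected <- correct_dataset(sim$dataset, mode = "all-elements")
scores <- compute_labeling_scores(corrected, sim$dataset$samples)
ga <- group_samples(sim$dataset$samples, "SXO_like")
gb <- group_samples(sim$dataset$samples, "GSC_like")
diff <- compare_models(scores, ga, gb)
plot(diff)
qea <- run_qea(scores, preset_metabolite_sets(), ga, gb, seed = 7)
```

The same chain, driven from files with a YAML config, is `run_pipeline()`;
a thin command-line wrapper lives at
`system.file("scripts", "tracescore.R", package = "tracescore")`.
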