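---
title: "Comparing LDL-C estimators: equations, an adjustable-factor table, and a selected neural network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing LDL-C estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Low-density-lipoprotein cholesterol (LDL-C) is the primary lipid treatment
target, but direct measurement (beta-quantification, or homogeneous direct
assays) is more expensive than the standard lipid panel, so clinical
laboratories usually *estimate* LDL-C from total cholesterol (TC), HDL-C and
triglycerides (TG), all in mg/dL. ldlbench implements the three standard
closed-form estimators plus a small neural-network estimator, together with
the method-comparison statistics used to judge them, and a synthetic-cohort
generator that provides a controlled test bed.

The estimators:

* **Friedewald**: `LDL = TC − HDL − TG/5`. The divisor 5 is a fixed assumed
  TG:VLDL-C ratio; the equation is considered inapplicable at
  TG ≥ 400 mg/dL. We flag but still compute such estimates, so whole-range
  comparisons remain possible.
* **Martin-style adjustable factor**: `LDL = TC − HDL − TG/f`, where `f` is
  a strata-specific median TG:VLDL-C ratio read from a two-dimensional
  table indexed by TG and non-HDL-C (default geometry 30 × 6 = 180 cells).
  The package does not ship the published factor values (they belong to the
  original authors); instead `derive_strata_table()` re-derives a table
  from any cohort with directly measured LDL-C, as the per-cell median of
  `tg / (tc − hdl − ldl_measured)`.
* **NIH (Sampson)**: `LDL = TC/0.948 − HDL/0.971 − (TG/8.56 +
  TG·nonHDL/2140 − TG²/16100) − 9.44`, a polynomial fit designed for
  hypertriglyceridemia and low LDL-C.
* **Network estimator**: a fully connected rectifier network with a single
  linear output on features `(tc, hdl, tg)`, selected by the
  pyramid/tournament procedure below.

## Network candidate space and selection

Candidates are *pyramids*: non-increasing hidden-layer width sequences over
a node grid. Two readings of the search-space description are supported:
one shared grid {10, 20, 30} for all depths (the `enumerate_candidates()`
default; 6 + 15 + 28 = 49 candidates at depths 2/4/6), and a per-depth cap
(`{2: 30, 4: 20, 6: 10}`, giving 6 + 5 + 1 = 12 candidates) in which deeper
models only use narrower layers. The comparison pipeline defaults to the
capped space: it is the more literal reading of the procedure this package
reproduces, and it keeps the search affordable.

Selection is two-stage and fully seeded:

1. **10-fold cross-validation** on the derivation set. All candidates see
   the identical fold partition; each is trained on nine folds and scored
   by MSE on the held-out fold; the fold-averaged MSE picks one winner per
   depth class.
2. **Tournament**: the depth winners are refitted on the full derivation
   set and compared by MSE on the internal validation set (the 30% split);
   the argmin wins, ties breaking toward fewer parameters, then fewer
   layers. The external set plays no role in selection; the pipeline stage
   log records the order of operations.

Training contract (deliberately the smallest standard assumption set):
mini-batch Adam on mean squared error, rectifier activations, He
initialisation, optional early stopping on an inner 10% holdout of the
training partition, and a post-fit recentring of the output intercept so
the mean training residual is exactly zero. Standardisation constants for
features and response are learned on the training partition only. Two
budgets are used. Cross-validation ranking runs a reduced budget (30
epochs, batch 2048, learning rate 0.006, early stop patience 4): candidate
*ordering* stabilises well before full convergence. The tournament refits
run a converged budget (300 epochs, batch 512, learning rate 0.003 annealed
as 1/(1 + 0.05·epoch), decoupled AdamW weight decay 0.4, no effective early
stop). The reason for the second budget is statistical, and worth spelling
out: with assay noise σ ≈ 5 mg/dL, a holdout of a few thousand records can
only resolve MSE differences of ~0.5 mg/dL², while the quantity that
separates a well-trained network from the strata table is a *model error*
of a few tenths of a mg/dL — far below what early stopping can see. Weight
decay controls the estimation variance (~σ²·p/n for a p-parameter network)
that otherwise dominates at these sample sizes, and the annealed rate
removes residual optimiser wobble. Everything is pure vectorised R; at
these widths the per-step cost is a few small BLAS matrix products, and a
converged refit on ~35,000 records takes under half a minute.

## Accuracy indices

For estimates `e` and directly measured values `m`:

* **bias** `mean(e − m)` with a one-sample t-test against zero (zero
  variance with zero mean is reported as t = 0);
* **RMSE** `sqrt(mean((e − m)²))`;
* **Pn** — the fraction of records with `|e − m| ≤ n% · m` for n = 10, 15,
  20. The band is per-record (relative to that record's measured value) and
  closed at the boundary;
* **concordance** — per clinical category `c`: `#{m ∈ c and e ∈ c} / #{m ∈
  c}`. The LDL scheme uses five bins `[0,100), [100,130), [130,160),
  [160,190), [190,∞)` — the only self-consistent reading of the usual
  guideline cutpoints with everything under 100 mg/dL pooled. Empty
  categories are reported as missing, never as zero, to keep averages
  honest.

Grouped RMSE tables (by TG category, non-HDL category, or risk stratum) use
50 mg/dL-wide default bins; the size-weighted pooled squared group RMSEs
recover the global squared RMSE exactly, which the tests assert.

## Risk stratification

Ten-year ASCVD risk is computed from a pluggable coefficient file
(YAML; transforms limited to identity/log/square/products), then the cohort
is ranked into 20 equal-frequency strata ("vigintiles"; sizes differ by at
most one, ties resolved by stable record order) and RMSE is reported per
stratum. Risk uses only the risk covariates plus TC and HDL-C — never any
estimated LDL value — so stratified accuracy comparisons are not circular.
The shipped coefficient set is **synthetic and explicitly non-clinical**: the
revised logistic model form with a plausible sign structure (risk rises with
age, blood pressure, TC, diabetes, smoking; falls with HDL-C). Since risk
scores only *rank* participants here, validation of this module is
structural and monotonic, not coefficient-exact. No race term is included by
default; the coefficient file format accepts any term list if one is wanted.

## The synthetic cohort generator

No subject-level data ships with the package, so all claims are exercised
on synthetic cohorts built to have the statistical structure the
comparisons presuppose:

* marginals: TC and HDL normal, TG log-normal, linked by a Gaussian copula
  (default correlations TC–HDL 0.30, TC–logTG 0.25, HDL–logTG −0.40);
* a **latent TG:VLDL-C divisor** `f(tg, non_hdl)` — by default a smooth
  logistic ramp `4.9 + 5.1·plogis((tg − 195)/70) − 0.4·(non_hdl − 140)/40`,
  clamped to [3, 12] — defines true LDL as `tc − hdl − tg/f`;
* measured LDL adds Gaussian assay noise (default sd 5 mg/dL, a realistic
  homogeneous-assay error scale);
* covariates (age, sex, systolic pressure, treatment, diabetes, smoking)
  with configurable prevalences, and block-wise missingness flags
  (demographics / lifestyle / laboratory) driving the sequential exclusion
  flow.

The default parameters target the published summary statistics of a large
Korean health check-up population (TC 198.3 ± 37.1, HDL 54.4 ± 13.2, TG
median 105 IQR ≈ 75–153, age 48.6 ± 11.5, 53.5% male), and the divisor ramp
and copula were calibrated once so that generated measured LDL-C lands
within 2 mg/dL of 124.8 ± 32.4 at n = 50,000. A `koica_params()` preset
shifts the population for external-validation realism (older, 76.2% male,
TG median 113, slightly lower TC/HDL). One consequence worth stating
plainly: under these marginals the Friedewald estimate is biased *low* by
about 5–6 mg/dL (198.3 − 54.4 − E[TG]/5 sits below 124.8), so the synthetic
bias sign need not match any particular field report; the orderings the
package asserts (network ≤ Sampson ≤ Friedewald RMSE, Friedewald error
growing with TG) are structural and do not depend on that sign.

What the generator does *not* emulate: reagent/analyzer batch effects,
longitudinal visits, non-Gaussian assay error, and real covariate–lipid
dependence beyond the single copula (the three lipid correlations are the
only dependence knobs). Passing tests therefore demonstrate correctness of
the machinery and qualitative separations under a controlled generative
model — not clinical performance on real populations.

## Numerical and design choices

* Strata and category bins are left-closed, right-open; out-of-range
  values clamp to edge bins, so no record is ever dropped by a lookup.
* Empty strata cells fill from the nearest non-empty cell (same TG row
  first, then same non-HDL column, then overall grid distance), each fill
  logged.
* Medians are the standard order-statistic definition (mean of the two
  central values for even counts).
* The 70/30 derivation/internal split uses rounded fraction sizes with the
  remainder to the first partition; vigintiles give the first `n mod 20`
  bins the extra record; both are seeded permutations, so re-runs are
  identical.
* Text serialisations (strata tables, fitted networks, report bundles)
  write doubles with 17 significant digits, so write → read round-trips are
  bit-identical, and the full `run_comparison()` bundle is a pure function
  of its configuration — run it twice and the files are byte-identical.
* Candidate order is by depth then lexicographically ascending width
  tuples; all seeds are derived from one master seed via a fixed affine
  map, kept inside 32-bit range.

## Problem sizes used in the shipped checks

The package's own validation runs at deliberately modest scale: equation
oracle checks at 10⁴ random panels, metric identities at a few × 10³
records over many seeds, table parameter recovery at 5 × 10³ records per
cell, and one end-to-end benchmark at 50,000 derivation-population records
(70/30 split) with an independent 40,000-record external draw — large
enough that RMSE differences of a few tenths of a mg/dL are resolved, small
enough to run on a laptop in minutes.

## Known limitations

* The network trainer is plain R; it is entirely adequate for ≤ 30-node
  pyramids on 10⁵-record panels, but it is not a general deep-learning
  stack (no GPU, no convolutions, no uncertainty quantification).
* The shipped PCE coefficients are placeholders; any real risk analysis
  must supply a coefficient file from a validated source.
* Derived strata tables inherit the edge configuration they were built
  with; comparing tables across different edge sets is not meaningful.
* With a strongly TG-dependent divisor, the Martin-style estimator is not
  monotone in TG across stratum boundaries (the factor jumps); monotonicity
  holds within strata, and globally only for the smooth closed-form
  estimators.
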