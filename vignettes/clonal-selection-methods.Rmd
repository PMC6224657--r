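---
title: "Modeling clonal selection under cytotoxic therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling clonal selection under cytotoxic therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonesel)
```

## The selection model and its assumptions

Clonal hematopoiesis driven by DNA-damage-response mutations (the
archetype being truncating *PPM1D* mutations, which stabilize a phosphatase
that dampens p53-mediated apoptosis) poses a specific quantitative
question: how much expansion should a modest per-dose survival difference
produce over a course of chemotherapy?

The package's answer is a per-dose survival-ratio model. A dose kills an
apoptotic fraction $a_\mathrm{mut}$ of mutant and $a_\mathrm{wt}$ of
wild-type cells, so one dose multiplies the mutant:wild-type ratio of live
cells by

$$r = \frac{1 - a_\mathrm{mut}}{1 - a_\mathrm{wt}}.$$

With apoptotic fractions of 49% and 65% this is $0.51/0.35 = 1.457$,
conventionally quoted as 1.46. The model's assumptions are deliberately
minimal:

- selection acts only at dose times (apoptosis differential); regrowth
  between doses is clone-neutral, reflecting the empirical absence of
  proliferation differences in cell-cycle analyses. An optional
  `growth_adv_mut` multiplier can represent a minor drug-free growth
  advantage; it defaults to off because its magnitude is not quantified in
  the data the model was built around.
- two clones only; no spatial structure, no de novo mutation.
- fitness is parameterized **per dose**, not per day: the dose schedule
  carries the timing, and compounding happens once per treatment round.

### Two compounding conventions

`compound_naive()` multiplies the mutant *proportion* by $r$ each round and
clamps at 1 ($f_n = \min(f_0 r^n, 1)$). This is the form in which the
arithmetic is usually quoted — it reproduces the familiar chain
$20\% \times 1.457^4 \approx 90\%$ and $10\% \times 1.457^4 \approx 45\%$ —
but it is not a consistent two-clone update (it ignores the shrinking
wild-type denominator and must be clamped).

`compound_normalized()` applies $r$ to the odds:
$\mathrm{odds}_n = \frac{f_0}{1-f_0} r^n$,
$f_n = \mathrm{odds}_n/(1+\mathrm{odds}_n)$. It is always in $(0,1)$ and
composes exactly ($n$ steps of $r$ equal one step of $r^n$). Every
simulation and fit in the package uses the normalized form; the naive form
is retained because published back-of-envelope figures are stated in it,
and every output records which model produced it.

A note on rounding: the quoted chain compounds the *unrounded* ratio.
$0.2 \times 1.457^4 = 0.902$ prints as 90%, whereas compounding the
already-rounded 1.46 gives $0.909$, which prints as 91%. The package's
convention for reproducing printed values is therefore: compute the chain
at full precision, then round — ratios to two decimals, percentages to the
nearest integer.

## The stochastic simulator

`simulate_competition()` iterates dose cycles on integer cell counts:

1. binomial survival of each clone with probabilities $1-a_\mathrm{mut}$,
   $1-a_\mathrm{wt}$;
2. deterministic clone-neutral regrowth by `growth` (default 2.5 per
   cycle, roughly restoring a culture after a ~60% kill);
3. at each measurement day, a binomial draw of `sample_size` cells
   (default 10,000, a typical flow-cytometry event count) at the current
   fraction.

A measurement falling on a dose day is taken *before* that day's dose, so
the day-0 measurement is the pre-treatment baseline and the cumulative
dose count before a measurement at time $t$ is the number of dose days
strictly before $t$. Extinction is absorbing; if the whole population dies
the trajectory is truncated and flagged in `meta` rather than erroring, so
batch simulations never abort. Populations are capped at $10^9$ cells by
proportional (fraction-preserving) down-scaling, only reachable under
extreme growth settings.

The default experimental design mirrors the in vitro mixing studies this
model describes: mutants seeded at 20% ($f_0 = 0.20$), apoptotic fractions
0.49/0.65 per cisplatin dose, dosing every 4 days, and measurement every 4
days over 15 days. The number of doses underlying a 15-day horizon is not
uniquely determined by "every 4 days"; the package defaults to four doses
(days 0, 4, 8, 12), which is configurable.

## Fitness estimation

`fit_fitness()` maximizes the binomial log-likelihood
$\sum_i \log \mathrm{Bin}(k_i \mid n_i, p(f_0, r; d_i))$ over $r$, where
$d_i$ is the cumulative dose count before measurement $i$ and $p$ is the
chosen compounding model. The search is one-dimensional on $\log r$ over
$r \in [0.2, 5]$ (tolerance $10^{-6}$ on $\log r$), with $f_0$ profiled
out by an inner one-dimensional optimization unless fixed by the caller.
The 95% interval is a profile-likelihood interval at the $\chi^2_1$ cutoff
3.84; when the cutoff is not reached inside the search bounds the bound
itself is reported. Degenerate trajectories (all measurements at fraction
0 or 1) return a non-converged estimate with infinite bounds rather than
an error.

The likelihood models measurement noise only. In the parameter-recovery
checks the simulated cultures use $n_0 = 10^6$ cells so that process noise
(binomial survival of the culture itself) is negligible relative to the
10,000-event measurement noise; with small cultures the data would be
overdispersed relative to the likelihood and the profile intervals
anticonservative. This is a known limitation for low-cell-number
applications (e.g. transplant chimerism with few engrafted stem cells),
where the intervals should be read as approximate.

## Cohort statistics

- **Odds ratios** use the Woolf log-scale interval with
  $z = 1.959964$. Zero cells get the Haldane–Anscombe +0.5 added to every
  cell, applied only when needed and always flagged — this keeps log-ORs
  finite for co-occurrence displays. Applied to the published cohort
  counts (31/156 therapy-related vs 1/228 de novo carriers) this
  reproduces OR 56 with CI 7.6–417.3.
- **Fisher exact tests** use the two-sided "sum of tables no more probable
  than the observed" convention (the most common one; conventions differ,
  hence documented), computed by direct hypergeometric summation. The test
  suite checks it exhaustively against an independent enumeration oracle
  on all tables with margins ≤ 12.
- **FDR** is Benjamini–Hochberg step-up by default (the procedure behind
  reported FDR values is rarely named; BH is the field default), with
  Benjamini–Yekutieli selectable.
- **Exposure scans** drop rows with missing exposure data listwise per
  agent and surface the exclusion counts, mirroring how clinical-chart
  covariates are typically incomplete; zero-prevalence exposures are
  flagged non-estimable and excluded from the FDR family.
- 2×2 cell orientation is row-major by factor: $a$ = factor+/outcome+,
  $b$ = factor+/outcome−, $c$ = factor−/outcome+, $d$ = factor−/outcome−.

## Clonality utilities

The retention filter keeps variants with VAF ≥ 0.02 (inclusive), the
usual detection floor of targeted deep sequencing; clonal classification
is strict (VAF > 0.2). The cancer cell fraction uses the standard
purity/copy-number adjustment
$\mathrm{CCF} = v \cdot (\rho c_T + (1-\rho) c_N) / (\rho m)$ with
defaults $\rho = 1$, $c_T = c_N = 2$, $m = 1$ (heterozygous point
mutations), clamped to $[0,1]$ with raw values above 1.05 flagged. The
formula is an assumption of this package — publications reporting CCFs
frequently leave it unstated. HGVS-p parsing accepts `p.`-prefixed and
bare forms and `X`/`*`/`Ter` stop notations; `fs` marks frameshifts;
truncating = nonsense or frameshift. The shipped `ppm1d_exon_map()` is
approximate and marked provisional.

## The synthetic-data generator

`generate_cohort()` emulates a two-arm case/control genomic study:
therapy-exposed cases (default 156) versus chemo-naive controls (default
228). Exposure indicators are drawn for cases only — controls are
untreated by the design being emulated — so planted exposure effects also
induce case/control gene enrichment, as in the real design. Mutation flags
follow an additive logistic model: gene $g$'s log-odds start at
$\mathrm{logit}(\texttt{base\_rate}_g)$ and gain the planted
exposure log-ORs of the sample's exposures, plus planted pairwise
co-occurrence log-ORs conditional on earlier genes in the panel order.
This matches the odds-ratio analyses downstream, which is why effects are
planted on the log-odds scale.

VAFs are drawn from a Beta scaled to $[0.02, 0.47]$. The default shapes
$(0.262, 1.048)$ were fixed once by matching the scaled mean and median to
0.11 and 0.05 — the right-skewed profile typical of clonal-hematopoiesis
variant tables, where most clones are small and a few approach
heterozygous fixation. One variant is generated per mutated (sample,
gene); multi-hit samples are out of scope.

For the exposure-recovery checks at chart-review scale ($n = 140$), the
generator uses a base rate of 0.15 and pooled-platinum prevalence 0.40,
chosen so the marginal mutation frequency among cases is ~20%, the
published cohort frequency. The recovery window there spans roughly
±1.5 sampling standard deviations of the log-OR, so that check
characterizes the sampling distribution, not estimator bias.

`generate_competition()` splits the root seed into per-replicate streams
(`seed + replicate - 1`) so individual replicates are independently
reproducible. `generate_chimerism()` prepends an independent binomial
engraftment bottleneck on each clone's pool, emulating transplant loss;
with `engraft_frac = 1` the bottleneck draws are skipped so the output is
identical to the plain generator under the same seed.

What the generator does **not** emulate: sequencing reads and their error
model, copy-number profiles, germline contamination, inter-patient
covariate structure (age, primary malignancy), multi-clone competition,
and overdispersion beyond binomial sampling. Passing tests on synthetic
data therefore demonstrate correctness of the computations under the
stated model, not robustness to these real-data complications.

## Problem sizes and numerical choices in the checks

The test suite's distributional checks use: 2,000 replicate cultures at
$n_0 = 10^6$ for the stochastic/deterministic agreement (tolerance 3 Monte
Carlo SEs); 100 seeded simulations of 8 pooled replicates for
profile-interval coverage (nominal 95%, asserted ≥ 90% to allow Monte
Carlo slack); an exhaustive sweep of all 2×2 tables with margins ≤ 12 for
the exact test; 200 null cohorts for FDR control; and 50-seed recovery
runs for planted exposure and co-occurrence effects. All stochastic tests
run on fixed seeds.

## Known limitations

- The binomial likelihood ignores process noise (see above).
- The naive compounding form is intentionally inconsistent; it exists to
  reproduce quoted arithmetic and should not be used for inference.
- Exact tests are conditional on margins; for very sparse exposure tables
  the BH-adjusted exact p-values are conservative.
- The generator's planted co-occurrence effects are conditional (sequential
  logistic), so the marginal pairwise OR can differ slightly from the
  planted value when base rates are extreme.
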