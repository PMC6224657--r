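# clonesel

Quantitative analysis of how apoptosis-resistant hematopoietic clones —
the canonical example being clones carrying truncating *PPM1D* mutations —
expand under repeated doses of cytotoxic chemotherapy, and of the
cohort-level statistics that link such mutations to prior therapy. The
package is aimed at researchers studying clonal hematopoiesis and
therapy-related myeloid neoplasms who want to model treatment–mutation
selection, estimate per-dose fitness from competition assays, and run the
standard enrichment, co-occurrence and clonality computations on variant
tables.

## The model

A single dose of a cytotoxic agent kills an apoptotic fraction
*a*<sub>mut</sub> of mutant cells and *a*<sub>wt</sub> of wild-type cells.
The per-dose fitness of the mutant clone is the live-cell **survival
ratio**

> *r* = (1 − *a*<sub>mut</sub>) / (1 − *a*<sub>wt</sub>)

which compounds across treatment cycles. Two compounding conventions are
exposed:

- **naive** — the mutant proportion itself is multiplied by *r* each cycle
  and clamped at 1: *f*<sub>n</sub> = min(*f*<sub>0</sub>·*r*ⁿ, 1). This is
  the back-of-envelope form in which the arithmetic is usually quoted
  (49%/65% apoptosis → *r* ≈ 1.46; 20% seeded mutants → ≈ 90% after four
  cycles).
- **normalized** — the consistent two-clone update, applied to the odds:
  odds<sub>n</sub> = odds<sub>0</sub>·*r*ⁿ, *f*<sub>n</sub> =
  odds<sub>n</sub>/(1 + odds<sub>n</sub>). This is the default for
  simulation and fitting.

Around this core the package provides:

- a stochastic competition simulator (binomial per-dose survival,
  clone-neutral regrowth, flow-cytometry-style binomial sampling) and a
  chimerism variant with a binomial engraftment bottleneck;
- maximum-likelihood estimation of *r* from measured trajectories
  (binomial likelihood, profile-likelihood 95% CIs);
- cohort statistics: 2×2 construction, Woolf odds-ratio intervals with
  Haldane–Anscombe correction, two-sided Fisher exact tests, BH/BY FDR,
  pairwise co-occurrence/mutual-exclusivity matrices, exposure scans;
- clonality utilities: VAF retention filtering, strict clonal
  classification, cancer-cell-fraction conversion, HGVS-p consequence
  parsing, lineage concordance;
- a seeded synthetic-data generator (cohorts with planted exposure and
  co-occurrence log-odds effects, scaled-Beta VAFs, competition
  trajectories) so every stage is testable with known ground truth.

## Worked example

```r
library(clonesel)

# per-dose fitness from the measured apoptotic fractions
r <- survival_ratio(0.49, 0.65)
round(r, 2)
#> [1] 1.46

# expected expansion of a 20% clone across four cycles (naive compounding)
round(predict_trajectory(0.20, r, 4, model = "naive"), 3)
#> [1] 0.200 0.291 0.425 0.619 0.902

# cohort enrichment from a 2x2 (therapy-related vs de novo cases)
tab <- contingency_2x2(31, 125, 1, 227,
                       labels = c("therapy_related", "PPM1D"))
odds_ratio_woolf(tab)
#> OR = 56.3 (95% CI 7.59 - 417)
#>   exact p = 2.23e-12, asymptotic p = 8.03e-05

# recover the fitness from simulated flow-cytometry competition data
spec <- competition_spec(n0 = 1e6, replicates = 8, seed = 42)
fit <- fit_fitness(generate_competition(spec), dose_days = dose_days(spec))
fit
#> Per-dose survival-ratio fit (normalized model)
#>   r_hat = 1.4545  (95% profile CI 1.4475 - 1.4616)
#>   f0_hat = 0.2018, log-likelihood = -226.63, n = 40 obs
```

The fitted ratio recovers the value implied by the generating apoptotic
fractions (0.51/0.35 ≈ 1.457); the clone crosses 50% of the culture within
the four-dose horizon, and 90% of a culture seeded at 20% under naive
compounding.

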