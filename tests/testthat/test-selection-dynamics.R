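test_that("survival ratio matches closed forms and prints the quoted chain", {
  r <- survival_ratio(0.49, 0.65)
  expect_equal(r, 0.51 / 0.35)
  expect_equal(round(r, 2), 1.46)
  expect_equal(survival_ratio(0.3, 0.3), 1)
  expect_equal(survival_ratio(0, 0.5), 2)
  expect_error(survival_ratio(0.2, 1), "a_wt")
  # compounding the unrounded ratio reproduces the quoted integer percentages
  expect_equal(round(100 * compound_naive(0.20, r, 4)), 90)
  expect_equal(round(100 * compound_naive(0.10, r, 4)), 45)
})

test_that("naive and normalized compounding match direct arithmetic", {
  expect_equal(compound_naive(0.20, 1.46, 4), 0.2 * 1.46^4)
  expect_equal(compound_naive(0.10, 1.46, 4), 0.1 * 1.46^4)
  expect_equal(compound_naive(0.37, 1, 7), 0.37)     # neutral r
  expect_equal(compound_naive(0.5, 2, 10), 1)        # clamped at 1
  odds <- 0.25 * 1.46^4
  expect_equal(compound_normalized(0.20, 1.46, 4), odds / (1 + odds))
  expect_equal(compound_normalized(0.37, 1, 7), 0.37)
  expect_gt(compound_normalized(0.2, 50, 3), 0.999)  # r large -> 1
  expect_error(compound_naive(1.2, 1.5, 2), "f0")
})

test_that("compounding invariants hold over randomized parameters", {
  set.seed(42)
  for (i in 1:50) {
    f0 <- runif(1, 0.01, 0.99)
    r <- exp(runif(1, -1, 1))
    n <- sample(0:8, 1)
    k <- if (n > 0) sample(0:n, 1) else 0
    # odds update composes: k steps then n-k steps equal n steps
    expect_equal(compound_normalized(compound_normalized(f0, r, k), r, n - k),
                 compound_normalized(f0, r, n))
    if (n >= 1) {
      expect_equal(compound_normalized(f0, r, n),
                   compound_normalized(f0, r^n, 1))
    }
    # naive dominates normalized for advantageous clones; both start at f0
    if (r >= 1) {
      expect_gte(compound_naive(f0, r, n) - compound_normalized(f0, r, n),
                 -1e-12)
    }
    expect_equal(compound_naive(f0, r, 0), f0)
    expect_equal(compound_normalized(f0, r, 0), f0)
  }
})

test_that("predicted dose-by-dose trajectory follows the chosen model", {
  r <- 1.46
  expect_equal(predict_trajectory(0.20, r, 4, model = "naive"),
               pmin(0.2 * r^(0:4), 1))
  expect_equal(predict_trajectory(0.33, 1, 5), rep(0.33, 6))
  tr <- predict_trajectory(0.20, 1.46, 8, model = "normalized")
  expect_true(all(diff(tr) > 0))
  expect_true(all(tr < 1))
})

test_that("simulator: no kill and neutral growth keep the fraction at f0", {
  spec <- competition_spec(a_mut = 0, a_wt = 0, growth = 1, n0 = 1e4,
                           sample_size = 2000, replicates = 200, seed = 101)
  tr <- generate_competition(spec)
  fin <- tr[tr$day == max(tr$day), ]
  fr <- fin$mutant_count / fin$total_count
  mc_se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 0.20), 3 * mc_se)
})

test_that("simulator is deterministic under a fixed seed", {
  spec <- competition_spec(seed = 7)
  expect_identical(simulate_competition(spec), simulate_competition(spec))
})

test_that("whole-population extinction truncates and flags, never errors", {
  spec <- competition_spec(n0 = 20, a_mut = 0.97, a_wt = 0.97, growth = 1,
                           seed = 3)
  tr <- simulate_competition(spec)
  expect_true(attr(tr, "meta")$truncated)
  expect_lt(nrow(tr), length(spec$measure_days))
})

test_that("simulated mean final fraction tracks the odds-update prediction", {
  spec <- competition_spec(n0 = 1e5, replicates = 400, seed = 11)
  tr <- generate_competition(spec)
  fin <- tr[tr$day == 15, ]
  fr <- fin$mutant_count / fin$total_count
  pred <- compound_normalized(0.20, survival_ratio(0.49, 0.65), 4)
  mc_se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - pred), 3 * mc_se)
})

test_that("fitness estimator recovers neutrality, sign, and planted r", {
  flat <- data.frame(day = c(0, 4, 8, 12),
                     mutant_count = rep(20000, 4),
                     total_count = rep(1e5, 4))
  f <- fit_fitness(flat, dose_days = c(0, 4, 8))
  expect_lt(abs(f$r_hat - 1), 0.01)
  expect_true(f$converged)

  inc <- data.frame(day = c(0, 4, 8, 12),
                    mutant_count = c(2000, 2900, 4100, 5600),
                    total_count = rep(1e4, 4))
  expect_gt(fit_fitness(inc, dose_days = c(0, 4, 8))$r_hat, 1)

  spec <- competition_spec(n0 = 1e6, replicates = 8, seed = 4)
  tr <- generate_competition(spec)
  fit <- fit_fitness(tr, dose_days = dose_days(spec))
  r_true <- survival_ratio(0.49, 0.65)
  expect_lt(abs(fit$r_hat - r_true), 0.05)
  expect_lte(fit$ci_low, fit$r_hat)
  expect_lte(fit$r_hat, fit$ci_high)
})

test_that("degenerate trajectories give a flagged, unbounded estimate", {
  dg <- data.frame(day = c(0, 4), mutant_count = c(0, 0),
                   total_count = c(100, 100))
  f <- fit_fitness(dg, dose_days = 0)
  expect_false(f$converged)
  expect_true(is.infinite(f$ci_high))
  expect_error(fit_fitness(dg[1, ], dose_days = 0), "at least two")
})

test_that("fold-change normalization anchors the baseline at 1", {
  tr <- data.frame(day = c(4, 8, 12),
                   mutant_count = c(100, 200, 300), total_count = 1000)
  fc <- normalize_foldchange(tr, 4)
  expect_equal(fc$fold, c(1, 2, 3))
  expect_equal(normalize_foldchange(tr[1, ], 4)$fold, 1)
  tr$mutant_count[1] <- 0
  expect_error(normalize_foldchange(tr, 4), "baseline")
  # worked chimerism arithmetic: 13.9% baseline rising to 42% is a 3.02-fold
  ch <- data.frame(day = c(4, 13), mutant_count = c(139, 420),
                   total_count = 1000)
  expect_equal(round(normalize_foldchange(ch, 4)$fold[2], 2), 3.02)
})
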