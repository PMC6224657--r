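test_that("contingency tables are built with the documented orientation", {
  co <- cohort_from_counts(31, 125, 1, 227, "therapy_related", "PPM1D")
  tab <- build_contingency(co, "therapy_related", "PPM1D")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(31, 125, 1, 227))
  expect_equal(tab$n_excluded, 0)

  # all-zero outcome: every count lands in the outcome-negative column
  co2 <- data.frame(f = c(1, 1, 1, 0, 0), o = 0)
  tab2 <- build_contingency(co2, "f", "o")
  expect_equal(c(tab2$a, tab2$c), c(0, 0))
  expect_equal(c(tab2$b, tab2$d), c(3, 2))

  co3 <- data.frame(f = c(1, 1, NA, 0, 0, 0, NA, 1, NA, 0),
                    o = c(1, 0, 1, 0, 1, 0, 0, 1, 1, 0))
  tab3 <- build_contingency(co3, "f", "o")
  expect_equal(tab3$a + tab3$b + tab3$c + tab3$d, 7L)
  expect_equal(tab3$n_excluded, 3L)

  expect_error(build_contingency(data.frame(f = c(1, 2), o = c(0, 1)),
                                 "f", "o"), "not binary")
})

test_that("Woolf odds-ratio intervals match hand arithmetic", {
  sym <- odds_ratio_woolf(contingency_2x2(1, 1, 1, 1))
  expect_equal(sym$odds_ratio, 1)
  expect_equal(log(sym$ci_low), -log(sym$ci_high))  # symmetric in log space

  corr <- odds_ratio_woolf(contingency_2x2(0, 10, 5, 5))
  expect_true(corr$corrected)
  expect_equal(corr$odds_ratio, (0.5 * 5.5) / (10.5 * 5.5))
  expect_error(odds_ratio_woolf(contingency_2x2(0, 10, 5, 5),
                                zero_correction = FALSE), "zero cell")

  # axis-flip antisymmetry: swapping factor orientation inverts the OR
  set.seed(8)
  for (i in 1:20) {
    cells <- sample(1:40, 4, replace = TRUE)
    r1 <- odds_ratio_woolf(contingency_2x2(cells[1], cells[2], cells[3],
                                           cells[4]))
    r2 <- odds_ratio_woolf(contingency_2x2(cells[2], cells[1], cells[4],
                                           cells[3]))
    expect_equal(r1$log_or, -r2$log_or)
  }
})

test_that("Fisher exact p agrees with enumeration and the stats reference", {
  expect_equal(fisher_exact(contingency_2x2(1, 1, 1, 1)), 1)
  set.seed(19)
  for (i in 1:40) {
    cells <- sample(0:12, 4, replace = TRUE)
    if (sum(cells) == 0) next
    t <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
    p <- fisher_exact(t)
    expect_equal(p, fisher_oracle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-10)
    m <- matrix(c(cells[1], cells[3], cells[2], cells[4]), 2)
    expect_equal(p, stats::fisher.test(m)$p.value, tolerance = 1e-7)
  }
})

test_that("FDR adjustment reproduces step-up values and its invariances", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_error(bh_fdr(c(0.1, 1.7)), "\\[0, 1\\]")
  set.seed(23)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p))
    perm <- sample(seq_along(p))
    expect_equal(bh_fdr(p[perm]), q[perm])   # permutation equivariance
    j <- sample(seq_along(p), 1)
    p2 <- p
    p2[j] <- min(1, p[j] + runif(1, 0, 1 - p[j]))
    expect_true(all(bh_fdr(p2) >= q - 1e-12)) # monotone in each p
  }
})

test_that("co-occurrence matrices are symmetric and recover planted pairs", {
  rec <- 0
  for (s in 1:50) {
    cs <- cohort_spec(n_case = 250, n_control = 250,
                      genes = c("GENEA", "GENEB", "TP53", "TET2"),
                      base_rate = 0.2, exposures = NULL,
                      effect_log_or = NULL,
                      cooccur_log_or = data.frame(gene1 = "GENEA",
                                                  gene2 = "GENEB",
                                                  log_or = 2),
                      seed = 400 + s)
    g <- generate_cohort(cs)
    pm <- cooccurrence_matrix(g$cohort, cs$genes)
    expect_identical(pm$log_or, t(pm$log_or))
    expect_identical(pm$q, t(pm$q))
    rec <- rec + (pm$log_or["GENEA", "GENEB"] > 0 &&
                    pm$q["GENEA", "GENEB"] < 0.1)
  }
  expect_gte(rec, 45)  # >= 90% of 50 seeded cohorts
})

test_that("independent genes rarely reach significance (type-I control)", {
  flagged <- total <- 0
  for (s in 1:30) {
    cs <- cohort_spec(n_case = 250, n_control = 250,
                      genes = c("G1", "G2", "G3", "G4"),
                      base_rate = 0.2, exposures = NULL,
                      effect_log_or = NULL, seed = 500 + s)
    g <- generate_cohort(cs)
    pm <- cooccurrence_matrix(g$cohort, cs$genes)
    qs <- pm$q[upper.tri(pm$q)]
    flagged <- flagged + sum(qs < 0.1)
    total <- total + length(qs)
  }
  expect_lte(flagged / total, 0.10)
})

test_that("derived clonal items join the co-occurrence matrix", {
  cohort <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                       PPM1D = c(1, 1, 0, 0), TP53 = c(1, 0, 1, 0))
  variants <- data.frame(sample_id = c("s1", "s2"), gene = "PPM1D",
                         vaf = c(0.35, 0.08))
  pm <- cooccurrence_matrix(cohort, c("PPM1D", "TP53"), variants = variants,
                            clonal_only_for = c(PPM1D = 0.2))
  expect_true("PPM1D clonal" %in% pm$items)
  # only s1 exceeds the 0.2 clonality threshold
  expect_error(cooccurrence_matrix(cohort, c("PPM1D", "NPM1")), "NPM1")
})

test_that("exposure scans report ORs, handle degeneracies, and adjust FDR", {
  hits <- 0
  for (s in 1:100) {
    cs <- cohort_spec(n_case = 140, n_control = 10,
                      genes = c("PPM1D", "TP53"), base_rate = 0.15,
                      exposures = c(cisplatin = 0.40, etoposide = 0.25),
                      effect_log_or = data.frame(exposure = "cisplatin",
                                                 gene = "PPM1D",
                                                 log_or = log(2.9)),
                      seed = 600 + s)
    g <- generate_cohort(cs)
    cases <- g$cohort[g$cohort$group == "case", ]
    ee <- exposure_enrichment(cases, "PPM1D", c("cisplatin", "etoposide"))
    or <- ee$odds_ratio[ee$exposure == "cisplatin"]
    hits <- hits + (or >= 1.5 && or <= 5.5)
  }
  expect_gte(hits, 80)  # point estimate near planted OR 2.9 in >= 80%

  # degenerate scans: exposure equal to the outcome, and zero prevalence
  co <- data.frame(mut = c(1, 1, 0, 0, 0), same = c(1, 1, 0, 0, 0),
                   never = 0)
  ee2 <- exposure_enrichment(co, "mut", c("same", "never"))
  same_row <- ee2[ee2$exposure == "same", ]
  expect_true(same_row$corrected)
  expect_true(is.finite(same_row$odds_ratio))
  never_row <- ee2[ee2$exposure == "never", ]
  expect_false(never_row$estimable)
  expect_true(is.na(never_row$q))
  expect_error(exposure_enrichment(co, "mut", character(0)), "non-empty")
})

test_that("mutation frequencies summarize overall and by group", {
  co <- rbind(data.frame(grp = "tAML", PPM1D = rep(c(1, 0), c(15, 62))),
              data.frame(grp = "tMDS", PPM1D = rep(c(1, 0), c(16, 63))))
  overall <- mutation_frequency(co, "PPM1D")
  expect_equal(overall$mutated, 31)
  expect_equal(overall$n, 156)
  by_grp <- mutation_frequency(co, "PPM1D", by = "grp")
  expect_equal(by_grp$frequency[by_grp$group == "tAML"], 15 / 77)
})
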