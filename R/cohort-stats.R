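# Cohort-level contingency statistics: 2x2 construction from binary cohort
# columns, Woolf (log-scale asymptotic) odds-ratio intervals with optional
# Haldane-Anscombe zero-cell correction, two-sided Fisher exact p-values by
# direct hypergeometric summation, Benjamini-Hochberg FDR, pairwise gene
# co-occurrence / mutual-exclusivity matrices, and exposure-association scans.

Z975 <- 1.959964  # fixed z for 95% intervals

#' Build a 2x2 contingency table from two binary cohort columns
#'
#' Cross-tabulates a binary factor column against a binary outcome column.
#' Cell layout is row-major by factor: `a` = factor+/outcome+, `b` =
#' factor+/outcome-, `c` = factor-/outcome+, `d` = factor-/outcome-. Rows
#' with a missing value in either column are excluded and the exclusion count
#' is kept on the result.
#'
#' @param cohort Data frame (one row per sample).
#' @param factor_col,outcome_col Names of binary (0/1 or logical) columns.
#' @return An object of class `contingency_2x2`: list with integer cells
#'   `a`, `b`, `c`, `d`, `labels`, and `n_excluded`.
#' @examples
#' co <- data.frame(tmn = c(1, 1, 0, 0), mut = c(1, 0, 0, 0))
#' build_contingency(co, "tmn", "mut")
#' @export
build_contingency <- function(cohort, factor_col, outcome_col) {
  f <- check_binary(cohort[[factor_col]], factor_col)
  o <- check_binary(cohort[[outcome_col]], outcome_col)
  ok <- !is.na(f) & !is.na(o)
  f <- f[ok]; o <- o[ok]
  if (length(f) == 0) stop("no complete rows to tabulate", call. = FALSE)
  contingency_2x2(
    a = sum(f == 1 & o == 1), b = sum(f == 1 & o == 0),
    c = sum(f == 0 & o == 1), d = sum(f == 0 & o == 0),
    labels = c(factor_col, outcome_col),
    n_excluded = sum(!ok)
  )
}

#' Construct a 2x2 contingency table from counts
#' @param a,b,c,d Non-negative integer cell counts (`a` = factor+/outcome+,
#'   `b` = factor+/outcome-, `c` = factor-/outcome+, `d` = factor-/outcome-).
#' @param labels Optional axis names.
#' @param n_excluded Rows dropped for missingness when tabulated from data.
#' @return Object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d, labels = c("factor", "outcome"),
                            n_excluded = 0L) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("table total must be > 0", call. = FALSE)
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                 d = as.integer(d), labels = labels,
                 n_excluded = as.integer(n_excluded)),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(paste0(x$labels[1], c("+", "-")),
                              paste0(x$labels[2], c("+", "-"))))
  print(m)
  if (x$n_excluded > 0) cat(x$n_excluded, "rows excluded (missing values)\n")
  invisible(x)
}

check_binary <- function(x, name) {
  if (is.null(x)) stop("column '", name, "' not found", call. = FALSE)
  if (is.logical(x)) x <- as.integer(x)
  bad <- !is.na(x) & !(x %in% c(0, 1))
  if (any(bad)) {
    stop("column '", name, "' is not binary; offending values: ",
         paste(unique(x[bad])[1:min(5, length(unique(x[bad])))],
               collapse = ", "), call. = FALSE)
  }
  x
}

#' Odds ratio with Woolf 95% confidence interval
#'
#' Computes `OR = ad/bc` with the log-scale (Woolf) interval
#' `exp(ln OR +/- 1.959964 * sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is
#' zero and `zero_correction = TRUE`, 0.5 is added to every cell
#' (Haldane-Anscombe) before computing, and the result is flagged
#' `corrected`. The exact p-value is computed on the uncorrected table.
#'
#' @param t A `contingency_2x2` (see [build_contingency()]).
#' @param zero_correction Apply the +0.5 correction when a cell is zero
#'   (default `TRUE`); with it off, a zero cell is an error.
#' @return An object of class `association_result`: `odds_ratio`, `log_or`,
#'   `se_log_or`, `ci_low`, `ci_high`, `p_exact`, `p_asymptotic`,
#'   `corrected`, and a `q` slot filled by scan operations.
#' @examples
#' odds_ratio_woolf(contingency_2x2(31, 125, 1, 227))
#' @export
odds_ratio_woolf <- function(t, zero_correction = TRUE) {
  stopifnot(inherits(t, "contingency_2x2"))
  cells <- c(t$a, t$b, t$c, t$d)
  corrected <- FALSE
  if (any(cells == 0)) {
    if (!zero_correction) {
      stop("zero cell in 2x2 table; enable zero_correction or supply ",
           "non-degenerate counts", call. = FALSE)
    }
    cells <- cells + 0.5
    corrected <- TRUE
  }
  a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
  log_or <- log(a) + log(d) - log(b) - log(cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  structure(list(
    odds_ratio = exp(log_or), log_or = log_or, se_log_or = se,
    ci_low = exp(log_or - Z975 * se), ci_high = exp(log_or + Z975 * se),
    p_exact = fisher_exact(t),
    p_asymptotic = 2 * stats::pnorm(-abs(log_or) / se),
    corrected = corrected, q = NA_real_
  ), class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("OR = %.3g (95%% CI %.3g - %.3g)%s\n", x$odds_ratio,
              x$ci_low, x$ci_high,
              if (x$corrected) "  [+0.5 zero-cell correction]" else ""))
  cat(sprintf("  exact p = %.3g, asymptotic p = %.3g", x$p_exact,
              x$p_asymptotic))
  if (!is.na(x$q)) cat(sprintf(", q = %.3g", x$q))
  cat("\n")
  invisible(x)
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Direct hypergeometric computation: with margins fixed, sums the
#' probabilities of all tables whose probability does not exceed that of the
#' observed table (within a small relative tolerance), the usual two-sided
#' convention.
#'
#' @param t A `contingency_2x2`.
#' @return The two-sided exact p-value.
#' @examples
#' fisher_exact(contingency_2x2(1, 1, 1, 1))  # 1
#' @export
fisher_exact <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  m <- t$a + t$b          # factor+ margin
  n <- t$c + t$d          # factor- margin
  kk <- t$a + t$c         # outcome+ margin
  if (m == 0 || n == 0 || kk == 0 || t$b + t$d == 0) return(1)
  support <- max(0, kk - n):min(kk, m)
  probs <- stats::dhyper(support, m, n, kk)
  p_obs <- stats::dhyper(t$a, m, n, kk)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Benjamini-Hochberg (or Benjamini-Yekutieli) adjusted p-values
#'
#' Step-up FDR adjustment: `q(i) = min over j >= i (sorted)` of
#' `p(j) * m / j`, clamped to 1, returned in input order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param method `"BH"` (default) or `"BY"`.
#' @return Adjusted values in the order of `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = method)
}

#' Pairwise co-occurrence / mutual-exclusivity matrix
#'
#' For every unordered pair of lesions, builds the presence/absence 2x2
#' across samples and computes the log odds ratio (with the +0.5 correction
#' when a cell is zero), the two-sided exact p, and a BH q over all pairs.
#' Positive log-OR = co-occurrence, negative = mutual exclusivity.
#'
#' @param cohort Data frame with one binary column per lesion.
#' @param items Column names (genes or other lesions) to include.
#' @param variants Optional variant table (`sample_id`, `gene`, `vaf`) used
#'   with `clonal_only_for` to add derived "GENE clonal" items.
#' @param clonal_only_for Named numeric vector mapping gene -> VAF threshold;
#'   for each entry an item `"GENE clonal"` is added, flagging samples whose
#'   variant in that gene has `vaf > threshold`.
#' @param fdr_method Passed to [bh_fdr()].
#' @return Object of class `pairwise_matrix`: `items` plus symmetric
#'   matrices `log_or`, `p`, `q`, `corrected` (diagonal `NA`).
#' @export
cooccurrence_matrix <- function(cohort, items, variants = NULL,
                                clonal_only_for = NULL,
                                fdr_method = "BH") {
  missing_items <- setdiff(items, names(cohort))
  if (length(missing_items)) {
    stop("items absent from cohort table: ",
         paste(missing_items, collapse = ", "), call. = FALSE)
  }
  flags <- lapply(items, function(g) check_binary(cohort[[g]], g))
  names(flags) <- items
  if (!is.null(clonal_only_for)) {
    if (is.null(variants)) {
      stop("clonal_only_for requires a variants table", call. = FALSE)
    }
    for (g in names(clonal_only_for)) {
      thr <- clonal_only_for[[g]]
      hit <- unique(variants$sample_id[variants$gene == g &
                                         variants$vaf > thr])
      flags[[paste(g, "clonal")]] <- as.integer(cohort$sample_id %in% hit)
    }
  }
  labs <- names(flags)
  k <- length(labs)
  log_or <- p <- q <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  corrected <- matrix(NA, k, k, dimnames = list(labs, labs))
  pair_idx <- which(upper.tri(log_or), arr.ind = TRUE)
  pvec <- numeric(nrow(pair_idx))
  for (row in seq_len(nrow(pair_idx))) {
    i <- pair_idx[row, 1]; j <- pair_idx[row, 2]
    x <- flags[[i]]; y <- flags[[j]]
    ok <- !is.na(x) & !is.na(y)
    tab <- contingency_2x2(sum(x[ok] & y[ok]), sum(x[ok] & !y[ok]),
                           sum(!x[ok] & y[ok]), sum(!x[ok] & !y[ok]),
                           labels = labs[c(i, j)])
    res <- odds_ratio_woolf(tab, zero_correction = TRUE)
    log_or[i, j] <- log_or[j, i] <- res$log_or
    p[i, j] <- p[j, i] <- res$p_exact
    corrected[i, j] <- corrected[j, i] <- res$corrected
    pvec[row] <- res$p_exact
  }
  qvec <- bh_fdr(pvec, method = fdr_method)
  for (row in seq_len(nrow(pair_idx))) {
    i <- pair_idx[row, 1]; j <- pair_idx[row, 2]
    q[i, j] <- q[j, i] <- qvec[row]
  }
  structure(list(items = labs, log_or = log_or, p = p, q = q,
                 corrected = corrected),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat("Pairwise co-occurrence matrix over", length(x$items), "items\n")
  cat("log odds ratios (positive = co-occurrence):\n")
  print(round(x$log_or, 2))
  invisible(x)
}

#' Exposure-association scan against a mutated gene
#'
#' For each exposure, cross-tabulates the (binary) exposure indicator against
#' the outcome gene's mutation flag, reports the Woolf OR/CI and exact p, and
#' adjusts across the exposure family with BH FDR. Rows with a missing value
#' for an exposure are dropped for that agent only, with the count reported.
#' Exposures with zero (or full) prevalence among complete rows are flagged
#' non-estimable and excluded from the FDR family.
#'
#' @param cohort Data frame with binary exposure columns and a binary column
#'   for the outcome gene.
#' @param outcome_gene Name of the binary mutation column.
#' @param exposures Character vector of exposure column names (non-empty).
#' @param fdr_method Passed to [bh_fdr()].
#' @return Data frame (one row per exposure, sorted by q then p) with cells,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p`, `q`, `corrected`, `estimable`,
#'   and `n_excluded`.
#' @export
exposure_enrichment <- function(cohort, outcome_gene, exposures,
                                fdr_method = "BH") {
  if (length(exposures) == 0) {
    stop("exposure list must be non-empty", call. = FALSE)
  }
  rows <- lapply(exposures, function(e) {
    tab <- build_contingency(cohort, e, outcome_gene)
    est <- (tab$a + tab$b) > 0 && (tab$c + tab$d) > 0
    if (!est) {
      return(data.frame(exposure = e, a = tab$a, b = tab$b, c = tab$c,
                        d = tab$d, odds_ratio = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_, q = NA_real_,
                        corrected = NA, estimable = FALSE,
                        n_excluded = tab$n_excluded))
    }
    r <- odds_ratio_woolf(tab, zero_correction = TRUE)
    data.frame(exposure = e, a = tab$a, b = tab$b, c = tab$c, d = tab$d,
               odds_ratio = r$odds_ratio, ci_low = r$ci_low,
               ci_high = r$ci_high, p = r$p_exact, q = NA_real_,
               corrected = r$corrected, estimable = TRUE,
               n_excluded = tab$n_excluded)
  })
  out <- do.call(rbind, rows)
  est <- out$estimable
  if (any(est)) out$q[est] <- bh_fdr(out$p[est], method = fdr_method)
  out <- out[order(out$q, out$p, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mutation frequency summary, overall or by group
#'
#' @param cohort Data frame with a binary column per gene.
#' @param gene Name of the mutation-flag column.
#' @param by Optional grouping column (e.g. disease subtype).
#' @return Data frame with `group`, `n`, `mutated`, and `frequency`
#'   (proportion).
#' @examples
#' co <- data.frame(g = c("x", "x", "y"), PPM1D = c(1, 0, 1))
#' mutation_frequency(co, "PPM1D", by = "g")
#' @export
mutation_frequency <- function(cohort, gene, by = NULL) {
  flag <- check_binary(cohort[[gene]], gene)
  grp <- if (is.null(by)) rep("all", nrow(cohort)) else as.character(cohort[[by]])
  ok <- !is.na(flag) & !is.na(grp)
  agg <- tapply(flag[ok], grp[ok], function(v) c(n = length(v), k = sum(v)))
  out <- do.call(rbind, lapply(names(agg), function(g) {
    data.frame(group = g, n = agg[[g]]["n"], mutated = agg[[g]]["k"],
               frequency = agg[[g]]["k"] / agg[[g]]["n"])
  }))
  rownames(out) <- NULL
  out
}
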