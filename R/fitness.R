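# Maximum-likelihood estimation of the per-dose survival ratio r from
# measured competition trajectories. Each measurement contributes a binomial
# likelihood Bin(mutant_count | total_count, p(f0, r; doses)), where p is the
# odds-update (or naive) compounding model evaluated at the cumulative dose
# count before that measurement. The fit is a bounded one-dimensional search
# on log r with the initial fraction f0 profiled out; the confidence interval
# is a profile-likelihood interval at the chi-square(1) 95% cutoff (3.84).

R_BOUNDS_DEFAULT <- c(0.2, 5)
PROFILE_CUTOFF <- 3.84  # chi-square 1 df, 95%

#' Fit the per-dose survival ratio to a measured trajectory
#'
#' @param traj Data frame with columns `day`, `mutant_count`, `total_count`;
#'   multiple rows per day (pooled replicates) are allowed. At least two
#'   measurements with `total_count > 0` are required.
#' @param doses Cumulative number of doses given before each measurement:
#'   either a numeric vector aligned with the rows of `traj`, or `NULL` to
#'   derive it from `dose_days` via [doses_before()].
#' @param dose_days Days on which doses were given; used only when
#'   `doses = NULL`.
#' @param model Compounding model linking doses to the expected fraction:
#'   `"normalized"` (default) or `"naive"`.
#' @param f0 Fix the initial mutant fraction at this value instead of
#'   estimating it (default `NULL`: f0 is profiled out by an inner
#'   one-dimensional optimization).
#' @param r_bounds Search bounds for r (default `c(0.2, 5)`).
#' @return An object of class `fitness_fit`: a list with `r_hat`, `ci_low`,
#'   `ci_high` (95% profile likelihood), `f0_hat`, `loglik`, `n_obs`,
#'   `converged`, and `model`. Degenerate inputs (all measurements at
#'   fraction 0 or 1) give a non-converged estimate with infinite bounds.
#' @examples
#' spec <- competition_spec(n0 = 1e5, seed = 11)
#' tr <- simulate_competition(spec)
#' fit_fitness(tr, dose_days = dose_days(spec))
#' @export
fit_fitness <- function(traj, doses = NULL, dose_days = NULL,
                        model = c("normalized", "naive"),
                        f0 = NULL, r_bounds = R_BOUNDS_DEFAULT) {
  model <- match.arg(model)
  traj <- as.data.frame(traj)
  keep <- traj$total_count > 0
  traj <- traj[keep, , drop = FALSE]
  if (nrow(traj) < 2) {
    stop("need at least two measurements with total_count > 0", call. = FALSE)
  }
  if (is.null(doses)) {
    if (is.null(dose_days)) {
      stop("supply either `doses` or `dose_days`", call. = FALSE)
    }
    doses <- doses_before(traj$day, dose_days)
  } else {
    doses <- doses[keep]
    if (length(doses) != nrow(traj)) {
      stop("`doses` must align with the rows of `traj`", call. = FALSE)
    }
  }
  k <- traj$mutant_count
  n <- traj$total_count

  degenerate <- all(k == 0) || all(k == n)
  if (degenerate) {
    out <- list(r_hat = NA_real_, ci_low = 0, ci_high = Inf,
                f0_hat = NA_real_, loglik = NA_real_, n_obs = nrow(traj),
                converged = FALSE, model = model)
    class(out) <- "fitness_fit"
    return(out)
  }

  pred <- switch(model, normalized = compound_normalized,
                 naive = compound_naive)
  eps <- 1e-12
  nll <- function(f0v, r) {
    p <- pmin(pmax(pred(f0v, r, doses), eps), 1 - eps)
    -sum(stats::dbinom(k, n, p, log = TRUE))
  }
  # profile f0 out (or hold it fixed) at a given log r
  prof <- function(lr) {
    r <- exp(lr)
    if (!is.null(f0)) return(nll(f0, r))
    stats::optimize(nll, c(1e-8, 1 - 1e-8), r = r)$objective
  }
  prof_f0 <- function(lr) {
    r <- exp(lr)
    if (!is.null(f0)) return(f0)
    stats::optimize(nll, c(1e-8, 1 - 1e-8), r = r)$minimum
  }

  lb <- log(r_bounds[1]); ub <- log(r_bounds[2])
  opt <- stats::optimize(prof, c(lb, ub), tol = 1e-6)
  lr_hat <- opt$minimum
  nll_min <- opt$objective
  at_boundary <- min(lr_hat - lb, ub - lr_hat) < 1e-4
  target <- nll_min + PROFILE_CUTOFF / 2

  side <- function(a, b) {
    fa <- prof(a) - target
    if (fa < 0) return(exp(a))  # cutoff not reached inside bounds
    exp(stats::uniroot(function(x) prof(x) - target, c(a, b),
                       tol = 1e-6)$root)
  }
  ci_low <- side(lb, lr_hat)
  ci_high <- side(ub, lr_hat)

  out <- list(r_hat = exp(lr_hat),
              ci_low = min(ci_low, ci_high),
              ci_high = max(ci_low, ci_high),
              f0_hat = prof_f0(lr_hat),
              loglik = -nll_min, n_obs = nrow(traj),
              converged = !at_boundary, model = model)
  class(out) <- "fitness_fit"
  out
}

#' @export
print.fitness_fit <- function(x, ...) {
  cat("Per-dose survival-ratio fit (", x$model, " model)\n", sep = "")
  if (!x$converged && is.na(x$r_hat)) {
    cat("  non-converged (degenerate trajectory)\n")
    return(invisible(x))
  }
  cat(sprintf("  r_hat = %.4f  (95%% profile CI %.4f - %.4f)\n",
              x$r_hat, x$ci_low, x$ci_high))
  cat(sprintf("  f0_hat = %.4f, log-likelihood = %.2f, n = %d obs%s\n",
              x$f0_hat, x$loglik, x$n_obs,
              if (x$converged) "" else "  [estimate at search boundary]"))
  invisible(x)
}
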