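# Per-dose selection model: a mutant clone that dies less than wild-type at
# each chemotherapy dose compounds a survival-ratio advantage across treatment
# cycles. Two compounding conventions are exposed: the "naive" form applies the
# live-cell ratio directly to a proportion (matching how the arithmetic is
# usually quoted), the "normalized" form applies it to the odds, which is the
# mathematically consistent two-clone update and is the default everywhere a
# model is simulated or fitted.

#' Per-dose live-cell survival ratio
#'
#' Ratio of surviving mutant to surviving wild-type cells after a single dose
#' of a cytotoxic agent, given the apoptotic (killed) fraction of each clone.
#' With 49% apoptotic mutant cells versus 65% apoptotic wild-type cells the
#' live-cell ratio is 0.51/0.35 = 1.457, i.e. 1.46 at two decimals.
#'
#' @param a_mut Apoptotic fraction of the mutant clone, in `[0, 1)`.
#' @param a_wt Apoptotic fraction of the wild-type clone, in `[0, 1)`.
#' @return The per-dose survival ratio `(1 - a_mut) / (1 - a_wt)`.
#' @examples
#' survival_ratio(0.49, 0.65)
#' @export
survival_ratio <- function(a_mut, a_wt) {
  if (any(a_mut < 0 | a_mut >= 1)) {
    stop("a_mut must be in [0, 1)", call. = FALSE)
  }
  if (any(a_wt < 0 | a_wt >= 1)) {
    stop("a_wt must be in [0, 1): a fully killed wild-type pool leaves the ",
         "ratio undefined", call. = FALSE)
  }
  (1 - a_mut) / (1 - a_wt)
}

#' Compound a survival ratio across treatment rounds (naive form)
#'
#' Treats the mutant proportion itself as the quantity multiplied by the
#' per-dose ratio `r` at every round, and clamps at 1. This is the back-of-
#' envelope form in which the arithmetic is usually quoted (20% x 1.457^4 ->
#' 90%); it is not a consistent two-clone update, for which see
#' [compound_normalized()].
#'
#' @param f0 Initial mutant fraction, in `(0, 1)`.
#' @param r Per-dose survival ratio, `> 0`.
#' @param n Number of treatment rounds, `>= 0`.
#' @return `min(f0 * r^n, 1)`.
#' @seealso [compound_normalized()], [predict_trajectory()]
#' @examples
#' compound_naive(0.20, survival_ratio(0.49, 0.65), 4)  # ~0.90
#' @export
compound_naive <- function(f0, r, n) {
  check_fraction(f0, "f0")
  if (any(r <= 0)) stop("r must be > 0", call. = FALSE)
  if (any(n < 0)) stop("n must be >= 0", call. = FALSE)
  pmin(f0 * r^n, 1)
}

#' Compound a survival ratio across treatment rounds (odds form)
#'
#' The consistent two-clone update: each dose multiplies the mutant:wild-type
#' odds by `r`, so after `n` doses the mutant fraction is
#' `odds0 * r^n / (1 + odds0 * r^n)` with `odds0 = f0 / (1 - f0)`. Always in
#' `(0, 1)` and composable: `n` steps of `r` equal one step of `r^n`.
#'
#' @inheritParams compound_naive
#' @return Mutant fraction after `n` doses.
#' @examples
#' compound_normalized(0.20, 1.46, 4)
#' @export
compound_normalized <- function(f0, r, n) {
  check_fraction(f0, "f0")
  if (any(r <= 0)) stop("r must be > 0", call. = FALSE)
  if (any(n < 0)) stop("n must be >= 0", call. = FALSE)
  odds <- f0 / (1 - f0) * r^n
  odds / (1 + odds)
}

#' Expected mutant-fraction sequence across doses
#'
#' @param f0 Initial mutant fraction, in `(0, 1)`.
#' @param r Per-dose survival ratio, `> 0`.
#' @param n_doses Number of doses.
#' @param model `"normalized"` (odds update, default) or `"naive"`.
#' @return Numeric vector of length `n_doses + 1`: the expected mutant
#'   fraction after 0, 1, ..., `n_doses` doses. Non-decreasing when `r >= 1`,
#'   non-increasing when `r <= 1`.
#' @examples
#' predict_trajectory(0.20, 1.46, 4, model = "naive")
#' @export
predict_trajectory <- function(f0, r, n_doses,
                               model = c("normalized", "naive")) {
  model <- match.arg(model)
  fn <- switch(model, normalized = compound_normalized, naive = compound_naive)
  vapply(0:n_doses, function(k) fn(f0, r, k), numeric(1))
}

#' Fold change of a trajectory relative to a baseline time point
#'
#' Expresses each measured mutant fraction relative to the fraction at a
#' chosen baseline time, the convention used for post-transplant chimerism
#' curves (fold change relative to initial engraftment).
#'
#' @param traj A trajectory data frame with columns `day`, `mutant_count`,
#'   `total_count` (see [simulate_competition()]).
#' @param baseline_time Time (day) of the baseline measurement; must exist in
#'   `traj` with a positive measured fraction.
#' @return Data frame with columns `day` and `fold`; `fold` is exactly 1 at
#'   the baseline.
#' @examples
#' tr <- data.frame(day = c(4, 8, 12), mutant_count = c(10, 20, 30),
#'                  total_count = 100)
#' normalize_foldchange(tr, 4)
#' @export
normalize_foldchange <- function(traj, baseline_time) {
  traj <- as.data.frame(traj)
  need <- c("day", "mutant_count", "total_count")
  if (!all(need %in% names(traj))) {
    stop("traj must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  i <- which(traj$day == baseline_time)
  if (length(i) == 0) {
    stop("no measurement at baseline_time = ", baseline_time, call. = FALSE)
  }
  i <- i[1]
  if (traj$total_count[i] <= 0 || traj$mutant_count[i] <= 0) {
    stop("baseline fraction is 0 at day ", baseline_time,
         "; choose another baseline time", call. = FALSE)
  }
  frac <- traj$mutant_count / traj$total_count
  data.frame(day = traj$day, fold = frac / frac[i])
}

# shared argument check
check_fraction <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0 | x >= 1)) {
    stop(name, " must be in (0, 1)", call. = FALSE)
  }
  invisible(x)
}
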