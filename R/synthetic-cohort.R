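# Synthetic cohort generator with planted ground truth. Emulates a two-arm
# case/control study: therapy-exposed cases versus chemo-naive controls, with
# per-gene mutation flags whose log-odds are shifted by planted exposure
# effects and planted pairwise co-occurrence effects, and with per-variant
# VAFs drawn from a scaled Beta calibrated to a right-skewed clonal
# hematopoiesis-like distribution.

#' Specify a synthetic case/control cohort
#'
#' Mutation flags follow a logistic model: for gene g in sample s,
#' `logit P(mut) = logit(base_rate_g) + sum_e effect_log_or(e, g) * exposure_e(s)
#'  + sum_{g' earlier} cooccur_log_or(g', g) * mut_{g'}(s)`.
#' Exposure indicators are drawn for cases only (controls are chemo-naive by
#' the design being emulated), so planted exposure effects also induce a
#' case/control enrichment of the affected genes. Each mutated (sample, gene)
#' receives one variant record with
#' `VAF = vaf_min + (vaf_max - vaf_min) * Beta(vaf_shape)`.
#'
#' The default Beta shapes (0.262, 1.048) were chosen by matching the scaled
#' distribution's mean and median to 0.11 and 0.05 on `[0.02, 0.47]`, the
#' skew typical of clonal-hematopoiesis variant tables.
#'
#' @param n_case,n_control Number of case (therapy-exposed) and control
#'   samples, `>= 1`. Defaults 156 and 228.
#' @param genes Gene symbols in the panel.
#' @param base_rate Per-gene mutation probability in unexposed samples;
#'   scalar or named vector aligned with `genes`, in `[0, 1]`.
#' @param exposures Named numeric vector of exposure prevalences among
#'   cases, in `[0, 1]`.
#' @param effect_log_or Data frame (`exposure`, `gene`, `log_or`) of planted
#'   exposure effects; default plants log(2.9) for cisplatin -> PPM1D and
#'   log(2.98) for etoposide -> PPM1D.
#' @param cooccur_log_or Data frame (`gene1`, `gene2`, `log_or`) of planted
#'   pairwise effects; gene order in `genes` determines the conditioning
#'   direction (`gene2`'s log-odds shift by `log_or` when `gene1` is
#'   mutated).
#' @param vaf_shape Length-2 positive Beta shape parameters.
#' @param vaf_min,vaf_max VAF support bounds, `0 <= vaf_min < vaf_max <= 1`.
#' @param seed Integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_case = 156, n_control = 228,
                        genes = c("PPM1D", "TP53", "TET2", "DNMT3A",
                                  "ASXL1", "RUNX1"),
                        base_rate = 0.05,
                        exposures = c(cisplatin = 0.30, etoposide = 0.25,
                                      doxorubicin = 0.35, vincristine = 0.20,
                                      radiation = 0.50),
                        effect_log_or = data.frame(
                          exposure = c("cisplatin", "etoposide"),
                          gene = c("PPM1D", "PPM1D"),
                          log_or = log(c(2.9, 2.98))),
                        cooccur_log_or = NULL,
                        vaf_shape = c(0.262, 1.048),
                        vaf_min = 0.02, vaf_max = 0.47,
                        seed = 1L) {
  if (n_case < 1 || n_control < 1) {
    stop("n_case and n_control must be >= 1", call. = FALSE)
  }
  if (length(base_rate) == 1) {
    base_rate <- stats::setNames(rep(base_rate, length(genes)), genes)
  }
  if (!all(genes %in% names(base_rate))) {
    stop("base_rate must cover every gene", call. = FALSE)
  }
  if (any(base_rate < 0 | base_rate > 1)) {
    stop("base_rate must be in [0, 1]", call. = FALSE)
  }
  if (is.null(exposures)) exposures <- stats::setNames(numeric(0), character(0))
  if (any(exposures < 0 | exposures > 1)) {
    stop("exposures prevalences must be in [0, 1]", call. = FALSE)
  }
  if (length(exposures) &&
      (is.null(names(exposures)) || any(!nzchar(names(exposures))))) {
    stop("exposures must be a named vector", call. = FALSE)
  }
  if (!is.null(effect_log_or) && nrow(effect_log_or) > 0) {
    if (!all(effect_log_or$exposure %in% names(exposures))) {
      stop("effect_log_or references unknown exposures", call. = FALSE)
    }
    if (!all(effect_log_or$gene %in% genes)) {
      stop("effect_log_or references unknown genes", call. = FALSE)
    }
  }
  if (!is.null(cooccur_log_or) && nrow(cooccur_log_or) > 0 &&
      !all(c(cooccur_log_or$gene1, cooccur_log_or$gene2) %in% genes)) {
    stop("cooccur_log_or references unknown genes", call. = FALSE)
  }
  if (any(vaf_shape <= 0)) stop("vaf_shape must be > 0", call. = FALSE)
  if (!(vaf_min >= 0 && vaf_min < vaf_max && vaf_max <= 1)) {
    stop("need 0 <= vaf_min < vaf_max <= 1", call. = FALSE)
  }
  structure(list(n_case = n_case, n_control = n_control, genes = genes,
                 base_rate = base_rate[genes], exposures = exposures,
                 effect_log_or = effect_log_or,
                 cooccur_log_or = cooccur_log_or,
                 vaf_shape = vaf_shape, vaf_min = vaf_min,
                 vaf_max = vaf_max, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort table and variant table
#'
#' Draws exposure indicators (cases only), mutation flags under the planted
#' logistic model, and one variant record per mutated (sample, gene) with a
#' scaled-Beta VAF and a synthetic truncating or missense protein change.
#' Fully deterministic given the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return List with `cohort` (sample_id, group, exposure columns, one
#'   binary column per gene) and `variants` (sample_id, gene,
#'   protein_change, consequence, vaf).
#' @examples
#' gc <- generate_cohort(cohort_spec(n_case = 30, n_control = 30, seed = 2))
#' head(gc$variants)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_case + spec$n_control
  group <- rep(c("case", "control"), c(spec$n_case, spec$n_control))
  sample_id <- sprintf("S%04d", seq_len(n))

  expo <- as.data.frame(lapply(stats::setNames(nm = names(spec$exposures)),
                               function(e) {
    ifelse(group == "case", stats::rbinom(n, 1, spec$exposures[[e]]), 0L)
  }))
  if (length(spec$exposures) == 0) {
    expo <- as.data.frame(matrix(integer(0), nrow = n, ncol = 0))
  }

  flags <- matrix(0L, n, length(spec$genes),
                  dimnames = list(NULL, spec$genes))
  for (g in spec$genes) {
    eta <- rep(stats::qlogis(spec$base_rate[[g]]), n)
    eff <- spec$effect_log_or
    if (!is.null(eff)) {
      for (i in which(eff$gene == g)) {
        eta <- eta + eff$log_or[i] * expo[[eff$exposure[i]]]
      }
    }
    co <- spec$cooccur_log_or
    if (!is.null(co)) {
      for (i in which(co$gene2 == g)) {
        g1 <- co$gene1[i]
        if (match(g1, spec$genes) < match(g, spec$genes)) {
          eta <- eta + co$log_or[i] * flags[, g1]
        }
      }
    }
    flags[, g] <- stats::rbinom(n, 1, stats::plogis(eta))
  }

  cohort <- cbind(data.frame(sample_id = sample_id, group = group),
                  expo, as.data.frame(flags))

  hits <- which(flags == 1, arr.ind = TRUE)
  if (nrow(hits) > 0) {
    gene <- spec$genes[hits[, 2]]
    vaf <- spec$vaf_min + (spec$vaf_max - spec$vaf_min) *
      stats::rbeta(nrow(hits), spec$vaf_shape[1], spec$vaf_shape[2])
    # synthetic protein changes: truncating for PPM1D-like exon-6 lesions,
    # mixed classes elsewhere
    consequence <- ifelse(gene == "PPM1D",
                          sample(c("nonsense", "frameshift"), nrow(hits),
                                 replace = TRUE),
                          sample(c("missense", "nonsense", "frameshift"),
                                 nrow(hits), replace = TRUE,
                                 prob = c(0.7, 0.15, 0.15)))
    pos <- ifelse(gene == "PPM1D",
                  sample(420:550, nrow(hits), replace = TRUE),
                  sample(30:500, nrow(hits), replace = TRUE))
    aa <- sample(c("R", "L", "Q", "E", "K", "S"), nrow(hits), replace = TRUE)
    protein_change <- ifelse(
      consequence == "nonsense", sprintf("p.%s%dX", aa, pos),
      ifelse(consequence == "frameshift", sprintf("p.%s%dfs", aa, pos),
             sprintf("p.%s%dV", aa, pos)))
    variants <- data.frame(sample_id = sample_id[hits[, 1]], gene = gene,
                           protein_change = protein_change,
                           consequence = consequence, vaf = vaf)
    variants <- variants[order(variants$sample_id, variants$gene), ,
                         drop = FALSE]
    rownames(variants) <- NULL
  } else {
    variants <- data.frame(sample_id = character(0), gene = character(0),
                           protein_change = character(0),
                           consequence = character(0), vaf = numeric(0))
  }
  list(cohort = cohort, variants = variants)
}

#' Generate replicate competition trajectories with known ground truth
#'
#' Runs [simulate_competition()] once per replicate, splitting the root seed
#' into per-replicate streams (`spec$seed + replicate - 1`), and stacks the
#' measurements into one long table. The generating parameters travel with
#' the result as attribute `truth`.
#'
#' @param spec A [competition_spec()].
#' @return Data frame with columns `replicate`, `day`, `mutant_count`,
#'   `total_count`; attribute `truth` holds the spec (including the implied
#'   per-dose survival ratio).
#' @examples
#' generate_competition(competition_spec(replicates = 2, seed = 5))
#' @export
generate_competition <- function(spec) {
  stopifnot(inherits(spec, "competition_spec"))
  out <- lapply(seq_len(spec$replicates), function(i) {
    tr <- simulate_competition(spec, seed = spec$seed + i - 1L)
    if (nrow(tr) == 0) return(NULL)
    cbind(replicate = i, as.data.frame(tr))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(replicate = integer(0), day = numeric(0),
                      mutant_count = numeric(0), total_count = numeric(0))
  }
  rownames(out) <- NULL
  attr(out, "truth") <- c(unclass(spec),
                          list(r = survival_ratio(spec$a_mut, spec$a_wt)))
  out
}

#' Generate chimerism trajectories with an engraftment bottleneck
#'
#' As [generate_competition()], but before dosing each replicate passes its
#' mutant and wild-type pools independently through a binomial engraftment
#' bottleneck retaining each cell with probability `engraft_frac`, emulating
#' the loss of transplanted cells during marrow engraftment. With
#' `engraft_frac = 1` the bottleneck draws are skipped, making the output
#' identical to [generate_competition()] under the same seed.
#'
#' @param spec A [competition_spec()]; for a weekly-dosing transplant design
#'   set `dose_interval_days = 7`.
#' @param engraft_frac Probability a transplanted cell engrafts, in
#'   `(0, 1]`.
#' @return As [generate_competition()]; `truth` additionally records
#'   `engraft_frac`.
#' @export
generate_chimerism <- function(spec, engraft_frac = 1) {
  stopifnot(inherits(spec, "competition_spec"))
  if (engraft_frac <= 0 || engraft_frac > 1) {
    stop("engraft_frac must be in (0, 1]", call. = FALSE)
  }
  out <- lapply(seq_len(spec$replicates), function(i) {
    set.seed(spec$seed + i - 1L)
    m <- round(spec$n0 * spec$f0)
    w <- round(spec$n0) - m
    if (engraft_frac < 1) {
      m <- stats::rbinom(1, m, engraft_frac)
      w <- stats::rbinom(1, w, engraft_frac)
    }
    res <- sim_core(m, w, spec)
    if (nrow(res$traj) == 0) return(NULL)
    cbind(replicate = i, res$traj)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(replicate = integer(0), day = numeric(0),
                      mutant_count = numeric(0), total_count = numeric(0))
  }
  rownames(out) <- NULL
  attr(out, "truth") <- c(unclass(spec),
                          list(r = survival_ratio(spec$a_mut, spec$a_wt),
                               engraft_frac = engraft_frac))
  out
}
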