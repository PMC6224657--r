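# Variant-level utilities: VAF retention filtering, clonal classification,
# summary statistics, cancer-cell-fraction conversion, and HGVS-p style
# protein-change parsing into consequence classes.

#' Filter variants by a minimum VAF (inclusive)
#'
#' The standard retention filter for deep-sequencing variant tables: keeps
#' records with `vaf >= min_vaf` (the default 0.02 matches the usual
#' detection floor of targeted panels). Order is preserved; the number of
#' removed records is attached as attribute `n_removed`.
#'
#' @param records Data frame with a numeric `vaf` column.
#' @param min_vaf Inclusive lower bound, in `[0, 1]` (default 0.02).
#' @return Filtered data frame with attribute `n_removed`.
#' @examples
#' v <- data.frame(vaf = c(0.01, 0.02, 0.05))
#' filter_vaf(v)  # keeps 0.02 and 0.05
#' @export
filter_vaf <- function(records, min_vaf = 0.02) {
  if (min_vaf < 0 || min_vaf > 1) {
    stop("min_vaf must be in [0, 1]", call. = FALSE)
  }
  keep <- records$vaf >= min_vaf
  out <- records[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Classify a variant as clonal or subclonal by VAF
#'
#' Clonal iff `vaf > threshold`, strictly: a variant exactly at the threshold
#' is subclonal. The default threshold 0.2 corresponds (for a heterozygous
#' diploid mutation) to roughly 40% of cells carrying the variant.
#'
#' @param vaf Numeric VAF(s) in `[0, 1]`.
#' @param threshold Strict lower bound for clonality, in `(0, 1)`.
#' @return Character vector, `"clonal"` or `"subclonal"`.
#' @examples
#' classify_clonal(c(0.21, 0.20, 0.05))
#' @export
classify_clonal <- function(vaf, threshold = 0.2) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must be in (0, 1)", call. = FALSE)
  }
  ifelse(vaf > threshold, "clonal", "subclonal")
}

#' Summary statistics of a set of VAFs
#'
#' @param records Data frame with a `vaf` column, or a numeric vector.
#' @return Data frame with `n`, `mean`, `median` (midpoint convention for
#'   even n), `min`, `max`.
#' @examples
#' vaf_summary(c(0.02, 0.05, 0.47))
#' @export
vaf_summary <- function(records) {
  v <- if (is.data.frame(records)) records$vaf else records
  if (length(v) == 0) stop("no VAFs to summarise", call. = FALSE)
  data.frame(n = length(v), mean = mean(v), median = stats::median(v),
             min = min(v), max = max(v))
}

#' Cancer cell fraction from VAF, purity and copy number
#'
#' The standard purity/copy-number adjustment for a point mutation:
#' `CCF = vaf * (purity * cn_tumor + (1 - purity) * cn_normal) /
#' (purity * multiplicity)`, clamped to `[0, 1]`. With the defaults (pure
#' diploid heterozygous) this reduces to `2 * vaf`. Values whose raw CCF
#' exceeds 1.05 before clamping are flagged in the `flagged` attribute.
#'
#' @param vaf Variant allele fraction(s), in `[0, 1]`.
#' @param purity Tumor purity, in `(0, 1]` (default 1).
#' @param cn_tumor Total tumor copy number at the locus, `>= 1` (default 2).
#' @param cn_normal Normal copy number (default 2).
#' @param multiplicity Mutated copies per tumor cell, `>= 1` (default 1,
#'   the heterozygous case).
#' @return Numeric CCF(s) in `[0, 1]` with logical attribute `flagged`.
#' @examples
#' compute_ccf(0.25)            # 0.5
#' compute_ccf(0.40, purity = 0.8)  # exactly 1
#' @export
compute_ccf <- function(vaf, purity = 1, cn_tumor = 2, cn_normal = 2,
                        multiplicity = 1) {
  if (any(purity <= 0 | purity > 1)) {
    stop("purity must be in (0, 1]", call. = FALSE)
  }
  if (any(cn_tumor < 1) || any(multiplicity < 1)) {
    stop("cn_tumor and multiplicity must be >= 1", call. = FALSE)
  }
  if (any(vaf < 0 | vaf > 1)) stop("vaf must be in [0, 1]", call. = FALSE)
  raw <- vaf * (purity * cn_tumor + (1 - purity) * cn_normal) /
    (purity * multiplicity)
  out <- pmin(pmax(raw, 0), 1)
  attr(out, "flagged") <- raw > 1.05
  out
}

#' Parse an HGVS-p style protein change into a consequence class
#'
#' Accepts both `"p."`-prefixed and bare forms, and both `"X"` and `"*"`
#' stop notations. A terminal stop after a residue is `nonsense`; an `fs`
#' suffix is `frameshift`; a single-letter substitution is `missense`;
#' anything else (including nucleotide-level notation) is `unparsed`.
#' `truncating` is `TRUE` for nonsense and frameshift. When a residue-range
#' map is supplied the affected exon is reported.
#'
#' @param protein_change Character vector of protein changes (non-empty
#'   strings), e.g. `"R458X"`, `"p.L450fs"`, `"D314A"`.
#' @param exon_map Optional data frame with columns `exon`, `start`, `end`
#'   (residue ranges); see [ppm1d_exon_map()].
#' @return Data frame with `protein_change`, `consequence` (one of
#'   `nonsense`, `frameshift`, `missense`, `unparsed`), `residue`, `exon`,
#'   and `truncating`.
#' @examples
#' classify_consequence(c("R458X", "D314A", "p.L450fs", "c.100del"))
#' @export
classify_consequence <- function(protein_change, exon_map = NULL) {
  if (any(!nzchar(protein_change))) {
    stop("protein_change must be non-empty", call. = FALSE)
  }
  core <- sub("^p\\.", "", protein_change)
  res_num <- function(x) as.integer(sub("^[A-Z](\\d+).*$", "\\1", x))
  is_nonsense <- grepl("^[A-Z]\\d+(X|\\*|Ter)$", core)
  is_fs <- grepl("^[A-Z]\\d+[A-Za-z]*fs(\\*?\\d*|Ter\\d*)?$", core)
  is_mis <- grepl("^[A-Z]\\d+[A-WYZ]$", core) & !is_nonsense
  consequence <- rep("unparsed", length(core))
  consequence[is_mis] <- "missense"
  consequence[is_fs] <- "frameshift"
  consequence[is_nonsense] <- "nonsense"
  residue <- rep(NA_integer_, length(core))
  parsed <- consequence != "unparsed"
  residue[parsed] <- suppressWarnings(res_num(core[parsed]))
  exon <- rep(NA_integer_, length(core))
  if (!is.null(exon_map)) {
    for (i in which(!is.na(residue))) {
      hit <- which(exon_map$start <= residue[i] & exon_map$end >= residue[i])
      if (length(hit)) exon[i] <- exon_map$exon[hit[1]]
    }
  }
  data.frame(protein_change = protein_change, consequence = consequence,
             residue = residue, exon = exon,
             truncating = consequence %in% c("nonsense", "frameshift"))
}

#' Provisional residue-range map of PPM1D coding exons
#'
#' Approximate amino-acid boundaries of the six PPM1D coding exons, for
#' assigning truncating variants to exons. The boundaries are approximate
#' (derived from the protein's 605-residue length and published exon
#' structure, not from a transcript annotation) and should be replaced with
#' an authoritative map for production annotation work.
#'
#' @return Data frame with columns `exon`, `start`, `end`.
#' @export
ppm1d_exon_map <- function() {
  data.frame(exon = 1:6,
             start = c(1, 127, 227, 275, 329, 387),
             end = c(126, 226, 274, 328, 386, 605))
}

#' Lineage concordance of a variant across sorted blood fractions
#'
#' Compares the VAF of a variant in lymphoid versus non-lymphoid sorted
#' fractions against a detection threshold. Detection in both compartments
#' (multilineage) is consistent with an origin in a stem or early progenitor
#' cell.
#'
#' @param vaf_lymphoid,vaf_nonlymphoid VAF in each sorted fraction.
#' @param lod Detection threshold (default 0.02, mirroring the retention
#'   filter).
#' @return Character vector: `"multilineage"`, `"lineage_restricted"`, or
#'   `"undetected"`.
#' @examples
#' lineage_concordance(0.10, 0.12)
#' @export
lineage_concordance <- function(vaf_lymphoid, vaf_nonlymphoid, lod = 0.02) {
  if (any(lod <= 0)) stop("lod must be > 0", call. = FALSE)
  if (any(vaf_lymphoid < 0 | vaf_lymphoid > 1) ||
      any(vaf_nonlymphoid < 0 | vaf_nonlymphoid > 1)) {
    stop("VAFs must be in [0, 1]", call. = FALSE)
  }
  n_det <- (vaf_lymphoid >= lod) + (vaf_nonlymphoid >= lod)
  c("undetected", "lineage_restricted", "multilineage")[n_det + 1]
}
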