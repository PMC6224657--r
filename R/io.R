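# Tabular I/O with schema validation. One tabular dialect throughout: TSV
# with a header line, no quoting; JSON for machine-readable results and
# provenance; YAML (or JSON) for run configuration.

ch_schemas <- list(
  cohort = list(required = c("sample_id", "group"),
                numeric = character(0)),
  variants = list(required = c("sample_id", "gene", "protein_change",
                               "consequence", "vaf"),
                  numeric = "vaf"),
  trajectory = list(required = c("replicate", "day", "mutant_count",
                                 "total_count"),
                    numeric = c("replicate", "day", "mutant_count",
                                "total_count"))
)

#' Read a tab-delimited table and validate it against a named schema
#'
#' @param path Path to a TSV file with a header line.
#' @param schema One of `"cohort"`, `"variants"`, `"trajectory"`.
#' @param verbose Log the row count to stderr.
#' @return The validated data frame.
#' @export
read_ch_table <- function(path, schema = c("cohort", "variants",
                                           "trajectory"),
                          verbose = FALSE) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         check.names = FALSE)
  sc <- ch_schemas[[schema]]
  missing_cols <- setdiff(sc$required, names(x))
  if (length(missing_cols)) {
    stop("schema '", schema, "': missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in sc$numeric) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    bad <- which(is.na(v) & !is.na(x[[col]]))
    if (length(bad)) {
      stop("schema '", schema, "': column '", col,
           "' not numeric at row ", bad[1], call. = FALSE)
    }
    x[[col]] <- v
  }
  if (verbose) message("read ", nrow(x), " rows from ", path)
  x
}

#' Write a table as TSV with header
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ch_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run a configured analysis pipeline stage-by-stage
#'
#' Executes the configured stages in order and writes every output with a
#' provenance JSON sidecar (input checksums, seed, parameters, package
#' version). Deterministic stages produce byte-identical outputs, hence
#' identical checksums, on rerun with the same config. On a stage failure,
#' files already written to the output directory are quarantined under
#' `failed/` and the error is re-raised.
#'
#' Available stages:
#' \describe{
#'   \item{synth}{Generate a synthetic cohort, variant table, and
#'     competition trajectories (writes `cohort.tsv`, `variants.tsv`,
#'     `trajectories.tsv`).}
#'   \item{enrich}{Exposure-association scan of `cohort.tsv` against an
#'     outcome gene (writes `enrichment.tsv`, `enrichment.json`).}
#'   \item{fit}{Fit the per-dose survival ratio to `trajectories.tsv`
#'     (writes `fitness.json`).}
#' }
#'
#' @param config A list, or path to a YAML/JSON file, with fields `stages`
#'   (character vector), `out_dir`, `seed`, and optional per-stage parameter
#'   blocks `synth`, `enrich`, `fit`.
#' @param verbose Log progress to stderr.
#' @return Manifest data frame (`stage`, `file`, `md5`), invisibly also
#'   written to `manifest.json`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stages <- config$stages
  valid <- c("synth", "enrich", "fit")
  bad <- setdiff(stages, valid)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         "; valid stages are: ", paste(valid, collapse = ", "),
         call. = FALSE)
  }
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config must set out_dir", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  manifest <- data.frame(stage = character(0), file = character(0),
                         md5 = character(0))
  record <- function(stage, files, params, inputs = character(0)) {
    input_md5 <- tools::md5sum(inputs)
    names(input_md5) <- basename(inputs)  # keep provenance path-independent
    prov <- list(stage = stage, seed = seed, params = params,
                 package_version = as.character(utils::packageVersion("clonesel")),
                 inputs = as.list(input_md5))
    prov_path <- file.path(out_dir, paste0(stage, ".provenance.json"))
    jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, pretty = TRUE)
    files <- c(files, prov_path)
    rbind(manifest, data.frame(stage = stage, file = files,
                               md5 = unname(tools::md5sum(files))))
  }

  run_one <- function(stage) {
    if (verbose) message("running stage: ", stage)
    if (stage == "synth") {
      p <- config$synth
      cs <- do.call(cohort_spec, c(p$cohort, list(seed = seed)))
      gc <- generate_cohort(cs)
      ks <- do.call(competition_spec, c(p$competition, list(seed = seed)))
      tr <- generate_competition(ks)
      f1 <- file.path(out_dir, "cohort.tsv")
      f2 <- file.path(out_dir, "variants.tsv")
      f3 <- file.path(out_dir, "trajectories.tsv")
      write_ch_table(gc$cohort, f1)
      write_ch_table(gc$variants, f2)
      write_ch_table(tr, f3)
      manifest <<- record(stage, c(f1, f2, f3),
                          list(cohort = p$cohort, competition = p$competition))
    } else if (stage == "enrich") {
      p <- config$enrich
      cohort_path <- if (!is.null(p$cohort)) p$cohort else
        file.path(out_dir, "cohort.tsv")
      co <- read_ch_table(cohort_path, "cohort")
      sub <- co[co$group == "case", , drop = FALSE]
      res <- exposure_enrichment(sub, p$outcome_gene, unlist(p$exposures),
                                 fdr_method = if (is.null(p$fdr_method))
                                   "BH" else p$fdr_method)
      f1 <- file.path(out_dir, "enrichment.tsv")
      f2 <- file.path(out_dir, "enrichment.json")
      write_ch_table(res, f1)
      jsonlite::write_json(res, f2, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
      manifest <<- record(stage, c(f1, f2), p, inputs = cohort_path)
    } else if (stage == "fit") {
      p <- config$fit
      traj_path <- if (!is.null(p$trajectory)) p$trajectory else
        file.path(out_dir, "trajectories.tsv")
      tr <- read_ch_table(traj_path, "trajectory")
      fit <- fit_fitness(tr, dose_days = unlist(p$dose_days),
                         model = if (is.null(p$model)) "normalized" else
                           p$model)
      f1 <- file.path(out_dir, "fitness.json")
      jsonlite::write_json(unclass(fit), f1, auto_unbox = TRUE,
                           pretty = TRUE, digits = NA)
      manifest <<- record(stage, f1, p, inputs = traj_path)
    }
  }

  tryCatch(
    for (stage in stages) run_one(stage),
    error = function(e) {
      qdir <- file.path(out_dir, "failed")
      dir.create(qdir, showWarnings = FALSE)
      partial <- setdiff(list.files(out_dir, full.names = TRUE), qdir)
      partial <- partial[!dir.exists(partial)]
      file.rename(partial, file.path(qdir, basename(partial)))
      stop("pipeline stage failed (partial outputs moved to failed/): ",
           conditionMessage(e), call. = FALSE)
    }
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}
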