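#' Read a pipeline run configuration
#'
#' A single YAML (or JSON) file drives the file-based pipeline. Recognized
#' fields: `cohorts` (list of `{expression: path, clinical: path}`), `gmt`
#' (signature file path), `out` (output directory), `seed`, and the tuning
#' block `parameters` (`alpha_cells`, `alpha_pairs`, `ssgsea_alpha`,
#' `normalize`, `minprop`, `ties`, `min_coverage`, `horizons`,
#' `eval_cohort`). Explicit function arguments override file values.
#'
#' @param path Path to a YAML/JSON config file, or a list already in that
#'   shape.
#' @param overrides Named list overriding top-level fields.
#' @return A validated config list.
#' @export
readRunConfig <- function(path, overrides = list()) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  cfg <- utils::modifyList(cfg, overrides)
  defaults <- list(alpha_cells = 0.05, alpha_pairs = 0.05, ssgsea_alpha = 0.25,
                   normalize = TRUE, minprop = 0.1, ties = "efron",
                   min_coverage = 0.5, horizons = NULL, eval_cohort = NULL)
  cfg$parameters <- utils::modifyList(defaults, cfg$parameters %||% list())
  p <- cfg$parameters
  stopifnot(p$alpha_cells > 0, p$alpha_cells < 1,
            p$alpha_pairs > 0, p$alpha_pairs < 1,
            p$ssgsea_alpha >= 0, p$minprop > 0, p$minprop < 0.5,
            p$ties %in% c("efron", "breslow"))
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg
}

# polynomial rolling hash over the canonical JSON rendering; all arithmetic
# stays within exact double-precision integers, so it is platform-stable
config_hash <- function(x) {
  bytes <- utf8ToInt(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

provenance_block <- function(cfg) {
  list(package = "icpScore",
       version = as.character(utils::packageVersion("icpScore")),
       config_hash = config_hash(cfg),
       seed = cfg$seed)
}

prepare_out <- function(out, files, force) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  existing <- files[file.exists(file.path(out, files))]
  if (length(existing) && !force) {
    stop("output file(s) already exist (use force = TRUE to overwrite): ",
         paste(existing, collapse = ", "))
  }
  invisible(out)
}

#' Write a simulated study to disk
#'
#' Runs [simulateStudy()] and writes, per cohort, `cohortK_expression.tsv`
#' and `cohortK_clinical.tsv`, plus the shared `signatures.gmt`,
#' `truth.json` (true effects, censoring windows) and a `provenance.json`
#' block (package version, config hash, seed). Reruns with an identical
#' config produce byte-identical files.
#'
#' @param config A [simulationConfig()] or a list of arguments for one.
#' @param out Output directory.
#' @param force Overwrite existing outputs. Default `FALSE`.
#' @return Invisibly, the named character vector of written paths.
#' @export
runSimulate <- function(config, out, force = FALSE) {
  if (!inherits(config, "simulationConfig")) {
    config <- do.call(simulationConfig, config)
  }
  study <- simulateStudy(config)
  files <- c(sprintf("cohort%d_expression.tsv", seq_along(study)),
             sprintf("cohort%d_clinical.tsv", seq_along(study)),
             "signatures.gmt", "truth.json", "provenance.json")
  prepare_out(out, files, force)
  paths <- character()
  for (k in seq_along(study)) {
    co <- study[[k]]
    pe <- file.path(out, sprintf("cohort%d_expression.tsv", k))
    pc <- file.path(out, sprintf("cohort%d_clinical.tsv", k))
    writeMatrixTSV(co$expression, pe, id_name = "gene")
    utils::write.table(co$clinical, pc, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, pe, pc)
  }
  pg <- file.path(out, "signatures.gmt")
  writeGMT(study[[1]]$signatures, pg)
  truth <- list(beta = as.list(study[[1]]$truth$beta),
                prognostic_cells = cell_names(config)[config$prognostic_cells],
                censor_window = vapply(study, function(co)
                  co$truth$censor_window, numeric(1)),
                expected_censoring = vapply(study, function(co)
                  co$truth$expected_censoring, numeric(1)))
  pt <- file.path(out, "truth.json")
  jsonlite::write_json(truth, pt, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pp <- file.path(out, "provenance.json")
  jsonlite::write_json(provenance_block(list(config = unclass(config))),
                       pp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, pg, pt, pp))
}

# load cohorts named in a run config and score enrichment per cohort
load_and_enrich <- function(cfg) {
  stopifnot(length(cfg$cohorts) >= 1L)
  collection <- readGMT(cfg$gmt)
  p <- cfg$parameters
  lapply(cfg$cohorts, function(co) {
    expr <- readMatrixTSV(co$expression)
    clin <- readClinical(co$clinical)
    filtered <- filterToUniverse(collection, rownames(expr),
                                 min_coverage = p$min_coverage)
    list(enrichment = ssgsea(expr, filtered, alpha = p$ssgsea_alpha,
                             normalize = p$normalize),
         clinical = clin)
  })
}

#' Fit an ICP model from files
#'
#' Reads the configured cohorts and signature GMT, scores ssGSEA enrichment
#' per cohort (each cohort independently), fits the pair model with
#' [fitICP()], and writes `model.json` plus `fit_report.json` with per-step
#' selection counts and a provenance block.
#'
#' @param config Path to a YAML/JSON run config, or an equivalent list (see
#'   [readRunConfig()]).
#' @param out Output directory; defaults to the config's `out` field.
#' @param force Overwrite existing outputs.
#' @return Invisibly, the fitted [ICPModel].
#' @export
runFit <- function(config, out = NULL, force = FALSE) {
  cfg <- readRunConfig(config)
  out <- out %||% cfg$out
  if (is.null(out)) stop("no output directory configured")
  prepare_out(out, c("model.json", "fit_report.json"), force)
  cohorts <- load_and_enrich(cfg)
  p <- cfg$parameters
  model <- fitICP(cohorts, alpha_cells = p$alpha_cells,
                  alpha_pairs = p$alpha_pairs,
                  eval_cohort = p$eval_cohort, minprop = p$minprop,
                  ties = p$ties)
  writeICPModel(model, file.path(out, "model.json"))
  report <- list(provenance = provenance_block(cfg),
                 n_cohorts = length(cohorts),
                 cohort_sizes = vapply(cohorts, function(co)
                   ncol(co$enrichment), numeric(1)),
                 cells_tested = nrow(cohorts[[1]]$enrichment),
                 anchors = model@provenance$anchors,
                 selection_counts = model@provenance$selection_counts,
                 n_selected_pairs = nrow(selectedPairs(model)))
  jsonlite::write_json(report, file.path(out, "fit_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(model)
}

#' Score and validate cohorts against a fitted model from files
#'
#' For each configured cohort: ssGSEA enrichment, ICP scores, per-dataset
#' cutpoint and high/low groups, and the [validateICP()] report. Writes
#' `cohortK_samples.tsv` (sample, icp_score, group) and
#' `cohortK_report.json` per cohort. `runScore()` is the same operation
#' without horizon AUCs.
#'
#' @param config Path to a YAML/JSON run config, or an equivalent list.
#' @param model An [ICPModel] or a path to a `model.json`.
#' @param out Output directory; defaults to the config's `out` field.
#' @param force Overwrite existing outputs.
#' @return Invisibly, the list of per-cohort validation reports.
#' @export
runValidate <- function(config, model, out = NULL, force = FALSE) {
  cfg <- readRunConfig(config)
  out <- out %||% cfg$out
  if (is.null(out)) stop("no output directory configured")
  if (is.character(model)) model <- readICPModel(model)
  files <- c(sprintf("cohort%d_samples.tsv", seq_along(cfg$cohorts)),
             sprintf("cohort%d_report.json", seq_along(cfg$cohorts)))
  prepare_out(out, files, force)
  cohorts <- load_and_enrich(cfg)
  p <- cfg$parameters
  reports <- vector("list", length(cohorts))
  for (k in seq_along(cohorts)) {
    rep_k <- validateICP(model, cohorts[[k]]$enrichment,
                         cohorts[[k]]$clinical,
                         horizons = p$horizons, minprop = p$minprop)
    utils::write.table(rep_k$samples,
                       file.path(out, sprintf("cohort%d_samples.tsv", k)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    json_rep <- list(provenance = provenance_block(cfg),
                     cohort = k,
                     n = nrow(rep_k$samples),
                     cutoff = rep_k$cutoff,
                     logrank = rep_k$logrank[c("chi2", "p", "z")],
                     cox_high_vs_low = rep_k$cox_high_vs_low,
                     c_index = rep_k$c_index,
                     auc_horizons = as.list(rep_k$auc_horizons),
                     annotations = rep_k$annotations)
    jsonlite::write_json(json_rep,
                         file.path(out, sprintf("cohort%d_report.json", k)),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    reports[[k]] <- rep_k
  }
  invisible(reports)
}

#' @rdname runValidate
#' @export
runScore <- function(config, model, out = NULL, force = FALSE) {
  cfg <- readRunConfig(config)
  cfg$parameters$horizons <- NULL
  runValidate(cfg, model, out = out, force = force)
}
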