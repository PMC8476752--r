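#' Select prognosis-associated cell types across discovery cohorts
#'
#' For every cohort, fits a univariate Cox model of each cell type's
#' enrichment score against overall survival; a cell type is retained only if
#' its Wald p-value is below `alpha` in EVERY cohort (the "overlap" rule that
#' stabilizes anchor choice across platforms). Covariates are standardized
#' per cohort before fitting, which leaves Wald p-values unchanged but keeps
#' the Newton iterations well-conditioned.
#'
#' @param cohorts List of cohorts, each a list with `enrichment` (cell types
#'   by samples matrix, shared rownames across cohorts) and `clinical` (a
#'   [clinicalTable()] data.frame whose `sample` column matches the
#'   enrichment colnames).
#' @param alpha Per-cohort significance level. Default 0.05.
#' @param ties Tie correction for [coxFit()].
#' @return Character vector of retained cell types, in catalogue (row) order.
#' @export
selectPrognosticCells <- function(cohorts, alpha = 0.05, ties = "efron") {
  stopifnot(is.list(cohorts), length(cohorts) >= 1L)
  cells <- rownames(cohorts[[1]]$enrichment)
  pmat <- vapply(cohorts, function(co) {
    enr <- co$enrichment
    if (!identical(rownames(enr), cells)) {
      stop("cohorts must share an identical cell-type universe (row order included)")
    }
    cl <- clinicalTable(co$clinical)
    enr <- alignEnrichment(enr, cl)
    vapply(cells, function(ct) {
      v <- enr[ct, ]
      if (max(v) == min(v)) return(1)
      coxFit(as.numeric(scale(v)), cl$time, cl$event, ties = ties)$wald_p
    }, numeric(1))
  }, numeric(length(cells)))
  pmat <- matrix(pmat, nrow = length(cells),
                 dimnames = list(cells, NULL))
  keep <- cells[apply(pmat < alpha, 1L, all)]
  if (length(keep) == 0L) {
    stop("no cell type is prognostic in every cohort; ",
         "consider a more permissive alpha or fewer discovery cohorts")
  }
  keep
}

# reorder enrichment columns to the clinical table's samples
alignEnrichment <- function(enr, clinical) {
  missing <- setdiff(clinical$sample, colnames(enr))
  if (length(missing)) {
    stop("samples in clinical table missing from enrichment: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  enr[, clinical$sample, drop = FALSE]
}

#' Binary cell-pair indicator matrix
#'
#' For every ordered pair (Ci, Cj) with anchor `Ci` and partner `Cj != Ci`,
#' the indicator for a sample is 1 when Ci's enrichment strictly exceeds
#' Cj's, else 0 (ties score 0, so the two orientations never both score 1).
#' Because the comparison is entirely within-sample, the indicator is
#' invariant to any per-sample monotone transform of expression and to any
#' cohort-wide rescaling of enrichment scores — the property that lets a
#' fitted pair list transfer across platforms.
#'
#' @param enr Cell-types-by-samples enrichment matrix.
#' @param anchors Character vector of anchor cell types Ci.
#' @param partners Character vector of partner cell types Cj; defaults to
#'   all rows of `enr`.
#' @return Binary matrix, one row per ordered pair (rownames `"Ci|Cj"`), with
#'   attributes `pair_ci` and `pair_cj`.
#' @export
pairIndicatorMatrix <- function(enr, anchors, partners = rownames(enr)) {
  unknown <- setdiff(c(anchors, partners), rownames(enr))
  if (length(unknown)) {
    stop("unknown cell type(s): ", paste(unknown, collapse = ", "))
  }
  if (length(anchors) == 0L) stop("no anchor cell types supplied")
  ci <- rep(anchors, each = length(partners))
  cj <- rep(partners, times = length(anchors))
  keep <- ci != cj
  ci <- ci[keep]; cj <- cj[keep]
  ind <- (enr[ci, , drop = FALSE] > enr[cj, , drop = FALSE]) * 1L
  rownames(ind) <- paste(ci, cj, sep = "|")
  attr(ind, "pair_ci") <- ci
  attr(ind, "pair_cj") <- cj
  ind
}

#' Evaluate cell-pair indicators against survival
#'
#' For each pair indicator row: Harrell's C of the indicator as a risk score,
#' and a univariate Cox fit giving the hazard ratio and Wald p-value. Rows
#' whose indicator is constant across samples carry no information and are
#' excluded (reported in the `dropped` attribute).
#'
#' @param psm Pair indicator matrix from [pairIndicatorMatrix()].
#' @param clinical A [clinicalTable()] data.frame covering the matrix's
#'   samples.
#' @param ties Tie correction for [coxFit()].
#' @return data.frame with columns `ci`, `cj`, `c_index`, `hr`, `p`, `beta`,
#'   `se`, one row per informative pair; attribute `dropped` lists excluded
#'   degenerate pairs.
#' @export
evaluatePairs <- function(psm, clinical, ties = "efron") {
  clinical <- clinicalTable(clinical)
  ci <- attr(psm, "pair_ci")
  cj <- attr(psm, "pair_cj")
  psm <- psm[, clinical$sample, drop = FALSE]
  if (is.null(ci) || is.null(cj)) {
    parts <- strsplit(rownames(psm), "|", fixed = TRUE)
    ci <- vapply(parts, `[`, character(1), 1L)
    cj <- vapply(parts, `[`, character(1), 2L)
  }
  if (sum(clinical$event) == 0L) stop("no events in the evaluation cohort")
  const <- apply(psm, 1L, function(v) max(v) == min(v))
  dropped <- rownames(psm)[const]
  if (all(const)) stop("every pair indicator is constant; nothing to evaluate")
  if (any(const)) {
    message(sprintf("evaluatePairs: excluding %d constant indicator(s): %s",
                    length(dropped),
                    paste(utils::head(dropped, 5L), collapse = ", ")))
  }
  idx <- which(!const)
  comp <- concordance_mask(clinical$time, clinical$event)
  rows <- lapply(idx, function(k) {
    v <- as.numeric(psm[k, ])
    fit <- coxFit(v, clinical$time, clinical$event, ties = ties)
    data.frame(ci = ci[k], cj = cj[k],
               c_index = concordance_with_mask(v, comp),
               hr = fit$hr, p = fit$wald_p, beta = fit$beta, se = fit$se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Select the final cell-pair signature
#'
#' Reduces evaluated pairs to the transferable model in four deterministic
#' steps: (1) keep pairs with Wald `p < alpha`; (2) per anchor Ci keep the
#' single pair with the highest C-index (ties: larger HR, then
#' lexicographic partner); (3) drop pairs with `HR <= 1` (only hazardous
#' indicators enter the score); (4) remove duplicates under unordered-pair
#' identity, keeping the first by anchor catalogue order. The result is
#' ordered by anchor catalogue order.
#'
#' @param stats Pair statistics from [evaluatePairs()].
#' @param alpha Significance level for step 1. Default 0.05.
#' @param cellOrder Character vector fixing the anchor catalogue order
#'   (typically the signature collection's cell types). Defaults to
#'   first-appearance order in `stats`.
#' @param parameters,provenance Optional lists stored on the model.
#' @return An [ICPModel].
#' @export
selectPairs <- function(stats, alpha = 0.05, cellOrder = unique(stats$ci),
                        parameters = list(), provenance = list()) {
  if (nrow(stats) == 0L) stop("no pair statistics supplied")
  counts <- list(evaluated = nrow(stats))
  s1 <- stats[stats$p < alpha, , drop = FALSE]
  counts$after_p_filter <- nrow(s1)
  if (nrow(s1) == 0L) {
    stop(selectionFailureMessage(counts))
  }
  anchors <- intersect(cellOrder, s1$ci)
  s2 <- do.call(rbind, lapply(anchors, function(a) {
    sa <- s1[s1$ci == a, , drop = FALSE]
    sa <- sa[order(-sa$c_index, -sa$hr, sa$cj), , drop = FALSE]
    sa[1L, , drop = FALSE]
  }))
  counts$after_best_per_anchor <- nrow(s2)
  s3 <- s2[s2$hr > 1, , drop = FALSE]
  counts$after_hr_filter <- nrow(s3)
  if (nrow(s3) == 0L) {
    stop(selectionFailureMessage(counts))
  }
  key <- paste(pmin(s3$ci, s3$cj), pmax(s3$ci, s3$cj), sep = "\r")
  s4 <- s3[!duplicated(key), , drop = FALSE]
  counts$after_dedup <- nrow(s4)
  rownames(s4) <- NULL
  attr(s4, "dropped") <- NULL
  parameters <- utils::modifyList(
    list(alpha_pairs = alpha, schema_version = "1.0"), parameters)
  provenance <- utils::modifyList(provenance, list(selection_counts = counts))
  new("ICPModel", pairs = s4,
      cellTypes = unique(c(cellOrder, s4$ci, s4$cj)),
      parameters = parameters, provenance = provenance)
}

selectionFailureMessage <- function(counts) {
  paste0("no cell pair survived selection (",
         paste(sprintf("%s=%d", names(counts), unlist(counts)), collapse = ", "),
         ")")
}

#' ICP score: sum of selected pair indicators
#'
#' Recomputes every selected pair's within-sample indicator from the target
#' cohort's own enrichment matrix and sums them, giving each sample an
#' integer score in `[0, number of pairs]`. Nothing but the pair list is
#' transferred from discovery.
#'
#' @param model An [ICPModel].
#' @param enr Cell-types-by-samples enrichment matrix containing every cell
#'   type named in the model.
#' @return Named integer vector of per-sample ICP scores.
#' @export
scoreSamples <- function(model, enr) {
  stopifnot(is(model, "ICPModel"))
  p <- selectedPairs(model)
  if (nrow(p) == 0L) {
    return(stats::setNames(integer(ncol(enr)), colnames(enr)))
  }
  absent <- setdiff(unique(c(p$ci, p$cj)), rownames(enr))
  if (length(absent)) {
    stop("cell type(s) in the model absent from the enrichment matrix: ",
         paste(absent, collapse = ", "))
  }
  ind <- (enr[p$ci, , drop = FALSE] > enr[p$cj, , drop = FALSE]) * 1L
  stats::setNames(as.integer(colSums(ind)), colnames(enr))
}

#' Dichotomize ICP scores at a maximally selected cutpoint
#'
#' Finds the score cutoff maximizing the standardized log-rank statistic
#' (see [maxSelCutpoint()]) and labels samples `"high"` (score > cutoff) or
#' `"low"`. The cutoff is always re-derived in the cohort being scored; a
#' discovery cutoff is never imported.
#'
#' @param scores Named per-sample scores (from [scoreSamples()]).
#' @param clinical A [clinicalTable()] data.frame for the same samples.
#' @param minprop Minimum group fraction, passed to [maxSelCutpoint()].
#' @return An [ICPResult].
#' @export
dichotomize <- function(scores, clinical, minprop = 0.1) {
  clinical <- clinicalTable(clinical)
  scores <- scores[clinical$sample]
  if (anyNA(scores)) stop("clinical samples missing from scores")
  cp <- maxSelCutpoint(as.numeric(scores), clinical$time, clinical$event,
                       minprop = minprop)
  grp <- ifelse(scores > cp$cutoff, "high", "low")
  new("ICPResult", scores = as.integer(scores), cutoff = cp$cutoff,
      group = stats::setNames(grp, names(scores)),
      cutpoint = list(max_stat = cp$max_stat, candidates = cp$candidates))
}

#' Fit an ICP model on discovery cohorts
#'
#' End-to-end discovery: anchor cell types significant in every cohort
#' ([selectPrognosticCells()]), pair indicators against all catalogue cell
#' types ([pairIndicatorMatrix()]), pair evaluation by C-index and Cox
#' ([evaluatePairs()]) on either the pooled discovery samples (default) or a
#' designated cohort, and the four-step pair selection ([selectPairs()]).
#'
#' @param discovery List of cohorts as in [selectPrognosticCells()].
#' @param alpha_cells Per-cohort significance level for anchor selection.
#' @param alpha_pairs Significance level for pair selection.
#' @param eval_cohort `NULL` to evaluate pairs on the pooled discovery
#'   samples (indicators are within-sample, so pooling needs no
#'   normalization), or the index of a single discovery cohort.
#' @param minprop Stored on the model for downstream dichotomization.
#' @param ties Cox tie correction used throughout.
#' @return An [ICPModel] with step-labelled provenance.
#' @examples
#' cfg <- simulationConfig(n_cohorts = 2, n_samples = 120, n_cells = 6,
#'                         genes_per_signature = 10, n_noise_genes = 40,
#'                         seed = 42)
#' study <- simulateStudy(cfg)
#' cohorts <- lapply(study, function(co)
#'   list(enrichment = ssgsea(co$expression, co$signatures),
#'        clinical = co$clinical))
#' model <- fitICP(cohorts)
#' selectedPairs(model)
#' @export
fitICP <- function(discovery, alpha_cells = 0.05, alpha_pairs = 0.05,
                   eval_cohort = NULL, minprop = 0.1, ties = "efron") {
  stopifnot(is.list(discovery), length(discovery) >= 1L)
  cellOrder <- rownames(discovery[[1]]$enrichment)
  anchors <- withCallingHandlers(
    selectPrognosticCells(discovery, alpha = alpha_cells, ties = ties),
    error = function(e) stop("anchor selection: ", conditionMessage(e), call. = FALSE)
  )
  use <- if (is.null(eval_cohort)) seq_along(discovery) else eval_cohort
  psm_list <- list(); clin_list <- list()
  for (k in use) {
    cl <- clinicalTable(discovery[[k]]$clinical)
    enr <- alignEnrichment(discovery[[k]]$enrichment, cl)
    psm <- pairIndicatorMatrix(enr, anchors, cellOrder)
    colnames(psm) <- paste0("c", k, ".", colnames(psm))
    cl$sample <- paste0("c", k, ".", cl$sample)
    psm_list[[length(psm_list) + 1L]] <- psm
    clin_list[[length(clin_list) + 1L]] <- cl[, c("sample", "time", "event")]
  }
  psm <- do.call(cbind, psm_list)
  attr(psm, "pair_ci") <- attr(psm_list[[1]], "pair_ci")
  attr(psm, "pair_cj") <- attr(psm_list[[1]], "pair_cj")
  clin <- do.call(rbind, clin_list)
  stats <- tryCatch(evaluatePairs(psm, clin, ties = ties),
                    error = function(e) stop("pair evaluation: ",
                                             conditionMessage(e), call. = FALSE))
  model <- tryCatch(
    selectPairs(stats, alpha = alpha_pairs, cellOrder = cellOrder,
                parameters = list(alpha_cells = alpha_cells,
                                  alpha_pairs = alpha_pairs,
                                  minprop = minprop, ties = ties,
                                  eval_cohort = if (is.null(eval_cohort)) "pooled"
                                                else eval_cohort),
                provenance = list(
                  n_cohorts = length(discovery),
                  cohort_sizes = vapply(discovery,
                                        function(co) ncol(co$enrichment),
                                        numeric(1)),
                  anchors = anchors,
                  n_pairs_dropped_degenerate = length(attr(stats, "dropped")))),
    error = function(e) stop("pair selection: ", conditionMessage(e), call. = FALSE))
  model@cellTypes <- cellOrder
  validObject(model)
  model
}

#' Validate an ICP model in a cohort
#'
#' Scores the cohort, re-derives the high/low cutpoint, and assembles a
#' machine-readable report: Kaplan-Meier curves per group, log-rank
#' chi-square and p, univariate Cox HR of high vs low, Harrell's C of the
#' integer score, time-dependent AUC at each horizon, plus optional
#' annotation statistics (ROC AUC against binary annotations, Pearson
#' correlation against numeric ones, rank tests against categorical ones).
#'
#' @param model An [ICPModel].
#' @param enr Cell-types-by-samples enrichment matrix of the target cohort.
#' @param clinical A [clinicalTable()] data.frame; extra columns are treated
#'   as annotations.
#' @param horizons Numeric vector of time horizons for [aucAtHorizon()]
#'   (cohort-local units); unreachable horizons are reported as `NA` with a
#'   message rather than failing the whole report.
#' @param minprop Passed to [dichotomize()].
#' @return A list of class `"icpValidation"`: `result` (an [ICPResult]),
#'   `samples` (per-sample data.frame), `logrank`, `cox_high_vs_low`,
#'   `c_index`, `auc_horizons`, `km`, `annotations`.
#' @export
validateICP <- function(model, enr, clinical, horizons = NULL, minprop = 0.1) {
  clinical <- clinicalTable(clinical)
  enr <- alignEnrichment(enr, clinical)
  scores <- scoreSamples(model, enr)
  res <- dichotomize(scores, clinical, minprop = minprop)
  grp <- icpGroups(res) == "high"
  lr <- logrankTest(grp, clinical$time, clinical$event)
  cox <- coxFit(as.numeric(grp), clinical$time, clinical$event,
                ties = model@parameters$ties %||% "efron")
  cidx <- harrellC(as.numeric(scores), clinical$time, clinical$event)
  aucs <- NULL
  if (!is.null(horizons)) {
    aucs <- vapply(horizons, function(h) {
      tryCatch(aucAtHorizon(as.numeric(scores), clinical$time, clinical$event, h),
               error = function(e) {
                 message("aucAtHorizon skipped: ", conditionMessage(e))
                 NA_real_
               })
    }, numeric(1))
    names(aucs) <- paste0("t", horizons)
  }
  km <- list(high = kmCurve(clinical$time[grp], clinical$event[grp]),
             low = kmCurve(clinical$time[!grp], clinical$event[!grp]))
  ann_cols <- setdiff(names(clinical), c("sample", "time", "event"))
  annotations <- list()
  for (a in ann_cols) {
    v <- clinical[[a]]
    if (is.numeric(v) && length(unique(v[!is.na(v)])) > 2L) {
      annotations[[a]] <- c(list(type = "numeric"),
                            correlate(as.numeric(scores), v))
    } else {
      vv <- as.factor(as.character(v))
      if (nlevels(vv) == 2L) {
        annotations[[a]] <- list(
          type = "binary",
          auc = rocAuc(as.numeric(scores), vv == levels(vv)[2L]),
          p = groupCompare(as.numeric(scores), vv, test = "wilcoxon"))
      } else if (nlevels(vv) > 2L) {
        annotations[[a]] <- list(
          type = "categorical",
          p = groupCompare(as.numeric(scores), vv, test = "kruskal"))
      }
    }
  }
  out <- list(
    result = res,
    samples = data.frame(sample = clinical$sample,
                         icp_score = as.integer(scores),
                         group = unname(icpGroups(res)),
                         stringsAsFactors = FALSE),
    cutoff = icpCutoff(res),
    logrank = lr,
    cox_high_vs_low = list(hr = cox$hr, p = cox$wald_p, beta = cox$beta,
                           se = cox$se, converged = cox$converged),
    c_index = cidx,
    auc_horizons = aucs,
    km = km,
    annotations = annotations)
  class(out) <- "icpValidation"
  out
}

#' @export
print.icpValidation <- function(x, ...) {
  cat(sprintf("ICP validation: n=%d, cutoff=%.3g\n",
              nrow(x$samples), x$cutoff))
  cat(sprintf("  log-rank chi2=%.2f p=%.3g; high-vs-low HR=%.2f; C=%.3f\n",
              x$logrank$chi2, x$logrank$p, x$cox_high_vs_low$hr, x$c_index))
  if (!is.null(x$auc_horizons)) {
    cat("  AUC at horizons:",
        paste(sprintf("%s=%.3f", names(x$auc_horizons), x$auc_horizons),
              collapse = ", "), "\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize an ICP model to JSON
#'
#' Writes `schema_version`, `parameters`, `cell_types`, `selected_pairs`
#' (records with `ci`, `cj`, `c_index`, `hr`, `p`, `beta`, `se`) and
#' `provenance`; [readICPModel()] restores the model exactly.
#'
#' @param model An [ICPModel].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
writeICPModel <- function(model, path) {
  stopifnot(is(model, "ICPModel"))
  validObject(model)
  obj <- list(schema_version = model@parameters$schema_version %||% "1.0",
              parameters = model@parameters,
              cell_types = model@cellTypes,
              selected_pairs = selectedPairs(model),
              provenance = model@provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an ICP model from JSON
#'
#' @param path Path to a model file written by [writeICPModel()].
#' @return An [ICPModel].
#' @export
readICPModel <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("schema_version", "parameters", "cell_types", "selected_pairs")
  miss <- setdiff(req, names(obj))
  if (length(miss)) {
    stop("invalid model JSON; missing field(s): ", paste(miss, collapse = ", "))
  }
  pairs <- as.data.frame(obj$selected_pairs, stringsAsFactors = FALSE)
  need <- c("ci", "cj", "c_index", "hr", "p")
  if (nrow(pairs) == 0L || !all(need %in% names(pairs))) {
    stop("invalid model JSON: selected_pairs must have columns ",
         paste(need, collapse = ", "))
  }
  new("ICPModel", pairs = pairs, cellTypes = as.character(obj$cell_types),
      parameters = as.list(obj$parameters),
      provenance = as.list(obj$provenance))
}
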