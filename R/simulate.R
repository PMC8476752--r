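#' Configuration for the synthetic multi-cohort generator
#'
#' The generator draws, for each cohort, latent per-sample immune-cell
#' abundances that (i) drive marker-gene expression through a log-linear
#' loading and (ii) drive proportional-hazards survival through standardized
#' log-abundances, with independent uniform-window censoring and per-cohort
#' gene-level batch shifts. Defaults define the package's reference recovery
#' design: three discovery cohorts plus one held-out validation cohort of 300
#' samples each, 20 cell types with disjoint 30-gene signatures, two truly
#' prognostic cell types at 1.0 log-hazard-ratio per SD of log-abundance,
#' expression noise SD 0.5 on the log scale, and ~30% censoring.
#'
#' @param n_cohorts Number of cohorts (the last is conventionally held out
#'   for validation). Default 4.
#' @param n_samples Samples per cohort. Default 300.
#' @param n_cells Number of cell types. Default 20.
#' @param genes_per_signature Marker genes per cell type (signatures are
#'   disjoint unless `signature_overlap > 0`). Default 30.
#' @param n_noise_genes Abundance-free background genes. Default 200.
#' @param prognostic_cells Indices (into the cell catalogue) of truly
#'   prognostic cell types. Default `c(1, 2)`.
#' @param beta Log-hazard effect per SD of log-abundance, recycled over
#'   `prognostic_cells`. Default 1.0.
#' @param signature_loading Mean log-expression uplift per unit
#'   log-abundance for a cell's marker genes. Default 1.
#' @param noise_sd SD of log-scale expression noise. Default 0.5.
#' @param baseline_log_expr Baseline log-expression of every gene. Default 2.
#' @param baseline_hazard Exponential baseline hazard rate (1/time-unit).
#'   Default 0.1, i.e. a 10-time-unit mean survival at the baseline.
#' @param censoring_rate Target fraction of censored samples; the censoring
#'   window is solved by bisection to hit it in expectation. Default 0.3.
#' @param batch_shift_sd SD of per-cohort per-gene log-expression offsets.
#'   Default 0.3.
#' @param signature_overlap Fraction of each signature shared with the next
#'   cell type's, stressing pair selection with correlated enrichments.
#'   Default 0.
#' @param weibull_shape Shape of the Weibull baseline (1 = exponential).
#'   Default 1.
#' @param response_model List with `eta0` (logit baseline response rate) and
#'   `gamma` (per-cell effects, aligned so high-hazard profiles respond
#'   less), or `NULL`. Default `list(eta0 = 0, gamma = NULL)` where `gamma`
#'   defaults to the survival effects at simulation time.
#' @param seed Integer master seed. Default 1.
#' @return A list of class `"simulationConfig"`.
#' @export
simulationConfig <- function(n_cohorts = 4L, n_samples = 300L, n_cells = 20L,
                             genes_per_signature = 30L, n_noise_genes = 200L,
                             prognostic_cells = c(1L, 2L), beta = 1.0,
                             signature_loading = 1, noise_sd = 0.5,
                             baseline_log_expr = 2, baseline_hazard = 0.1,
                             censoring_rate = 0.3, batch_shift_sd = 0.3,
                             signature_overlap = 0, weibull_shape = 1,
                             response_model = list(eta0 = 0, gamma = NULL),
                             seed = 1L) {
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              n_samples = as.integer(n_samples),
              n_cells = as.integer(n_cells),
              genes_per_signature = as.integer(genes_per_signature),
              n_noise_genes = as.integer(n_noise_genes),
              prognostic_cells = as.integer(prognostic_cells),
              beta = rep_len(beta, length(prognostic_cells)),
              signature_loading = signature_loading, noise_sd = noise_sd,
              baseline_log_expr = baseline_log_expr,
              baseline_hazard = baseline_hazard,
              censoring_rate = censoring_rate,
              batch_shift_sd = batch_shift_sd,
              signature_overlap = signature_overlap,
              weibull_shape = weibull_shape,
              response_model = response_model,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_cohorts >= 1L, n_samples >= 2L, n_cells >= 2L,
              genes_per_signature >= 1L, n_noise_genes >= 0L,
              noise_sd > 0, baseline_hazard > 0,
              censoring_rate >= 0, censoring_rate < 1,
              signature_overlap >= 0, signature_overlap < 1,
              weibull_shape > 0)
    if (length(prognostic_cells) &&
        (min(prognostic_cells) < 1L || max(prognostic_cells) > n_cells)) {
      stop("prognostic_cells must index into 1..n_cells")
    }
  })
  class(cfg) <- c("simulationConfig", "list")
  cfg
}

cell_names <- function(cfg) sprintf("cell%02d", seq_len(cfg$n_cells))

#' Signature collection implied by a simulation config
#'
#' Disjoint marker sets `cellXX_gYYY` per cell type, plus an optional overlap
#' fraction shared with the catalogue-adjacent cell type.
#'
#' @param config A [simulationConfig()].
#' @return A [SignatureCollection].
#' @export
simulatedSignatures <- function(config) {
  cells <- cell_names(config)
  g <- config$genes_per_signature
  own <- lapply(seq_along(cells), function(i) {
    sprintf("%s_g%03d", cells[i], seq_len(g))
  })
  n_share <- floor(config$signature_overlap * g)
  sets <- lapply(seq_along(cells), function(i) {
    extra <- if (n_share > 0) {
      nxt <- if (i == length(cells)) 1L else i + 1L
      own[[nxt]][seq_len(n_share)]
    } else character()
    unique(c(own[[i]], extra))
  })
  names(sets) <- cells
  SignatureCollection(sets, sources = stats::setNames(
    as.list(rep("synthetic", length(cells))), cells))
}

# derive a deterministic, cohort-distinct substream seed below 2^31
substream_seed <- function(seed, index) {
  s <- (as.double(seed) * 48271 + as.double(index) * 104729 + 11) %% 2147483647
  as.integer(s)
}

# expected censoring fraction if C ~ Unif(0, cmax): P(C < T_i) = min(T_i/cmax, 1)
censor_window <- function(t_raw, target) {
  if (target <= 0) return(Inf)
  f <- function(cmax) mean(pmin(t_raw / cmax, 1)) - target
  lo <- min(t_raw) / 2
  hi <- max(t_raw) * 2
  # f is decreasing in cmax; widen until bracketed
  while (f(hi) > 0) hi <- hi * 2
  while (f(lo) < 0) lo <- lo / 2
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Simulate one cohort with known ground truth
#'
#' Latent abundances `A[c, s] ~ LogNormal(0, 1)`; marker genes of cell c get
#' `log expr = baseline + loading * log A[c, s] + batch_shift_g + noise`;
#' noise genes omit the abundance term. Survival times are Weibull
#' (exponential by default) with rate
#' `baseline_hazard * exp(sum_c beta_c * z(log A[c, ]))`, `z` standardized
#' per cohort; censoring is uniform on a window solved by bisection so the
#' expected censored fraction equals `censoring_rate`. Deterministic given
#' `(config$seed, cohort_index)`, with distinct streams per cohort.
#'
#' @param config A [simulationConfig()].
#' @param cohort_index 1-based cohort index.
#' @return A list of class `"syntheticCohort"`: `expression` (genes by
#'   samples), `clinical` (sample/time/event), `signatures`
#'   (a [SignatureCollection]), `truth` (latent abundances, true effects,
#'   linear predictor, expected censoring), `cohort_index`.
#' @export
simulateCohort <- function(config, cohort_index = 1L) {
  stopifnot(inherits(config, "simulationConfig"))
  if (config$signature_loading == 0 && config$noise_sd == 0) {
    stop("config implies constant expression")
  }
  set.seed(substream_seed(config$seed, cohort_index))
  cells <- cell_names(config)
  n <- config$n_samples
  sig <- simulatedSignatures(config)
  genes <- c(unique(unlist(geneSets(sig), use.names = FALSE)),
             if (config$n_noise_genes > 0)
               sprintf("noise_g%04d", seq_len(config$n_noise_genes)))
  samples <- sprintf("c%d_s%03d", cohort_index, seq_len(n))

  logA <- matrix(stats::rnorm(config$n_cells * n), nrow = config$n_cells,
                 dimnames = list(cells, samples))
  A <- exp(logA)

  shift <- stats::rnorm(length(genes), 0, config$batch_shift_sd)
  names(shift) <- genes
  logexpr <- matrix(config$baseline_log_expr + shift, nrow = length(genes),
                    ncol = n, dimnames = list(genes, samples))
  for (i in seq_along(cells)) {
    gset <- geneSets(sig)[[i]]
    logexpr[gset, ] <- logexpr[gset, ] +
      matrix(config$signature_loading * logA[i, ], nrow = length(gset),
             ncol = n, byrow = TRUE)
  }
  logexpr <- logexpr + matrix(stats::rnorm(length(logexpr), 0, config$noise_sd),
                              nrow = nrow(logexpr))
  expr <- exp(logexpr)

  zA <- t(scale(t(logA)))
  lp <- if (length(config$prognostic_cells)) {
    colSums(zA[config$prognostic_cells, , drop = FALSE] * config$beta)
  } else {
    numeric(n)
  }
  rate <- config$baseline_hazard * exp(lp)
  # Weibull with shape k and PH rate multiplier: T = (E / rate)^(1/k), E ~ Exp(1)
  t_raw <- (stats::rexp(n) / rate)^(1 / config$weibull_shape)
  cmax <- censor_window(t_raw, config$censoring_rate)
  cens <- if (is.finite(cmax)) stats::runif(n, 0, cmax) else rep(Inf, n)
  time <- pmin(t_raw, cens)
  event <- as.integer(t_raw <= cens)

  beta_full <- stats::setNames(numeric(config$n_cells), cells)
  beta_full[config$prognostic_cells] <- config$beta
  out <- list(
    expression = expr,
    clinical = data.frame(sample = samples, time = time, event = event,
                          stringsAsFactors = FALSE),
    signatures = sig,
    truth = list(logA = logA, A = A, beta = beta_full, lp = lp,
                 t_raw = t_raw, censor_window = cmax,
                 expected_censoring = mean(pmin(t_raw / cmax, 1))),
    cohort_index = as.integer(cohort_index))
  class(out) <- c("syntheticCohort", "list")
  out
}

#' Simulate a multi-cohort study
#'
#' Cohorts share the signature catalogue and the true survival effects but
#' differ in samples and per-cohort batch shifts. The last cohort is
#' conventionally held out for validation.
#'
#' @param config A [simulationConfig()].
#' @return List of `config$n_cohorts` cohorts from [simulateCohort()].
#' @export
simulateStudy <- function(config) {
  stopifnot(inherits(config, "simulationConfig"))
  lapply(seq_len(config$n_cohorts), function(k) simulateCohort(config, k))
}

#' Simulate immunotherapy-response labels for a cohort
#'
#' Responder probability is `plogis(eta0 - sum_c gamma_c * z(log A[c, ]))`
#' with `gamma` aligned to the survival effects by default, so samples with
#' hazardous abundance profiles respond less — mirroring the observed
#' direction that high pair scores travel with worse checkpoint-blockade
#' response.
#'
#' @param cohort A cohort from [simulateCohort()].
#' @param config The [simulationConfig()] used to create it (must have a
#'   non-`NULL` `response_model`).
#' @return Named integer vector (1 = responder) with attribute `"prob"`
#'   holding the true responder probabilities.
#' @export
simulateResponseLabels <- function(cohort, config) {
  rm <- config$response_model
  if (is.null(rm)) stop("config has no response_model")
  gamma <- rm$gamma
  if (is.null(gamma)) {
    gamma <- stats::setNames(numeric(config$n_cells), cell_names(config))
    gamma[config$prognostic_cells] <- config$beta
  }
  zA <- t(scale(t(cohort$truth$logA)))
  prob <- stats::plogis(rm$eta0 - colSums(zA * gamma))
  set.seed(substream_seed(config$seed, cohort$cohort_index + 7919L))
  labels <- stats::setNames(as.integer(stats::runif(length(prob)) < prob),
                            colnames(cohort$truth$logA))
  attr(labels, "prob") <- prob
  labels
}
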