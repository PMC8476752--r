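# Small simulation setups shared across test files.

# compact multi-cohort design with a strong, easily recoverable signal
small_config <- function(seed = 1, ...) {
  defaults <- list(n_cohorts = 2L, n_samples = 100L, n_cells = 6L,
                   genes_per_signature = 10L, n_noise_genes = 40L,
                   prognostic_cells = c(1L, 2L), beta = 1.5,
                   noise_sd = 0.5, censoring_rate = 0.3, seed = seed)
  do.call(simulationConfig, utils::modifyList(defaults, list(...)))
}

enrich_study <- function(study) {
  lapply(study, function(co)
    list(enrichment = ssgsea(co$expression, co$signatures),
         clinical = co$clinical))
}
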