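# Memoized label-recovery study shared by the generator-invariant tests and
# the acceptance tests: 10 independent sessions of the default generator
# (seeds 1..10; 80 sites, 20 per intended pattern, ~60 retained hits/site).
.recovery_cache <- new.env(parent = emptyenv())

recovery_study <- function(seeds = 1:10) {
  key <- paste(seeds, collapse = ",")
  if (!is.null(.recovery_cache[[key]])) return(.recovery_cache[[key]])
  cms <- list()
  decisions <- matrix(NA, length(seeds), 2,
                      dimnames = list(NULL, c("coupled", "uncoupled")))
  for (i in seq_along(seeds)) {
    rec <- run_recovery(simulation_config(rng_seed = seeds[i]))
    cms[[i]] <- table(
      intended = factor(rec$classification$intended_pattern, pattern_levels()),
      recovered = factor(rec$classification$pattern, pattern_levels()))
    rt <- roi_rho_test(rec$rho_table[rec$rho_table$included, ], 10)
    coupled <- rt[rt$roi == "STGP", ]
    uncoupled <- rt[rt$roi == "IFGop", ]
    decisions[i, "coupled"] <- nrow(coupled) == 1 &&
      coupled$median_rho < 0 && coupled$p_fdr < 0.05
    decisions[i, "uncoupled"] <- nrow(uncoupled) == 1 &&
      uncoupled$p_fdr >= 0.05
  }
  out <- list(confusion = Reduce(`+`, cms), decisions = decisions)
  .recovery_cache[[key]] <- out
  out
}
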