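# Shared heavy simulation fixtures for the acceptance-grade tests. Each is
# computed lazily once per test run and cached, so several test blocks can
# interrogate the same replicated scenario without re-simulating.

.scen_cache <- new.env(parent = emptyenv())

scen_fixture <- function(name) {
  if (!is.null(.scen_cache[[name]])) return(.scen_cache[[name]])
  val <- switch(name,
    # genotype sets, one per sample size (reference geometry, seed 42)
    set200  = scenario_genotypes(scenario_config(n_samples = 200, seed = 42)),
    set500  = scenario_genotypes(scenario_config(n_samples = 500, seed = 42)),
    set1000 = scenario_genotypes(scenario_config(n_samples = 1000, seed = 42)),
    set2000 = scenario_genotypes(scenario_config(n_samples = 2000, seed = 42)),
    # scenario A: n=1000, causal MAF 25%, gamma effects (FDR calibration)
    runA = run_scenario(
      scenario_config(n_samples = 1000, causal_maf = 0.25, replicates = 10,
                      seed = 42),
      methods = c("pooled_bh", "eigenmt_bh", "bonferroni_bh"),
      shared = scen_fixture("set1000")),
    # scenario B: n=2000, causal MAF 50%, gamma effects (pooled inflation)
    runB = run_scenario(
      scenario_config(n_samples = 2000, causal_maf = 0.5, replicates = 10,
                      seed = 42),
      methods = c("pooled_bh", "pooled_st", "eigenmt_bh", "bonferroni_bh"),
      shared = scen_fixture("set2000")),
    # scenario C: n=200, causal MAF 5%, constant beta 1.5 (power)
    runC = run_scenario(
      scenario_config(n_samples = 200, causal_maf = 0.05,
                      effects = effect_dist("constant", beta = 1.5),
                      replicates = 10, seed = 42),
      methods = c("eigenmt_bh"), shared = scen_fixture("set200")),
    # scenario D: two high-power constant-effect scenarios with MAF <= 25%
    # (top-eSNP causal identification)
    runD1 = run_scenario(
      scenario_config(n_samples = 1000, causal_maf = 0.05,
                      effects = effect_dist("constant", beta = 1),
                      replicates = 10, seed = 42),
      methods = c("eigenmt_bh"), shared = scen_fixture("set1000")),
    runD2 = run_scenario(
      scenario_config(n_samples = 500, causal_maf = 0.25,
                      effects = effect_dist("constant", beta = 1.5),
                      replicates = 10, seed = 42),
      methods = c("eigenmt_bh"), shared = scen_fixture("set500")),
    # scenario E: low-power Winner's Curse scenario with bootstrap correction
    # (reduced gene count keeps 10 x 200 bootstraps affordable)
    runE = run_scenario(
      scenario_config(n_samples = 200, causal_maf = 0.05,
                      n_genes = 150, n_true_egenes = 60, n_snps = 8000,
                      region_length = 1e7, replicates = 10, seed = 42),
      methods = c("bonferroni_bh"), bootstrap = TRUE,
      bootstrap_gate = "bonferroni_bh", bootstrap_B = 200),
    stop(sprintf("unknown fixture '%s'", name)))
  .scen_cache[[name]] <- val
  val
}
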