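# shared fixtures: a default basis and a small simulated cohort, built once
default_basis <- build_basis()

small_cohort <- function(n_subjects = 4, n_runs = 4, seed = 42,
                         variant = "selective",
                         kinds = c("IEV", "DEV", "CEV", "CEVR")) {
  ps <- population_spec(n_subjects = n_subjects, n_runs = n_runs,
                        kinds = kinds, seed = seed)
  pop <- gen_population(ps)
  sim <- simulate_experiment(pop, basis = default_basis, variant = variant,
                             schedule = ps$schedule, seed = seed + 1)
  list(spec = ps, pop = pop, trials = sim$trials)
}
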