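# synthetic-data generators: determinism, distributional targets, planted
# couplings, and the end-to-end behavioral narrative

test_that("generated populations respect domains, seeds and SD-zero", {
  ps <- population_spec(n_subjects = 70, seed = 5)
  pop <- gen_population(ps)
  expect_equal(nrow(pop), 70)
  expect_true(all(pop$alpha > 0 & pop$alpha < 1))
  expect_true(all(pop$gamma > 0 & pop$gamma < 1))
  expect_true(all(pop$beta > 0))
  expect_identical(pop, gen_population(ps))   # bitwise reproducible
  ps0 <- population_spec(n_subjects = 5, sds = c(alpha = 0, gamma = 0,
                                                 beta = 0, tau = 0))
  p0 <- gen_population(ps0)
  expect_equal(length(unique(p0$alpha)), 1)
  # large-sample transformed means approach the spec means within 3 SE
  psbig <- population_spec(n_subjects = 1000, seed = 6)
  pb <- gen_population(psbig)
  for (p in c("alpha", "gamma", "beta", "tau")) {
    se <- psbig$sds[[p]] / sqrt(1000)
    expect_lt(abs(mean(pb[[paste0(p, "_t")]]) - psbig$means[[p]]), 3 * se)
  }
})

test_that("simulated experiments are seed-deterministic with valid rewards", {
  co <- small_cohort(n_subjects = 2, n_runs = 2, seed = 91)
  co2 <- small_cohort(n_subjects = 2, n_runs = 2, seed = 91)
  expect_identical(co$trials, co2$trials)
  tr <- co$trials
  # rewards are 0 or the contingency magnitude at the chosen rt
  for (k in unique(tr$contingency)) {
    cc <- make_contingency(k)
    rows <- tr[tr$contingency == k, ]
    expect_true(all(abs(rows$reward -
                          rows$rewarded * cc$mag_fn(rows$rt_ms)) < 1e-9))
  }
  expect_true(all(tr$iti_s >= 1 & tr$iti_s <= 10))
  expect_true(all(tr$rt_ms >= 0 & tr$rt_ms < 4000))
})

test_that("exploitative agents move toward the maximum in DEV", {
  ps <- population_spec(n_subjects = 8,
                        means = c(alpha = stats::qlogis(0.25),
                                  gamma = stats::qlogis(0.2),
                                  beta = log(15), tau = 0),
                        sds = c(alpha = 0.1, gamma = 0.1, beta = 0.1,
                                tau = 0),
                        n_runs = 2, kinds = "DEV", seed = 92)
  pop <- gen_population(ps)
  sim <- simulate_experiment(pop, basis = default_basis,
                             schedule = ps$schedule, seed = 93)
  tr <- sim$trials
  early <- mean(tr$rt_ms[tr$trial <= 10])
  late <- mean(tr$rt_ms[tr$trial > 10])
  expect_lt(late, early)   # DEV pays early: RTs shorten with learning
})

test_that("selective maintenance compresses late-learning entropy", {
  ps <- population_spec(n_subjects = 8, n_runs = 4,
                        kinds = c("IEV", "DEV"), seed = 94)
  pop <- gen_population(ps)
  sel <- simulate_experiment(pop, basis = default_basis,
                             variant = "selective",
                             schedule = ps$schedule, seed = 95)$trials
  ful <- simulate_experiment(pop, basis = default_basis, variant = "full",
                             schedule = ps$schedule, seed = 95)$trials
  late <- function(d) mean(d$entropy[d$trial > 40])
  expect_lt(late(sel), late(ful))
})

test_that("beta couplings are planted and nulls stay null", {
  ps <- population_spec(n_subjects = 200, seed = 96)
  pop <- gen_population(ps)
  # zero noise, unit coupling: perfect rank correlation with the parameter
  b0 <- gen_betas(pop, coupling = list(PH = c(beta_t = 1)), noise_sd = 0,
                  seed = 97)
  expect_equal(cor(b0$PH, pop$beta_t, method = "spearman"), 1)
  # zero coupling: independent of every parameter within 2 SE
  bn <- gen_betas(pop, coupling = list(X = c(beta_t = 0)), noise_sd = 1,
                  seed = 98)
  se <- 1 / sqrt(200 - 3)
  for (p in c("alpha_t", "gamma_t", "beta_t", "tau_t"))
    expect_lt(abs(cor(bn$X, pop[[p]])), 2.5 * se)
})

test_that("planted moderator coupling is recovered by the exploration index", {
  # subjects with higher temperature (beta) explore more; a synthetic
  # "PH beta" coupled to log-temperature should therefore show a negative
  # rt_prev x PH interaction (weaker autocorrelation for high-PH subjects)
  set.seed(99)
  signs <- numeric(10)
  for (r in 1:10) {
    ps <- population_spec(n_subjects = 12, n_runs = 2,
                          sds = c(alpha = 0.3, gamma = 0.3, beta = 1,
                                  tau = 0.3),
                          kinds = c("IEV", "DEV"), seed = 990 + r)
    pop <- gen_population(ps)
    sim <- simulate_experiment(pop, basis = default_basis,
                               schedule = ps$schedule, seed = 9900 + r)
    mods <- gen_betas(pop, coupling = list(PH = c(beta_t = 1)),
                      noise_sd = 0.2, seed = 99000 + r)
    lt <- lagged_trial_table(sim$trials, mods)
    cf <- exploration_index(lt, "PH")$coef
    signs[r] <- sign(cf$estimate[cf$term == "rt_prev:PH"])
  }
  expect_gte(mean(signs == -1), 0.8)
})

test_that("time-course presets differ in latency and scale noise", {
  ev <- seq(20, 220, by = 20)
  on <- gen_timecourses(ev, "onoff", noise_sd = 0)
  de <- gen_timecourses(ev, "delayed", noise_sd = 0)
  peak_lat <- function(x) {
    m <- timelock_trials(list(time = x$time, value = x$value), ev,
                         window = c(-1, 10))
    as.numeric(names(which.max(colMeans(m))))
  }
  expect_lt(peak_lat(on), peak_lat(de))
  # doubling the noise SD roughly doubles residual SD around the mean shape
  res_sd <- function(sd) {
    x <- gen_timecourses(ev, "onoff", noise_sd = sd, seed = 101)
    m <- timelock_trials(list(time = x$time, value = x$value), ev,
                         window = c(-1, 10))
    sd(sweep(m, 2, colMeans(m)))
  }
  expect_equal(res_sd(1) / res_sd(0.5), 2, tolerance = 0.2)
})
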