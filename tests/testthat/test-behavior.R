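# lagged design construction, exploration/convergence indices, and the
# counting-process survival table

make_lagged <- function(n_subjects = 4, seed = 70, trials = NULL) {
  co <- if (is.null(trials)) small_cohort(n_subjects, n_runs = 4,
                                          seed = seed) else NULL
  lagged_trial_table(if (is.null(trials)) co$trials else trials)
}

test_that("lags never cross run boundaries", {
  lt <- make_lagged()
  firsts <- lt$trial == 1
  expect_true(all(is.na(lt$rt_prev[firsts])))
  expect_true(all(is.na(lt$rt_vmax_prev[firsts])))
  expect_true(all(!is.na(lt$rt_prev[!firsts])))
  # lagged value equals previous row within run
  i <- which(!firsts)
  expect_equal(lt$rt_prev[i], lt$rt_ms[i - 1])
  expect_equal(lt$inv_trial, -1 / lt$trial)
})

test_that("perseverative agents show autocorrelation ~1, random ~0", {
  set.seed(71)
  mk <- function(rts) {
    do.call(rbind, lapply(1:4, function(s) {
      data.frame(subject = s, run = rep(1:2, each = 50),
                 trial = rep(1:50, 2), rt_ms = rts(),
                 rewarded = rbinom(100, 1, 0.5), rt_vmax = 2000)
    }))
  }
  # perseveration as a slow within-run random walk (AR coefficient ~ 1)
  pers <- mk(function() as.vector(sapply(1:2, function(r)
    pmin(pmax(cumsum(c(runif(1, 1000, 3000), rnorm(49, 0, 60))), 200),
         3800))))
  fit_p <- exploration_index(lagged_trial_table(pers))
  cf <- fit_p$coef
  expect_equal(cf$estimate[cf$term == "rt_prev"], 1, tolerance = 0.1)
  rand <- mk(function() runif(100, 0, 4000))
  fit_r <- exploration_index(lagged_trial_table(rand))
  cfr <- fit_r$coef
  expect_lt(abs(cfr$estimate[cfr$term == "rt_prev"]), 0.15)
})

test_that("a moderator unrelated to behavior has a null interaction", {
  set.seed(72)
  co <- small_cohort(n_subjects = 8, n_runs = 2, seed = 72)
  mods <- data.frame(subject = unique(co$trials$subject),
                     noise_beta = rnorm(8))
  lt <- lagged_trial_table(co$trials, mods)
  fit <- exploration_index(lt, "noise_beta")
  cf <- fit$coef
  z <- with(cf[cf$term == "rt_prev:noise_beta", ], estimate / se)
  expect_lt(abs(z), 3)
})

test_that("greedy agents track rt_vmax; random agents do not", {
  set.seed(73)
  greedy <- do.call(rbind, lapply(1:4, function(s) {
    vmax <- cumsum(c(2000, rnorm(99, 0, 50)))
    vmax <- pmin(pmax(vmax, 500), 3500)
    data.frame(subject = s, run = rep(1:2, each = 50), trial = rep(1:50, 2),
               rt_ms = vmax + rnorm(100, 0, 30),
               rewarded = rbinom(100, 1, 0.5), rt_vmax = vmax)
  }))
  # rt tracks previous trial's vmax (vmax moves slowly, so lag-1 is close)
  cf <- convergence_index(lagged_trial_table(greedy))$coef
  expect_equal(cf$estimate[cf$term == "rt_vmax_prev"], 1, tolerance = 0.2)
  rand <- greedy; rand$rt_ms <- runif(nrow(rand), 0, 4000)
  cfr <- convergence_index(lagged_trial_table(rand))$coef
  expect_lt(abs(cfr$estimate[cfr$term == "rt_vmax_prev"]), 0.2)
})

test_that("survival rows match the brute-force counting oracle", {
  co <- small_cohort(n_subjects = 3, n_runs = 4, seed = 74)
  tr <- co$trials   # 600 trials
  st <- build_survival_table(tr, default_basis,
                             value_params = list(alpha = 0.1, gamma = 0.2),
                             unc_params = list(alpha = 0.1),
                             rescale = FALSE)
  # oracle: responded trials contribute ceil((min(rt,3500)-1000)/100) rows
  expected_rows <- sum(vapply(tr$rt_ms, function(rt) {
    if (rt <= 1000) return(0)
    ceiling((min(rt, 3500) - 1000) / 100)
  }, 0))
  expect_equal(nrow(st), expected_rows)
  # exactly one event per responded trial within the window, on its last row
  ev <- aggregate(event ~ subject + run + trial, st, sum)
  key <- paste(tr$subject, tr$run, tr$trial)
  in_win <- tr$rt_ms > 1000 & tr$rt_ms <= 3500
  expect_equal(sum(ev$event), sum(in_win))
  # rows are ordered, disjoint, and stop at the response
  one <- st[st$subject == st$subject[1] & st$run == st$run[1] &
              st$trial == st$trial[1], ]
  expect_true(all(diff(one$start) == 100))
  expect_true(all(one$stop > one$start))
  expect_equal(one$event[nrow(one)],
               as.integer(tr$rt_ms[1] <= 3500 && tr$rt_ms[1] > 1000))
})

test_that("survival window edge cases and no-go censoring", {
  b <- default_basis
  tr <- data.frame(subject = 1, run = 1, trial = 1:3,
                   rt_ms = c(2000, 950, 3950), reward = c(50, 0, 20),
                   rewarded = c(1, 0, 1))
  st <- build_survival_table(tr, b, list(alpha = 0.1, gamma = 0.2),
                             list(alpha = 0.1), rescale = FALSE)
  t1 <- st[st$trial == 1, ]
  expect_equal(nrow(t1), 10)                   # [1000, 2000] in 100 ms bins
  expect_equal(t1$event, c(rep(0L, 9), 1L))
  expect_equal(max(t1$stop), 2000)
  expect_false(2 %in% st$trial)                # rt before window start
  t3 <- st[st$trial == 3, ]
  expect_equal(nrow(t3), 25)                   # censored at 3500, no event
  expect_equal(sum(t3$event), 0)
  # no-go censoring drops edge bins
  st2 <- build_survival_table(tr, b, list(alpha = 0.1, gamma = 0.2),
                              list(alpha = 0.1), censor_no_go = TRUE,
                              rescale = FALSE)
  expect_gte(min(st2$start), 1100)
  expect_lte(max(st2$stop), 3400)
})

test_that("within-subject rescaling standardizes each subject", {
  set.seed(75)
  x <- c(rnorm(100, 10, 5), rnorm(100, -3, 0.2))
  s <- rep(1:2, each = 100)
  z <- rescale_within_subject(x, s)
  for (g in 1:2) {
    expect_equal(mean(z[s == g]), 0, tolerance = 1e-12)
    expect_equal(sd(z[s == g]), 1, tolerance = 1e-12)
  }
  # already standardized input is unchanged
  z2 <- rescale_within_subject(z, s)
  expect_equal(z2, z, tolerance = 1e-10)
  expect_warning(rescale_within_subject(c(rep(1, 5), rnorm(5)),
                                        rep(1:2, each = 5)), "constant")
})

test_that("hazard model runs on a synthetic survival table", {
  co <- small_cohort(n_subjects = 3, n_runs = 2, seed = 76)
  st <- build_survival_table(co$trials, default_basis,
                             list(alpha = 0.1, gamma = 0.2),
                             list(alpha = 0.1))
  fit <- fit_hazard_model(st)
  expect_s3_class(fit, "coxph")
  expect_true(all(c("value", "uncertainty") %in% names(coef(fit))))
})
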