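# one small shared fit keeps the fit-level tests fast
co_fit <- small_cohort(n = 16, seed = 101)
ctl_trials <- co_fit$trials[co_fit$trials$group == "control", ]
fit_small <- fit_group(ctl_trials, model_spec("dual", "training"),
                       fast_mcmc(seed = 5, loo_draws = 120))

test_that("model_spec and mcmc_config validate their arguments", {
  expect_error(model_spec(block_limit = 0), class = "pst_invalid_argument")
  expect_error(model_spec(scope = "training_plus_test", block_limit = 2),
               class = "pst_invalid_argument")
  expect_error(mcmc_config(chains = 0), class = "pst_invalid_argument")
})

test_that("fits are reproducible and respect scope and block limits", {
  fit2 <- fit_group(ctl_trials, model_spec("dual", "training"),
                    fast_mcmc(seed = 5, loo_draws = 120))
  expect_identical(fit_small$mu, fit2$mu)
  expect_identical(fit_small$theta, fit2$theta)
  expect_identical(fit_small$loo_ll, fit2$loo_ll)

  one_block <- fit_group(ctl_trials, model_spec("dual", "training",
                                                block_limit = 1),
                         mcmc_config(chains = 2, warmup = 50, iter = 50,
                                     seed = 1, loo_draws = 0))
  per_subj <- table(one_block$trial_info$participant_id)
  expect_true(all(per_subj == 60))

  expect_error(fit_group(ctl_trials, model_spec("dual", "training",
                                                block_limit = 7),
                         fast_mcmc()), class = "pst_invalid_argument")
  mixed <- co_fit$trials
  expect_error(fit_group(mixed, model_spec(), fast_mcmc()),
               class = "pst_invalid_argument")
  no_test <- ctl_trials[ctl_trials$phase == "training", ]
  expect_error(fit_group(no_test, model_spec("dual", "training_plus_test"),
                         fast_mcmc()), class = "pst_invalid_argument")
})

test_that("individual draws respect parameter bounds in every draw", {
  expect_true(all(fit_small$theta[, , "alpha_reward", ] >= 0 &
                    fit_small$theta[, , "alpha_reward", ] <= 1))
  expect_true(all(fit_small$theta[, , "alpha_loss", ] >= 0 &
                    fit_small$theta[, , "alpha_loss", ] <= 1))
  expect_true(all(fit_small$theta[, , "beta", ] >= 0 &
                    fit_small$theta[, , "beta", ] <= fit_small$beta_cap))
})

test_that("prior-predictive transforms cover the parameter ranges", {
  set.seed(8)
  mu <- rnorm(4000)
  sigma <- abs(rnorm(4000, 0, 0.2))
  z <- rnorm(4000)
  alpha <- pnorm(mu + sigma * z)
  beta <- 10 * pnorm(rnorm(4000) + abs(rnorm(4000, 0, 1)) * rnorm(4000))
  expect_lt(min(alpha), 0.05)
  expect_gt(max(alpha), 0.95)
  expect_lt(min(beta), 0.5)
  expect_gt(max(beta), 9.5)
})

test_that("diagnostics follow the rank-normalised split-chain definitions", {
  set.seed(12)
  base <- rnorm(2000)
  dup <- cbind(base, base, base, base)
  expect_lt(abs(split_rhat(dup) - 1), 0.01)

  shifted <- cbind(rnorm(1000), rnorm(1000) + 5)
  expect_gt(split_rhat(shifted), 1.1)

  white <- matrix(rnorm(4000), 1000, 4)
  expect_gt(ess_bulk(white), 1000)

  d <- diagnose(fit_small)
  expect_true(all(c("hyper", "individual", "per_individual") %in% names(d)))
  expect_true(all(d$hyper$rhat >= 1 - 1e-8))
  expect_true(all(d$individual$ess_bulk >= 0))
  expect_equal(nrow(d$per_individual), length(fit_small$participants))
})

test_that("convergence gating removes exactly the flagged individuals", {
  d <- diagnose(fit_small)
  # force convergence for the no-op check
  d_ok <- d
  d_ok$per_individual$worst_rhat <- 1.0
  d_ok$per_individual$min_ess_bulk <- 1e4
  res <- exclude_unconverged(fit_small, d_ok)
  expect_identical(res$fit$theta, fit_small$theta)
  expect_equal(nrow(res$log), 0)

  d_bad <- d_ok
  d_bad$per_individual$worst_rhat[2] <- 1.2   # at/above 1.1 -> removed
  d_bad$per_individual$min_ess_bulk[5] <- 50  # below 100 -> removed
  res2 <- exclude_unconverged(fit_small, d_bad)
  dropped <- d_ok$per_individual$participant_id[c(2, 5)]
  expect_setequal(res2$log$participant_id, dropped)
  expect_equal(length(res2$fit$participants),
               length(fit_small$participants) - 2)
  expect_false(any(dropped %in% res2$fit$participants))

  d_edge <- d_ok
  d_edge$per_individual$worst_rhat[1] <- 1.05
  d_edge$per_individual$min_ess_bulk[1] <- 150
  expect_equal(nrow(exclude_unconverged(fit_small, d_edge)$log), 0)
})

test_that("posterior predictions are seeded and cover observed accuracy", {
  ss <- stimulus_set()
  tr_sched <- build_training_schedule(ss, 6, 20, seed = 3)
  pp <- posterior_predict(fit_small, tr_sched, n_rep = 40, seed = 9)
  pp2 <- posterior_predict(fit_small, tr_sched, n_rep = 40, seed = 9)
  expect_identical(pp$summary, pp2$summary)
  expect_true(all(pp$summary$lower >= 0 & pp$summary$upper <= 1))
  expect_true(all(pp$summary$lower <= pp$summary$upper))
  expect_error(posterior_predict(fit_small, tr_sched, n_rep = 0),
               class = "pst_invalid_argument")

  # calibration pooled over well-mixed fits of both groups
  # (36 pair-by-block cells)
  cells <- lapply(c(control = 0L, distanced = 1L), function(off) {
    tr <- co_fit$trials[co_fit$trials$group ==
                          names(which(c(control = 0L, distanced = 1L) == off)), ]
    fit <- fit_group(tr, model_spec("dual", "training"),
                     mcmc_config(chains = 4, warmup = 400, iter = 1000,
                                 seed = 5 + off, loo_draws = 0))
    ppg <- posterior_predict(fit, tr_sched, n_rep = 150, seed = 9 + off)
    obs <- training_accuracy(tr[tr$phase == "training", ], ss)
    obs_block <- stats::aggregate(accuracy ~ pair + block, obs$blocks, mean)
    merge(obs_block, ppg$summary, by = c("pair", "block"))
  })
  m <- do.call(rbind, cells)
  covered <- mean(m$accuracy >= m$lower & m$accuracy <= m$upper)
  expect_gte(covered, 0.9)
})
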