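test_that("cohort allocation, determinism and degenerate hyper-SDs", {
  co <- small_cohort(n = 20, seed = 31)
  expect_equal(sum(co$participants$group == "distanced"), 10)
  expect_equal(sum(co$participants$group == "control"), 10)

  co2 <- small_cohort(n = 20, seed = 31)
  expect_identical(co$trials, co2$trials)
  expect_identical(co$participants, co2$participants)
  expect_identical(co$items, co2$items)

  degen <- generate_cohort(cohort_config(n_participants = 12, seed = 5,
                                         sd_alpha_reward = 0,
                                         sd_alpha_loss = 0, sd_beta = 0))
  tr <- degen$truth
  for (g in c("control", "distanced")) {
    sub <- tr[tr$group == g, ]
    expect_equal(var(sub$alpha_reward), 0)
    expect_equal(var(sub$beta), 0)
  }
  # the configured group effects separate the degenerate groups
  expect_gt(mean(tr$alpha_loss[tr$group == "distanced"]) /
              mean(tr$alpha_loss[tr$group == "control"]), 1.1)
})

test_that("cohort trials follow the task structure and carry affect ratings", {
  co <- small_cohort(n = 6, seed = 77)
  tr <- co$trials
  expect_equal(nrow(tr), 6 * (360 + 60))
  one <- tr[tr$participant_id == tr$participant_id[1], ]
  expect_equal(sum(one$phase == "training"), 360)
  expect_equal(sum(one$phase == "test"), 60)
  expect_true(all(is.na(one$reward[one$phase == "test"])))
  expect_true(all(one$reward[one$phase == "training"] %in% 0:1))
  is_tr <- one$phase == "training"
  expect_true(all(one$affect_question[is_tr] %in%
                    c("happy", "confident", "engaged")))
  expect_true(all(one$affect_rating[is_tr] >= 0 & one$affect_rating[is_tr] <= 100))
  expect_true(all(is.na(one$affect_rating[!is_tr])))
})

test_that("noise-free affect ratings reproduce the configured slope exactly", {
  co <- generate_cohort(cohort_config(n_participants = 4, seed = 9,
                                      affect_noise_sd = 0))
  tr <- co$trials[co$trials$phase == "training", ]
  for (id in unique(tr$participant_id)) {
    one <- tr[tr$participant_id == id, ]
    m <- stats::aggregate(affect_rating ~ block, one, mean)
    slope <- coef(stats::lm(affect_rating ~ block, m))[["block"]]
    expected <- -1.0 + 0.425 * (one$group[1] == "distanced")
    expect_equal(slope, expected, tolerance = 1e-10)
  }
})

test_that("exclusion filters follow the catch-question rules and are idempotent", {
  base <- data.frame(
    participant_id = sprintf("p%d", 1:6),
    n_standard_wrong = c(1L, 0L, 0L, 0L, 0L, 0L),
    n_hard_wrong = c(0L, 1L, 2L, 0L, 0L, 0L),
    digit_span = c(7L, 7L, 7L, 0L, 7L, 7L),
    neuro_flag = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    english_flag = FALSE, stringsAsFactors = FALSE)
  res <- apply_exclusions(base)
  expect_setequal(res$participants$participant_id, c("p2", "p6"))
  expect_true("p1" %in% res$excluded$participant_id)  # one standard wrong
  expect_false("p2" %in% res$excluded$participant_id) # one hard wrong retained
  expect_true("p3" %in% res$excluded$participant_id)  # both hard wrong
  expect_true("p4" %in% res$excluded$participant_id)  # digit span 0
  expect_equal(res$log$n[res$log$reason == "digit_span_zero"], 1)

  again <- apply_exclusions(res$participants)
  expect_equal(nrow(again$excluded), 0)
  expect_equal(again$participants$participant_id, res$participants$participant_id)
  expect_error(apply_exclusions(base[, 1:3]), class = "pst_data_integrity")
})

test_that("true parameters beat latent-perturbed ones in likelihood", {
  co <- generate_cohort(cohort_config(n_participants = 30, seed = 13))
  truth <- co$truth
  set.seed(4)
  wins <- vapply(seq_len(nrow(truth)), function(i) {
    rec <- co$trials[co$trials$participant_id == truth$participant_id[i] &
                       co$trials$phase == "training", ]
    pt <- agent_params("dual", alpha_reward = truth$alpha_reward[i],
                       alpha_loss = truth$alpha_loss[i], beta = truth$beta[i])
    shift <- sample(c(-0.3, 0.3), 3, replace = TRUE)
    pp <- agent_params("dual",
                       alpha_reward = pnorm(qnorm(truth$alpha_reward[i]) + shift[1]),
                       alpha_loss = pnorm(qnorm(truth$alpha_loss[i]) + shift[2]),
                       beta = 10 * pnorm(qnorm(truth$beta[i] / 10) + shift[3]))
    log_likelihood(pt, rec, "training") > log_likelihood(pp, rec, "training")
  }, TRUE)
  expect_gte(mean(wins), 0.95)
})

test_that("cohort questionnaire items come from the planted factor model", {
  co <- small_cohort(n = 60, seed = 41)
  expect_equal(dim(co$items), c(60, 209))
  expect_true(all(co$items %in% 0:4))
  expect_equal(sum(co$item_meta$informative), 30)
  # informative items correlate with their generating factor scores
  f <- as.matrix(co$truth[, c("anxiety_depression", "compulsive_behaviour",
                              "social_withdrawal")])
  inf <- which(co$item_meta$informative)
  cors <- vapply(inf, function(j) max(abs(cor(co$items[, j], f))), 0)
  expect_gt(mean(cors > 0.4), 0.8)
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(prop_distanced = 0), class = "pst_invalid_argument")
  expect_error(cohort_config(sd_beta = -1), class = "pst_invalid_argument")
  expect_error(cohort_config(n_items = 2), class = "pst_invalid_argument")
})

test_that("cohort CSV export and tidy draws round-trip", {
  co <- small_cohort(n = 4, seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_cohort_csv(co, dir)
  expect_true(all(file.exists(paths)))
  tr <- utils::read.csv(paths[2], stringsAsFactors = FALSE)
  expect_equal(nrow(tr), nrow(co$trials))
  expect_equal(tr$choice, co$trials$choice)

  fit <- fit_group(co$trials[co$trials$group == "control", ],
                   model_spec("dual", "training"),
                   mcmc_config(chains = 2, warmup = 50, iter = 80, seed = 1,
                               loo_draws = 0))
  td <- tidy_draws(fit)
  expect_setequal(unique(td$parameter),
                  c(outer(c("mu", "sigma"),
                          c("alpha_reward", "alpha_loss", "beta"),
                          paste, sep = "_")))
  expect_equal(nrow(td), 2 * 3 * 2 * 80)
  tdi <- tidy_draws(fit, include_individuals = TRUE)
  expect_gt(nrow(tdi), nrow(td))
})
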