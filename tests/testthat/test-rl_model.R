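test_that("q_update applies the signed learning rate to the prediction error", {
  dual <- agent_params("dual", alpha_reward = 0.5, alpha_loss = 0.2, beta = 1)
  up <- q_update(0, 1, dual)
  expect_equal(up$new_q, 0.5)
  expect_equal(up$prediction_error, 1)
  down <- q_update(0.5, 0, dual)
  expect_equal(down$new_q, 0.4)
  expect_equal(down$prediction_error, -0.5)
  frozen <- agent_params("dual", alpha_reward = 0, alpha_loss = 0, beta = 1)
  expect_equal(q_update(0.37, 1, frozen)$new_q, 0.37)
  expect_equal(q_update(0.37, 0, frozen)$new_q, 0.37)
  expect_error(q_update(0.2, 0.5, dual), class = "pst_invalid_argument")
})

test_that("choice_prob is the two-option softmax", {
  expect_equal(choice_prob(0.4, 0.4, 5), 0.5)
  expect_equal(choice_prob(0.9, 0.1, 0), 0.5)
  expect_equal(choice_prob(1, 0, 1), 1 / (1 + exp(-1)), tolerance = 1e-10)
  expect_equal(choice_prob(1, 0, 1) + choice_prob(0, 1, 1), 1)
  betas <- seq(0.5, 10, by = 0.5)
  expect_true(all(diff(choice_prob(0.6, 0.2, betas)) > 0))
  expect_error(choice_prob(1, 0, -1), class = "pst_invalid_argument")
})

test_that("log-likelihood matches hand-computed rollouts", {
  params <- agent_params("dual", alpha_reward = 0.5, alpha_loss = 0.5, beta = 2)
  one <- data.frame(participant_id = "p1", phase = "training", block = 1L,
                    trial = 1L, pair = "AB", left_symbol = "A",
                    right_symbol = "B", choice = "A", reward = 1L,
                    stringsAsFactors = FALSE)
  expect_equal(log_likelihood(params, one, "training"), log(0.5),
               tolerance = 1e-12)
  two <- rbind(one, transform(one, trial = 2L, reward = 1L))
  expect_equal(log_likelihood(params, two, "training"),
               log(0.5) + log(1 / (1 + exp(-1))), tolerance = 1e-12)
})

test_that("log-likelihood agrees with the brute-force oracle", {
  set.seed(11)
  ss <- stimulus_set()
  tr <- build_training_schedule(ss, 2, 5, seed = 3)
  te <- build_test_schedule(ss, 1, seed = 4)
  for (params in list(
    agent_params("dual", alpha_reward = 0.4, alpha_loss = 0.1, beta = 3),
    agent_params("single", alpha = 0.25, beta = 7),
    agent_params("dual", alpha_reward = 0.9, alpha_loss = 0.8, beta = 0.3))) {
    rec <- simulate_agent(params, tr, te, ss, seed = 17)
    for (scope in c("training", "training_plus_test")) {
      expect_equal(log_likelihood(params, rec, scope),
                   oracle_loglik(params, rec, scope), tolerance = 1e-10)
    }
  }
})

test_that("choice-sequence probabilities sum to one (3-trial enumeration)", {
  for (params in list(
    agent_params("dual", alpha_reward = 0.7, alpha_loss = 0.15, beta = 4.2),
    agent_params("single", alpha = 0.33, beta = 0.9),
    agent_params("dual", alpha_reward = 0, alpha_loss = 1, beta = 9))) {
    expect_equal(sum(enumerate_sequences(params)), 1, tolerance = 1e-10)
  }
})

test_that("the dual model nests the single model exactly", {
  ss <- stimulus_set()
  rec <- simulate_agent(agent_params("dual", alpha_reward = 0.4,
                                     alpha_loss = 0.1, beta = 5),
                        build_training_schedule(ss, 3, 10, seed = 6),
                        build_test_schedule(ss, 2, seed = 7), ss, seed = 8)
  for (a in c(0.1, 0.5, 0.95)) {
    dual <- agent_params("dual", alpha_reward = a, alpha_loss = a, beta = 2.5)
    single <- agent_params("single", alpha = a, beta = 2.5)
    for (scope in c("training", "training_plus_test"))
      expect_equal(log_likelihood(dual, rec, scope),
                   log_likelihood(single, rec, scope), tolerance = 1e-12)
  }
})

test_that("training-plus-test scope with no test rows reduces to training", {
  ss <- stimulus_set()
  params <- agent_params("dual", alpha_reward = 0.3, alpha_loss = 0.2, beta = 4)
  rec <- simulate_agent(params, build_training_schedule(ss, 2, 6, seed = 2),
                        test = NULL, ss, seed = 3)
  expect_identical(log_likelihood(params, rec, "training_plus_test"),
                   log_likelihood(params, rec, "training"))
})

test_that("record integrity violations are rejected", {
  ss <- stimulus_set()
  params <- agent_params("single", alpha = 0.3, beta = 2)
  rec <- simulate_agent(params, build_training_schedule(ss, 1, 3, seed = 1),
                        build_test_schedule(ss, 1, seed = 2), ss, seed = 3)
  bad_reward <- rec
  bad_reward$reward[bad_reward$phase == "test"] <- 1L
  expect_error(log_likelihood(params, bad_reward), class = "pst_data_integrity")
  unordered <- rec[rev(seq_len(nrow(rec))), ]
  expect_error(log_likelihood(params, unordered), class = "pst_invalid_argument")
  bad_choice <- rec
  bad_choice$choice[1] <- setdiff(ss$symbols, c(bad_choice$left_symbol[1],
                                                bad_choice$right_symbol[1]))[1]
  expect_error(log_likelihood(params, bad_choice), class = "pst_data_integrity")
})

test_that("simulated Q-values and likelihood respect structural bounds", {
  # random choice at beta = 0, and accuracy ordering by contingency at high beta
  ss <- stimulus_set()
  tr <- build_training_schedule(ss, 6, 20, seed = 5)
  rand <- simulate_agent(agent_params("single", alpha = 0.3, beta = 0),
                         tr, test = NULL, ss, seed = 21)
  acc <- training_accuracy(rand, ss)$blocks
  expect_true(abs(mean(acc$accuracy) - 0.5) < 0.08)

  set.seed(99)
  seeds <- sample.int(1e6, 200)
  diffs <- vapply(seeds, function(s) {
    rec <- simulate_agent(agent_params("single", alpha = 0.3, beta = 8),
                          tr, test = NULL, ss, seed = s)
    final <- rec[rec$block == 6, ]
    better <- c(AB = "A", CD = "C", EF = "E")
    mean(final$choice[final$pair == "AB"] == "A") -
      mean(final$choice[final$pair == "EF"] == "E")
  }, 0)
  expect_gt(mean(diffs), 0)
})

test_that("simulation is reproducible given the seed", {
  ss <- stimulus_set()
  tr <- build_training_schedule(ss, 2, 5, seed = 1)
  te <- build_test_schedule(ss, 1, seed = 2)
  params <- agent_params("dual", alpha_reward = 0.5, alpha_loss = 0.2, beta = 3)
  expect_identical(simulate_agent(params, tr, te, ss, seed = 77),
                   simulate_agent(params, tr, te, ss, seed = 77))
})
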