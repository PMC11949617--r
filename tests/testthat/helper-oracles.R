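# Independent brute-force Q-learning likelihood calculator used as an oracle
# against the package's C++ likelihood. Deliberately written as a plain
# data.frame walk with no shared code.
oracle_loglik <- function(params, records, scope = "training_plus_test") {
  q <- stats::setNames(rep(0, 6), LETTERS[1:6])
  ll <- 0
  for (r in seq_len(nrow(records))) {
    row <- records[r, ]
    if (scope == "training" && row$phase == "test") next
    other <- if (row$choice == row$left_symbol) row$right_symbol else row$left_symbol
    p <- 1 / (1 + exp(-params$beta * (q[[row$choice]] - q[[other]])))
    ll <- ll + log(p)
    if (row$phase == "training") {
      delta <- row$reward - q[[row$choice]]
      a <- if (params$model == "single") params$alpha
      else if (delta >= 0) params$alpha_reward else params$alpha_loss
      q[[row$choice]] <- q[[row$choice]] + a * delta
    }
  }
  ll
}

# a fixed 3-trial training mini-schedule with a predetermined reward rule
# (reward depends only on trial and chosen symbol), so that choices are the
# only random variable and choice-sequence probabilities must sum to 1
mini_schedule <- data.frame(
  phase = "training", block = 1L, trial = 1:3,
  pair = c("AB", "AB", "CD"),
  left_symbol = c("A", "B", "C"), right_symbol = c("B", "A", "D"),
  stringsAsFactors = FALSE)

mini_reward <- function(trial, symbol) {
  # arbitrary but fixed: A rewarded on trials 1-2, C on trial 3, others not
  as.integer((symbol == "A" & trial <= 2) | (symbol == "C" & trial == 3))
}

enumerate_sequences <- function(params) {
  probs <- numeric(8)
  combos <- expand.grid(c1 = 1:2, c2 = 1:2, c3 = 1:2)
  for (s in seq_len(nrow(combos))) {
    rec <- mini_schedule
    rec$participant_id <- "p1"
    pick <- as.integer(combos[s, ])
    rec$choice <- vapply(1:3, function(t)
      c(rec$left_symbol[t], rec$right_symbol[t])[pick[t]], "")
    rec$reward <- mini_reward(rec$trial, rec$choice)
    probs[s] <- exp(log_likelihood(params, rec, "training"))
  }
  probs
}

# small two-group cohort for fit-level tests
small_cohort <- function(n = 16, seed = 101, ...) {
  generate_cohort(cohort_config(n_participants = n, seed = seed, ...))
}

fast_mcmc <- function(seed = 1, loo_draws = 0)
  mcmc_config(chains = 2, warmup = 250, iter = 500, seed = seed,
              loo_draws = loo_draws)
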