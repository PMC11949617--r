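#' Specify which Q-learning model variant to fit
#'
#' @param learning_rates `"single"` or `"dual"`.
#' @param scope `"training"` (training choices only) or
#'   `"training_plus_test"` (log-density additionally incremented on
#'   feedback-free test choices with Q-values frozen at end of training;
#'   parameters from this scope are conventionally reported primed, e.g.
#'   `beta'`).
#' @param block_limit Integer `1..n_blocks` to restrict the likelihood to the
#'   first `block_limit` training blocks (used by the increasing-blocks
#'   analysis), or `NULL` for all blocks.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(learning_rates = c("dual", "single"),
                       scope = c("training", "training_plus_test"),
                       block_limit = NULL) {
  learning_rates <- match.arg(learning_rates)
  scope <- match.arg(scope)
  if (!is.null(block_limit)) {
    if (!is.numeric(block_limit) || block_limit < 1 ||
        block_limit != round(block_limit))
      stop_invalid("`block_limit` must be a positive integer or NULL")
    if (scope == "training_plus_test")
      stop_invalid("`block_limit` applies only to training-scope fits")
  }
  structure(list(learning_rates = learning_rates, scope = scope,
                 block_limit = block_limit), class = "model_spec")
}

spec_par_names <- function(spec) {
  if (spec$learning_rates == "single") c("alpha", "beta")
  else c("alpha_reward", "alpha_loss", "beta")
}

#' MCMC configuration for hierarchical fits
#'
#' Desk-scale defaults (4 chains, 600 warm-up + 1500 kept draws) keep a
#' 60-participant fit under a minute; publication-scale budgets are a matter
#' of raising `warmup`/`iter`.
#'
#' @param chains Number of chains (run sequentially, seeded `seed + 0:…`).
#' @param warmup Adaptation iterations discarded per chain.
#' @param iter Kept iterations per chain.
#' @param seed Base integer seed.
#' @param loo_draws Total number of kept draws (spread evenly across chains)
#'   at which per-trial log-likelihoods are stored for PSIS-LOO; `0` disables
#'   storage.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4, warmup = 600, iter = 1500, seed = 1,
                        loo_draws = 400) {
  if (chains < 1 || warmup < 1 || iter < 1)
    stop_invalid("`chains`, `warmup` and `iter` must be positive")
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter), seed = as.integer(seed),
                 loo_draws = as.integer(loo_draws)), class = "mcmc_config")
}

#' Fit the hierarchical Q-learning model to one experimental group
#'
#' Individual parameters follow a non-centred latent-normal construction:
#' `z_ip ~ N(0, 1)`, learning rates `= Phi(mu_p + sigma_p z_ip)` and inverse
#' temperature `= beta_cap * Phi(mu_p + sigma_p z_ip)`, with hyper-priors
#' `mu_p ~ N(0, 1)` and `sigma_p ~ half-N(0, s0_p)` (`s0 = 0.2` for learning
#' rates, `1` for the inverse temperature). Sampling uses adaptive
#' Metropolis-within-Gibbs (joint random-walk updates of each participant's
#' latent block, scalar updates of the hyper-parameters) with proposal-scale
#' adaptation confined to warm-up; chains are reproducible given the seed.
#'
#' Fits are per-group by design: hierarchical shrinkage is then estimated
#' within each arm, so group contrasts computed downstream are not diluted
#' by partial pooling across arms.
#'
#' @param trials Trial records for one group (all rows must share one group
#'   label), ordered within participant.
#' @param spec A [model_spec()].
#' @param mcmc An [mcmc_config()].
#' @param stim A [stimulus_set()].
#' @param beta_cap Upper bound of the inverse-temperature transform.
#' @return An object of class `pst_group_fit` carrying hyper-parameter and
#'   individual-level draws (natural scale), per-trial log-likelihood draws,
#'   and sampler metadata.
#' @export
fit_group <- function(trials, spec = model_spec(), mcmc = mcmc_config(),
                      stim = stimulus_set(), beta_cap = 10) {
  grp <- unique(trials$group)
  grp <- grp[!is.na(grp)]
  if (length(grp) != 1L)
    stop_invalid("all trial records must share a single group label")
  check_records(trials, stim)

  if (spec$scope == "training") {
    trials <- trials[trials$phase == "training", ]
    if (!is.null(spec$block_limit)) {
      if (spec$block_limit > max(trials$block))
        stop_invalid("`block_limit` exceeds the number of training blocks")
      trials <- trials[trials$block <= spec$block_limit, ]
    }
  } else if (!any(trials$phase == "test")) {
    stop_invalid("scope 'training_plus_test' requires test rows")
  }
  enc <- encode_trials(trials, stim)
  n_subj <- length(enc$ids)
  n_par <- length(spec_par_names(spec))
  sigma_prior <- c(rep(0.2, n_par - 1), 1.0)

  per_chain_loo <- if (mcmc$loo_draws > 0)
    max(1L, ceiling(mcmc$loo_draws / mcmc$chains)) else 0L
  loo_iters <- if (per_chain_loo > 0)
    unique(round(seq(1, mcmc$iter, length.out = min(per_chain_loo, mcmc$iter))))
  else integer(0)

  chains <- vector("list", mcmc$chains)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  for (ch in seq_len(mcmc$chains)) {
    set.seed(mcmc$seed + ch - 1L)
    chains[[ch]] <- cpp_fit_group(enc$pid, enc$phase, enc$chosen, enc$other,
                                  enc$reward, n_subj, n_par, mcmc$warmup,
                                  mcmc$iter, sigma_prior, beta_cap,
                                  as.integer(loo_iters))
  }

  par_names <- spec_par_names(spec)
  mu <- array(NA_real_, c(mcmc$iter, n_par, mcmc$chains),
              dimnames = list(NULL, par_names, NULL))
  sigma <- mu
  theta <- array(NA_real_, c(mcmc$iter, n_subj, n_par, mcmc$chains),
                 dimnames = list(NULL, enc$ids, par_names, NULL))
  for (ch in seq_len(mcmc$chains)) {
    mu[, , ch] <- chains[[ch]]$mu
    sigma[, , ch] <- chains[[ch]]$sigma
    theta[, , , ch] <- chains[[ch]]$theta
  }
  loo_ll <- if (length(loo_iters) > 0)
    do.call(rbind, lapply(chains, `[[`, "loo_ll")) else NULL

  structure(list(
    spec = spec, group = grp, participants = enc$ids, mu = mu, sigma = sigma,
    theta = theta, loo_ll = loo_ll,
    trial_info = trials[, c("participant_id", "phase", "block", "trial")],
    accept = list(z = mean(vapply(chains, `[[`, 0, "accept_z")),
                  hyper = mean(vapply(chains, `[[`, 0, "accept_hyper"))),
    mcmc = mcmc, beta_cap = beta_cap, stim = stim), class = "pst_group_fit")
}

#' @export
print.pst_group_fit <- function(x, ...) {
  cat(sprintf("Hierarchical Q-learning fit (%s learning rate, scope %s%s)\n",
              x$spec$learning_rates, x$spec$scope,
              if (!is.null(x$spec$block_limit))
                sprintf(", blocks 1..%d", x$spec$block_limit) else ""))
  cat(sprintf("  group: %s | %d participants | %d chains x %d draws\n",
              x$group, length(x$participants), x$mcmc$chains, x$mcmc$iter))
  hm <- apply(x$mu, 2, mean)
  hs <- apply(x$sigma, 2, mean)
  for (p in seq_along(hm))
    cat(sprintf("  %-13s latent mu = %6.3f, sigma = %5.3f\n",
                dimnames(x$mu)[[2]][p], hm[p], hs[p]))
  invisible(x)
}

#' Individual-level posterior summaries
#'
#' @param fit A [fit_group()] result.
#' @param prob Credible-interval mass for the reported bounds.
#' @return A `data.frame` with one row per participant x parameter:
#'   posterior mean, SD and central credible bounds.
#' @export
individual_means <- function(fit, prob = 0.95) {
  par_names <- dimnames(fit$theta)[[3]]
  lo_q <- (1 - prob) / 2
  rows <- list()
  for (p in seq_along(par_names)) {
    draws <- fit$theta[, , p, , drop = FALSE] # iter x subj x 1 x chain
    m <- apply(draws, 2, mean)
    s <- apply(draws, 2, sd)
    qs <- apply(draws, 2, quantile, probs = c(lo_q, 1 - lo_q))
    rows[[p]] <- data.frame(
      participant_id = fit$participants, parameter = par_names[p],
      mean = m, sd = s, lower = qs[1, ], upper = qs[2, ],
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$group <- fit$group
  out
}

#' Wide table of individual posterior means
#'
#' Convenience reshaping of [individual_means()] into one row per participant
#' with one column per parameter, the shape expected by
#' [fit_parameter_glm()].
#'
#' @inheritParams individual_means
#' @return A wide `data.frame`.
#' @export
parameter_table <- function(fit) {
  par_names <- dimnames(fit$theta)[[3]]
  out <- data.frame(participant_id = fit$participants, group = fit$group,
                    stringsAsFactors = FALSE)
  for (p in seq_along(par_names))
    out[[par_names[p]]] <- apply(fit$theta[, , p, , drop = FALSE], 2, mean)
  out
}

#' Posterior predictive simulation of choices
#'
#' For each replicate, one posterior draw is selected per participant and the
#' task is re-simulated through the forward model; per-pair, per-block
#' accuracy (probability of choosing the better symbol) is summarised across
#' participants, and uncertainty bands are taken across replicates.
#'
#' @param fit A [fit_group()] result.
#' @param training,test Schedules to simulate (test may be `NULL`).
#' @param n_rep Number of posterior replicates.
#' @param seed Integer seed.
#' @return List with `summary` (pair x block x phase bands across replicates)
#'   and `replicates` (per-replicate mean accuracies).
#' @export
posterior_predict <- function(fit, training, test = NULL, n_rep = 100,
                              seed = 1) {
  if (n_rep < 1) stop_invalid("`n_rep` must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  stim <- fit$stim
  better <- vapply(stim$training_pairs, `[`, "", 1)
  names(better) <- vapply(stim$training_pairs,
                          function(p) pair_label(p[1], p[2]), "")
  n_iter <- dim(fit$theta)[1]
  n_chain <- dim(fit$theta)[4]
  par_names <- dimnames(fit$theta)[[3]]
  sim_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 n_rep * length(fit$participants),
                                 replace = TRUE), n_rep)
  rep_rows <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    it <- sample.int(n_iter, 1)
    ch <- sample.int(n_chain, 1)
    recs <- vector("list", length(fit$participants))
    for (i in seq_along(fit$participants)) {
      th <- fit$theta[it, i, , ch]
      params <- if (length(par_names) == 2)
        agent_params("single", alpha = th[["alpha"]], beta = th[["beta"]])
      else
        agent_params("dual", alpha_reward = th[["alpha_reward"]],
                     alpha_loss = th[["alpha_loss"]], beta = th[["beta"]])
      recs[[i]] <- simulate_agent(params, training, test, stim,
                                  seed = sim_seeds[r, i],
                                  participant_id = fit$participants[i])
    }
    rec <- do.call(rbind, recs)
    rec_tr <- rec[rec$phase == "training", ]
    rec_tr$correct <- rec_tr$choice == better[rec_tr$pair]
    agg <- stats::aggregate(correct ~ pair + block, rec_tr, mean)
    agg$replicate <- r
    rep_rows[[r]] <- agg
  }
  reps <- do.call(rbind, rep_rows)
  bands <- do.call(rbind, lapply(split(reps, list(reps$pair, reps$block)),
    function(d) data.frame(pair = d$pair[1], block = d$block[1],
                           mean = mean(d$correct),
                           lower = unname(quantile(d$correct, 0.025)),
                           upper = unname(quantile(d$correct, 0.975)))))
  rownames(bands) <- NULL
  list(summary = bands, replicates = reps)
}

#' Long-format posterior draws
#'
#' Flattens a fit's hyper-parameter (and optionally individual-level) draws
#' into a tidy `data.frame` with columns `chain`, `draw`, `parameter`,
#' `value`, ready for `write.csv` or plotting.
#'
#' @param fit A [fit_group()] result.
#' @param include_individuals Also emit per-participant parameter draws
#'   (`parameter` then looks like `"beta[p0003]"`).
#' @return A long `data.frame`.
#' @export
tidy_draws <- function(fit, include_individuals = FALSE) {
  par_names <- dimnames(fit$mu)[[2]]
  n_iter <- dim(fit$mu)[1]
  n_chain <- dim(fit$mu)[3]
  out <- list()
  for (what in c("mu", "sigma")) {
    arr <- fit[[what]]
    for (p in seq_along(par_names)) {
      out[[length(out) + 1L]] <- data.frame(
        chain = rep(seq_len(n_chain), each = n_iter),
        draw = rep(seq_len(n_iter), n_chain),
        parameter = sprintf("%s_%s", what, par_names[p]),
        value = as.vector(arr[, p, ]), stringsAsFactors = FALSE)
    }
  }
  if (include_individuals) {
    for (p in seq_along(par_names)) {
      for (i in seq_along(fit$participants)) {
        out[[length(out) + 1L]] <- data.frame(
          chain = rep(seq_len(n_chain), each = n_iter),
          draw = rep(seq_len(n_iter), n_chain),
          parameter = sprintf("%s[%s]", par_names[p], fit$participants[i]),
          value = as.vector(fit$theta[, i, p, ]), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
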