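#' PSIS-LOO estimate of out-of-sample predictive accuracy
#'
#' Computes the expected log pointwise predictive density (ELPD) by
#' Pareto-smoothed importance sampling: per data point, the importance
#' ratios `1 / p(y_i | theta_s)` are tail-smoothed by a generalised Pareto
#' fit (Zhang–Stephens estimator) to the largest `min(0.2 S, 3 sqrt(S))`
#' weights, truncated at the raw maximum. `LOOIC = -2 * ELPD` by definition.
#' The leave-one-out unit is the individual trial.
#'
#' @param log_lik Matrix of pointwise log-likelihoods, draws x data points,
#'   or a [fit_group()] result with stored log-likelihood draws.
#' @return An object of class `pst_loo`: `elpd`, `se`, `looic`, `pointwise`
#'   ELPD contributions and per-point Pareto `k` values.
#' @export
compute_loo <- function(log_lik) {
  if (inherits(log_lik, "pst_group_fit")) {
    if (is.null(log_lik$loo_ll))
      stop_invalid("fit carries no log-likelihood draws (loo_draws = 0)")
    log_lik <- log_lik$loo_ll
  }
  log_lik <- as.matrix(log_lik)
  if (!all(is.finite(log_lik)))
    stop_data_integrity("log-likelihood draws must all be finite")
  S <- nrow(log_lik)
  N <- ncol(log_lik)
  pointwise <- numeric(N)
  k_hat <- rep(NA_real_, N)
  for (i in seq_len(N)) {
    ll <- log_lik[, i]
    sm <- psis_smooth(-ll)
    lw <- sm$lw
    pointwise[i] <- logsumexp(ll + lw) - logsumexp(lw)
    k_hat[i] <- sm$k
  }
  elpd <- sum(pointwise)
  se <- sqrt(N * var(pointwise))
  structure(list(elpd = elpd, se = se, looic = -2 * elpd,
                 looic_se = 2 * se, pointwise = pointwise, pareto_k = k_hat,
                 n_draws = S, n_points = N), class = "pst_loo")
}

#' @export
print.pst_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO over %d points (%d draws)\n", x$n_points, x$n_draws))
  cat(sprintf("  ELPD  %10.1f (SE %.1f)\n", x$elpd, x$se))
  cat(sprintf("  LOOIC %10.1f (SE %.1f)\n", x$looic, x$looic_se))
  bad <- sum(x$pareto_k > 0.7, na.rm = TRUE)
  if (bad > 0) cat(sprintf("  %d point(s) with Pareto k > 0.7\n", bad))
  invisible(x)
}

# Pareto-smoothed log importance weights for one data point.
# lw_raw: raw log ratios (-log-likelihood up to a constant).
psis_smooth <- function(lw_raw) {
  S <- length(lw_raw)
  lw <- lw_raw - max(lw_raw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5 || S < 16) return(list(lw = lw, k = NA_real_))
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- lw[ord[S - M]]
  exceed <- exp(lw[tail_ids]) - exp(cutoff)
  if (max(exceed) <= 0) return(list(lw = lw, k = NA_real_))
  fit <- gpd_fit(exceed)
  if (!is.finite(fit$k)) return(list(lw = lw, k = fit$k))
  # replace tail by expected order statistics of the fitted GPD
  p <- (seq_len(M) - 0.5) / M
  q <- gpd_quantile(p, fit$k, fit$sigma)
  smoothed <- log(exp(cutoff) + q)
  smoothed <- pmin(smoothed, 0) # truncate at the raw maximum (= 0 after shift)
  lw[tail_ids[order(lw[tail_ids])]] <- smoothed
  list(lw = lw, k = fit$k)
}

# Zhang & Stephens (2009) quasi-Bayesian generalised Pareto fit with the
# usual weakly-informative shrinkage of k for small tails
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  k_j <- vapply(theta, function(t) mean(log1p(-t * x)), 0)
  l_j <- n * (log(-theta / k_j) - k_j - 1)
  w <- vapply(jj, function(j) 1 / sum(exp(l_j - l_j[j])), 0)
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  # weak prior pulling k towards 0.5 in small tails
  k <- k * n / (n + 10) + 0.5 * 10 / (n + 10)
  list(k = k, sigma = sigma)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

#' Compare two fitted models by ELPD difference
#'
#' Both fits must carry pointwise log-likelihood draws over identical data.
#' The reported difference is `ELPD(model1) - ELPD(model2)` (positive favours
#' the first model) with the paired standard error over pointwise
#' contributions.
#'
#' @param fit1,fit2 [fit_group()] results (by convention the richer model,
#'   e.g. dual learning rate, first), or `pst_loo` objects over the same
#'   points.
#' @return An object of class `pst_model_comparison`.
#' @export
compare_models <- function(fit1, fit2) {
  get_loo <- function(f) if (inherits(f, "pst_loo")) f else compute_loo(f)
  check_same <- function(a, b) {
    if (inherits(a, "pst_group_fit") && inherits(b, "pst_group_fit")) {
      if (!identical(a$trial_info, b$trial_info))
        stop_invalid("models were not fit to identical data")
      if (a$spec$scope != b$spec$scope)
        stop_invalid("models were not fit with the same scope")
    }
  }
  check_same(fit1, fit2)
  l1 <- get_loo(fit1)
  l2 <- get_loo(fit2)
  if (l1$n_points != l2$n_points)
    stop_invalid("pointwise log-likelihoods cover different numbers of points")
  d <- l1$pointwise - l2$pointwise
  diff <- sum(d)
  se <- sqrt(length(d) * var(d))
  structure(list(elpd = c(model1 = l1$elpd, model2 = l2$elpd),
                 elpd_se = c(model1 = l1$se, model2 = l2$se),
                 looic = c(model1 = l1$looic, model2 = l2$looic),
                 elpd_diff = diff, elpd_diff_se = se,
                 pareto_k_high = c(model1 = sum(l1$pareto_k > 0.7, na.rm = TRUE),
                                   model2 = sum(l2$pareto_k > 0.7, na.rm = TRUE))),
            class = "pst_model_comparison")
}

#' @export
print.pst_model_comparison <- function(x, ...) {
  cat("Model comparison (positive ELPD difference favours model 1)\n")
  cat(sprintf("  ELPD:  %.1f vs %.1f | LOOIC: %.1f vs %.1f\n",
              x$elpd[1], x$elpd[2], x$looic[1], x$looic[2]))
  cat(sprintf("  ELPD difference: %.2f (SE %.2f)\n", x$elpd_diff,
              x$elpd_diff_se))
  invisible(x)
}

#' Parameter-recovery harness for the simulate-fit loop
#'
#' Simulates cohorts from known parameters, fits each experimental group
#' hierarchically, and tabulates true versus estimated individual-level
#' parameters: Pearson correlation, bias, RMSE and 95% credible-interval
#' coverage per parameter (pooled over groups and replicates).
#'
#' @param spec A [model_spec()] describing the fitted model.
#' @param config A [cohort_config()] for the simulated cohorts.
#' @param n_rep Number of simulate-fit replicates.
#' @param mcmc An [mcmc_config()].
#' @param seed Seed offsetting the per-replicate cohort seeds.
#' @return An object of class `pst_recovery_report` with `summary` (one row
#'   per parameter) and `pairs` (all true/estimated pairs).
#' @export
run_recovery <- function(spec = model_spec(), config = cohort_config(),
                         n_rep = 1, mcmc = mcmc_config(), seed = 1) {
  if (n_rep < 1) stop_invalid("`n_rep` must be >= 1")
  pair_rows <- list()
  for (r in seq_len(n_rep)) {
    cfg <- config
    cfg$seed <- seed + 7919L * (r - 1L)
    cohort <- generate_cohort(cfg)
    for (g in unique(cohort$participants$group)) {
      tr <- cohort$trials[cohort$trials$group == g, ]
      m <- mcmc
      m$seed <- mcmc$seed + 131L * (r - 1L) + as.integer(g == "distanced")
      fit <- tryCatch(fit_group(tr, spec, m),
                      error = function(e)
                        stop(sprintf("replicate %d (%s): %s", r, g,
                                     conditionMessage(e)), call. = FALSE))
      est <- individual_means(fit)
      truth <- cohort$truth
      truth_long <- data.frame(
        participant_id = rep(truth$participant_id, 3),
        parameter = rep(c("alpha_reward", "alpha_loss", "beta"),
                        each = nrow(truth)),
        true = c(truth$alpha_reward, truth$alpha_loss, truth$beta),
        stringsAsFactors = FALSE)
      if (spec$learning_rates == "single") {
        # single-model alpha is compared against the generating reward rate
        truth_long$parameter[truth_long$parameter == "alpha_reward"] <- "alpha"
        truth_long <- truth_long[truth_long$parameter != "alpha_loss", ]
      }
      est <- merge(est, truth_long, by = c("participant_id", "parameter"))
      est$replicate <- r
      pair_rows[[length(pair_rows) + 1L]] <- est
    }
  }
  pairs <- do.call(rbind, pair_rows)
  summary <- do.call(rbind, lapply(split(pairs, pairs$parameter), function(d)
    data.frame(parameter = d$parameter[1],
               correlation = stats::cor(d$true, d$mean),
               bias = mean(d$mean - d$true),
               rmse = sqrt(mean((d$mean - d$true)^2)),
               coverage95 = mean(d$true >= d$lower & d$true <= d$upper),
               n = nrow(d), stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  structure(list(summary = summary, pairs = pairs), class = "pst_recovery_report")
}

#' @export
print.pst_recovery_report <- function(x, ...) {
  cat("Parameter recovery (true vs posterior-mean individual values)\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
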