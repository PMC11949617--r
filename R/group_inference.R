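#' Highest density interval of a set of draws
#'
#' Empirical shortest interval containing the requested posterior mass.
#'
#' @param draws Numeric vector of posterior draws.
#' @param mass Probability mass in (0, 1).
#' @return Length-2 numeric vector `(lower, upper)`.
#' @examples
#' compute_hdi(rnorm(4000), 0.95)
#' @export
compute_hdi <- function(draws, mass = 0.95) {
  if (!is.numeric(mass) || length(mass) != 1 || mass <= 0 || mass >= 1)
    stop_invalid("`mass` must lie strictly in (0, 1)")
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 2) stop_invalid("need at least 2 finite draws")
  x <- sort(draws)
  keep <- max(1L, ceiling(mass * n))
  if (keep >= n) return(c(x[1], x[n]))
  starts <- seq_len(n - keep)
  widths <- x[starts + keep] - x[starts]
  s <- which.min(widths)
  c(x[s], x[s + keep])
}

# --- generic component-wise adaptive Metropolis ----------------------------
# log_post: function(par) -> scalar; deterministic under set.seed
amh_chain <- function(log_post, init, n_warmup, n_iter, scale0 = 0.5) {
  k <- length(init)
  par <- init
  lp <- log_post(par)
  if (!is.finite(lp)) stop_invalid("initial value has zero posterior density")
  s <- rep(scale0, k)
  draws <- matrix(NA_real_, n_iter, k)
  total <- n_warmup + n_iter
  for (it in seq_len(total)) {
    eta <- if (it <= n_warmup) it^-0.6 else 0
    for (j in seq_len(k)) {
      cand <- par
      cand[j] <- par[j] + s[j] * rnorm(1)
      lp_new <- log_post(cand)
      acc <- if (is.finite(lp_new)) min(1, exp(lp_new - lp)) else 0
      if (runif(1) < acc) {
        par <- cand
        lp <- lp_new
      }
      if (eta > 0) s[j] <- s[j] * exp(eta * (acc - 0.44))
    }
    if (it > n_warmup) draws[it - n_warmup, ] <- par
  }
  draws
}

#' Bayesian GLM relating a learning parameter to a predictor
#'
#' Fits `outcome ~ predictor + covariates` with either a gamma family and
#' log link (for positively-skewed learning-rate outcomes; the predictor
#' effect is then also reported as a multiplier, `exp` of the coefficient
#' applied per draw) or a gaussian family with identity link (for inverse
#' temperatures). Coefficient priors are weakly informative normals centred
#' at zero with scale `2.5 * sd(link-scale outcome) / sd(x)` (autoscaled, in
#' the style of common Bayesian regression defaults); the gamma shape has an
#' exponential(1) prior and the gaussian residual SD an exponential prior
#' with rate `1 / sd(y)`. Sampling is component-wise adaptive
#' Metropolis-Hastings, reproducible given `seed`.
#'
#' Continuous covariates are standardised internally; the focal predictor is
#' left on its natural scale so its coefficient is interpretable per unit
#' (or per group indicator).
#'
#' @param data Data frame of individual-level posterior means plus
#'   covariates.
#' @param outcome Name of the outcome column (a learning parameter).
#' @param predictor Name of the focal predictor column (group indicator or a
#'   factor score).
#' @param family `"gamma-log"` or `"gaussian-identity"`.
#' @param covariates Adjustment covariate column names; zero-variance
#'   covariates are dropped with a warning.
#' @param chains,warmup,iter,seed MCMC controls.
#' @return An object of class `glm_effect` with coefficient draws, posterior
#'   mean, 95% and 99% HDIs and (for log links) the multiplier scale.
#' @export
fit_parameter_glm <- function(data, outcome, predictor,
                              family = c("gamma-log", "gaussian-identity"),
                              covariates = c("age", "gender", "digit_span"),
                              chains = 2, warmup = 500, iter = 1000,
                              seed = 1) {
  family <- match.arg(family)
  for (col in c(outcome, predictor, covariates))
    if (!col %in% names(data))
      stop_invalid(sprintf("column '%s' missing from `data`", col))
  y <- data[[outcome]]
  if (anyNA(y)) stop_invalid("outcome contains missing values")
  if (family == "gamma-log" && any(y <= 0))
    stop_data_integrity("gamma-log family requires strictly positive outcomes")

  to_numeric <- function(v) {
    if (is.character(v) || is.factor(v)) as.numeric(factor(v)) - 1 else as.numeric(v)
  }
  x_focal <- to_numeric(data[[predictor]])
  X <- cbind(`(Intercept)` = 1, focal = x_focal)
  colnames(X)[2] <- predictor
  for (cv in covariates) {
    v <- to_numeric(data[[cv]])
    if (anyNA(v)) stop_invalid(sprintf("covariate '%s' contains missing values", cv))
    if (sd(v) < 1e-12) {
      warning(sprintf("covariate '%s' has zero variance; dropped", cv))
      next
    }
    X <- cbind(X, (v - mean(v)) / sd(v))
    colnames(X)[ncol(X)] <- cv
  }
  if (sd(x_focal) < 1e-12) stop_invalid("focal predictor has zero variance")
  k <- ncol(X)

  y_link <- if (family == "gamma-log") log(y) else y
  prior_loc <- c(mean(y_link), rep(0, k - 1))
  prior_scale <- c(10 * max(sd(y_link), 1e-3),
                   2.5 * sd(y_link) / apply(X[, -1, drop = FALSE], 2, sd))
  sd_y <- sd(y)

  if (family == "gamma-log") {
    log_post <- function(par) {
      b <- par[1:k]
      nu <- exp(par[k + 1])
      mu <- exp(drop(X %*% b))
      sum(dgamma(y, shape = nu, rate = nu / mu, log = TRUE)) +
        sum(dnorm(b, prior_loc, prior_scale, log = TRUE)) +
        (-nu) + par[k + 1] # exponential(1) prior on nu + log-Jacobian
    }
    init <- c(mean(y_link), rep(0, k - 1), log(5))
  } else {
    log_post <- function(par) {
      b <- par[1:k]
      sig <- exp(par[k + 1])
      mu <- drop(X %*% b)
      sum(dnorm(y, mu, sig, log = TRUE)) +
        sum(dnorm(b, prior_loc, prior_scale, log = TRUE)) +
        (-sig / sd_y) + par[k + 1] # exponential(1/sd_y) prior + Jacobian
    }
    init <- c(mean(y), rep(0, k - 1), log(sd_y))
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  chain_draws <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(seed + ch - 1L)
    chain_draws[[ch]] <- amh_chain(log_post, init, warmup, iter, scale0 = 0.2)
  }
  draws <- do.call(rbind, chain_draws)
  colnames(draws) <- c(colnames(X), if (family == "gamma-log") "log_shape"
                       else "log_sigma")
  focal <- draws[, predictor]
  focal_mat <- sapply(chain_draws, function(d) d[, 2])
  out <- list(
    outcome = outcome, predictor = predictor, family = family,
    coef_names = colnames(X), draws = draws, coef_draws = focal,
    mean = mean(focal), hdi95 = compute_hdi(focal, 0.95),
    hdi99 = compute_hdi(focal, 0.99), rhat_focal = split_rhat(focal_mat),
    n = nrow(X))
  if (family == "gamma-log") {
    mult <- exp(focal)
    out$multiplier_mean <- mean(mult)
    out$multiplier_hdi95 <- compute_hdi(mult, 0.95)
    out$multiplier_hdi99 <- compute_hdi(mult, 0.99)
    out$exp_mean_coef <- exp(mean(focal))
  }
  structure(out, class = "glm_effect")
}

#' @export
print.glm_effect <- function(x, ...) {
  cat(sprintf("Bayesian GLM (%s): %s ~ %s + covariates, n = %d\n",
              x$family, x$outcome, x$predictor, x$n))
  cat(sprintf("  coefficient: %.3f  95%% HDI (%.3f, %.3f)  99%% HDI (%.3f, %.3f)\n",
              x$mean, x$hdi95[1], x$hdi95[2], x$hdi99[1], x$hdi99[2]))
  if (!is.null(x$multiplier_mean))
    cat(sprintf("  multiplier:  %.3f  95%% HDI (%.3f, %.3f)\n",
                x$multiplier_mean, x$multiplier_hdi95[1], x$multiplier_hdi95[2]))
  if (is.finite(x$rhat_focal) && x$rhat_focal > 1.1)
    cat(sprintf("  warning: focal-coefficient R-hat %.2f\n", x$rhat_focal))
  invisible(x)
}

#' Temporal-emergence analysis over increasing numbers of training blocks
#'
#' For each `k = 1..k_max`, fits the dual learning rate model separately per
#' group to trials from blocks `1..k` (all earlier trials are always
#' included, as the start of training is the only point at which all
#' Q-values can be assumed zero), then runs group-difference GLMs per
#' parameter: gamma-log for the learning rates, gaussian for the inverse
#' temperature.
#'
#' @param trials Trial records for both groups.
#' @param covariates Participant covariate table (must include
#'   `participant_id` and the GLM adjustment covariates).
#' @param k_max Largest number of blocks to include.
#' @param mcmc An [mcmc_config()] used for every per-group fit.
#' @param glm_args List of extra arguments passed to [fit_parameter_glm()].
#' @return An object of class `blockwise_effects`: a data.frame of effect
#'   summaries per (k, parameter) plus the underlying `glm_effect` objects.
#' @export
increasing_blocks_analysis <- function(trials, covariates, k_max = 6,
                                       mcmc = mcmc_config(),
                                       glm_args = list()) {
  n_blocks <- max(trials$block[trials$phase == "training"])
  if (k_max > n_blocks)
    stop_invalid("`k_max` exceeds the number of training blocks")
  effects <- list()
  rows <- list()
  for (k in seq_len(k_max)) {
    spec <- model_spec("dual", "training", block_limit = k)
    tabs <- list()
    for (g in unique(trials$group)) {
      m <- mcmc
      m$seed <- mcmc$seed + 17L * k + as.integer(g == "distanced")
      fit <- fit_group(trials[trials$group == g, ], spec, m)
      tabs[[g]] <- parameter_table(fit)
    }
    tab <- do.call(rbind, tabs)
    tab$distanced <- as.integer(tab$group == "distanced")
    tab <- merge(tab, covariates[, setdiff(names(covariates), "group")],
                 by = "participant_id")
    for (par in c("alpha_reward", "alpha_loss", "beta")) {
      fam <- if (par == "beta") "gaussian-identity" else "gamma-log"
      eff <- do.call(fit_parameter_glm,
                     c(list(data = tab, outcome = par,
                            predictor = "distanced", family = fam,
                            seed = mcmc$seed + 23L * k), glm_args))
      effects[[sprintf("k%d_%s", k, par)]] <- eff
      rows[[length(rows) + 1L]] <- data.frame(
        k = k, parameter = par, mean = eff$mean,
        hdi95_lo = eff$hdi95[1], hdi95_hi = eff$hdi95[2],
        hdi99_lo = eff$hdi99[1], hdi99_hi = eff$hdi99[2],
        multiplier_mean = if (!is.null(eff$multiplier_mean))
          eff$multiplier_mean else NA_real_, stringsAsFactors = FALSE)
    }
  }
  structure(list(summary = do.call(rbind, rows), effects = effects),
            class = "blockwise_effects")
}

#' @export
print.blockwise_effects <- function(x, ...) {
  cat("Group effects from fits to increasing numbers of training blocks\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
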