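#' MCMC convergence diagnostics
#'
#' Rank-normalised split-chain R-hat and bulk effective sample size, computed
#' per parameter (hyper-parameters and every individual-level parameter) and
#' aggregated per individual as the worst R-hat / smallest bulk ESS over that
#' individual's parameters.
#'
#' @param fit A [fit_group()] result (at least 2 chains).
#' @return An object of class `pst_diagnostics`: `hyper` and `individual`
#'   parameter tables plus `per_individual` aggregates.
#' @export
diagnose <- function(fit) {
  n_chain <- dim(fit$mu)[3]
  if (n_chain < 2) stop_invalid("diagnostics require at least 2 chains")
  par_names <- dimnames(fit$mu)[[2]]

  hyper_rows <- list()
  for (p in seq_along(par_names)) {
    for (what in c("mu", "sigma")) {
      draws <- fit[[what]][, p, ] # iter x chain
      hyper_rows[[length(hyper_rows) + 1L]] <- data.frame(
        parameter = sprintf("%s_%s", what, par_names[p]),
        rhat = split_rhat(draws), ess_bulk = ess_bulk(draws),
        stringsAsFactors = FALSE)
    }
  }
  hyper <- do.call(rbind, hyper_rows)

  n_subj <- dim(fit$theta)[2]
  indiv <- expand.grid(participant_id = fit$participants,
                       parameter = par_names, stringsAsFactors = FALSE)
  indiv$rhat <- NA_real_
  indiv$ess_bulk <- NA_real_
  k <- 1L
  for (p in seq_along(par_names)) {
    for (i in seq_len(n_subj)) {
      draws <- fit$theta[, i, p, ]
      row <- which(indiv$participant_id == fit$participants[i] &
                     indiv$parameter == par_names[p])
      indiv$rhat[row] <- split_rhat(draws)
      indiv$ess_bulk[row] <- ess_bulk(draws)
    }
  }
  agg <- do.call(rbind, lapply(split(indiv, indiv$participant_id), function(d)
    data.frame(participant_id = d$participant_id[1],
               worst_rhat = max(d$rhat), min_ess_bulk = min(d$ess_bulk),
               stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  structure(list(hyper = hyper, individual = indiv, per_individual = agg),
            class = "pst_diagnostics")
}

#' @export
print.pst_diagnostics <- function(x, ...) {
  cat("MCMC diagnostics (rank-normalised split chains)\n")
  cat(sprintf("  hyper-parameters: max R-hat %.3f, min bulk ESS %.0f\n",
              max(x$hyper$rhat), min(x$hyper$ess_bulk)))
  cat(sprintf("  individuals:      max R-hat %.3f, min bulk ESS %.0f\n",
              max(x$per_individual$worst_rhat),
              min(x$per_individual$min_ess_bulk)))
  invisible(x)
}

# --- rank-normalised split-chain machinery ---------------------------------

split_chain_matrix <- function(x) {
  # x: iter x chain -> (iter/2) x (2*chain), dropping an odd final draw
  n <- nrow(x)
  half <- floor(n / 2)
  cbind(x[seq_len(half), , drop = FALSE],
        x[(n - half + 1):n, , drop = FALSE])
}

rank_normalize <- function(x) {
  r <- rank(x, ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  matrix(z, nrow(x), ncol(x))
}

rhat_basic <- function(x) {
  # x: iter x chain (already split)
  n <- nrow(x)
  if (n < 2) return(NA_real_)
  chain_means <- colMeans(x)
  chain_vars <- apply(x, 2, var)
  W <- mean(chain_vars)
  B <- n * var(chain_means)
  if (W < 1e-300) return(1)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

#' Split R-hat of a set of chains
#'
#' Rank-normalised split-chain potential scale reduction factor: the maximum
#' of the bulk statistic and the statistic of the folded (median-absolute)
#' draws, following the rank-normalisation construction of modern MCMC
#' diagnostics.
#'
#' @param x Matrix of draws, iterations x chains.
#' @return Scalar R-hat.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  if (all(abs(x - x[1]) < 1e-300)) return(1)
  s <- split_chain_matrix(x)
  bulk <- rhat_basic(rank_normalize(s))
  folded <- rhat_basic(rank_normalize(abs(s - median(s))))
  max(bulk, folded)
}

ess_basic <- function(x) {
  # Geyer initial-monotone-positive-sequence ESS on split chains
  n <- nrow(x)
  m <- ncol(x)
  if (n < 4) return(NA_real_)
  chain_vars <- apply(x, 2, var)
  W <- mean(chain_vars)
  B <- n * var(colMeans(x))
  var_plus <- (n - 1) / n * W + B / n
  if (var_plus < 1e-300) return(n * m)
  # mean autocovariance across chains (denominator n, as in acf)
  acov <- sapply(seq_len(m), function(c)
    acf(x[, c], lag.max = n - 1, type = "covariance",
        plot = FALSE, demean = TRUE)$acf[, 1, 1])
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus # rho[1] is lag 0 (~1)
  # sum of paired autocorrelations (lags 0+1, 2+3, ...), truncated at the
  # first negative pair and forced monotone non-increasing
  S <- 0
  k <- 0
  prev_pair <- Inf
  while (2 * k + 2 <= length(rho)) {
    pair <- rho[2 * k + 1] + rho[2 * k + 2]
    if (pair < 0) break
    pair <- min(pair, prev_pair)
    S <- S + pair
    prev_pair <- pair
    k <- k + 1
  }
  tau <- max(-1 + 2 * S, 1 / log10(n * m + 10))
  ess <- n * m / tau
  min(ess, n * m * log10(n * m))
}

#' Bulk effective sample size
#'
#' Effective sample size of the rank-normalised split chains, using mean
#' within-chain autocovariances combined by Geyer's initial monotone
#' positive sequence.
#'
#' @inheritParams split_rhat
#' @return Scalar ESS estimate.
#' @export
ess_bulk <- function(x) {
  x <- as.matrix(x)
  if (all(abs(x - x[1]) < 1e-300)) return(nrow(x) * ncol(x))
  ess_basic(rank_normalize(split_chain_matrix(x)))
}

#' Drop individuals whose parameters failed to converge
#'
#' Individuals with split R-hat at or above `rhat_max`, or bulk ESS below
#' `ess_min`, on any of their parameters are removed from the posterior's
#' individual-level draws (hyper-parameter draws are untouched).
#'
#' @param fit A [fit_group()] result.
#' @param diagnostics The matching [diagnose()] output (computed if `NULL`).
#' @param rhat_max,ess_min Convergence thresholds.
#' @return List with `fit` (individuals removed) and `log` (flagged
#'   individuals and the offending statistics).
#' @export
exclude_unconverged <- function(fit, diagnostics = NULL, rhat_max = 1.1,
                                ess_min = 100) {
  if (is.null(diagnostics)) diagnostics <- diagnose(fit)
  agg <- diagnostics$per_individual
  if (!setequal(agg$participant_id, fit$participants))
    stop_invalid("diagnostics do not match the posterior's participants")
  bad <- agg$worst_rhat >= rhat_max | agg$min_ess_bulk < ess_min
  flagged <- agg[bad, , drop = FALSE]
  if (any(bad)) {
    keep <- !(fit$participants %in% flagged$participant_id)
    fit$theta <- fit$theta[, keep, , , drop = FALSE]
    fit$participants <- fit$participants[keep]
  }
  list(fit = fit, log = flagged)
}
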