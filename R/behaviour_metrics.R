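#' Training-phase accuracy tables and block-lagged learning curves
#'
#' "Correct" means choosing the symbol with the higher reward probability in
#' its pair (canonically A, C or E). Returns per-participant, per-pair,
#' per-block accuracy plus a trailing-window ("block-lagged") cumulative
#' curve: at each presentation of a pair, the proportion correct over that
#' pair's last `lag` presentations (one block's worth by default).
#'
#' @param trials Training-phase trial records.
#' @param stim A [stimulus_set()].
#' @param lag Trailing window length in presentations of the pair.
#' @return List with `blocks` (participant x pair x block accuracy) and
#'   `lagged` (participant x pair x presentation trailing accuracy, defined
#'   from presentation `lag` onwards).
#' @export
training_accuracy <- function(trials, stim = stimulus_set(), lag = 20) {
  if (any(trials$phase != "training"))
    stop_invalid("`trials` must contain training rows only")
  better <- vapply(stim$training_pairs, `[`, "", 1)
  names(better) <- vapply(stim$training_pairs,
                          function(p) pair_label(p[1], p[2]), "")
  if (!all(trials$pair %in% names(better)))
    stop_invalid("training trials contain non-training pairs")
  trials$correct <- as.integer(trials$choice == better[trials$pair])

  blocks <- stats::aggregate(correct ~ participant_id + pair + block, trials,
                             function(z) c(n = length(z), acc = mean(z)))
  blocks <- data.frame(blocks[1:3], n_trials = blocks$correct[, "n"],
                       accuracy = blocks$correct[, "acc"],
                       stringsAsFactors = FALSE)

  lag_rows <- lapply(split(trials, list(trials$participant_id, trials$pair),
                           drop = TRUE), function(d) {
    d <- d[order(d$block, d$trial), ]
    cs <- cumsum(d$correct)
    m <- nrow(d)
    if (m < lag) return(NULL)
    idx <- lag:m
    acc <- (cs[idx] - c(0, cs)[idx - lag + 1]) / lag
    data.frame(participant_id = d$participant_id[1], pair = d$pair[1],
               presentation = idx, accuracy = acc, stringsAsFactors = FALSE)
  })
  lagged <- do.call(rbind, lag_rows)
  rownames(lagged) <- NULL
  list(blocks = blocks, lagged = lagged)
}

#' Test-phase accuracy by pair category
#'
#' "Correct" is choosing the symbol of each pair that was most often correct
#' during training, i.e. the one with the higher training reward probability
#' (within C/E, choosing C). Pairs are grouped by [categorize_pair()]
#' category.
#'
#' @param trials Test-phase trial records.
#' @param stim A [stimulus_set()].
#' @return Data frame of participant x category accuracies with trial counts.
#' @export
test_accuracy <- function(trials, stim = stimulus_set()) {
  if (any(trials$phase != "test"))
    stop_invalid("`trials` must contain test rows only")
  pairs <- all_pairs(stim)
  if (!all(trials$pair %in% pairs$pair))
    stop_invalid("unknown pair in test trials")
  cat_of <- vapply(seq_len(nrow(pairs)), function(i)
    categorize_pair(c(pairs$sym1[i], pairs$sym2[i]), stim), "")
  names(cat_of) <- pairs$pair
  best_of <- vapply(seq_len(nrow(pairs)), function(i) {
    s <- c(pairs$sym1[i], pairs$sym2[i])
    s[which.max(stim$reward_probs[s])]
  }, "")
  names(best_of) <- pairs$pair
  trials$category <- unname(cat_of[trials$pair])
  trials$correct <- as.integer(trials$choice == best_of[trials$pair])
  agg <- stats::aggregate(correct ~ participant_id + category, trials,
                          function(z) c(n = length(z), acc = mean(z)))
  data.frame(agg[1:2], n_trials = agg$correct[, "n"],
             accuracy = agg$correct[, "acc"], stringsAsFactors = FALSE)
}

# tie-corrected within-stratum rank statistics for two groups
stratum_stats <- function(values, groups, g1) {
  r <- rank(values)
  n <- length(values)
  n1 <- sum(groups == g1)
  n2 <- n - n1
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  R1 <- sum(r[groups == g1])
  E1 <- n1 * (n + 1) / 2
  V1 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  list(R1 = R1, E1 = E1, V1 = V1, n = n)
}

stratified_stat <- function(values, groups, strata, g1) {
  Tsum <- 0
  Vsum <- 0
  for (s in unique(strata)) {
    in_s <- strata == s
    st <- stratum_stats(values[in_s], groups[in_s], g1)
    w <- 1 / (st$n + 1)
    Tsum <- Tsum + w * (st$R1 - st$E1)
    Vsum <- Vsum + w^2 * st$V1
  }
  if (Vsum <= 0) return(0)
  Tsum^2 / Vsum
}

#' Stratified Kruskal-Wallis test of a group difference
#'
#' Per-outcome mode computes a van-Elteren-style statistic for two groups:
#' within-stratum rank sums are centred, weighted by `1/(n_s + 1)` and
#' combined, and the squared standardised sum is referred to a chi-square
#' distribution on 1 degree of freedom (with tie correction). With a single
#' stratum this equals the ordinary tie-corrected Kruskal-Wallis statistic.
#' Omnibus mode sums the per-outcome statistics across several outcomes and
#' obtains its p-value from a permutation null in which group labels are
#' permuted within strata (rows of the outcome matrix stay together).
#'
#' @param values Numeric vector (per-outcome mode) or matrix/data.frame with
#'   one column per outcome (omnibus mode).
#' @param groups Two-level group labels.
#' @param strata Stratum labels (e.g. training block).
#' @param mode `"per-outcome"` or `"omnibus-permutation"`.
#' @param n_perm Number of label permutations for the omnibus null.
#' @param seed Seed for the permutation draw.
#' @return An object of class `stratified_kw` with `statistic`, `df`,
#'   `p_value` and per-stratum contributions.
#' @export
stratified_kruskal_wallis <- function(values, groups, strata,
                                      mode = c("per-outcome",
                                               "omnibus-permutation"),
                                      n_perm = 999, seed = 1) {
  mode <- match.arg(mode)
  vm <- as.matrix(values)
  groups <- as.character(groups)
  strata <- as.character(strata)
  if (nrow(vm) != length(groups) || length(groups) != length(strata))
    stop_invalid("`values`, `groups` and `strata` must have matching lengths")
  lev <- unique(groups)
  if (length(lev) != 2)
    stop_invalid("exactly two groups are required")
  for (s in unique(strata)) {
    if (length(unique(groups[strata == s])) < 2)
      stop_invalid(sprintf("stratum '%s' does not contain both groups", s))
  }
  g1 <- lev[1]

  if (mode == "per-outcome") {
    if (ncol(vm) != 1)
      stop_invalid("per-outcome mode expects a single outcome vector")
    contrib <- vapply(unique(strata), function(s) {
      in_s <- strata == s
      st <- stratum_stats(vm[in_s, 1], groups[in_s], g1)
      (st$R1 - st$E1) / (st$n + 1)
    }, 0)
    stat <- stratified_stat(vm[, 1], groups, strata, g1)
    out <- list(statistic = stat, df = 1,
                p_value = pchisq(stat, 1, lower.tail = FALSE),
                per_stratum = contrib, mode = mode)
  } else {
    # precompute per-stratum ranks and moments once; permutations then only
    # redraw which rows within each stratum belong to group 1
    strat_idx <- split(seq_along(strata), strata)
    pre <- lapply(strat_idx, function(idx) {
      n <- length(idx)
      n1 <- sum(groups[idx] == g1)
      per_outcome <- lapply(seq_len(ncol(vm)), function(j) {
        v <- vm[idx, j]
        r <- rank(v)
        ties <- table(v)
        list(r = r,
             V1 = n1 * (n - n1) / 12 *
               ((n + 1) - sum(ties^3 - ties) / (n * (n - 1))))
      })
      list(idx = idx, n = n, n1 = n1, E1 = n1 * (n + 1) / 2,
           w = 1 / (n + 1), per_outcome = per_outcome)
    })
    eval_stat <- function(is_g1) {
      # is_g1: logical over all rows
      total <- 0
      for (j in seq_len(ncol(vm))) {
        Tsum <- 0
        Vsum <- 0
        for (st in pre) {
          po <- st$per_outcome[[j]]
          Tsum <- Tsum + st$w * (sum(po$r[is_g1[st$idx]]) - st$E1)
          Vsum <- Vsum + st$w^2 * po$V1
        }
        if (Vsum > 0) total <- total + Tsum^2 / Vsum
      }
      total
    }
    obs <- eval_stat(groups == g1)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    perm_stats <- vapply(seq_len(n_perm), function(p) {
      is_g1 <- logical(length(groups))
      for (st in pre) is_g1[st$idx[sample.int(st$n, st$n1)]] <- TRUE
      eval_stat(is_g1)
    }, 0)
    out <- list(statistic = obs, df = ncol(vm),
                p_value = (1 + sum(perm_stats >= obs)) / (1 + n_perm),
                per_stratum = NULL, n_perm = n_perm, mode = mode)
  }
  structure(out, class = "stratified_kw")
}

#' @export
print.stratified_kw <- function(x, ...) {
  cat(sprintf("Stratified Kruskal-Wallis (%s): chi2(%d) = %.3f, p = %.4g\n",
              x$mode, x$df, x$statistic, x$p_value))
  invisible(x)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Sorts the p-values ascending, multiplies the i-th smallest by
#' `m - i + 1`, enforces monotone non-decreasing adjusted values, caps at 1
#' and returns them in the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @examples
#' holm_bonferroni(c(0.01, 0.02, 0.04))
#' @export
holm_bonferroni <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop_invalid("p-values must lie in [0, 1]")
  p.adjust(p, method = "holm")
}
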