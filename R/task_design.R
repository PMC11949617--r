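#' Define the stimulus set of a probabilistic selection task
#'
#' The canonical task uses six abstract symbols `A`-`F` arranged in three
#' fixed training pairs, each pair mixing a better and a worse option whose
#' reward probabilities sum to one: A/B at 0.8/0.2, C/D at 0.7/0.3 and E/F at
#' 0.6/0.4. Symbols are abstract labels; on-screen rendering and
#' per-participant symbol randomisation are presentation-layer concerns and
#' are not modelled.
#'
#' @param symbols Character vector of six distinct symbol labels.
#' @param training_pairs List of three length-2 character vectors, each
#'   `(better, worse)`, jointly covering all six symbols.
#' @param reward_probs Named numeric vector mapping each symbol to its
#'   probability of positive feedback when chosen.
#' @return An object of class `stimulus_set`.
#' @examples
#' ss <- stimulus_set()
#' ss$reward_probs[["A"]]
#' @export
stimulus_set <- function(symbols = LETTERS[1:6],
                         training_pairs = list(c("A", "B"), c("C", "D"), c("E", "F")),
                         reward_probs = c(A = 0.8, B = 0.2, C = 0.7, D = 0.3,
                                          E = 0.6, F = 0.4)) {
  if (length(symbols) != 6L || anyDuplicated(symbols) > 0L)
    stop_invalid("`symbols` must be 6 distinct labels")
  if (length(training_pairs) != 3L ||
      !setequal(unlist(training_pairs), symbols) ||
      length(unlist(training_pairs)) != 6L)
    stop_invalid("`training_pairs` must be 3 disjoint pairs covering all symbols")
  if (!setequal(names(reward_probs), symbols))
    stop_invalid("`reward_probs` must name every symbol exactly once")
  if (any(reward_probs <= 0 | reward_probs >= 1))
    stop_invalid("reward probabilities must lie strictly in (0, 1)")
  for (pr in training_pairs) {
    if (abs(sum(reward_probs[pr]) - 1) > 1e-12)
      stop_invalid(sprintf("reward probabilities within pair %s must sum to 1",
                           paste(pr, collapse = "")))
  }
  structure(list(symbols = as.character(symbols),
                 training_pairs = lapply(training_pairs, as.character),
                 reward_probs = reward_probs[symbols]),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat("Probabilistic selection task stimulus set\n")
  for (pr in x$training_pairs)
    cat(sprintf("  %s/%s  p(reward) = %.2f/%.2f\n", pr[1], pr[2],
                x$reward_probs[[pr[1]]], x$reward_probs[[pr[2]]]))
  invisible(x)
}

pair_label <- function(a, b) paste0(pmin(a, b), pmax(a, b))

all_pairs <- function(stim) {
  cmb <- combn(stim$symbols, 2)
  data.frame(sym1 = cmb[1, ], sym2 = cmb[2, ],
             pair = pair_label(cmb[1, ], cmb[2, ]),
             stringsAsFactors = FALSE)
}

#' Build a training-phase trial schedule
#'
#' The standard layout is six blocks of sixty trials with exactly twenty
#' presentations of each of the three training pairs per block. Within each
#' block the presentation order of pairs is a seeded random permutation
#' (counterbalanced pair order), and the left/right assignment of each pair
#' alternates across its presentations so that sides are balanced to within
#' one trial.
#'
#' @param stim A [stimulus_set()].
#' @param n_blocks Number of training blocks (default 6).
#' @param per_pair_per_block Presentations of each pair in each block
#'   (default 20, i.e. 60 trials per block).
#' @param seed Integer seed controlling the permutation.
#' @return A `data.frame` with columns `phase`, `block`, `trial`, `pair`,
#'   `left_symbol`, `right_symbol`.
#' @export
build_training_schedule <- function(stim = stimulus_set(), n_blocks = 6,
                                    per_pair_per_block = 20, seed = 1) {
  if (!is.numeric(n_blocks) || n_blocks < 1 || n_blocks != round(n_blocks))
    stop_invalid("`n_blocks` must be a positive integer")
  if (!is.numeric(per_pair_per_block) || per_pair_per_block < 1 ||
      per_pair_per_block != round(per_pair_per_block))
    stop_invalid("`per_pair_per_block` must be a positive integer")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  rows <- vector("list", n_blocks)
  # per-pair side counters persist across blocks (exact alternation)
  side_count <- integer(3)
  for (b in seq_len(n_blocks)) {
    pair_idx <- rep(1:3, each = per_pair_per_block)
    pair_idx <- pair_idx[sample.int(length(pair_idx))]
    left <- right <- character(length(pair_idx))
    for (k in 1:3) {
      pr <- stim$training_pairs[[k]]
      pos <- which(pair_idx == k)
      flip <- (side_count[k] + seq_along(pos) - 1L) %% 2L == 1L
      left[pos] <- ifelse(flip, pr[2], pr[1])
      right[pos] <- ifelse(flip, pr[1], pr[2])
      side_count[k] <- side_count[k] + length(pos)
    }
    rows[[b]] <- data.frame(
      phase = "training", block = b, trial = seq_along(pair_idx),
      pair = pair_label(left, right), left_symbol = left, right_symbol = right,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a feedback-free test-phase schedule
#'
#' The test phase presents every unordered pair of the six symbols — the three
#' training pairs plus the twelve novel combinations, fifteen in all — each
#' `per_pair` times (default 4, giving sixty trials), in seeded shuffled order
#' with alternating left/right assignment per pair.
#'
#' @inheritParams build_training_schedule
#' @param per_pair Presentations of each of the 15 pairs.
#' @return A `data.frame` in the same layout as [build_training_schedule()]
#'   with `block = 1`.
#' @export
build_test_schedule <- function(stim = stimulus_set(), per_pair = 4, seed = 1) {
  if (!is.numeric(per_pair) || per_pair < 1 || per_pair != round(per_pair))
    stop_invalid("`per_pair` must be a positive integer")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  pairs <- all_pairs(stim)
  idx <- rep(seq_len(nrow(pairs)), each = per_pair)
  idx <- idx[sample.int(length(idx))]
  left <- right <- character(length(idx))
  for (k in seq_len(nrow(pairs))) {
    pos <- which(idx == k)
    flip <- (seq_along(pos) - 1L) %% 2L == 1L
    left[pos] <- ifelse(flip, pairs$sym2[k], pairs$sym1[k])
    right[pos] <- ifelse(flip, pairs$sym1[k], pairs$sym2[k])
  }
  data.frame(phase = "test", block = 1L, trial = seq_along(idx),
             pair = pair_label(left, right), left_symbol = left,
             right_symbol = right, stringsAsFactors = FALSE)
}

#' Categorise a test-phase pair
#'
#' Training pairs are labelled `training`; pairs containing the best symbol
#' (highest reward probability, canonically `A`) but not the worst are
#' `chooseA`; pairs containing the worst symbol (`B`) but not the best are
#' `avoidB`; the remaining pairs, which exclude the symbols most and least
#' associated with reward, are `novel`. The four categories partition the
#' fifteen pairs as 3/4/4/4.
#'
#' @param pair Length-2 character vector of symbols, or a single string such
#'   as `"AC"`.
#' @param stim A [stimulus_set()].
#' @return One of `"training"`, `"chooseA"`, `"avoidB"`, `"novel"`.
#' @export
categorize_pair <- function(pair, stim = stimulus_set()) {
  if (length(pair) == 1L && nchar(pair) == 2L)
    pair <- strsplit(pair, "")[[1]]
  if (length(pair) != 2L || !all(pair %in% stim$symbols) || pair[1] == pair[2])
    stop_invalid("`pair` must be two distinct symbols from the stimulus set")
  best <- names(which.max(stim$reward_probs))
  worst <- names(which.min(stim$reward_probs))
  lbl <- pair_label(pair[1], pair[2])
  train_lbls <- vapply(stim$training_pairs,
                       function(p) pair_label(p[1], p[2]), "")
  if (lbl %in% train_lbls) return("training")
  has_best <- best %in% pair
  has_worst <- worst %in% pair
  if (has_best && !has_worst) return("chooseA")
  if (has_worst && !has_best) return("avoidB")
  "novel"
}

#' Draw feedback for a chosen symbol
#'
#' Feedback is an independent Bernoulli draw on the chosen symbol's reward
#' probability (within-pair probabilities summing to one makes the marginal
#' contingencies identical whether or not feedback is coupled within a pair).
#'
#' @param chosen Symbol label.
#' @param stim A [stimulus_set()].
#' @param n Number of draws.
#' @return Integer vector of 0/1 rewards.
#' @export
sample_feedback <- function(chosen, stim = stimulus_set(), n = 1) {
  if (!chosen %in% stim$symbols)
    stop_invalid(sprintf("unknown symbol '%s'", chosen))
  as.integer(runif(n) < stim$reward_probs[[chosen]])
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
}
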