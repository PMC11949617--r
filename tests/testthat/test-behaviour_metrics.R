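make_training_records <- function(choices_correct = TRUE, seed = 3) {
  ss <- stimulus_set()
  sched <- build_training_schedule(ss, 6, 20, seed = seed)
  better <- c(AB = "A", CD = "C", EF = "E")
  worse <- c(AB = "B", CD = "D", EF = "F")
  sched$participant_id <- "p1"
  sched$choice <- if (choices_correct) better[sched$pair] else worse[sched$pair]
  sched$reward <- 1L
  sched
}

test_that("training accuracy tables count 20 trials per pair per block", {
  rec <- make_training_records(TRUE)
  acc <- training_accuracy(rec)
  expect_true(all(acc$blocks$accuracy == 1))
  expect_true(all(acc$blocks$n_trials == 20))
  expect_equal(nrow(acc$blocks), 3 * 6)
  # lagged curves: window of 20 presentations, defined from presentation 20
  expect_equal(min(acc$lagged$presentation), 20)
  expect_equal(max(acc$lagged$presentation), 120)
  expect_true(all(acc$lagged$accuracy == 1))
  expect_error(training_accuracy(transform(rec, phase = "test")),
               class = "pst_invalid_argument")
})

test_that("lagged curves are trailing-window proportions", {
  rec <- make_training_records(TRUE)
  # make the first 10 AB presentations incorrect
  ab <- which(rec$pair == "AB")[1:10]
  rec$choice[ab] <- "B"
  lag <- training_accuracy(rec)$lagged
  ab_curve <- lag[lag$pair == "AB", ]
  expect_equal(ab_curve$accuracy[ab_curve$presentation == 20], 0.5)
  expect_equal(ab_curve$accuracy[ab_curve$presentation == 30], 1)
})

test_that("test accuracy categorises pairs and counts 12/16/16/16", {
  ss <- stimulus_set()
  sched <- build_test_schedule(ss, 4, seed = 2)
  sched$participant_id <- "p1"
  best <- vapply(strsplit(sched$pair, ""), function(s)
    s[which.max(stimulus_set()$reward_probs[s])], "")
  sched$choice <- best
  sched$reward <- NA_integer_
  acc <- test_accuracy(sched, ss)
  counts <- stats::setNames(acc$n_trials, acc$category)
  expect_equal(counts[["training"]], 12)
  expect_equal(counts[["chooseA"]], 16)
  expect_equal(counts[["avoidB"]], 16)
  expect_equal(counts[["novel"]], 16)
  expect_true(all(acc$accuracy == 1)) # omniscient agent
  # C beats E within the CE pair
  ce <- sched[sched$pair == "CE", ]
  expect_true(all(ce$choice == "C"))
})

test_that("single-stratum statistic equals the textbook Kruskal-Wallis", {
  set.seed(6)
  for (r in 1:5) {
    v <- round(c(rnorm(18), rnorm(22, 0.4)), 1) # rounding induces ties
    g <- rep(c("a", "b"), c(18, 22))
    kw <- stats::kruskal.test(v, factor(g))
    mine <- stratified_kruskal_wallis(v, g, strata = rep(1, 40))
    expect_equal(unname(mine$statistic), unname(kw$statistic),
                 tolerance = 1e-10)
    expect_equal(mine$df, 1)
  }
})

test_that("stratified statistic is rank-based and detects separation", {
  set.seed(8)
  g <- rep(c("a", "b"), 36)
  s <- rep(1:6, each = 12)
  v <- rnorm(72) + 0.5 * (g == "b")
  r1 <- stratified_kruskal_wallis(v, g, s)
  r2 <- stratified_kruskal_wallis(exp(v), g, s) # strictly monotone transform
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)

  far <- rnorm(72) + 50 * (g == "b")
  expect_lt(stratified_kruskal_wallis(far, g, s)$p_value, 0.001)

  expect_error(stratified_kruskal_wallis(v, rep("a", 72), s),
               class = "pst_invalid_argument")
  expect_error(stratified_kruskal_wallis(v, c(rep("a", 12), rep("b", 60)), s),
               class = "pst_invalid_argument")
})

test_that("omnibus permutation p-values are approximately uniform under the null", {
  set.seed(14)
  pvals <- vapply(1:400, function(r) {
    g <- rep(c("a", "b"), 18)
    s <- rep(1:3, each = 12)
    v <- cbind(rnorm(36), rnorm(36))
    stratified_kruskal_wallis(v, g, s, mode = "omnibus-permutation",
                              n_perm = 99, seed = r)$p_value
  }, 0)
  # permutation p-values live on the lattice k/100; de-lattice them with
  # sub-grid uniform noise (distribution is exactly U(0,1) under the null)
  pvals <- pvals - runif(length(pvals), 0, 1 / 100)
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("Holm-Bonferroni matches the hand-applied step-down definition", {
  expect_equal(holm_bonferroni(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(holm_bonferroni(0.2), 0.2)
  expect_equal(holm_bonferroni(rep(1, 4)), rep(1, 4))
  p <- c(0.3, 0.001, 0.04, 0.9)
  adj <- holm_bonferroni(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_error(holm_bonferroni(c(0.5, 1.2)), class = "pst_invalid_argument")
})
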