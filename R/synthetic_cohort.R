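#' Configuration for a synthetic PST cohort
#'
#' Defaults emulate the structure of a large online two-arm study: 995
#' participants randomised half-and-half to a distancing intervention, six
#' 60-trial training blocks plus a 60-trial feedback-free test phase, affect
#' ratings after every training trial with a declining block trend and a
#' small positive group-by-block interaction, a 209-item questionnaire
#' battery generated from a 3-factor latent model, and catch questions with
#' realistic error rates.
#'
#' Individual learning parameters are drawn on a latent-normal scale and
#' probit-transformed (learning rates to `[0, 1]`, inverse temperature to
#' `[0, beta_cap]`), mirroring the hierarchical fitting model so that
#' parameter recovery is well-posed. Group effects are stated on the natural
#' scale — a multiplicative shift on learning rates and an additive shift on
#' the inverse temperature — and applied to the group-level means.
#'
#' @param n_participants Cohort size.
#' @param prop_distanced Proportion allocated to the distanced arm
#'   (allocation is exact, not binomial).
#' @param mu_alpha_reward,mu_alpha_loss,mu_beta Control-group hyper-means on
#'   the latent (probit) scale; the defaults correspond to mean
#'   `alpha_reward` 0.30, `alpha_loss` 0.15 and `beta` 2.0.
#' @param sd_alpha_reward,sd_alpha_loss,sd_beta Hyper-SDs on the latent scale.
#' @param alpha_reward_multiplier,alpha_loss_multiplier Multiplicative group
#'   effects on the learning-rate means (distanced / control).
#' @param beta_shift Additive group effect on the inverse-temperature mean.
#' @param beta_cap Upper bound of the inverse-temperature transform.
#' @param n_blocks,per_pair_per_block,test_per_pair Task shape.
#' @param age_mean,age_sd,age_range,p_female,span_mean,span_sd,span_range,p_span_zero
#'   Covariate distributions (age truncated normal, rounded; gender binary;
#'   digit span rounded normal with a small probability of a zero span).
#' @param affect_intercept,affect_slope,affect_slope_interaction,affect_noise_sd
#'   Affect-rating model: rating = intercept + slope x (block - 1), plus
#'   interaction x (block - 1) if distanced, plus noise; clamped to `[0, 100]`.
#' @param n_items,n_informative,n_factors,item_noise_sd Questionnaire battery
#'   generated from a sparse 3-factor linear model, thresholded to 0-4
#'   ordinal ratings.
#' @param n_catch_standard,n_catch_hard,p_catch_standard_wrong,p_catch_hard_wrong
#'   Catch-question counts and per-question error probabilities.
#' @param p_neuro,p_english Probabilities of the simulated
#'   neurological-disorder and low-English exclusion flags.
#' @param seed Master seed; every downstream draw derives from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 995, prop_distanced = 0.5,
                          mu_alpha_reward = qnorm(0.30),
                          mu_alpha_loss = qnorm(0.15),
                          mu_beta = qnorm(0.20),
                          sd_alpha_reward = 0.25, sd_alpha_loss = 0.25,
                          sd_beta = 0.3,
                          alpha_reward_multiplier = 1.0,
                          alpha_loss_multiplier = 1.2,
                          beta_shift = 0.2, beta_cap = 10,
                          n_blocks = 6, per_pair_per_block = 20,
                          test_per_pair = 4,
                          age_mean = 45, age_sd = 15, age_range = c(18, 80),
                          p_female = 0.5, span_mean = 7, span_sd = 1.3,
                          span_range = c(2, 11), p_span_zero = 0.005,
                          affect_intercept = 70, affect_slope = -1.0,
                          affect_slope_interaction = 0.425,
                          affect_noise_sd = 10,
                          n_items = 209, n_informative = 30, n_factors = 3,
                          item_noise_sd = 0.3,
                          n_catch_standard = 2, n_catch_hard = 2,
                          p_catch_standard_wrong = 0.008,
                          p_catch_hard_wrong = 0.14,
                          p_neuro = 0.018, p_english = 0.003,
                          seed = 1) {
  if (prop_distanced <= 0 || prop_distanced >= 1)
    stop_invalid("`prop_distanced` must lie strictly in (0, 1)")
  if (any(c(sd_alpha_reward, sd_alpha_loss, sd_beta) < 0))
    stop_invalid("hyper-SDs must be non-negative")
  if (n_items < n_factors)
    stop_invalid("`n_items` must be at least `n_factors`")
  if (n_participants < 1) stop_invalid("`n_participants` must be positive")
  cfg <- as.list(environment())
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Synthetic PST cohort config: n = %d (%.0f%% distanced), %d x %d-trial blocks + %d-trial test\n",
              x$n_participants, 100 * x$prop_distanced, x$n_blocks,
              3 * x$per_pair_per_block, 15 * x$test_per_pair))
  cat(sprintf("  group effects: alpha_loss x%.2f, alpha_reward x%.2f, beta %+.2f\n",
              x$alpha_loss_multiplier, x$alpha_reward_multiplier, x$beta_shift))
  invisible(x)
}

# latent mean of the distanced group implied by a natural-scale effect
shift_latent <- function(mu_control, multiplier = NULL, shift = NULL,
                         cap = 1) {
  nat <- cap * pnorm(mu_control)
  nat_new <- if (!is.null(multiplier)) nat * multiplier else nat + shift
  nat_new <- min(max(nat_new / cap, 1e-6), 1 - 1e-6)
  qnorm(nat_new)
}

#' Generate a complete synthetic cohort
#'
#' Draws each participant's learning parameters from their group's
#' hyper-distribution, simulates training and test choices through the
#' Q-learning forward model on per-participant schedules, emits affect
#' ratings after each training trial (cycling happy/confident/engaged),
#' generates questionnaire item responses from the 3-factor latent model,
#' and simulates catch-question and exclusion-flag outcomes. Ground-truth
#' parameters and factor scores are returned separately from the "observed"
#' outputs.
#'
#' @param config A [cohort_config()].
#' @return A list of class `pst_cohort` with elements `participants`,
#'   `trials`, `truth`, `items` (ordinal 0-4 ratings, respondents x items),
#'   `item_meta`, and the `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) stop_invalid("`config` must be a cohort_config")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  n <- config$n_participants
  stim <- stimulus_set()

  n_dist <- round(n * config$prop_distanced)
  group <- sample(rep(c("distanced", "control"), c(n_dist, n - n_dist)))
  ids <- sprintf("p%04d", seq_len(n))

  # group-level latent means
  mu_c <- c(config$mu_alpha_reward, config$mu_alpha_loss, config$mu_beta)
  mu_d <- c(shift_latent(config$mu_alpha_reward, multiplier = config$alpha_reward_multiplier),
            shift_latent(config$mu_alpha_loss, multiplier = config$alpha_loss_multiplier),
            shift_latent(config$mu_beta, shift = config$beta_shift,
                         cap = config$beta_cap))
  sds <- c(config$sd_alpha_reward, config$sd_alpha_loss, config$sd_beta)

  z <- matrix(rnorm(n * 3), n, 3)
  mu_mat <- t(vapply(group, function(g) if (g == "distanced") mu_d else mu_c,
                     numeric(3)))
  latent <- mu_mat + sweep(z, 2, sds, `*`)
  alpha_reward <- pnorm(latent[, 1])
  alpha_loss <- pnorm(latent[, 2])
  beta <- config$beta_cap * pnorm(latent[, 3])

  # covariates
  age <- pmin(pmax(round(rnorm(n, config$age_mean, config$age_sd)),
                   config$age_range[1]), config$age_range[2])
  gender <- ifelse(runif(n) < config$p_female, "female", "male")
  digit_span <- pmin(pmax(round(rnorm(n, config$span_mean, config$span_sd)),
                          config$span_range[1]), config$span_range[2])
  digit_span[runif(n) < config$p_span_zero] <- 0L

  # catch questions and exclusion flags
  n_standard_wrong <- rbinom(n, config$n_catch_standard,
                             config$p_catch_standard_wrong)
  n_hard_wrong <- rbinom(n, config$n_catch_hard, config$p_catch_hard_wrong)
  neuro_flag <- runif(n) < config$p_neuro
  english_flag <- runif(n) < config$p_english

  # transdiagnostic factor scores and questionnaire items
  fac <- draw_factors(n)
  battery <- draw_item_model(config$n_items, config$n_informative,
                             config$item_noise_sd)
  items <- render_items(fac$scores_std, battery)

  # per-participant schedule / simulation seeds from the master stream
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, n * 3L,
                             replace = TRUE), n, 3)

  affect_qs <- c("happy", "confident", "engaged")
  trial_list <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- build_training_schedule(stim, config$n_blocks,
                                  config$per_pair_per_block,
                                  seed = seeds[i, 1])
    te <- build_test_schedule(stim, config$test_per_pair, seed = seeds[i, 2])
    params <- agent_params("dual", alpha_reward = alpha_reward[i],
                           alpha_loss = alpha_loss[i], beta = beta[i])
    rec <- simulate_agent(params, tr, te, stim, seed = seeds[i, 3],
                          participant_id = ids[i], group = group[i])
    is_tr <- rec$phase == "training"
    slope <- config$affect_slope +
      (group[i] == "distanced") * config$affect_slope_interaction
    rating <- config$affect_intercept + slope * (rec$block[is_tr] - 1) +
      rnorm(sum(is_tr), 0, config$affect_noise_sd)
    rec$affect_question <- NA_character_
    rec$affect_rating <- NA_real_
    rec$affect_question[is_tr] <-
      affect_qs[(seq_len(sum(is_tr)) - 1L) %% 3L + 1L]
    rec$affect_rating[is_tr] <- pmin(pmax(rating, 0), 100)
    trial_list[[i]] <- rec
  }
  trials <- do.call(rbind, trial_list)
  rownames(trials) <- NULL

  participants <- data.frame(
    participant_id = ids, group = group, age = age, gender = gender,
    digit_span = digit_span, n_standard_wrong = n_standard_wrong,
    n_hard_wrong = n_hard_wrong, neuro_flag = neuro_flag,
    english_flag = english_flag, excluded = FALSE,
    exclusion_reason = NA_character_, stringsAsFactors = FALSE)

  truth <- data.frame(
    participant_id = ids, group = group, alpha_reward = alpha_reward,
    alpha_loss = alpha_loss, beta = beta,
    z_alpha_reward = z[, 1], z_alpha_loss = z[, 2], z_beta = z[, 3],
    anxiety_depression = fac$scores[, 1],
    compulsive_behaviour = fac$scores[, 2],
    social_withdrawal = fac$scores[, 3], stringsAsFactors = FALSE)

  rownames(items) <- ids
  structure(list(participants = participants, trials = trials, truth = truth,
                 items = items, item_meta = battery$meta, config = config),
            class = "pst_cohort")
}

#' @export
print.pst_cohort <- function(x, ...) {
  cat(sprintf("Synthetic PST cohort: %d participants (%d distanced), %d trials, %d questionnaire items\n",
              nrow(x$participants),
              sum(x$participants$group == "distanced"), nrow(x$trials),
              ncol(x$items)))
  invisible(x)
}

# standardised factor draws plus scores on the reporting scale used for
# the three transdiagnostic dimensions
FACTOR_NAMES <- c("anxiety_depression", "compulsive_behaviour",
                  "social_withdrawal")
FACTOR_MEANS <- c(2.76, 2.05, 1.41)
FACTOR_SDS <- c(0.60, 0.55, 0.50)

draw_factors <- function(n, cor_f = 0.3) {
  R <- matrix(cor_f, 3, 3); diag(R) <- 1
  z <- matrix(rnorm(n * 3), n, 3) %*% chol(R)
  scores <- sweep(sweep(z, 2, FACTOR_SDS, `*`), 2, FACTOR_MEANS, `+`)
  colnames(scores) <- colnames(z) <- FACTOR_NAMES
  list(scores_std = z, scores = scores)
}

# sparse loading structure: informative items split evenly over the three
# factors; remaining items are pure noise. Draws loadings from the current
# RNG stream.
draw_item_model <- function(n_items, n_informative, noise_sd) {
  loadings <- matrix(0, n_items, 3)
  informative <- sort(sample.int(n_items, n_informative))
  fac_of <- rep_len(1:3, n_informative)
  strength <- runif(n_informative, 0.7, 1.2) *
    sample(c(-1, 1), n_informative, replace = TRUE, prob = c(0.2, 0.8))
  loadings[cbind(informative, fac_of)] <- strength
  quests <- paste0("Q", rep_len(1:8, n_items)[order(runif(n_items))])
  meta <- data.frame(item = paste0("item_", seq_len(n_items)),
                     questionnaire = quests,
                     informative = seq_len(n_items) %in% informative,
                     stringsAsFactors = FALSE)
  list(loadings = loadings, informative = informative, noise_sd = noise_sd,
       meta = meta)
}

# ordinal 0-4 ratings by thresholding the continuous latents
render_items <- function(f_std, battery) {
  n <- nrow(f_std)
  latent <- f_std %*% t(battery$loadings) +
    matrix(rnorm(n * nrow(battery$loadings), 0, battery$noise_sd), n)
  sds <- sqrt(rowSums(battery$loadings^2) + battery$noise_sd^2)
  latent <- sweep(latent, 2, pmax(sds, 1e-8), `/`)
  items <- matrix(findInterval(latent, c(-1.5, -0.5, 0.5, 1.5)),
                  n, nrow(battery$loadings))
  colnames(items) <- battery$meta$item
  items
}

#' Apply the study exclusion filters
#'
#' A participant is excluded if they answered any standard catch question
#' wrongly, both harder catch questions wrongly, have a digit span of zero,
#' or carry the neurological-disorder or low-English flag. The filter is
#' idempotent.
#'
#' @param participants Participant table from [generate_cohort()].
#' @return List with `participants` (retained rows), `excluded` (dropped rows
#'   with `exclusion_reason` filled in) and `log` (count per reason).
#' @export
apply_exclusions <- function(participants) {
  need <- c("n_standard_wrong", "n_hard_wrong", "digit_span", "neuro_flag",
            "english_flag")
  if (!all(need %in% names(participants)))
    stop_data_integrity(sprintf("participant table lacks columns: %s",
                                paste(setdiff(need, names(participants)),
                                      collapse = ", ")))
  reasons <- list(
    standard_catch_wrong = participants$n_standard_wrong >= 1,
    both_hard_catch_wrong = participants$n_hard_wrong >= 2,
    digit_span_zero = participants$digit_span == 0,
    neurological_disorder = participants$neuro_flag,
    low_english = participants$english_flag)
  flag_mat <- do.call(cbind, reasons)
  excl <- rowSums(flag_mat) > 0
  reason_str <- apply(flag_mat, 1, function(r)
    if (any(r)) paste(names(reasons)[r], collapse = ";") else NA_character_)
  participants$excluded <- excl
  participants$exclusion_reason <- reason_str
  log <- data.frame(reason = names(reasons), n = colSums(flag_mat),
                    row.names = NULL, stringsAsFactors = FALSE)
  list(participants = participants[!excl, , drop = FALSE],
       excluded = participants[excl, , drop = FALSE], log = log)
}

#' Write a cohort to CSV files
#'
#' Emits `participants.csv`, `trials.csv` (trial-record dialect, including
#' affect columns), `truth.csv` (hidden ground truth) and `items.csv`
#' (questionnaire ratings with participant ids) into a directory.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  if (!inherits(cohort, "pst_cohort")) stop_invalid("`cohort` must be a pst_cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("participants.csv", "trials.csv", "truth.csv",
                            "items.csv"))
  utils::write.csv(cohort$participants, paths[1], row.names = FALSE)
  utils::write.csv(cohort$trials, paths[2], row.names = FALSE)
  utils::write.csv(cohort$truth, paths[3], row.names = FALSE)
  items <- data.frame(participant_id = rownames(cohort$items), cohort$items,
                      check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(items, paths[4], row.names = FALSE)
  invisible(paths)
}
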