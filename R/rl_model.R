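#' Construct agent-level Q-learning parameters
#'
#' @param model `"single"` (one learning rate `alpha`) or `"dual"` (separate
#'   `alpha_reward` for non-negative prediction errors and `alpha_loss` for
#'   negative ones).
#' @param alpha,alpha_reward,alpha_loss Learning rates in `[0, 1]`.
#' @param beta Softmax inverse temperature, `>= 0`.
#' @return An object of class `agent_params`.
#' @examples
#' agent_params("dual", alpha_reward = 0.4, alpha_loss = 0.1, beta = 3)
#' @export
agent_params <- function(model = c("dual", "single"), alpha = NULL,
                         alpha_reward = NULL, alpha_loss = NULL, beta = NULL) {
  model <- match.arg(model)
  if (is.null(beta) || !is.numeric(beta) || beta < 0)
    stop_invalid("`beta` must be a non-negative number")
  if (model == "single") {
    if (is.null(alpha)) stop_invalid("single model requires `alpha`")
    if (alpha < 0 || alpha > 1) stop_invalid("`alpha` must lie in [0, 1]")
    out <- list(model = "single", alpha = unname(alpha), beta = unname(beta))
  } else {
    if (is.null(alpha_reward) || is.null(alpha_loss))
      stop_invalid("dual model requires `alpha_reward` and `alpha_loss`")
    if (any(c(alpha_reward, alpha_loss) < 0 | c(alpha_reward, alpha_loss) > 1))
      stop_invalid("learning rates must lie in [0, 1]")
    out <- list(model = "dual", alpha_reward = unname(alpha_reward),
                alpha_loss = unname(alpha_loss), beta = unname(beta))
  }
  structure(out, class = "agent_params")
}

params_rates <- function(params) {
  if (params$model == "single")
    c(alpha_r = params$alpha, alpha_l = params$alpha)
  else
    c(alpha_r = params$alpha_reward, alpha_l = params$alpha_loss)
}

#' Single Q-value update
#'
#' Computes the prediction error `delta = reward - q_chosen` and the updated
#' value `q + alpha_eff * delta`, where `alpha_eff` is `alpha` (single model)
#' or `alpha_reward` when `delta >= 0` and `alpha_loss` when `delta < 0`
#' (dual model; ties at `delta == 0` use the reward rate). Only the chosen
#' symbol's value changes.
#'
#' @param q_chosen Current Q-value of the chosen symbol.
#' @param reward Feedback, 0 or 1.
#' @param params An [agent_params()] object.
#' @return List with `new_q` and `prediction_error`.
#' @export
q_update <- function(q_chosen, reward, params) {
  if (!is.finite(q_chosen)) stop_invalid("`q_chosen` must be finite")
  if (!reward %in% c(0, 1)) stop_invalid("`reward` must be 0 or 1")
  rates <- params_rates(params)
  delta <- reward - q_chosen
  a <- if (delta >= 0) rates[["alpha_r"]] else rates[["alpha_l"]]
  list(new_q = q_chosen + a * delta, prediction_error = delta)
}

#' Softmax probability of choosing the left option
#'
#' Two-option softmax in its numerically stable logistic form:
#' `p(left) = 1 / (1 + exp(-beta * (q_left - q_right)))`.
#'
#' @param q_left,q_right Q-values of the two options.
#' @param beta Inverse temperature, `>= 0`.
#' @return Probability of choosing the left option.
#' @export
choice_prob <- function(q_left, q_right, beta) {
  if (!all(is.finite(c(q_left, q_right)))) stop_invalid("Q-values must be finite")
  if (!is.numeric(beta) || any(beta < 0)) stop_invalid("`beta` must be >= 0")
  plogis(beta * (q_left - q_right))
}

#' Simulate one agent through training and test phases
#'
#' Training choices are sampled from the softmax on the evolving Q-values
#' (initialised at zero), with feedback drawn from each chosen symbol's reward
#' probability; test choices are sampled with Q-values frozen at their
#' end-of-training state and no feedback recorded.
#'
#' @param params An [agent_params()] object.
#' @param training,test Schedules from [build_training_schedule()] /
#'   [build_test_schedule()]; `test` may be `NULL`.
#' @param stim A [stimulus_set()].
#' @param seed Integer seed.
#' @param participant_id,group Optional labels copied into the output.
#' @return A trial-record `data.frame` with columns `participant_id`, `group`,
#'   `phase`, `block`, `trial`, `pair`, `left_symbol`, `right_symbol`,
#'   `choice`, `reward` (`NA` on test rows).
#' @export
simulate_agent <- function(params, training, test = NULL,
                           stim = stimulus_set(), seed = 1,
                           participant_id = "agent", group = NA_character_) {
  check_schedule(training, stim, "training")
  if (!is.null(test)) check_schedule(test, stim, "test")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  sym <- stim$symbols
  rates <- params_rates(params)
  tr <- cpp_simulate_phase(match(training$left_symbol, sym) - 1L,
                           match(training$right_symbol, sym) - 1L,
                           TRUE, unname(stim$reward_probs[sym]),
                           rates[["alpha_r"]], rates[["alpha_l"]],
                           params$beta, numeric(6))
  out_tr <- training
  out_tr$choice <- sym[tr$choice + 1L]
  out_tr$reward <- tr$reward
  out <- out_tr
  if (!is.null(test)) {
    te <- cpp_simulate_phase(match(test$left_symbol, sym) - 1L,
                             match(test$right_symbol, sym) - 1L,
                             FALSE, unname(stim$reward_probs[sym]),
                             rates[["alpha_r"]], rates[["alpha_l"]],
                             params$beta, tr$q_end)
    out_te <- test
    out_te$choice <- sym[te$choice + 1L]
    out_te$reward <- NA_integer_
    out <- rbind(out_tr, out_te)
  }
  cbind(data.frame(participant_id = participant_id, group = group,
                   stringsAsFactors = FALSE),
        out)
}

check_schedule <- function(sched, stim, phase) {
  need <- c("phase", "block", "trial", "pair", "left_symbol", "right_symbol")
  if (!all(need %in% names(sched)))
    stop_invalid(sprintf("schedule lacks columns: %s",
                         paste(setdiff(need, names(sched)), collapse = ", ")))
  if (!all(c(sched$left_symbol, sched$right_symbol) %in% stim$symbols))
    stop_invalid("schedule contains symbols not in the stimulus set")
  if (!all(sched$phase == phase))
    stop_invalid(sprintf("expected a %s-phase schedule", phase))
  invisible(TRUE)
}

#' Q-learning log-likelihood of observed choices
#'
#' Sums the log softmax probability of each observed choice. Q-values start at
#' zero, evolve only on training trials and are fixed at their end-of-training
#' state for test trials; with `scope = "training"` test rows are ignored,
#' with `scope = "training_plus_test"` the log-density is additionally
#' incremented on feedback-free test choices.
#'
#' @param params An [agent_params()] object.
#' @param records Trial records for one or more participants, in presentation
#'   order within participant (training rows before test rows).
#' @param scope `"training"` or `"training_plus_test"`.
#' @param stim A [stimulus_set()].
#' @return Total log-likelihood (scalar).
#' @export
log_likelihood <- function(params, records,
                           scope = c("training", "training_plus_test"),
                           stim = stimulus_set()) {
  scope <- match.arg(scope)
  check_records(records, stim)
  if (scope == "training") records <- records[records$phase == "training", ]
  enc <- encode_trials(records, stim)
  rates <- params_rates(params)
  n <- length(unique(enc$pid))
  ll <- cpp_pointwise_loglik(enc$pid, enc$phase, enc$chosen, enc$other,
                             enc$reward, rep(rates[["alpha_r"]], n),
                             rep(rates[["alpha_l"]], n),
                             rep(params$beta, n))
  sum(ll)
}

check_records <- function(records, stim) {
  need <- c("participant_id", "phase", "block", "trial", "left_symbol",
            "right_symbol", "choice")
  if (!all(need %in% names(records)))
    stop_invalid(sprintf("trial records lack columns: %s",
                         paste(setdiff(need, names(records)), collapse = ", ")))
  if (!all(records$choice == records$left_symbol |
           records$choice == records$right_symbol))
    stop_data_integrity("some choices are not members of their pair")
  is_test <- records$phase == "test"
  if ("reward" %in% names(records)) {
    if (any(is_test & !is.na(records$reward)))
      stop_data_integrity("test rows must not carry reward values")
    if (any(!is_test & is.na(records$reward)))
      stop_data_integrity("training rows must carry 0/1 rewards")
  } else if (any(!is_test)) {
    stop_data_integrity("training rows must carry 0/1 rewards")
  }
  # training must precede test, and presentation order must be sorted,
  # within every participant
  for (id in unique(records$participant_id)) {
    r <- records[records$participant_id == id, ]
    ph <- as.integer(r$phase == "test")
    if (is.unsorted(ph))
      stop_invalid("training rows must precede test rows within participant")
    key <- ph * 1e6 + r$block * 1e3 + r$trial
    if (is.unsorted(key))
      stop_invalid("trials must be in presentation order within participant")
  }
  invisible(TRUE)
}

# 0-based encoding used by the C++ kernels; participants kept contiguous
encode_trials <- function(records, stim) {
  sym <- stim$symbols
  ids <- unique(records$participant_id)
  pid <- match(records$participant_id, ids) - 1L
  left <- match(records$left_symbol, sym) - 1L
  right <- match(records$right_symbol, sym) - 1L
  chosen <- match(records$choice, sym) - 1L
  other <- ifelse(chosen == left, right, left)
  reward <- if ("reward" %in% names(records))
    ifelse(is.na(records$reward), -1L, as.integer(records$reward))
  else rep(-1L, nrow(records))
  list(pid = pid, phase = as.integer(records$phase == "test"),
       chosen = as.integer(chosen), other = as.integer(other),
       reward = reward, ids = ids)
}
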