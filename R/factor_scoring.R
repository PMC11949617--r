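#' Simulate a questionnaire battery from a planted 3-factor model
#'
#' Generates respondents' scores on three transdiagnostic dimensions
#' (anxiety/depression, compulsive behaviour, social withdrawal) and a
#' 209-item battery (by default) in which a small subset of items load
#' linearly on the factors; continuous item latents are thresholded to 0-4
#' ordinal ratings. Items are tagged with one of eight pseudo-questionnaire
#' labels. Intended for validating the subset-selection machinery; it
#' contains no real questionnaire content.
#'
#' @param n Number of respondents.
#' @param n_items Battery size.
#' @param n_informative Number of items with non-zero loadings.
#' @param noise_sd Residual SD of the continuous item latents.
#' @param seed Integer seed.
#' @return List with `items` (n x n_items ordinal matrix), `scores`
#'   (n x 3 factor scores), `meta` (item metadata, including the planted
#'   `informative` flag) and `loadings`.
#' @export
simulate_item_battery <- function(n, n_items = 209, n_informative = 30,
                                  noise_sd = 0.3, seed = 1) {
  if (n_items < 3 || n_informative > n_items)
    stop_invalid("need n_items >= 3 and n_informative <= n_items")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fac <- draw_factors(n)
  battery <- draw_item_model(n_items, n_informative, noise_sd)
  items <- render_items(fac$scores_std, battery)
  list(items = items, scores = fac$scores, meta = battery$meta,
       loadings = battery$loadings)
}

#' Multi-target lasso path over question subsets
#'
#' Fits a multi-response gaussian lasso (via \pkg{glmnet}'s `mgaussian`
#' family) of the three factor scores on the item ratings. The penalty is a
#' group lasso on each item's coefficient triple, so an item is selected for
#' all three factors jointly or excluded from all three — yielding a single
#' shared question subset per penalty. Predictive accuracy is assessed by
#' k-fold cross-validated R-squared per factor.
#'
#' @param items Respondents x items numeric matrix.
#' @param targets Respondents x 3 matrix (or data.frame) of factor scores.
#' @param penalty Optional decreasing penalty grid; defaults to the
#'   glmnet-generated path.
#' @param cv_folds Number of cross-validation folds.
#' @param seed Seed for the fold assignment.
#' @return An object of class `subset_path`: a list of subset models, each
#'   with `penalty`, `items` (selected indices), `coef` (items x 3),
#'   `intercept`, `n_selected` and `cv_r2` (per factor).
#' @export
fit_subset_path <- function(items, targets, penalty = NULL, cv_folds = 5,
                            seed = 1) {
  x <- as.matrix(items)
  y <- as.matrix(targets)
  if (nrow(x) != nrow(y))
    stop_invalid("`items` and `targets` must have aligned rows")
  if (ncol(y) != 3)
    stop_invalid("`targets` must have exactly 3 columns")
  if (anyNA(x) || anyNA(y))
    stop_invalid("missing entries must be handled before fitting")
  if (is.null(colnames(y))) colnames(y) <- FACTOR_NAMES
  if (!is.null(penalty) && is.unsorted(rev(penalty)))
    stop_invalid("`penalty` must be a decreasing grid")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- nrow(x)
  folds <- sample(rep_len(seq_len(cv_folds), n))

  full <- glmnet::glmnet(x, y, family = "mgaussian", lambda = penalty,
                         standardize = TRUE)
  lambda <- full$lambda
  n_lambda <- length(lambda)

  sse <- matrix(0, n_lambda, 3)
  for (f in seq_len(cv_folds)) {
    hold <- folds == f
    cvfit <- glmnet::glmnet(x[!hold, , drop = FALSE], y[!hold, , drop = FALSE],
                            family = "mgaussian", lambda = lambda,
                            standardize = TRUE)
    pred <- predict(cvfit, newx = x[hold, , drop = FALSE], s = lambda)
    for (j in 1:3)
      sse[, j] <- sse[, j] +
        colSums((matrix(pred[, j, ], ncol = n_lambda) - y[hold, j])^2)
  }
  sstot <- colSums(sweep(y, 2, colMeans(y))^2)
  cv_r2 <- 1 - sweep(sse, 2, sstot, `/`)

  cf <- coef(full) # list of 3 sparse matrices, (p+1) x n_lambda
  models <- vector("list", n_lambda)
  for (l in seq_len(n_lambda)) {
    B <- sapply(cf, function(m) as.numeric(m[, l]))
    rownames(B) <- rownames(cf[[1]])
    colnames(B) <- colnames(y)
    intercept <- B[1, ]
    Bi <- B[-1, , drop = FALSE]
    sel <- which(rowSums(Bi != 0) > 0)
    models[[l]] <- structure(list(
      penalty = lambda[l], items = sel, item_names = rownames(Bi)[sel],
      coef = Bi[sel, , drop = FALSE], intercept = intercept,
      n_selected = length(sel), cv_r2 = cv_r2[l, ],
      factor_names = colnames(y), n_items_total = ncol(x)),
      class = "subset_model")
  }
  structure(models, class = "subset_path")
}

#' @export
print.subset_path <- function(x, ...) {
  cat(sprintf("Multi-target lasso path: %d penalties over %d items\n",
              length(x), x[[1]]$n_items_total))
  sizes <- vapply(x, `[[`, 0L, "n_selected")
  r2min <- vapply(x, function(m) min(m$cv_r2), 0)
  cat(sprintf("  subset sizes %d..%d; min CV R^2 %.3f..%.3f\n",
              min(sizes), max(sizes), min(r2min), max(r2min)))
  invisible(x)
}

#' @export
print.subset_model <- function(x, ...) {
  cat(sprintf("Question subset model: %d of %d items (penalty %.4g)\n",
              x$n_selected, x$n_items_total, x$penalty))
  cat(sprintf("  CV R^2: %s\n",
              paste(sprintf("%s %.3f", x$factor_names, x$cv_r2),
                    collapse = ", ")))
  invisible(x)
}

#' Choose the sparsest subset meeting an accuracy floor
#'
#' Returns the model with the smallest selected-item count whose
#' cross-validated R-squared is at least `r2_min` on all three factors
#' (ties broken towards the larger penalty). Errors if no model on the path
#' qualifies.
#'
#' @param path A [fit_subset_path()] result.
#' @param r2_min Per-factor CV R-squared floor.
#' @return A `subset_model`.
#' @export
select_operating_point <- function(path, r2_min = 0.9) {
  if (length(path) == 0) stop_invalid("`path` is empty")
  ok <- vapply(path, function(m) all(m$cv_r2 >= r2_min), TRUE)
  if (!any(ok))
    stop_no_solution(sprintf(
      "no subset on the path reaches CV R^2 >= %.3g on all three factors",
      r2_min))
  cand <- path[ok]
  sizes <- vapply(cand, `[[`, 0L, "n_selected")
  pens <- vapply(cand, `[[`, 0, "penalty")
  best <- order(sizes, -pens)[1]
  cand[[best]]
}

#' Predict factor scores for new respondents
#'
#' Linear prediction from the selected items' coefficients; items not in
#' the subset are ignored, so appending irrelevant columns leaves
#' predictions unchanged.
#'
#' @param model A `subset_model` from [select_operating_point()] or
#'   [fit_subset_path()].
#' @param new_items Matrix or data.frame of item ratings containing at least
#'   the selected items (matched by column name when available, otherwise by
#'   index).
#' @return Respondents x 3 matrix of predicted factor scores.
#' @export
predict_scores <- function(model, new_items) {
  x <- as.matrix(new_items)
  if (!is.null(colnames(x)) && all(model$item_names %in% colnames(x))) {
    xs <- x[, model$item_names, drop = FALSE]
  } else if (is.null(colnames(x))) {
    if (max(model$items) > ncol(x))
      stop_data_integrity("new items are missing selected item columns")
    xs <- x[, model$items, drop = FALSE]
  } else {
    stop_data_integrity(sprintf(
      "new items are missing selected columns: %s",
      paste(setdiff(model$item_names, colnames(x)), collapse = ", ")))
  }
  if (anyNA(xs)) stop_data_integrity("selected item ratings contain NA")
  out <- sweep(xs %*% model$coef, 2, model$intercept, `+`)
  colnames(out) <- model$factor_names
  out
}
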