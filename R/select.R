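#' Subject-grouped k-fold CV RMSE of a feature subset
#'
#' The evaluation criterion used by SFFS: the wrapper model is fit on
#' k-1 fold groups and predicts the held-out group; predictions are
#' pooled and one RMSE is returned. Folds group whole subjects, so no
#' subject contributes to both sides of a split, and fold assignment and
#' every stochastic fit are seeded, making the criterion a deterministic
#' function of the subset.
#'
#' @param fm A `feature_matrix`.
#' @param features Character vector of feature column names (empty vector
#'   allowed: the predict-the-mean baseline).
#' @param wrapper A [model_spec()] (default: a small random forest).
#' @param k Number of fold groups.
#' @param seed Seed for fold assignment and fits.
#' @return Pooled CV RMSE (m/s).
#' @export
cv_rmse <- function(fm, features, wrapper = sffs_wrapper(), k = 5, seed = 1L) {
  y <- fm$speed
  folds <- grouped_folds(fm$subject_id, k = k, seed = seed)
  pred <- rep(NA_real_, length(y))
  if (length(features) == 0) {
    for (f in unique(folds)) pred[folds == f] <- mean(y[folds != f])
    return(rmse(pred, y))
  }
  x <- as_design(fm, features)
  for (f in unique(folds)) {
    tr <- folds != f
    fit <- fit_model(wrapper, x[tr, , drop = FALSE], y[tr])
    pred[!tr] <- predict_model(fit, x[!tr, , drop = FALSE])
  }
  rmse(pred, y)
}

#' @rdname cv_rmse
#' @details `sffs_wrapper()` is the default wrapper: a deliberately small
#'   random forest (50 trees), cheap enough to be refit thousands of
#'   times during selection.
#' @export
sffs_wrapper <- function(seed = 1L) {
  model_spec("rf", num.trees = 50, min.node.size = 5, seed = seed)
}

#' Sequential floating forward selection with an RMSE criterion
#'
#' Classic SFFS over the feature columns of a matrix. Forward step: add
#' the candidate whose inclusion minimises the subject-grouped k-fold CV
#' RMSE, accepted only if it improves on the current RMSE by more than
#' `criterion` (0.01 m/s). Floating step: while removing some selected
#' feature (other than the one just added) improves RMSE by more than
#' `criterion`, remove the best such feature. Selection stops when no
#' forward addition qualifies, or at `cap` features.
#'
#' @param fm A `feature_matrix`.
#' @param wrapper [model_spec()] used to score subsets.
#' @param k Fold-group count (folds group subjects).
#' @param criterion Minimum RMSE improvement (m/s) to accept a step.
#' @param cap Hard limit on the selected-set size.
#' @param seed Seed controlling folds and fits.
#' @param verbose Print accepted steps.
#' @return An `sffs_selection`: `ordered_features` (in acceptance order,
#'   after floating removals), `rmse_trajectory` (RMSE after each
#'   accepted step), `baseline_rmse` (mean predictor), `flags`
#'   (`"empty"` when nothing qualified, `"cap"` when the cap was hit),
#'   plus the wrapper/fold bookkeeping.
#' @export
sffs_select <- function(fm, wrapper = sffs_wrapper(), k = 5,
                        criterion = 0.01, cap = 30, seed = 1L,
                        verbose = FALSE) {
  stopifnot(inherits(fm, "data.frame"), criterion > 0)
  pool <- feature_columns(fm)
  if (length(pool) < 2) stop("need at least 2 candidate features")
  if (var(fm$speed) == 0) stop("constant target: selection undefined")
  n_subj <- length(unique(fm$subject_id))
  if (k > n_subj) stop("k exceeds the number of subjects")
  if (nrow(fm) < 2 * k) stop("too few rows for ", k, "-fold CV")

  cache <- new.env(parent = emptyenv())
  score <- function(features) {
    key <- paste0("s:", paste(sort(features), collapse = "|"))
    if (is.null(cache[[key]]))
      cache[[key]] <- cv_rmse(fm, features, wrapper = wrapper, k = k, seed = seed)
    cache[[key]]
  }

  selected <- character(0)
  current <- score(character(0)) # predict-the-mean baseline
  baseline <- current
  trajectory <- numeric(0)
  flags <- character(0)

  repeat {
    if (length(selected) >= cap) {
      flags <- c(flags, "cap")
      break
    }
    candidates <- setdiff(pool, selected)
    if (length(candidates) == 0) break
    scores <- vapply(candidates, function(f) score(c(selected, f)), numeric(1))
    best <- which.min(scores) # ties: lowest column index (vapply keeps order)
    if (current - scores[best] <= criterion) break
    selected <- c(selected, candidates[best])
    current <- scores[best]
    trajectory <- c(trajectory, current)
    if (verbose)
      message(sprintf("+ %s  (CV RMSE %.4f)", candidates[best], current))
    just_added <- candidates[best]

    # floating removals
    while (length(selected) >= 2) {
      removable <- setdiff(selected, just_added)
      if (length(removable) == 0) break
      rm_scores <- vapply(removable, function(f)
        score(setdiff(selected, f)), numeric(1))
      best_rm <- which.min(rm_scores)
      if (current - rm_scores[best_rm] <= criterion) break
      if (verbose)
        message(sprintf("- %s  (CV RMSE %.4f)", removable[best_rm],
                        rm_scores[best_rm]))
      selected <- setdiff(selected, removable[best_rm])
      current <- rm_scores[best_rm]
      trajectory <- c(trajectory, current)
    }
  }
  if (length(selected) == 0) flags <- c(flags, "empty")

  structure(list(
    ordered_features = selected,
    rmse_trajectory = trajectory,
    baseline_rmse = baseline,
    final_rmse = current,
    wrapper = wrapper,
    k_folds = k,
    criterion = criterion,
    seed = seed,
    flags = flags
  ), class = "sffs_selection")
}

#' Audit a selection for floating-step convergence
#'
#' Verifies that no selected feature could still be removed with an RMSE
#' improvement above the criterion — the defining post-condition of the
#' floating step.
#'
#' @param selection An `sffs_selection`.
#' @param fm The feature matrix it was computed on.
#' @return TRUE if converged, FALSE otherwise.
#' @export
sffs_audit <- function(selection, fm) {
  s <- selection$ordered_features
  if (length(s) < 2) return(TRUE)
  current <- cv_rmse(fm, s, wrapper = selection$wrapper,
                     k = selection$k_folds, seed = selection$seed)
  for (f in s) {
    r <- cv_rmse(fm, setdiff(s, f), wrapper = selection$wrapper,
                 k = selection$k_folds, seed = selection$seed)
    if (current - r > selection$criterion) return(FALSE)
  }
  TRUE
}

#' @export
print.sffs_selection <- function(x, ...) {
  cat(sprintf("<sffs_selection> %d feature(s), baseline RMSE %.3f -> %.3f m/s\n",
              length(x$ordered_features), x$baseline_rmse, x$final_rmse))
  if (length(x$ordered_features) > 0)
    cat(" ", paste(sprintf("%s (%.3f)", x$ordered_features,
                           x$rmse_trajectory[seq_along(x$ordered_features)]),
                   collapse = "\n  "), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
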