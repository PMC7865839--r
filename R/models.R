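#' Specify a regression model family
#'
#' The five families compared in the pipeline: support-vector machine
#' (`svm`, radial kernel, e1071), decision tree (`dt`, rpart), random
#' forest (`rf`, ranger), boosted trees (`bt`, least-squares gradient
#' boosting via xgboost), and Gaussian process regression (`gpr`,
#' kernlab). Hyperparameters not supplied fall back to family defaults.
#' `tune` may hold a list of alternative hyperparameter lists; when more
#' than one candidate is present, [fit_model()] picks the best by
#' subject-grouped inner 3-fold CV on the training data.
#'
#' @param family One of `"svm"`, `"dt"`, `"rf"`, `"bt"`, `"gpr"`.
#' @param ... Named hyperparameters overriding the defaults.
#' @param tune Optional list of candidate hyperparameter lists.
#' @param seed Integer seed recorded in the spec and used by stochastic
#'   fitters.
#' @return A `model_spec` object.
#' @export
model_spec <- function(family = c("rf", "svm", "dt", "bt", "gpr"), ...,
                       tune = NULL, seed = 1L) {
  family <- match.arg(family)
  hp <- utils::modifyList(default_hyperparameters(family), list(...))
  structure(list(family = family, hyperparameters = hp, tune = tune,
                 seed = as.integer(seed)),
            class = "model_spec")
}

default_hyperparameters <- function(family) {
  switch(family,
    rf  = list(num.trees = 150, min.node.size = 5, mtry = NULL),
    dt  = list(cp = 0.005, minsplit = 10, maxdepth = 30),
    bt  = list(nrounds = 100, eta = 0.1, max_depth = 4, subsample = 0.8),
    svm = list(cost = 10, epsilon = 0.1, kernel = "radial"),
    gpr = list(kernel = "rbfdot", var = 0.01)
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec: %s> %s\n", x$family,
              paste(names(x$hyperparameters), unlist(x$hyperparameters),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

# standardise the design matrix: stable syntactic names, numeric matrix
as_design <- function(fm, features) {
  missing_f <- setdiff(features, names(fm))
  if (length(missing_f) > 0)
    stop("selected feature(s) not in matrix: ",
         paste(head(missing_f, 3), collapse = ", "))
  x <- as.matrix(fm[, features, drop = FALSE])
  colnames(x) <- paste0("f", seq_along(features))
  storage.mode(x) <- "double"
  x
}

#' Fit one model family
#'
#' Trains `spec$family` on a design matrix. With multiple `tune`
#' candidates, each is scored by subject-grouped 3-fold CV RMSE on the
#' training data and the best is refit on all rows.
#'
#' @param spec A [model_spec()].
#' @param x Numeric design matrix.
#' @param y Numeric response (speed, m/s).
#' @param subjects Optional subject ids (needed only when tuning).
#' @return A fitted model wrapper usable with [predict_model()].
#' @export
fit_model <- function(spec, x, y, subjects = NULL) {
  stopifnot(inherits(spec, "model_spec"), nrow(x) == length(y))
  hp <- spec$hyperparameters
  if (!is.null(spec$tune) && length(spec$tune) > 1) {
    hp <- tune_hyperparameters(spec, x, y, subjects)
  }
  fit <- fit_family(spec$family, hp, x, y, spec$seed)
  structure(list(family = spec$family, hyperparameters = hp,
                 fit = fit, p = ncol(x)),
            class = "equispeed_fit")
}

tune_hyperparameters <- function(spec, x, y, subjects) {
  if (is.null(subjects)) subjects <- rep("all", length(y))
  folds <- grouped_folds(subjects, k = min(3, length(unique(subjects))),
                         seed = spec$seed)
  scores <- vapply(spec$tune, function(hp0) {
    hp <- utils::modifyList(spec$hyperparameters, hp0)
    pred <- rep(NA_real_, length(y))
    for (f in unique(folds)) {
      tr <- folds != f
      fit <- fit_family(spec$family, hp, x[tr, , drop = FALSE], y[tr], spec$seed)
      pred[!tr] <- predict_family(spec$family,
                                  structure(list(fit = fit), class = "equispeed_fit"),
                                  x[!tr, , drop = FALSE])
    }
    rmse(pred, y)
  }, numeric(1))
  utils::modifyList(spec$hyperparameters, spec$tune[[which.min(scores)]])
}

fit_family <- function(family, hp, x, y, seed) {
  switch(family,
    rf = ranger::ranger(
      x = as.data.frame(x), y = y,
      num.trees = hp$num.trees,
      mtry = if (is.null(hp$mtry)) NULL else min(hp$mtry, ncol(x)),
      min.node.size = hp$min.node.size,
      seed = seed, num.threads = 1, verbose = FALSE
    ),
    dt = {
      d <- data.frame(.y = y, x, check.names = TRUE)
      rpart::rpart(.y ~ ., data = d, method = "anova",
                   control = rpart::rpart.control(cp = hp$cp,
                                                  minsplit = hp$minsplit,
                                                  maxdepth = hp$maxdepth))
    },
    bt = {
      set.seed(seed)
      xgboost::xgb.train(
        params = list(objective = "reg:squarederror", eta = hp$eta,
                      max_depth = hp$max_depth, subsample = hp$subsample,
                      tree_method = "hist", max_bin = 64,
                      seed = seed, nthread = 1),
        data = xgboost::xgb.DMatrix(data = x, label = y, nthread = 1),
        nrounds = hp$nrounds, verbose = 0)
    },
    svm = e1071::svm(x = x, y = y, type = "eps-regression",
                     kernel = hp$kernel, cost = hp$cost, epsilon = hp$epsilon,
                     scale = apply(x, 2, sd) > 0),
    gpr = {
      set.seed(seed) # sigma estimation of the RBF kernel samples data
      fit <- NULL
      invisible(capture.output(
        fit <- kernlab::gausspr(x = x, y = y, kernel = hp$kernel,
                                var = hp$var, scaled = apply(x, 2, sd) > 0)))
      fit
    }
  )
}

#' @rdname fit_model
#' @param object A fitted wrapper from [fit_model()].
#' @param newx Numeric design matrix with the same columns as `x`.
#' @export
predict_model <- function(object, newx) {
  stopifnot(inherits(object, "equispeed_fit"))
  predict_family(object$family, object, newx)
}

predict_family <- function(family, object, newx) {
  fit <- object$fit
  switch(family,
    rf = predict(fit, data = as.data.frame(newx), num.threads = 1)$predictions,
    dt = as.numeric(predict(fit, newdata = as.data.frame(newx))),
    bt = as.numeric(predict(fit, xgboost::xgb.DMatrix(newx, nthread = 1))),
    svm = as.numeric(predict(fit, newdata = newx)),
    gpr = as.numeric(kernlab::predict(fit, newx))
  )
}

# deterministic subject-grouped fold assignment
grouped_folds <- function(subjects, k, seed) {
  subj <- sort(unique(subjects))
  if (k > length(subj)) stop("k exceeds the number of subjects")
  set.seed(seed)
  perm <- sample(subj)
  assign <- setNames(rep(seq_len(k), length.out = length(subj)), perm)
  unname(assign[subjects])
}

#' Leave-one-subject-out evaluation of one model on one feature set
#'
#' One fold per subject: the model is refit on all other subjects and
#' predicts the held-out subject's windows. Predictions are pooled across
#' folds before computing MAE, RMSE and nRMSE; per-gait metrics are
#' computed on the pooled predictions grouped by the window gait label.
#'
#' @param fm A `feature_matrix` (from [build_feature_matrix()]).
#' @param spec A [model_spec()].
#' @param selection Optional `sffs_selection` (or character vector of
#'   feature names); default: all feature columns.
#' @return An `evaluation_report`: list with `feature_set`, `family`,
#'   `mae`, `rmse`, `nrmse`, `per_gait` (data frame `gait`, `n`,
#'   `mean_speed`, `rmse`, `nrmse`), and the pooled `predictions` data
#'   frame.
#' @export
loso_cv <- function(fm, spec, selection = NULL) {
  stopifnot(inherits(fm, "data.frame"))
  features <- selection_features(selection, fm)
  subjects <- fm$subject_id
  subj <- unique(subjects)
  if (length(subj) < 2) stop("LOSO needs at least 2 subjects")
  zero <- table(factor(subjects, levels = subj)) == 0
  if (any(zero)) warning("subject(s) without windows dropped")

  x <- as_design(fm, features)
  y <- fm$speed
  pred <- rep(NA_real_, length(y))
  for (s in subj) {
    test <- subjects == s
    fit <- fit_model(spec, x[!test, , drop = FALSE], y[!test],
                     subjects = subjects[!test])
    pred[test] <- predict_model(fit, x[test, , drop = FALSE])
  }

  per_gait <- do.call(rbind, lapply(split(seq_along(y), fm$gait), function(i) {
    r <- rmse(pred[i], y[i])
    data.frame(gait = fm$gait[i[1]], n = length(i),
               mean_speed = mean(y[i]), rmse = r,
               nrmse = nrmse(r, measured = y[i]))
  }))
  rownames(per_gait) <- NULL

  structure(list(
    feature_set = attr(fm, "feature_set"),
    family = spec$family,
    n_subjects = length(subj),
    n_windows = length(y),
    n_features = length(features),
    mae = mae(pred, y),
    rmse = rmse(pred, y),
    nrmse = nrmse(estimated = pred, measured = y),
    per_gait = per_gait,
    predictions = data.frame(window_id = fm$window_id,
                             subject_id = subjects, gait = fm$gait,
                             measured = y, estimated = pred,
                             stringsAsFactors = FALSE),
    hyperparameters = spec$hyperparameters,
    seed = spec$seed
  ), class = "evaluation_report")
}

selection_features <- function(selection, fm) {
  if (is.null(selection)) return(feature_columns(fm))
  if (inherits(selection, "sffs_selection")) return(selection$ordered_features)
  as.character(selection)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s x %s: MAE %.3f, RMSE %.3f m/s, nRMSE %.2f%% (%d windows, %d subjects)\n",
              x$feature_set, x$family, x$mae, x$rmse, x$nrmse,
              x$n_windows, x$n_subjects))
  print(x$per_gait, digits = 3)
  invisible(x)
}

#' Run the full feature-set x model-family grid
#'
#' Evaluates every requested feature set under every model family with
#' [loso_cv()] — 55 cells for the 11 standard sets and 5 families. The
#' `All` feature matrix is built once and column-subset per set. A failed
#' cell is recorded (with its error message) and the grid still returns.
#'
#' @param windows A `speed_windows` object covering all 7 locations.
#' @param families Character vector of model families.
#' @param sets Character vector of feature-set names.
#' @param specs Optional named list of [model_spec()]s keyed by family
#'   (overrides `families` defaults).
#' @param selections Optional named list of selections keyed by set name.
#' @param seed Seed passed to default model specs.
#' @return A `grid_result`: list with `reports` (list of
#'   `evaluation_report` or `grid_failure`) and `table` (a data frame
#'   shaped rows = feature sets, columns = MAE/RMSE per family).
#' @export
run_grid <- function(windows, families = c("svm", "dt", "rf", "bt", "gpr"),
                     sets = names(feature_set_defs()),
                     specs = NULL, selections = NULL, seed = 1L) {
  fm_all <- build_feature_matrix(windows, "All")
  if (is.null(specs))
    specs <- setNames(lapply(families, model_spec, seed = seed), families)

  reports <- list()
  for (set in sets) {
    locs <- feature_set_defs()[[set]]
    cols <- unlist(lapply(locs, function(loc)
      grep(sprintf("(%s)", loc), names(fm_all), fixed = TRUE, value = TRUE)))
    fm <- fm_all[, c("window_id", "subject_id", "breed", "gait", "speed", cols)]
    attr(fm, "feature_set") <- set
    class(fm) <- c("feature_matrix", "data.frame")
    for (fam in families) {
      key <- paste(set, fam, sep = " x ")
      reports[[key]] <- tryCatch(
        loso_cv(fm, specs[[fam]], selection = selections[[set]]),
        error = function(e) structure(list(feature_set = set, family = fam,
                                           error = conditionMessage(e)),
                                      class = "grid_failure")
      )
    }
  }

  tab <- data.frame(feature_set = sets, stringsAsFactors = FALSE)
  for (fam in families) {
    tab[[paste0("MAE_", fam)]] <- vapply(sets, function(set) {
      r <- reports[[paste(set, fam, sep = " x ")]]
      if (inherits(r, "grid_failure")) NA_real_ else r$mae
    }, numeric(1))
    tab[[paste0("RMSE_", fam)]] <- vapply(sets, function(set) {
      r <- reports[[paste(set, fam, sep = " x ")]]
      if (inherits(r, "grid_failure")) NA_real_ else r$rmse
    }, numeric(1))
  }
  structure(list(reports = reports, table = tab), class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("<grid_result> %d cells\n", length(x$reports)))
  print(x$table, digits = 3, row.names = FALSE)
  invisible(x)
}
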