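#' Reference hyperparameters for the classical baselines
#'
#' Grid-search-selected settings for the four baseline families: a max-margin
#' RBF-kernel classifier (`svm`: C = 10, scale-style gamma), a random decision
#' forest (`rf`: 1000 trees, depth 3), Gaussian naive Bayes (`nb`: variance
#' smoothing 1e-9) and gradient-boosted trees (`xgb`: depth 15, eta 0.1,
#' 2000 rounds, min child weight 5, subsample 0.8, column subsample 0.7,
#' lambda 0.4, scale_pos_weight 0.8, logistic objective).
#'
#' @param model One of `"svm"`, `"rf"`, `"nb"`, `"xgb"`.
#' @param ... Overrides merged over the defaults.
#' @return Named list of hyperparameters with attribute `model`.
#' @export
baseline_config <- function(model = c("svm", "rf", "nb", "xgb"), ...) {
  model <- match.arg(model)
  defaults <- switch(model,
    svm = list(C = 10, gamma = "scale", kernel = "rbf"),
    rf = list(n_estimators = 1000, max_depth = 3, random_state = 0),
    nb = list(var_smoothing = 1e-9),
    xgb = list(
      max_depth = 15, learning_rate = 0.1, n_estimators = 2000,
      min_child_weight = 5, max_delta_step = 0, subsample = 0.8,
      colsample_bytree = 0.7, reg_alpha = 0, reg_lambda = 0.4,
      scale_pos_weight = 0.8, objective = "binary:logistic",
      eval_metric = "auc", seed = 1440, gamma = 0
    )
  )
  cfg <- utils::modifyList(defaults, list(...))
  attr(cfg, "model") <- model
  cfg
}

#' Fit one classical baseline
#'
#' @param x Numeric feature matrix (samples x features).
#' @param y Binary 0/1 labels.
#' @param model Baseline family (see [baseline_config()]).
#' @param config Hyperparameters; defaults to [baseline_config()] for `model`.
#' @param seed Integer seed (tree-based learners).
#' @return Object of class `baseline_fit` usable with [predict_proba()].
#' @export
fit_baseline <- function(x, y, model = c("svm", "rf", "nb", "xgb"),
                         config = NULL, seed = 0) {
  model <- match.arg(model)
  cfg <- config %||% baseline_config(model)
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2) abort("both classes must be present for fitting")
  if (all(apply(x, 2, stats::var) == 0)) {
    warn("feature matrix has zero variance everywhere")
  }
  fit <- with_private_seed(derive_seed(seed, model), switch(model,
    svm = {
      gamma <- if (identical(cfg$gamma, "scale")) {
        v <- stats::var(as.vector(x))
        if (v == 0) 1 else 1 / (ncol(x) * v)
      } else {
        cfg$gamma
      }
      e1071::svm(x, factor(y, levels = c(0, 1)),
        kernel = "radial", cost = cfg$C, gamma = gamma,
        probability = TRUE, scale = FALSE
      )
    },
    rf = ranger::ranger(
      y = factor(y, levels = c(0, 1)), x = as.data.frame(x),
      num.trees = cfg$n_estimators, max.depth = cfg$max_depth,
      probability = TRUE, seed = cfg$random_state + seed,
      num.threads = 1
    ),
    nb = {
      nb <- e1071::naiveBayes(x, factor(y, levels = c(0, 1)))
      # emulate scikit-style variance smoothing so zero-variance features
      # cannot produce degenerate Gaussian densities
      floor_sd <- sqrt(cfg$var_smoothing * max(apply(x, 2, stats::var), 1e-12))
      nb$tables <- lapply(nb$tables, function(tab) {
        tab[, 2] <- pmax(tab[, 2], floor_sd)
        tab
      })
      nb
    },
    xgb = xgboost::xgb.train(
      params = list(
        max_depth = cfg$max_depth, eta = cfg$learning_rate,
        min_child_weight = cfg$min_child_weight,
        max_delta_step = cfg$max_delta_step, subsample = cfg$subsample,
        colsample_bytree = cfg$colsample_bytree, alpha = cfg$reg_alpha,
        lambda = cfg$reg_lambda, scale_pos_weight = cfg$scale_pos_weight,
        objective = cfg$objective, eval_metric = cfg$eval_metric,
        gamma = cfg$gamma, nthread = 1, seed = cfg$seed + seed
      ),
      data = xgboost::xgb.DMatrix(x, label = y),
      nrounds = cfg$n_estimators, verbose = 0
    )
  ))
  structure(list(model = model, config = cfg, fit = fit, n_features = ncol(x)),
    class = "baseline_fit"
  )
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat("<baseline_fit>", x$model, "on", x$n_features, "features\n")
  invisible(x)
}

#' Druggability probability for new samples
#'
#' @param object A fitted classifier (`baseline_fit`, `dnn_fit`, `capsnet_fit`,
#'   `bilstm_fit`, `gpt_fit`, or a fine-tuned embedder).
#' @param x New feature matrix (or records, for sequence models).
#' @param ... Unused.
#' @return Numeric vector of probabilities in \[0, 1\] for the positive
#'   (druggable) class.
#' @export
predict_proba <- function(object, x, ...) UseMethod("predict_proba")

#' @export
predict_proba.baseline_fit <- function(object, x, ...) {
  x <- as.matrix(x)
  if (ncol(x) != object$n_features) abort("feature width differs from training")
  switch(object$model,
    svm = {
      pr <- attr(predict(object$fit, x, probability = TRUE), "probabilities")
      unname(pr[, "1"])
    },
    rf = unname(predict(object$fit, as.data.frame(x), num.threads = 1)$predictions[, "1"]),
    nb = unname(predict(object$fit, x, type = "raw")[, "1"]),
    xgb = unname(predict(object$fit, xgboost::xgb.DMatrix(x)))
  )
}

#' Cross-validate a classifier on a feature matrix
#'
#' Runs a stratified k-fold plan, fits on each training portion and scores the
#' held-out fold with the six confusion-matrix metrics plus AUC
#' (threshold 0.5 for the hard calls).
#'
#' @param x Feature matrix.
#' @param y Binary labels.
#' @param fit_fun `function(x_train, y_train)` returning an object supported
#'   by [predict_proba()] — or a baseline family name.
#' @param k Number of folds.
#' @param seed Integer seed (fold assignment and fitting).
#' @return Tibble of per-fold rows: `fold`, `acc`, `p`, `sn`, `sp`, `f1`,
#'   `mcc`, `auc`.
#' @export
cross_validate <- function(x, y, fit_fun = "xgb", k = 5, seed = 1) {
  if (is.character(fit_fun)) {
    fam <- fit_fun
    fit_fun <- function(xtr, ytr) fit_baseline(xtr, ytr, fam, seed = seed)
  }
  x <- as.matrix(x)
  plan <- kfold_plan(y, k = k, seed = seed)
  purrr::imap_dfr(plan, function(fold, i) {
    fit <- fit_fun(x[fold$fit, , drop = FALSE], y[fold$fit])
    prob <- predict_proba(fit, x[fold$holdout, , drop = FALSE])
    truth <- y[fold$holdout]
    m <- compute_metrics(truth, as.integer(prob >= 0.5))
    auc <- if (length(unique(truth)) == 2) roc_auc(prob, truth)$auc else NA_real_
    dplyr::bind_cols(tibble::tibble(fold = i), m, tibble::tibble(auc = auc))
  })
}

#' Run the four classical baselines over one train/test split
#'
#' Fits each family with its reference hyperparameters on the training rows
#' of the split, evaluates with k-fold cross-validation within the training
#' rows (mean and sd per metric) and once on the held-out test rows.
#'
#' @param features Feature tibble (`id`, `label`, feature columns).
#' @param split A [stratified_three_way_split()] result (validation rows are
#'   folded into training for cross-validation, mirroring a final refit).
#' @param models Subset of `c("svm", "rf", "nb", "xgb")`.
#' @param k Folds for the within-training cross-validation.
#' @param seed Integer seed.
#' @return List with `cv` (tibble: model, metric, mean, sd) and `test`
#'   (tibble: one metric row per model on the test split).
#' @export
run_baselines <- function(features, split, models = c("svm", "rf", "nb", "xgb"),
                          k = 5, seed = 1) {
  fm <- feature_matrix(features)
  tr <- sort(c(split$indices$train, split$indices$validation))
  te <- split$indices$test
  cv <- purrr::map_dfr(models, function(mod) {
    folds <- cross_validate(fm$x[tr, , drop = FALSE], fm$y[tr], mod, k = k, seed = seed)
    dplyr::bind_cols(tibble::tibble(model = mod), summarize_folds(folds))
  })
  test <- purrr::map_dfr(models, function(mod) {
    fit <- fit_baseline(fm$x[tr, , drop = FALSE], fm$y[tr], mod, seed = seed)
    prob <- predict_proba(fit, fm$x[te, , drop = FALSE])
    m <- compute_metrics(fm$y[te], as.integer(prob >= 0.5))
    auc <- roc_auc(prob, fm$y[te])$auc
    dplyr::bind_cols(tibble::tibble(model = mod), m, tibble::tibble(auc = auc))
  })
  list(cv = cv, test = test)
}
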