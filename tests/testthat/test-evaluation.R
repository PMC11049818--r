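fake_records <- function(n, prefix) {
  tibble::tibble(id = sprintf("%s%05d", prefix, seq_len(n)), sequence = strrep("A", 10))
}

test_that("downsampling balances 704 against 5516 reproducibly", {
  pos <- fake_records(704, "tclin")
  neg <- fake_records(5516, "tdark")
  bal <- balance_by_downsampling(pos, neg, seed = 42)
  expect_equal(nrow(bal), 1408)
  expect_equal(sum(bal$label == 1), 704)
  expect_equal(sum(bal$label == 0), 704)
  again <- balance_by_downsampling(pos, neg, seed = 42)
  expect_identical(bal, again)
  other <- balance_by_downsampling(pos, neg, seed = 43)
  expect_false(identical(bal$id, other$id))
  # equal classes pass through untouched
  same <- balance_by_downsampling(pos, fake_records(704, "x"), seed = 1)
  expect_equal(nrow(same), 1408)
  expect_identical(same$id[1:704], pos$id)
})

test_that("the two-stage stratified split reproduces the published class counts", {
  jam <- tibble::tibble(label = rep(c(1L, 0L), c(1224, 1319)))
  s <- stratified_three_way_split(jam, seed = 1)
  expect_equal(
    s$counts[s$counts$label == 1, c("train", "validation", "test")],
    tibble::tibble(train = 784, validation = 196, test = 244)
  )
  expect_equal(
    s$counts[s$counts$label == 0, c("train", "validation", "test")],
    tibble::tibble(train = 845, validation = 211, test = 263)
  )
  ph <- tibble::tibble(label = rep(c(1L, 0L), c(704, 704)))
  s2 <- stratified_three_way_split(ph, seed = 1)
  expect_true(all(s2$counts$train == 452))
  expect_true(all(s2$counts$validation == 112))
  expect_true(all(s2$counts$test == 140))
  # floor at both stages on a small class
  ten <- tibble::tibble(label = rep(1:0, c(10, 10)))
  s3 <- stratified_three_way_split(ten, seed = 2)
  expect_equal(unlist(s3$counts[1, c("train", "validation", "test")], use.names = FALSE), c(7, 1, 2))
  expect_error(stratified_three_way_split(tibble::tibble(label = c(1, 1, 0)), seed = 1), "fewer than 3")
})

test_that("split index sets are disjoint, exhaustive and seed-deterministic", {
  withr::with_seed(6, df <- tibble::tibble(label = sample(0:1, 57, TRUE, prob = c(.6, .4))))
  s <- stratified_three_way_split(df, seed = 9)
  all_idx <- sort(unname(unlist(s$indices)))
  expect_equal(all_idx, seq_len(57))
  expect_identical(s$indices, stratified_three_way_split(df, seed = 9)$indices)
  expect_false(identical(s$indices, stratified_three_way_split(df, seed = 10)$indices))
})

test_that("k-fold plans are stratified partitions with near-equal folds", {
  y10 <- rep(c(1, 0), 5)
  plan <- kfold_plan(y10, k = 5, seed = 1)
  expect_true(all(vapply(plan, function(f) length(f$holdout), numeric(1)) == 2))
  y11 <- rep(c(1, 0), c(6, 5))
  plan2 <- kfold_plan(y11, k = 5, seed = 1)
  sizes <- sort(vapply(plan2, function(f) length(f$holdout), numeric(1)), decreasing = TRUE)
  expect_equal(sizes, c(3, 2, 2, 2, 2))
  hold <- unlist(lapply(plan2, `[[`, "holdout"))
  expect_equal(sort(hold), seq_len(11))
  expect_equal(anyDuplicated(hold), 0)
  for (f in plan2) expect_equal(sort(c(f$fit, f$holdout)), seq_len(11))
  expect_error(kfold_plan(y10, k = 1), "k")
})

test_that("the six metrics match their closed forms on anchor cases", {
  perfect <- compute_metrics(list(tp = 5, fp = 0, tn = 5, fn = 0))
  expect_equal(unlist(perfect), c(acc = 1, p = 1, sn = 1, sp = 1, f1 = 1, mcc = 1))
  m <- compute_metrics(list(tp = 2, fp = 1, tn = 3, fn = 0))
  expect_equal(m$acc, 5 / 6)
  expect_equal(m$p, 2 / 3)
  expect_equal(m$sn, 1)
  expect_equal(m$sp, 3 / 4)
  expect_equal(m$f1, 0.8)
  expect_equal(m$mcc, 6 / sqrt(72))
  worst <- compute_metrics(list(tp = 0, fp = 3, tn = 0, fn = 3))
  expect_equal(worst$acc, 0)
  expect_equal(worst$mcc, -1)
  expect_warning(z <- compute_metrics(list(tp = 0, fp = 0, tn = 4, fn = 0)), "MCC")
  expect_equal(z$mcc, 0)
})

test_that("metrics agree with an independent confusion-matrix oracle on random counts", {
  withr::with_seed(21, {
    for (i in 1:200) {
      cts <- as.list(setNames(sample(0:40, 4, TRUE), c("tp", "fp", "tn", "fn")))
      if (sum(unlist(cts)) == 0) cts$tp <- 1
      m <- suppressWarnings(compute_metrics(cts))
      with(cts, {
        expect_equal(m$acc, (tp + tn) / (tp + fp + tn + fn))
        expect_equal(m$f1, 2 * tp / (2 * tp + fp + fn))
        den <- (tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
        if (den > 0) expect_equal(m$mcc, (tp * tn - fp * fn) / sqrt(den))
      })
    }
  })
})

test_that("AUC equals exhaustive pair counting and the trapezoidal ROC area", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))$auc, 0.75)
  pair_auc <- function(scores, labels) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  withr::with_seed(22, {
    for (i in 1:30) {
      n <- sample(6:40, 1)
      labels <- c(1, 0, sample(0:1, n - 2, TRUE))
      scores <- round(runif(n), 2) # coarse grid forces ties
      r <- roc_auc(scores, labels)
      expect_equal(r$auc, pair_auc(scores, labels))
      expect_equal(r$auc, drugseqr:::trapezoid_auc(r$roc), tolerance = 1e-9)
    }
  })
  expect_error(roc_auc(runif(4), rep(1, 4)), "both classes")
})

test_that("AUC agrees with the reference ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(23, {
    scores <- runif(60)
    labels <- sample(0:1, 60, TRUE)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE, direction = "<")))
    expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-12)
  })
})

test_that("attribution-group aggregation averages absolute values per group", {
  a <- matrix(c(1, -1, 2, 0, 3, 1, -2, 0), 2, 4, byrow = TRUE)
  out <- aggregate_group_importance(a, groups = c("g1", "g1", "g2", "g2"))
  expect_equal(out$importance[out$group == "g1"], 1.5)
  expect_equal(out$importance[out$group == "g2"], 1.0)
  expect_equal(out$group[1], "g1") # sorted descending
  zero <- aggregate_group_importance(matrix(0, 3, 4), groups = rep(c("a", "b"), 2))
  expect_true(all(zero$importance == 0))
  # homogeneity under scaling
  out3 <- aggregate_group_importance(-3 * a, groups = c("g1", "g1", "g2", "g2"))
  expect_equal(out3$importance, 3 * out$importance)
  expect_error(aggregate_group_importance(a, groups = c("g1", "g1")), "per feature")
})

test_that("the baseline configurations carry the documented hyperparameters", {
  svm <- baseline_config("svm")
  expect_equal(svm$C, 10)
  expect_equal(svm$gamma, "scale")
  expect_equal(svm$kernel, "rbf")
  rf <- baseline_config("rf")
  expect_equal(rf$n_estimators, 1000)
  expect_equal(rf$max_depth, 3)
  nb <- baseline_config("nb")
  expect_equal(nb$var_smoothing, 1e-9)
  xgb <- baseline_config("xgb")
  expect_equal(xgb$max_depth, 15)
  expect_equal(xgb$learning_rate, 0.1)
  expect_equal(xgb$n_estimators, 2000)
  expect_equal(xgb$subsample, 0.8)
  expect_equal(xgb$reg_lambda, 0.4)
  expect_equal(xgb$scale_pos_weight, 0.8)
  expect_equal(xgb$objective, "binary:logistic")
  expect_equal(baseline_config("svm", C = 1)$C, 1) # overrides merge
})

test_that("every baseline family separates synthetic blobs", {
  withr::with_seed(30, {
    n <- 120
    y <- rep(c(1L, 0L), each = n / 2)
    x <- matrix(rnorm(n * 2), n, 2) + 3 * cbind(y, y)
    colnames(x) <- c("f1", "f2")
  })
  tr <- seq(1, n, by = 2)
  te <- seq(2, n, by = 2)
  for (mod in c("svm", "rf", "nb", "xgb")) {
    cfg <- if (mod == "xgb") baseline_config("xgb", n_estimators = 100) else NULL
    fit <- fit_baseline(x[tr, ], y[tr], mod, config = cfg, seed = 1)
    acc <- mean((predict_proba(fit, x[te, ]) >= 0.5) == y[te])
    expect_gte(acc, 0.95)
  }
})

test_that("cross-validation on shuffled labels stays at chance", {
  withr::with_seed(31, {
    x <- matrix(rnorm(200 * 10), 200, 10)
    colnames(x) <- paste0("f", 1:10)
    y <- sample(rep(0:1, 100))
  })
  folds <- cross_validate(x, y, "nb", k = 5, seed = 3)
  expect_equal(mean(folds$acc), 0.5, tolerance = 0.1)
})
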