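#' Balance two classes by downsampling the larger one
#'
#' The larger class is sampled without replacement down to the size of the
#' smaller class with a seeded generator, so the balanced dataset is exactly
#' reproducible. With 704 clinically validated targets against 5516 unstudied
#' proteins this yields the 704 + 704 benchmark design.
#'
#' @param pos,neg Record tibbles for the positive and negative class.
#' @param seed Integer seed for the downsampling draw.
#' @return Tibble of positives followed by the retained negatives, with a
#'   `label` column (1 then 0).
#' @export
balance_by_downsampling <- function(pos, neg, seed = 42) {
  assert_records(pos)
  assert_records(neg)
  if (nrow(pos) == 0 || nrow(neg) == 0) abort("both classes must be non-empty")
  pos$label <- 1L
  neg$label <- 0L
  n <- min(nrow(pos), nrow(neg))
  with_private_seed(seed, {
    if (nrow(pos) > n) pos <- pos[sort(sample.int(nrow(pos), n)), ]
    if (nrow(neg) > n) neg <- neg[sort(sample.int(nrow(neg), n)), ]
  })
  dplyr::bind_rows(pos, neg)
}

#' Stratified two-stage train/validation/test split
#'
#' Per class, the test set takes `floor(test_frac * N)` samples; the
#' validation set then takes `floor(val_frac * (N - test))` of the remainder;
#' everything else trains. Assignment within a class is a seeded permutation.
#' This floor-at-both-stages convention reproduces the published per-class
#' counts for class totals 1224/1319 (784/845 train, 196/211 validation,
#' 244/263 test) and 704/704 (452, 112, 140 per class).
#'
#' @param records Labeled record tibble (or any tibble with a `label` column).
#' @param test_frac,val_frac Held-out fractions (defaults 0.2 and 0.2).
#' @param seed Integer seed.
#' @return A list of class `three_way_split`: `counts` (tibble of per-class
#'   train/validation/test sizes) and `indices` (list of integer row-index
#'   vectors `train`, `validation`, `test`).
#' @export
stratified_three_way_split <- function(records, test_frac = 0.2, val_frac = 0.2, seed = 1) {
  stopifnot(is.data.frame(records), "label" %in% names(records))
  if (!all(records$label %in% c(0, 1))) abort("labels must be binary 0/1")
  idx <- list(train = integer(), validation = integer(), test = integer())
  counts <- list()
  for (cl in c(1L, 0L)) {
    rows <- which(records$label == cl)
    n <- length(rows)
    if (n < 3) abort(paste0("class ", cl, " has fewer than 3 samples"))
    n_test <- floor(test_frac * n)
    n_val <- floor(val_frac * (n - n_test))
    perm <- with_private_seed(derive_seed(seed, paste0("split", cl)), sample(rows))
    idx$test <- c(idx$test, perm[seq_len(n_test)])
    idx$validation <- c(idx$validation, perm[n_test + seq_len(n_val)])
    idx$train <- c(idx$train, perm[-(seq_len(n_test + n_val))])
    counts[[as.character(cl)]] <- tibble::tibble(
      label = cl, train = n - n_test - n_val, validation = n_val, test = n_test
    )
  }
  idx <- lapply(idx, sort)
  structure(list(counts = dplyr::bind_rows(counts), indices = idx, seed = seed),
    class = "three_way_split"
  )
}

#' @export
print.three_way_split <- function(x, ...) {
  cat("<three_way_split> seed=", x$seed, "\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Stratified k-fold plan
#'
#' Folds are disjoint, exhaustive, stratified by label and near-equal in size
#' (any two fold sizes differ by at most 1).
#'
#' @param labels Binary label vector (the indices returned refer to its
#'   positions) — or a labeled tibble, in which case its `label` column is used.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return List of `k` elements, each `list(fit = <indices>, holdout = <indices>)`.
#' @export
kfold_plan <- function(labels, k = 5, seed = 1) {
  if (is.data.frame(labels)) labels <- labels$label
  if (k < 2) abort("k must be >= 2")
  n <- length(labels)
  if (n < k) abort("need at least k samples")
  fold_of <- integer(n)
  for (cl in unique(labels)) {
    rows <- which(labels == cl)
    perm <- with_private_seed(derive_seed(seed, paste0("fold", cl)), sample(rows))
    fold_of[perm] <- rep_len(seq_len(k), length(perm))
  }
  lapply(seq_len(k), function(f) {
    list(fit = which(fold_of != f), holdout = which(fold_of == f))
  })
}

#' Confusion counts from predictions
#' @param truth Binary 0/1 vector.
#' @param predicted Binary 0/1 vector (same length).
#' @return One-row tibble with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  tibble::tibble(
    tp = sum(truth == 1 & predicted == 1),
    fp = sum(truth == 0 & predicted == 1),
    tn = sum(truth == 0 & predicted == 0),
    fn = sum(truth == 1 & predicted == 0)
  )
}

#' The six confusion-matrix metrics
#'
#' Accuracy, precision, sensitivity (recall), specificity, F1 and the
#' Matthews correlation coefficient, computed exactly from the four counts:
#' \deqn{ACC = (TP+TN)/N,\; P = TP/(TP+FP),\; SN = TP/(TP+FN),}
#' \deqn{SP = TN/(TN+FP),\; F1 = 2TP/(2TP+FP+FN),}
#' \deqn{MCC = (TP\cdot TN - FP\cdot FN)/\sqrt{(TP+FN)(TN+FP)(TP+FP)(TN+FN)}.}
#' A metric whose denominator is zero is returned as `NaN`, except MCC which
#' follows the standard zero-denominator convention and returns 0 (with a
#' warning).
#'
#' @param counts One-row tibble/list with `tp`, `fp`, `tn`, `fn` — or the
#'   `truth` vector, in which case `predicted` must be given too.
#' @param predicted Optional 0/1 predictions when `counts` is a truth vector.
#' @return One-row tibble: `acc`, `p`, `sn`, `sp`, `f1`, `mcc`.
#' @examples
#' compute_metrics(list(tp = 2, fp = 1, tn = 3, fn = 0))
#' @export
compute_metrics <- function(counts, predicted = NULL) {
  if (!is.null(predicted)) counts <- confusion_counts(counts, predicted)
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  n <- tp + fp + tn + fn
  if (n <= 0) abort("confusion counts sum to zero")
  denom <- sqrt(prod(c(tp + fn, tn + fp, tp + fp, tn + fn)))
  mcc <- if (denom == 0) {
    warn("MCC denominator is zero; returning 0 by convention")
    0
  } else {
    (tp * tn - fp * fn) / denom
  }
  tibble::tibble(
    acc = (tp + tn) / n,
    p = tp / (tp + fp),
    sn = tp / (tp + fn),
    sp = tn / (tn + fp),
    f1 = 2 * tp / (2 * tp + fp + fn),
    mcc = mcc
  )
}

#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney pair statistic — the probability that a
#' randomly drawn positive scores above a randomly drawn negative, counting
#' ties as one half — which equals the trapezoidal area under the ROC curve.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary 0/1 truth, both classes present.
#' @return List of class `roc_result`: `auc` (scalar) and `roc` (tibble of
#'   `threshold`, `fpr`, `tpr` points, one per distinct score plus endpoints).
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) abort("ROC needs both classes present")
  r <- rank(scores) # midranks handle ties
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- purrr::map(thr, function(t) {
    pred <- as.integer(scores >= t)
    tibble::tibble(
      threshold = t,
      fpr = sum(pred == 1 & labels == 0) / n_neg,
      tpr = sum(pred == 1 & labels == 1) / n_pos
    )
  })
  roc <- dplyr::bind_rows(
    tibble::tibble(threshold = Inf, fpr = 0, tpr = 0),
    dplyr::bind_rows(pts)
  )
  structure(list(auc = auc, roc = roc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC =", format(x$auc, digits = 4), "\n")
  invisible(x)
}

# trapezoidal integral of the ROC polyline; used as a cross-check of the
# pair-counting AUC
trapezoid_auc <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  f <- roc$fpr[o]; t <- roc$tpr[o]
  sum(diff(f) * (head(t, -1) + tail(t, -1)) / 2)
}

#' Aggregate attribution magnitudes over feature groups
#'
#' Per feature, the mean absolute attribution over samples; per group, the
#' mean of its features' scores. This is the standard way to rank descriptor
#' families (for example the three 400-feature profile blocks) from a matrix
#' of per-sample attribution values such as SHAP values.
#'
#' @param attributions Samples x features numeric matrix (or tibble).
#' @param groups Character vector tagging each column with its group; groups
#'   must partition the columns.
#' @return Tibble (`group`, `n_features`, `importance`) sorted by descending
#'   importance.
#' @export
aggregate_group_importance <- function(attributions, groups = attr(attributions, "groups")) {
  a <- as.matrix(attributions)
  if (is.null(groups)) abort("`groups` is required")
  if (length(groups) != ncol(a)) abort("one group tag per feature column is required")
  per_feature <- colMeans(abs(a))
  out <- tibble::tibble(group = groups, score = per_feature) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_features = dplyr::n(), importance = mean(.data$score)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
  if (any(out$n_features == 0)) abort("empty feature group")
  out
}

#' Per-fold metrics summarised as mean and standard deviation
#' @param fold_metrics Tibble of per-fold metric rows (as from [cross_validate()]).
#' @return Tibble with one row per metric: `metric`, `mean`, `sd`.
#' @export
summarize_folds <- function(fold_metrics) {
  fold_metrics |>
    dplyr::select(dplyr::any_of(c("acc", "p", "sn", "sp", "f1", "mcc", "auc"))) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value))
}
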