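#' Regression metrics
#'
#' Coefficient of determination (R2 = 1 - SS_res/SS_tot), mean absolute
#' error, and sample Pearson correlation between predictions and observed
#' values.
#'
#' @param pred,actual numeric vectors of equal length >= 2.
#' @return named vector `c(r2, mae, pearson)`; `pearson` is NaN with a
#'   warning when `actual` is constant.
#' @export
regression_metrics <- function(pred, actual) {
  stopifnot(length(pred) == length(actual), length(pred) >= 2)
  ss_res <- sum((actual - pred)^2)
  ss_tot <- sum((actual - mean(actual))^2)
  r2 <- 1 - ss_res / ss_tot
  mae <- mean(abs(pred - actual))
  if (stats::sd(actual) == 0) {
    warnf("constant actual values: Pearson r undefined")
    r <- NaN
  } else if (stats::sd(pred) == 0) {
    r <- NaN
  } else {
    r <- stats::cor(pred, actual)
  }
  c(r2 = r2, mae = mae, pearson = r)
}

## binary AUROC by midranks (ties handled by average rank)
auroc_binary <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## binary area under the precision-recall curve (step interpolation,
## ties grouped at equal thresholds)
auprc_binary <- function(scores, positive) {
  P <- sum(positive)
  if (P == 0 || all(positive)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- positive[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Classification metrics
#'
#' Accuracy, macro-averaged F1 / precision / recall on argmax predictions,
#' and macro one-vs-rest AUROC / AUPRC on the probability columns.  Classes
#' present in the class list but absent from the labels contribute 0 to the
#' macro F1 (with a warning) and are skipped for AUROC/AUPRC.
#'
#' @param proba batch x C probability matrix (rows sum to 1); column names,
#'   if present, must match the label levels.
#' @param labels factor (or integer indices in 1..C).
#' @return named vector `c(accuracy, macro_f1, precision, recall, auroc, auprc)`.
#' @export
classification_metrics <- function(proba, labels) {
  C <- ncol(proba)
  if (is.factor(labels)) {
    if (nlevels(labels) != C)
      stopf("probability matrix has %d columns but labels have %d levels",
            C, nlevels(labels))
    y <- as.integer(labels)
  } else y <- as.integer(labels)
  if (any(y < 1 | y > C)) stopf("label outside 1..%d", C)
  pred <- max.col(proba, ties.method = "first")
  acc <- mean(pred == y)
  f1 <- prec <- rec <- auc <- apr <- numeric(C)
  absent <- logical(C)
  for (c in seq_len(C)) {
    tp <- sum(pred == c & y == c)
    fpv <- sum(pred == c & y != c)
    fn <- sum(pred != c & y == c)
    prec[c] <- if (tp + fpv > 0) tp / (tp + fpv) else 0
    rec[c] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[c] <- if (prec[c] + rec[c] > 0) 2 * prec[c] * rec[c] / (prec[c] + rec[c]) else 0
    pos <- y == c
    absent[c] <- !any(pos)
    auc[c] <- auroc_binary(proba[, c], pos)
    apr[c] <- auprc_binary(proba[, c], pos)
  }
  if (any(absent))
    warnf("class(es) absent from labels contribute 0 to macro-F1: %s",
          paste(which(absent), collapse = ", "))
  c(accuracy = acc,
    macro_f1 = mean(f1),
    precision = mean(prec),
    recall = mean(rec),
    auroc = mean(auc, na.rm = TRUE),
    auprc = mean(apr, na.rm = TRUE))
}

#' Row-normalized confusion matrix
#'
#' Rows are actual classes, columns predicted; each supported row sums to 1
#' and its diagonal entry is the class recall.  Zero-support classes give
#' an all-zero row and are flagged.
#'
#' @param pred_labels,labels vectors of class labels.
#' @param class_list class order (default: levels of `labels` or the sorted
#'   union).
#' @return list of class `confusion_matrix`: `prop` (row-normalized),
#'   `counts`, `precision`, `recall`, `support`, `zero_support`.
#' @export
confusion_matrix <- function(pred_labels, labels, class_list = NULL) {
  if (is.null(class_list))
    class_list <- if (is.factor(labels)) levels(labels)
                  else sort(unique(as.character(labels)))
  labels <- as.character(labels); pred_labels <- as.character(pred_labels)
  if (!all(labels %in% class_list))
    stopf("label(s) outside the class list: %s",
          paste(setdiff(labels, class_list), collapse = ", "))
  if (!all(pred_labels %in% class_list))
    stopf("predicted label(s) outside the class list")
  f <- function(x) factor(x, levels = class_list)
  counts <- table(actual = f(labels), predicted = f(pred_labels))
  counts <- unclass(counts)
  support <- rowSums(counts)
  prop <- counts / ifelse(support > 0, support, 1)
  prop[support == 0, ] <- 0
  precision <- diag(counts) / pmax(colSums(counts), 1)
  recall <- diag(prop)
  structure(list(prop = prop, counts = counts, precision = precision,
                 recall = recall, support = support,
                 zero_support = class_list[support == 0]),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, digits = 3, ...) {
  cat("Row-normalized confusion matrix (rows = actual):\n")
  print(round(x$prop, digits))
  if (length(x$zero_support))
    cat("zero-support class(es):", paste(x$zero_support, collapse = ", "), "\n")
  invisible(x)
}

#' Two-tailed paired t test
#'
#' Standard paired Student t statistic on per-fold metric values.  When the
#' paired differences have zero variance the statistic is degenerate: the
#' p value is 1 if all differences are zero and 0 otherwise, flagged via
#' `degenerate = TRUE`.
#'
#' @param a,b numeric vectors of equal length >= 2, paired by fold.
#' @return list with `p_value`, `statistic`, `df`, `mean_diff`, `degenerate`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stopf("length mismatch: %d vs %d", length(a), length(b))
  if (length(a) < 2) stopf("need >= 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    return(list(p_value = if (all(d == 0)) 1 else 0,
                statistic = NA_real_, df = length(d) - 1L,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(p_value = unname(tt$p.value), statistic = unname(tt$statistic),
       df = unname(tt$parameter), mean_diff = mean(d), degenerate = FALSE)
}

## 95% CI of the mean via the t distribution
mean_ci <- function(x, level = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  m <- mean(x)
  if (n < 2) return(c(mean = m, lower = m, upper = m))
  half <- stats::qt(1 - (1 - level) / 2, n - 1) * stats::sd(x) / sqrt(n)
  c(mean = m, lower = m - half, upper = m + half)
}

## fold metrics for one prediction set
fold_metrics <- function(preds, targets) {
  if (inherits(targets, "response_matrix")) {
    per <- per_drug_metrics_matrix(preds, targets)
    colMeans(per[, c("r2", "mae", "pearson"), drop = FALSE], na.rm = TRUE)
  } else {
    classification_metrics(preds, targets)
  }
}

per_drug_metrics_matrix <- function(preds, targets, min_obs = 2L) {
  drugs <- colnames(targets$values)
  out <- lapply(seq_along(drugs), function(j) {
    obs <- targets$observed[, j]
    if (sum(obs) < min_obs) return(NULL)
    m <- suppressWarnings(
      regression_metrics(preds[obs, j], targets$values[obs, j]))
    data.frame(drug = drugs[j], n = sum(obs), r2 = m[["r2"]],
               mae = m[["mae"]], pearson = m[["pearson"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Repeated k-fold cross-validation
#'
#' `r` independent random shuffles, each split into `k` disjoint covering
#' folds (stratified by class for classification), yielding `k * r` values
#' per metric.  Regression metrics are computed per drug over the observed
#' test entries and then averaged across drugs; classification metrics come
#' from [classification_metrics()].  The 95% CI of the mean is taken from
#' the t distribution over the `k * r` values, treated as exchangeable.
#'
#' @param ds a `multiomic_dataset` with targets.
#' @param model_factory `function(train_ds)` returning a fitted object.
#' @param k folds (>= 2).
#' @param r repeats.
#' @param seed root seed; each repeat uses a derived sub-seed.
#' @param predict_fun `function(model, test_ds)` returning predictions
#'   (default calls [predict()]; classification must return probabilities).
#' @return object of class `eval_result`: `values` data frame
#'   (metric, repeat, fold, value), `summary` (mean and 95% CI per metric),
#'   `k`, `r`, `seed`.
#' @export
repeated_cv <- function(ds, model_factory, k = 5L, r = 5L, seed = 1L,
                        predict_fun = function(model, test_ds)
                          stats::predict(model, test_ds)) {
  stopifnot(inherits(ds, "multiomic_dataset"), k >= 2)
  N <- length(ds$sample_ids)
  if (N < k) stopf("need at least k = %d samples, have %d", k, N)
  classif <- inherits(ds$targets, "label_vector")
  rows_out <- list()
  for (rep_i in seq_len(r)) {
    set.seed(derive_seed(seed, sprintf("cv-rep-%d", rep_i)))
    fold_id <- integer(N)
    if (classif) {
      for (cl in levels(ds$targets)) {
        idx <- which(as.character(ds$targets) == cl)
        fold_id[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    } else {
      fold_id <- sample(rep_len(seq_len(k), N))
    }
    if (any(tabulate(fold_id, k) < 2))
      stopf("repeat %d produced a fold with < 2 samples", rep_i)
    for (fold in seq_len(k)) {
      test_ids <- ds$sample_ids[fold_id == fold]
      train_ids <- ds$sample_ids[fold_id != fold]
      fit <- model_factory(subset_dataset(ds, train_ids))
      test_ds <- subset_dataset(ds, test_ids)
      preds <- predict_fun(fit, test_ds)
      mets <- fold_metrics(preds, test_ds$targets)
      rows_out[[length(rows_out) + 1L]] <-
        data.frame(metric = names(mets), rep = rep_i, fold = fold,
                   value = unname(mets), stringsAsFactors = FALSE)
    }
  }
  values <- do.call(rbind, rows_out)
  summ <- do.call(rbind, lapply(split(values$value, values$metric), mean_ci))
  structure(list(values = values,
                 summary = data.frame(metric = rownames(summ), summ,
                                      row.names = NULL),
                 k = k, r = r, seed = seed),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, digits = 4, ...) {
  cat(sprintf("repeated CV: k = %d, r = %d (%d values per metric)\n",
              x$k, x$r, x$k * x$r))
  s <- x$summary
  s[-1] <- lapply(s[-1], round, digits)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Write an eval_result to TSV + JSON summary
#' @param x an `eval_result`.
#' @param tsv_path,json_path output paths (NULL to skip either).
#' @export
write_eval_result <- function(x, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(x$values, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(k = x$k, r = x$r, seed = x$seed,
                              summary = x$summary),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(x)
}

#' Per-drug test-set metrics
#'
#' Computes R2, MAE and Pearson r per drug over the observed test
#' responses; drugs with fewer than `min_obs` observations are excluded
#' with a warning.
#'
#' @param model fitted model with a `predict` method.
#' @param test_ds `multiomic_dataset` with a `response_matrix` target.
#' @param min_obs minimum observed responses per drug (default 2).
#' @param predict_fun override for prediction.
#' @return data frame (drug, n, r2, mae, pearson).
#' @export
per_drug_test_metrics <- function(model, test_ds, min_obs = 2L,
                                  predict_fun = function(model, test_ds)
                                    stats::predict(model, test_ds)) {
  stopifnot(inherits(test_ds$targets, "response_matrix"))
  preds <- predict_fun(model, test_ds)
  tab <- per_drug_metrics_matrix(preds, test_ds$targets, min_obs = min_obs)
  dropped <- setdiff(colnames(test_ds$targets$values), tab$drug)
  if (length(dropped))
    warnf("excluded drug(s) with < %d observed test responses: %s",
          min_obs, paste(dropped, collapse = ", "))
  tab
}

#' Per-drug win/loss comparison of two models
#'
#' Counts, per metric, the drugs on which model A beats model B (higher R2
#' or Pearson r, lower MAE), loses, or ties.
#'
#' @param tab_a,tab_b per-drug tables from [per_drug_test_metrics()].
#' @return data frame (metric, a_wins, b_wins, ties).
#' @export
per_drug_comparison <- function(tab_a, tab_b) {
  m <- merge(tab_a, tab_b, by = "drug", suffixes = c("_a", "_b"))
  cmp <- function(da) c(a_wins = sum(da > 0), b_wins = sum(da < 0),
                        ties = sum(da == 0))
  rbind(
    data.frame(metric = "r2", t(cmp(m$r2_a - m$r2_b))),
    data.frame(metric = "mae", t(cmp(m$mae_b - m$mae_a))),
    data.frame(metric = "pearson", t(cmp(m$pearson_a - m$pearson_b)))
  )
}

#' Stability index across CV repeats (non-canonical placeholder)
#'
#' One minus the coefficient of variation of a metric across repeats.  This
#' is a clearly-labeled stand-in summarizing run-to-run consistency, not a
#' reproduction of any published stability definition.
#'
#' @param x numeric vector of per-repeat metric values (e.g. accuracy).
#' @return scalar in (-Inf, 1]; 1 means perfectly stable.
#' @export
stability_index <- function(x) {
  stopifnot(length(x) >= 2)
  1 - stats::sd(x) / abs(mean(x))
}
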