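## independent textbook-formula oracles, written only in terms of base
## arithmetic so they stay independent of the implementation path
oracle_r2 <- function(p, a) 1 - sum((a - p)^2) / sum((a - mean(a))^2)
oracle_mae <- function(p, a) sum(abs(p - a)) / length(a)
oracle_pearson <- function(p, a) {
  pc <- p - mean(p); ac <- a - mean(a)
  sum(pc * ac) / sqrt(sum(pc^2) * sum(ac^2))
}
oracle_auprc <- function(scores, pos) {
  ## brute force over all distinct thresholds, step interpolation
  th <- sort(unique(scores), decreasing = TRUE)
  P <- sum(pos)
  prev_rec <- 0
  area <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(sel & pos)
    prec <- tp / sum(sel)
    rec <- tp / P
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

test_that("regression metrics match hand-derived and oracle values", {
  x <- c(0.3, 1.2, -0.5, 2)
  expect_equal(unname(regression_metrics(x, x)), c(1, 0, 1))
  a <- c(1, 2, 3, 7)
  expect_equal(regression_metrics(rep(mean(a), 4), a)[["r2"]], 0)
  ## the fully hand-derived case
  m <- regression_metrics(c(1, 2, 3), c(2, 4, 6))
  expect_equal(m[["mae"]], 2)
  expect_equal(m[["pearson"]], 1)
  expect_equal(m[["r2"]], -0.75)
  ## random instances against the textbook formulas
  set.seed(42)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    p <- rnorm(n); a <- rnorm(n)
    m <- regression_metrics(p, a)
    expect_equal(m[["r2"]], oracle_r2(p, a), tolerance = 1e-8)
    expect_equal(m[["mae"]], oracle_mae(p, a), tolerance = 1e-8)
    expect_equal(m[["pearson"]], oracle_pearson(p, a), tolerance = 1e-8)
  }
  expect_warning(m <- regression_metrics(c(1, 2), c(3, 3)), "constant")
  expect_true(is.nan(m[["pearson"]]))
})

test_that("classification metrics match hand computations and pROC", {
  ## perfect one-hot predictions
  lab <- factor(c("a", "b", "c", "a"))
  proba <- diag(3)[as.integer(lab), ]
  m <- classification_metrics(proba, lab)
  expect_equal(unname(m[c("accuracy", "macro_f1", "auroc")]), c(1, 1, 1))

  ## all predictions class A on half-A half-B labels:
  ## per-class F1 = 2/3 and 0 -> macro 1/3
  labs2 <- factor(rep(c("A", "B"), each = 5))
  proba2 <- cbind(A = rep(0.9, 10), B = rep(0.1, 10))
  m2 <- classification_metrics(proba2, labs2)
  expect_equal(m2[["accuracy"]], 0.5)
  expect_equal(m2[["macro_f1"]], 1 / 3, tolerance = 1e-12)

  ## AUROC against pROC on random binary scores (midrank ties)
  skip_if_not_installed("pROC")
  set.seed(7)
  for (i in 1:20) {
    n <- 60
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 2)   # forces ties
    ours <- deepathnet:::auroc_binary(s, y == 1)
    ref <- as.numeric(suppressMessages(pROC::auc(y, s,
                                                 direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-6)
  }
})

test_that("AUROC is invariant to monotone transforms; random scores near 0.5", {
  set.seed(11)
  y <- rbinom(10000, 1, 0.5) == 1
  s <- runif(10000)
  expect_lt(abs(deepathnet:::auroc_binary(s, y) - 0.5), 0.02)
  expect_equal(deepathnet:::auroc_binary(s, y),
               deepathnet:::auroc_binary(exp(3 * s) + 2, y), tolerance = 1e-12)
})

test_that("AUPRC agrees with a brute-force threshold sweep", {
  set.seed(3)
  for (i in 1:25) {
    n <- sample(10:50, 1)
    y <- rbinom(n, 1, 0.4) == 1
    if (!any(y) || all(y)) next
    s <- round(runif(n), 1)
    expect_equal(deepathnet:::auprc_binary(s, y), oracle_auprc(s, y),
                 tolerance = 1e-8)
  }
})

test_that("confusion matrices row-normalize with recall on the diagonal", {
  cm <- confusion_matrix(c("a", "b", "a"), c("a", "b", "a"),
                         class_list = c("a", "b"))
  expect_equal(unname(cm$prop), diag(2))
  ## counts ((3,1),(2,4)) -> rows (0.75, 0.25), (1/3, 2/3)
  actual <- rep(c("x", "y"), c(4, 6))
  pred <- c(rep("x", 3), "y", rep("x", 2), rep("y", 4))
  cm2 <- confusion_matrix(pred, actual, class_list = c("x", "y"))
  expect_equal(unname(cm2$counts), matrix(c(3, 2, 1, 4), 2))
  expect_equal(unname(cm2$prop[1, ]), c(0.75, 0.25))
  expect_equal(unname(cm2$prop[2, ]), c(1/3, 2/3))
  expect_equal(unname(cm2$recall), c(0.75, 2/3))
  expect_equal(rowSums(cm2$prop), c(x = 1, y = 1))
  ## zero-support class flagged, row all zero
  cm3 <- confusion_matrix(c("a", "a"), c("a", "a"),
                          class_list = c("a", "z"))
  expect_equal(cm3$zero_support, "z")
  expect_true(all(cm3$prop["z", ] == 0))
  expect_error(confusion_matrix("q", "a", class_list = c("a")), "class list")
})

test_that("paired t test matches the textbook formula and flags degeneracy", {
  expect_equal(paired_ttest(1:5, 1:5)$p_value, 1)
  expect_true(paired_ttest(1:5, 1:5)$degenerate)
  ## constant non-zero differences: degenerate, p -> 0
  r <- paired_ttest(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  expect_true(r$degenerate)
  expect_equal(r$p_value, 0)
  ## non-degenerate case against the direct formula
  a <- c(1, 2, 3, 4, 6); b <- c(2, 3, 4, 5, 6)
  d <- a - b
  tstat <- mean(d) / (sd(d) / sqrt(length(d)))
  pval <- 2 * pt(-abs(tstat), length(d) - 1)
  r2 <- paired_ttest(a, b)
  expect_equal(r2$statistic, tstat, tolerance = 1e-12)
  expect_equal(r2$p_value, pval, tolerance = 1e-12)
  ## two-tailed symmetry
  expect_equal(paired_ttest(b, a)$p_value, r2$p_value)
  expect_error(paired_ttest(1:3, 1:4), "length")
})

test_that("repeated CV yields k*r values per metric over exact partitions", {
  sim <- tiny_dataset(n = 40, p = 3, gpp = 4, drugs = 2, seed = 5)
  res <- repeated_cv(sim$dataset, mean_feature_factory, k = 5, r = 5,
                     seed = 3)
  per_metric <- table(res$values$metric)
  expect_true(all(per_metric == 25L))
  expect_equal(sort(unique(res$values$fold)), 1:5)
  expect_equal(sort(unique(res$values$rep)), 1:5)
  s <- res$summary
  expect_true(all(s$lower <= s$mean & s$mean <= s$upper))
  ## determinism
  res2 <- repeated_cv(sim$dataset, mean_feature_factory, k = 5, r = 5,
                      seed = 3)
  expect_identical(res$values, res2$values)
  res3 <- repeated_cv(sim$dataset, mean_feature_factory, k = 5, r = 5,
                      seed = 4)
  expect_false(identical(res$values$value, res3$values$value))
})

test_that("stratified classification folds cover every class", {
  sim <- tiny_dataset(n = 60, p = 3, gpp = 4, seed = 8,
                      task = "classification", classes = 3)
  ds <- sim$dataset
  res <- repeated_cv(ds, mean_feature_factory, k = 3, r = 2, seed = 2)
  expect_true(all(table(res$values$metric) == 6L))
  expect_true(all(is.finite(res$values$value)))
})

test_that("per-drug tables and win counts behave on constructed predictions", {
  sim <- tiny_dataset(n = 30, p = 3, gpp = 4, drugs = 3, seed = 10,
                      miss_resp = 0.1)
  ds <- sim$dataset
  truthy <- function(model, test_ds) test_ds$targets$values |>
    (\(v) { v[!test_ds$targets$observed] <- 0; v })()
  noisy <- function(sdev) function(model, test_ds) {
    set.seed(1)
    v <- test_ds$targets$values
    v[!test_ds$targets$observed] <- 0
    v + matrix(rnorm(length(v), sd = sdev), nrow(v))
  }
  tab_a <- per_drug_test_metrics(NULL, ds, predict_fun = noisy(0.1))
  tab_b <- per_drug_test_metrics(NULL, ds, predict_fun = noisy(2))
  expect_equal(nrow(tab_a), 3L)
  cmp <- per_drug_comparison(tab_a, tab_b)
  ## the low-noise model wins every drug on every metric
  expect_true(all(cmp$a_wins == 3L))
  ## identical models tie everywhere
  cmp0 <- per_drug_comparison(tab_a, tab_a)
  expect_true(all(cmp0$ties == 3L))
})

test_that("fold metrics are invariant to sample order given the same split", {
  sim <- tiny_dataset(n = 30, p = 3, gpp = 4, drugs = 2, seed = 6)
  ds <- sim$dataset
  shuf <- deepathnet:::subset_dataset(ds, rev(ds$sample_ids))
  ## same sorted split -> same per-fold values regardless of row order
  ids <- ds$sample_ids
  test_ids <- ids[1:10]
  fit1 <- mean_feature_factory(deepathnet:::subset_dataset(ds, setdiff(ids, test_ids)))
  fit2 <- mean_feature_factory(deepathnet:::subset_dataset(shuf, setdiff(ids, test_ids)))
  m1 <- deepathnet:::fold_metrics(predict(fit1, deepathnet:::subset_dataset(ds, test_ids)),
                                  deepathnet:::subset_dataset(ds, test_ids)$targets)
  m2 <- deepathnet:::fold_metrics(predict(fit2, deepathnet:::subset_dataset(shuf, test_ids)),
                                  deepathnet:::subset_dataset(shuf, test_ids)$targets)
  expect_equal(m1, m2, tolerance = 1e-9)
})
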