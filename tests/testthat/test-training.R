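test_that("masked MSE averages over observed entries only", {
  p <- matrix(c(1, 3), 1); t <- matrix(c(1, 1), 1)
  all_obs <- matrix(TRUE, 1, 2)
  expect_equal(masked_mse(p, p, all_obs), 0)
  expect_equal(masked_mse(p, t, all_obs), 2)       # (0 + 4) / 2
  m2 <- matrix(c(TRUE, FALSE), 1)
  expect_equal(masked_mse(p, t, m2), 0)            # only the exact entry
  ## oracle: sum over unmasked terms, random cases
  set.seed(2)
  for (i in 1:20) {
    pr <- matrix(rnorm(12), 3); ta <- matrix(rnorm(12), 3)
    mk <- matrix(runif(12) > 0.4, 3)
    if (!any(mk)) mk[1, 1] <- TRUE
    want <- sum(((pr - ta)[mk])^2) / sum(mk)
    expect_equal(masked_mse(pr, ta, mk), want, tolerance = 1e-12)
    ## all-true mask equals the plain MSE
    expect_equal(masked_mse(pr, ta, matrix(TRUE, 3, 4)),
                 mean((pr - ta)^2), tolerance = 1e-12)
  }
  expect_error(masked_mse(p, t, matrix(FALSE, 1, 2)), "no observed")
})

test_that("cross-entropy matches the log-sum-exp closed form", {
  expect_equal(cross_entropy(matrix(0, 1, 4), 1L), log(4), tolerance = 1e-12)
  ## huge true-class score drives the loss to zero
  s <- matrix(c(50, 0, 0), 1)
  expect_lt(cross_entropy(s, 1L), 1e-12)
  set.seed(4)
  for (i in 1:20) {
    sc <- matrix(rnorm(15, sd = 5), 3, 5)
    y <- sample(5, 3, replace = TRUE)
    want <- mean(vapply(1:3, function(r)
      log(sum(exp(sc[r, ]))) - sc[r, y[r]], 0))
    expect_equal(cross_entropy(sc, y), want, tolerance = 1e-8)
  }
  expect_error(cross_entropy(matrix(0, 1, 3), 4L), "label")
})

test_that("analytic gradients match central finite differences", {
  sim <- tiny_dataset(n = 5, p = 3, gpp = 3, drugs = 2, seed = 31)
  ds <- sim$dataset
  model <- tiny_model(ds, d = 8, layers = 2)
  cfg <- model$config
  A <- deepathnet:::pathway_input_list(ds)
  Y <- ds$targets$values; M <- ds$targets$observed; Y[!M] <- 0
  lossfun <- function(par)
    masked_mse(deepathnet:::nn_forward(par, cfg, A)$out, Y, M)
  fw <- deepathnet:::nn_forward(model$par, cfg, A, keep_cache = TRUE)
  gr <- deepathnet:::nn_backward(model$par, cfg, fw$cache,
                                 deepathnet:::masked_mse_grad(fw$out, Y, M))
  set.seed(1)
  eps <- 1e-6
  for (nm in sample(names(model$par), 12)) {
    i <- sample(length(model$par[[nm]]), 1)
    p2 <- model$par; p2[[nm]][i] <- p2[[nm]][i] + eps
    p3 <- model$par; p3[[nm]][i] <- p3[[nm]][i] - eps
    fd <- (lossfun(p2) - lossfun(p3)) / (2 * eps)
    expect_lt(abs(fd - gr[[nm]][i]), 1e-5)
  }
})

test_that("fused training-step gradients equal the staged path", {
  sim <- tiny_dataset(n = 6, p = 3, gpp = 3, drugs = 2, seed = 17)
  ds <- sim$dataset
  model <- tiny_model(ds, d = 8, layers = 2)
  cfg <- model$config
  A <- deepathnet:::pathway_input_list(ds)
  Y <- ds$targets$values; M <- ds$targets$observed; Y[!M] <- 0
  res <- deepathnet:::nn_fwdbwd_cpp(model$par, A, Y, M + 0, integer(0), 0L,
                                    rep(1, 3), cfg$embed_dim, cfg$n_layers,
                                    cfg$n_heads, 2L, 0L)
  fw <- deepathnet:::nn_forward(model$par, cfg, A, keep_cache = TRUE)
  expect_equal(res$loss, masked_mse(fw$out, Y, M), tolerance = 1e-12)
  gr <- deepathnet:::nn_backward(model$par, cfg, fw$cache,
                                 deepathnet:::masked_mse_grad(fw$out, Y, M))
  for (nm in names(gr))
    expect_equal(as.vector(res$gr[[nm]]), as.vector(gr[[nm]]),
                 tolerance = 1e-10)
})

test_that("gradients of encoder columns fed by all-zero features are exact zeros", {
  sim <- tiny_dataset(n = 8, p = 3, gpp = 4, seed = 23, miss_mod = 0.3)
  ds <- sim$dataset
  model <- tiny_model(ds, d = 8)
  cfg <- model$config
  A <- deepathnet:::pathway_input_list(ds)
  Y <- ds$targets$values; M <- ds$targets$observed; Y[!M] <- 0
  fw <- deepathnet:::nn_forward(model$par, cfg, A, keep_cache = TRUE)
  gr <- deepathnet:::nn_backward(model$par, cfg, fw$cache,
                                 deepathnet:::masked_mse_grad(fw$out, Y, M))
  found_zero_col <- FALSE
  for (k in seq_along(A)) {
    zero_cols <- which(colSums(A[[k]] != 0) == 0)
    if (!length(zero_cols)) next
    found_zero_col <- TRUE
    expect_true(all(gr[[sprintf("enc%d.W", k)]][, zero_cols] == 0))
  }
  expect_true(found_zero_col)
})

test_that("training reduces the loss and is seed-reproducible", {
  sim <- tiny_dataset(n = 64, p = 3, gpp = 4, drugs = 2, seed = 77)
  ds <- sim$dataset
  cfg <- deepathnet_config(embed_dim = 8, n_heads = 2, mlp_hidden = 16,
                           head_hidden = 8, seed = 5)
  ctl <- train_control(epochs = 30, batch_size = 16, learning_rate = 1e-3,
                       seed = 9)
  fit <- deepathnet(ds, cfg, ctl)
  expect_lt(tail(fit$history$loss, 1), fit$history$loss[1])
  fit2 <- deepathnet(ds, cfg, ctl)
  expect_identical(fit$par, fit2$par)
  expect_identical(fit$history, fit2$history)
})

test_that("the network can overfit a tiny dataset (capacity sanity check)", {
  sim <- tiny_dataset(n = 16, p = 2, gpp = 4, drugs = 1, seed = 3,
                      miss_resp = 0)
  ds <- sim$dataset
  cfg <- deepathnet_config(embed_dim = 16, n_heads = 2, mlp_hidden = 32,
                           head_hidden = 16, pathway_dropout = 0, seed = 5)
  ctl <- train_control(epochs = 250, batch_size = 16, learning_rate = 3e-3,
                       seed = 2)
  fit <- deepathnet(ds, cfg, ctl)
  expect_lt(tail(fit$history$loss, 1), 0.05)
})

test_that("zero-feature encoder weights are bit-identical after training", {
  ## the zero-insertion contract: absent (gene, modality) inputs leave
  ## their weight columns untouched by the optimizer (weight_decay 0)
  sim <- tiny_dataset(n = 32, p = 3, gpp = 4, seed = 55, miss_mod = 0.3)
  ds <- sim$dataset
  cfg <- deepathnet_config(embed_dim = 8, n_heads = 2, mlp_hidden = 16,
                           head_hidden = 8, seed = 5)
  ctl <- train_control(epochs = 20, batch_size = 8, learning_rate = 1e-3,
                       seed = 4)
  cfg_full <- cfg
  cfg_full$output_dim <- ncol(ds$targets$values)
  before <- deepathnet_init(cfg_full, ds$pathways, ds$modality_list)$par
  fit <- deepathnet(ds, cfg, ctl)
  A <- deepathnet:::pathway_input_list(ds)
  checked <- 0L
  for (k in seq_along(A)) {
    zero_cols <- which(colSums(A[[k]] != 0) == 0)
    if (!length(zero_cols)) next
    nm <- sprintf("enc%d.W", k)
    expect_identical(fit$par[[nm]][, zero_cols], before[[nm]][, zero_cols])
    checked <- checked + length(zero_cols)
    ## and the trained columns did move
    moved <- setdiff(seq_len(ncol(A[[k]])), zero_cols)
    expect_false(identical(fit$par[[nm]][, moved], before[[nm]][, moved]))
  }
  expect_gt(checked, 0L)
})

test_that("prediction is deterministic, batch-size invariant, and normalized", {
  sim <- tiny_dataset(n = 40, p = 3, gpp = 4, seed = 12,
                      task = "classification", classes = 3)
  ds <- sim$dataset
  cfg <- deepathnet_config(embed_dim = 8, n_heads = 2, mlp_hidden = 16,
                           head_hidden = 8, task = "classification", seed = 5)
  ctl <- train_control(epochs = 5, batch_size = 16, learning_rate = 1e-3,
                       seed = 2)
  fit <- deepathnet(ds, cfg, ctl)
  pr <- predict(fit, ds)
  expect_equal(unname(rowSums(pr)), rep(1, 40), tolerance = 1e-6)
  expect_identical(predict(fit, ds), pr)
  pr1 <- predict(fit, ds, batch_size = 1L)
  pr32 <- predict(fit, ds, batch_size = 32L)
  expect_equal(pr1, pr32, tolerance = 1e-5)
})

test_that("validation trace, early stopping and recalibration engage", {
  sim <- tiny_dataset(n = 60, p = 3, gpp = 4, drugs = 2, seed = 14)
  ds <- sim$dataset
  tr <- deepathnet:::subset_dataset(ds, ds$sample_ids[1:40])
  va <- deepathnet:::subset_dataset(ds, ds$sample_ids[41:60])
  cfg <- deepathnet_config(embed_dim = 8, n_heads = 2, mlp_hidden = 16,
                           head_hidden = 8, seed = 5)
  ctl <- train_control(epochs = 200, batch_size = 16, learning_rate = 3e-3,
                       seed = 2, patience = 10)
  fit <- deepathnet(tr, cfg, ctl, validation = va, calibrate = TRUE)
  expect_true("val_loss" %in% names(fit$history))
  expect_lt(nrow(fit$history), 200L)          # stopped early
  expect_equal(dim(fit$calibration), c(2L, 2L))
  ## calibration is an affine map of the raw scores
  raw <- predict(fit, va, type = "scores")
  cal <- predict(fit, va, type = "response")
  j <- 1L
  expect_equal(cal[, j], fit$calibration[1, j] + fit$calibration[2, j] * raw[, j],
               tolerance = 1e-10)
})

test_that("model methods print, summarize, and expose components", {
  sim <- tiny_dataset(n = 20, p = 2, gpp = 3, drugs = 2, seed = 8)
  ds <- sim$dataset
  cfg <- deepathnet_config(embed_dim = 8, n_heads = 2, mlp_hidden = 16,
                           head_hidden = 8, seed = 5)
  fit <- deepathnet(ds, cfg, train_control(epochs = 2, batch_size = 8,
                                           learning_rate = 1e-3, seed = 1))
  expect_output(print(fit), "deepathnet model")
  expect_output(summary(fit), "trained 2 epoch")
  expect_type(coef(fit), "list")
  expect_equal(dim(fitted(fit)), c(20L, 2L))
  r <- residuals(fit)
  expect_equal(dim(r), c(20L, 2L))
  o <- ds$targets$observed
  expect_equal(r[o], (ds$targets$values - fitted(fit))[o])
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})
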