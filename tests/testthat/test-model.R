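test_that("encoder weights and embedding tensor have the published shapes", {
  ## m = 4 modalities, pathway of n genes -> encoder weight d x 4n;
  ## stacked embeddings N x 512 x p
  genes <- split(sprintf("G%03d", 1:30), rep(1:3, c(10, 12, 8)))
  names(genes) <- c("A", "B", "C")
  pw <- pathway_collection(genes)
  cfg <- deepathnet_config(output_dim = 5)   # d = 512 default
  model <- deepathnet_init(cfg, pw, c("mutation", "CNV", "RNA", "protein"))
  expect_equal(dim(model$par[["enc1.W"]]), c(512L, 4L * 10L))
  expect_equal(dim(model$par[["enc2.W"]]), c(512L, 4L * 12L))
  expect_equal(length(model$par[["enc1.b"]]), 512L)

  mats <- lapply(c("mutation", "CNV", "RNA", "protein"), function(mod) {
    v <- matrix(if (mod == "mutation") rbinom(90, 1, 0.2) else rnorm(90),
                3, 30, dimnames = list(paste0("s", 1:3), sprintf("G%03d", 1:30)))
    omic_matrix(v, mod)
  })
  ds <- assemble_dataset(mats, pw, verbose = FALSE)
  tens <- encode_all_pathways(model, ds)
  expect_equal(dim(tens), c(3L, 512L, 3L))
})

test_that("classification head width matches the class count", {
  pw <- pathway_collection(list(P1 = c("G1", "G2")))
  cfg <- deepathnet_config(embed_dim = 16, n_heads = 2, head_hidden = 8,
                           task = "classification", output_dim = 23)
  model <- deepathnet_init(cfg, pw, "RNA")
  expect_equal(ncol(model$par[["head2.W"]]), 23L)
})

test_that("pathway encoding is the exact affine map A W^T + B", {
  expect_equal(encode_pathway(matrix(c(1, 2), 1), diag(2), c(1, 1)),
               matrix(c(2, 3), 1))
  W0 <- matrix(0, 4, 6)
  expect_equal(encode_pathway(matrix(rnorm(12), 2, 6), W0, rep(0, 4)),
               matrix(0, 2, 4))
  expect_error(encode_pathway(matrix(0, 2, 3), matrix(0, 4, 6), rep(0, 4)),
               "width mismatch")
  ## naive triple-loop oracle on random instances
  set.seed(5)
  for (i in 1:10) {
    n <- sample(2:6, 1); w <- sample(2:8, 1); d <- sample(2:8, 1)
    A <- matrix(rnorm(n * w), n, w)
    W <- matrix(rnorm(d * w), d, w)
    b <- rnorm(d)
    want <- matrix(0, n, d)
    for (r in seq_len(n)) for (cc in seq_len(d)) {
      acc <- b[cc]
      for (k in seq_len(w)) acc <- acc + A[r, k] * W[cc, k]
      want[r, cc] <- acc
    }
    expect_equal(encode_pathway(A, W, b), want, tolerance = 1e-10)
  }
})

test_that("layer-0 tensor matches per-pathway encoder calls; zero input gives bias", {
  sim <- tiny_dataset(n = 5, p = 3, gpp = 4, seed = 2)
  ds <- sim$dataset
  model <- tiny_model(ds, d = 8)
  tens <- encode_all_pathways(model, ds)
  for (k in 1:3) {
    A <- pathway_input_matrix(ds, ds$pathways$names[k])
    ref <- encode_pathway(A, model$par[[sprintf("enc%d.W", k)]],
                          model$par[[sprintf("enc%d.b", k)]])
    expect_equal(tens[, , k], unname(ref), tolerance = 1e-12)
  }
  ## a sample with all-zero features embeds exactly at the bias
  A0 <- matrix(0, 1, ncol(pathway_input_matrix(ds, "P02")))
  emb <- encode_pathway(A0, model$par[["enc2.W"]], model$par[["enc2.b"]])
  expect_equal(as.vector(emb), model$par[["enc2.b"]])
})

test_that("pathway dropout zeroes whole tokens, rescales, and is off in eval", {
  x <- array(rnorm(4 * 6 * 5), c(4, 6, 5))
  expect_identical(pathway_dropout(x, 0.5, training = FALSE), x)
  expect_identical(pathway_dropout(x, 0, training = TRUE), x)
  set.seed(1)
  y <- pathway_dropout(x, 0.5, training = TRUE)
  keep <- attr(y, "keep")
  for (k in 1:5) {
    if (keep[k]) expect_equal(y[, , k], x[, , k] * 2)
    else expect_true(all(y[, , k] == 0))
  }
})

test_that("dropout mask frequency matches the drop probability", {
  ## mean fraction of zeroed pathways over many batches: 0.5 +- 0.02
  x <- array(1, c(1, 2, 20))
  set.seed(99)
  frac <- vapply(seq_len(10000), function(i) {
    y <- pathway_dropout(x, 0.5, training = TRUE)
    mean(!attr(y, "keep"))
  }, 0)
  expect_lt(abs(mean(frac) - 0.5), 0.02)
})

test_that("transformer block handles degenerate and symmetric token sets", {
  ## p = 1: softmax over a single key is 1
  pw1 <- pathway_collection(list(P1 = paste0("G", 1:3)))
  cfg <- deepathnet_config(embed_dim = 8, n_heads = 2, mlp_hidden = 16,
                           head_hidden = 8, output_dim = 1)
  m1 <- deepathnet_init(cfg, pw1, "RNA")
  x1 <- array(rnorm(2 * 8 * 1), c(2, 8, 1))
  out1 <- transformer_block(m1, x1, layer = 1)
  expect_equal(dim(out1), dim(x1))
  ## two identical tokens give identical outputs
  pw2 <- pathway_collection(list(P1 = paste0("G", 1:3), P2 = paste0("H", 1:3)))
  m2 <- deepathnet_init(cfg, pw2, "RNA")
  tok <- matrix(rnorm(8), 1)
  x2 <- array(c(tok, tok), c(1, 8, 2))
  out2 <- transformer_block(m2, x2, layer = 1)
  expect_equal(out2[, , 1], out2[, , 2], tolerance = 1e-10)
})

test_that("blocks are permutation-equivariant along the pathway axis", {
  pw <- pathway_collection(split(paste0("G", 1:20), rep(1:5, each = 4)))
  cfg <- deepathnet_config(embed_dim = 8, n_heads = 2, mlp_hidden = 16,
                           head_hidden = 8, output_dim = 2)
  model <- deepathnet_init(cfg, pw, "RNA")
  x <- array(rnorm(3 * 8 * 5), c(3, 8, 5))
  perm <- c(4, 1, 5, 2, 3)
  out <- transformer_block(model, x, layer = 1)
  out_p <- transformer_block(model, x[, , perm], layer = 1)
  expect_equal(out_p, out[, , perm], tolerance = 1e-8)
})

test_that("predictions are invariant to pathway reordering (mean pooling)", {
  sim <- tiny_dataset(n = 6, p = 4, gpp = 3, seed = 13)
  ds <- sim$dataset
  model <- tiny_model(ds, d = 8, drop = 0.5)  # dropout off in eval anyway
  base <- predict(model, ds, type = "scores")
  perm <- c(3, 1, 4, 2)
  ## permute wiring and encoder parameters consistently
  g2 <- ds$pathways$genes[perm]
  pw2 <- pathway_collection(g2, descriptions = ds$pathways$descriptions[perm])
  ds2 <- ds
  ds2$pathways <- pw2
  model2 <- model
  model2$pathways <- pw2
  for (k in seq_along(perm)) {
    model2$par[[sprintf("enc%d.W", k)]] <- model$par[[sprintf("enc%d.W", perm[k])]]
    model2$par[[sprintf("enc%d.b", k)]] <- model$par[[sprintf("enc%d.b", perm[k])]]
  }
  expect_equal(predict(model2, ds2, type = "scores"), base, tolerance = 1e-5)
})

test_that("forward pass equals the manual chain of stage operations", {
  sim <- tiny_dataset(n = 4, p = 3, gpp = 4, seed = 21)
  ds <- sim$dataset
  model <- tiny_model(ds, d = 8, layers = 2)
  staged <- encode_all_pathways(model, ds)
  staged <- pathway_dropout(staged, model$config$pathway_dropout,
                            training = FALSE)
  staged <- transformer_block(model, staged, layer = 1)
  staged <- transformer_block(model, staged, layer = 2)
  staged <- predict_head(model, staged)
  full <- model_forward(model, ds)
  expect_equal(full, staged, tolerance = 1e-10)
  ## evaluation mode is deterministic
  expect_identical(model_forward(model, ds), full)
  ## training mode reproducible under a fixed RNG state
  set.seed(5); a <- model_forward(model, ds, training = TRUE)
  set.seed(5); b <- model_forward(model, ds, training = TRUE)
  expect_identical(a, b)
})

test_that("same seed gives bit-identical initializations", {
  pw <- pathway_collection(split(paste0("G", 1:12), rep(1:3, each = 4)))
  cfg <- deepathnet_config(embed_dim = 8, n_heads = 2, head_hidden = 4,
                           output_dim = 2, seed = 11)
  m1 <- deepathnet_init(cfg, pw, c("RNA", "CNV"))
  m2 <- deepathnet_init(cfg, pw, c("RNA", "CNV"))
  expect_identical(m1$par, m2$par)
  cfg2 <- cfg; cfg2$seed <- 12L
  m3 <- deepathnet_init(cfg2, pw, c("RNA", "CNV"))
  expect_false(identical(m1$par, m3$par))
})

test_that("config invariants are enforced", {
  expect_error(deepathnet_config(embed_dim = 10, n_heads = 4), "divisible")
  expect_error(deepathnet_config(pathway_dropout = 1), "dropout")
  expect_error(deepathnet_config(output_dim = 0), "output_dim")
})

test_that("parameter count follows the analytic formula", {
  sim <- tiny_dataset(n = 4, p = 3, gpp = 5, seed = 2)
  ds <- sim$dataset
  d <- 8L; mlp <- 16L; hh <- 8L; L <- 2L; od <- 2L
  model <- tiny_model(ds, d = d, layers = L, mlp = mlp, hh = hh)
  m <- length(ds$modality_list)
  widths <- m * lengths(ds$pathways$genes)
  enc <- sum(d * (widths + 1))
  per_block <- 2 * (2 * d) +                 # two layer norms
    4 * (d * d + d) +                        # q, k, v, o projections
    (d * mlp + mlp) + (mlp * d + d)          # mlp
  head <- (d * hh + hh) + (hh * od + od)
  expect_equal(n_parameters(model), enc + L * per_block + head)
})

test_that("checkpoints round-trip and verify wiring", {
  sim <- tiny_dataset(n = 4, p = 3, gpp = 4, seed = 2)
  ds <- sim$dataset
  model <- tiny_model(ds)
  f <- withr::local_tempfile(fileext = ".rds")
  save_deepathnet(model, f)
  back <- load_deepathnet(f, pathways = ds$pathways)
  expect_identical(back$par, model$par)
  expect_equal(predict(back, ds, type = "scores"),
               predict(model, ds, type = "scores"))
  other <- pathway_collection(list(X = c("G1", "G2")))
  expect_error(load_deepathnet(f, pathways = other), "wiring")
})

test_that("wiring mismatches between model and data are caught", {
  sim <- tiny_dataset(n = 4, p = 3, gpp = 4, seed = 2)
  ds <- sim$dataset
  model <- tiny_model(ds)
  sim2 <- tiny_dataset(n = 4, p = 2, gpp = 4, seed = 3)
  expect_error(predict(model, sim2$dataset), "pathway|modalit")
})
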