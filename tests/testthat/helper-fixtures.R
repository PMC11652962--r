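## Shared fixtures: everything is generated in code at test time.

## a small fully-specified multiomic dataset with known wiring
tiny_dataset <- function(n = 12, p = 3, gpp = 4, drugs = 2, seed = 42,
                         miss_mod = 0, miss_resp = 0,
                         task = "regression", classes = 3) {
  cfg <- sim_config(n_samples = n, n_pathways = p, genes_per_pathway = gpp,
                    n_causal = min(2, p), n_drugs = drugs,
                    n_classes = classes, task = task,
                    missing_modality_fraction = miss_mod,
                    missing_response_fraction = miss_resp, seed = seed)
  simulate_dataset(cfg)
}

## small untrained model wired to a dataset
tiny_model <- function(ds, d = 8, heads = 2, layers = 2, mlp = 16, hh = 8,
                       drop = 0, pooling = "mean", seed = 7,
                       output_dim = NULL) {
  od <- output_dim %||% if (inherits(ds$targets, "response_matrix"))
    ncol(ds$targets$values) else nlevels(ds$targets)
  cfg <- deepathnet_config(embed_dim = d, n_layers = layers, n_heads = heads,
                           mlp_hidden = mlp, head_hidden = hh,
                           pathway_dropout = drop, pooling = pooling,
                           seed = seed, output_dim = od)
  deepathnet_init(cfg, ds$pathways, ds$modality_list)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## a fast least-squares baseline on per-pathway RNA means, used where the
## CV/ablation protocol is under test rather than the network itself
mean_feature_factory <- function(train_ds) {
  X <- pathway_mean_features(train_ds)
  if (inherits(train_ds$targets, "response_matrix")) {
    Y <- train_ds$targets$values
    fits <- lapply(seq_len(ncol(Y)), function(j) {
      o <- train_ds$targets$observed[, j]
      stats::lm.fit(cbind(1, X[o, , drop = FALSE]), Y[o, j])$coefficients
    })
    structure(list(coef = fits, drugs = colnames(Y)), class = "mf_baseline")
  } else {
    lv <- levels(train_ds$targets)
    fits <- lapply(lv, function(cl) {
      y <- as.numeric(train_ds$targets == cl)
      stats::lm.fit(cbind(1, X), y)$coefficients
    })
    structure(list(coef = fits, classes = lv), class = "mf_baseline_cls")
  }
}

pathway_mean_features <- function(ds) {
  rna <- which(ds$modality_list == "RNA")[1]
  if (is.na(rna)) rna <- 1L
  sapply(seq_along(ds$pathways$genes), function(k) {
    A <- pathway_input_matrix(ds, ds$pathways$names[k])
    m <- length(ds$modality_list)
    cols <- seq(rna, ncol(A), by = m)
    rowMeans(A[, cols, drop = FALSE])
  })
}

registerS3method("predict", "mf_baseline",
                 function(object, test_ds, ...)
                   predict.mf_baseline(object, test_ds, ...))
registerS3method("predict", "mf_baseline_cls",
                 function(object, test_ds, ...)
                   predict.mf_baseline_cls(object, test_ds, ...))

predict.mf_baseline <- function(object, test_ds, ...) {
  X <- cbind(1, pathway_mean_features(test_ds))
  out <- sapply(object$coef, function(cf) {
    cf[is.na(cf)] <- 0
    X %*% cf
  })
  colnames(out) <- object$drugs
  rownames(out) <- test_ds$sample_ids
  out
}

predict.mf_baseline_cls <- function(object, test_ds, ...) {
  X <- cbind(1, pathway_mean_features(test_ds))
  sc <- sapply(object$coef, function(cf) {
    cf[is.na(cf)] <- 0
    X %*% cf
  })
  e <- exp(sc - apply(sc, 1, max))
  out <- e / rowSums(e)
  colnames(out) <- object$classes
  rownames(out) <- test_ds$sample_ids
  out
}

## brute-force Shapley oracle over all permutations, independent of the
## package's estimator
oracle_shapley <- function(f, x, bg, groups) {
  G <- length(groups)
  perms <- gtools_perms(G)
  phi <- numeric(G)
  for (pm in perms) {
    cur <- bg
    prev <- f(matrix(cur, 1))
    for (g in pm) {
      cur[groups[[g]]] <- x[groups[[g]]]
      val <- f(matrix(cur, 1))
      phi[g] <- phi[g] + (val - prev)
      prev <- val
    }
  }
  phi / length(perms)
}

gtools_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n))
    for (pm in gtools_perms(n - 1L))
      out <- c(out, list(c(i, setdiff(seq_len(n), i)[pm])))
  out
}

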