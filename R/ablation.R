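#' Size-matched random pathway rewiring
#'
#' Replaces each pathway's gene set by genes sampled uniformly without
#' replacement from the gene universe, preserving every pathway's size
#' exactly; pathway names gain a `_rand` suffix.  This is the
#' "transformer-only" control: identical architecture and parameter count,
#' no biological wiring.
#'
#' @param pathways a `pathway_collection`.
#' @param gene_universe candidate genes (default: the collection's own
#'   universe).
#' @param seed RNG seed.
#' @return a rewired `pathway_collection`.
#' @export
rewire_pathways <- function(pathways, gene_universe = NULL, seed = 1L) {
  stopifnot(inherits(pathways, "pathway_collection"))
  gene_universe <- gene_universe %||% pathways$gene_universe
  if (length(gene_universe) < max(lengths(pathways$genes)))
    stopf("gene universe (%d) smaller than the largest pathway (%d)",
          length(gene_universe), max(lengths(pathways$genes)))
  set.seed(seed)
  genes <- lapply(pathways$genes, function(g)
    sample(gene_universe, length(g)))
  names(genes) <- paste0(pathways$names, "_rand")
  pathway_collection(genes, descriptions = pathways$descriptions)
}

## swap the wiring of a dataset for a collection over the same gene universe
swap_pathways <- function(ds, pathways) {
  if (!all(pathways$gene_universe %in% ds$pathways$gene_universe))
    stopf("rewired collection must draw from the dataset's gene universe")
  out <- ds
  out$pathways <- pathways
  ## gene_index is keyed by the sorted universe, identical by construction
  out
}

## ---- plain MLP baseline --------------------------------------------------

#' Plain multilayer perceptron baseline
#'
#' The no-pathway, no-transformer control: a ReLU MLP consuming the flat
#' concatenation of all gene-by-modality features (same zero-fill
#' convention as the pathway model), trained with the same losses and
#' optimizer settings.
#'
#' @param ds a `multiomic_dataset` with targets.
#' @param hidden integer vector of hidden widths (default `c(512, 256)`).
#' @param control a [train_control()].
#' @param seed initialization seed.
#' @param validation optional `multiomic_dataset` for early stopping
#'   (with `control$patience`) and recalibration, mirroring the pathway
#'   model's fitting protocol.
#' @param calibrate per-drug linear recalibration on the validation split
#'   (regression only).
#' @return object of class `plain_mlp` with a `predict` method.
#' @export
plain_mlp <- function(ds, hidden = c(512L, 256L),
                      control = train_control(), seed = 1L,
                      validation = NULL, calibrate = FALSE) {
  ti <- target_info(ds)
  X <- feature_matrix(ds)
  dims <- c(ncol(X), hidden, ti$output_dim)
  set.seed(seed)
  par <- list()
  for (i in seq_len(length(dims) - 1L)) {
    lin <- init_lin(dims[i], dims[i + 1L])
    par[[sprintf("L%d.W", i)]] <- lin$W
    par[[sprintf("L%d.b", i)]] <- lin$b
  }
  nl <- length(dims) - 1L
  reg <- ti$task == "regression"
  if (reg) {
    Y <- ds$targets$values; Y[!ds$targets$observed] <- 0
    M <- ds$targets$observed
  } else lab <- as.integer(ds$targets)

  fwd <- function(par, X, cache = FALSE) {
    hin <- vector("list", nl); hpre <- vector("list", nl)
    A <- X
    for (i in seq_len(nl)) {
      hin[[i]] <- A
      Z <- addb(A %*% par[[sprintf("L%d.W", i)]], par[[sprintf("L%d.b", i)]])
      hpre[[i]] <- Z
      A <- if (i < nl) pmax(Z, 0) else Z
    }
    if (cache) list(out = A, hin = hin, hpre = hpre) else list(out = A)
  }

  vX <- NULL
  if (!is.null(validation)) {
    vX <- feature_matrix(validation)
    if (reg) {
      vY <- validation$targets$values; vM <- validation$targets$observed
      vY[!vM] <- 0
    } else vlab <- as.integer(validation$targets)
  }
  st <- adam_init(par)
  N <- nrow(X)
  hist_loss <- numeric(0)
  best_val <- Inf; best_par <- NULL; wait <- 0L
  set.seed(control$seed)
  for (ep in seq_len(control$epochs)) {
    ord <- sample.int(N)
    ep_loss <- 0
    for (b in seq(1L, N, by = control$batch_size)) {
      rows <- ord[b:min(b + control$batch_size - 1L, N)]
      fw <- fwd(par, X[rows, , drop = FALSE], cache = TRUE)
      if (reg) {
        mb <- M[rows, , drop = FALSE]
        if (!any(mb)) next
        loss <- masked_mse(fw$out, Y[rows, , drop = FALSE], mb)
        dout <- masked_mse_grad(fw$out, Y[rows, , drop = FALSE], mb)
      } else {
        loss <- cross_entropy(fw$out, lab[rows])
        dout <- cross_entropy_grad(fw$out, lab[rows])
      }
      if (!is.finite(loss)) stopf("non-finite MLP loss at epoch %d", ep)
      gr <- list()
      dX <- dout
      for (i in rev(seq_len(nl))) {
        if (i < nl) dX <- dX * (fw$hpre[[i]] > 0)
        gr[[sprintf("L%d.W", i)]] <- crossprod(fw$hin[[i]], dX)
        gr[[sprintf("L%d.b", i)]] <- colSums(dX)
        dX <- dX %*% t(par[[sprintf("L%d.W", i)]])
      }
      upd <- adam_step(par, gr, st, control$learning_rate,
                       weight_decay = control$weight_decay)
      par <- upd$par; st <- upd$state
      ep_loss <- ep_loss + loss * length(rows)
    }
    hist_loss[ep] <- ep_loss / N
    dpn_log("mlp epoch %3d  loss %.5f", ep, hist_loss[ep],
            verbose = control$verbose)
    if (!is.null(vX)) {
      vout <- fwd(par, vX)$out
      vl <- if (reg) masked_mse(vout, vY, vM)
            else cross_entropy(vout, vlab)
      if (!is.null(control$patience)) {
        if (vl < best_val - 1e-8) {
          best_val <- vl; best_par <- par; wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= control$patience) break
        }
      }
    }
  }
  if (!is.null(control$patience) && !is.null(best_par)) par <- best_par
  calibration <- NULL
  if (isTRUE(calibrate) && !is.null(vX) && reg) {
    pv <- fwd(par, vX)$out
    calibration <- vapply(seq_len(ncol(pv)), function(j) {
      o <- validation$targets$observed[, j]
      if (sum(o) == 0) return(c(0, 1))
      if (sum(o) < 3 || stats::sd(pv[o, j]) == 0)
        return(c(mean(validation$targets$values[o, j]), 0))
      cf <- stats::coef(stats::lm(validation$targets$values[o, j] ~ pv[o, j]))
      if (any(!is.finite(cf))) c(mean(validation$targets$values[o, j]), 0)
      else unname(cf)
    }, numeric(2))
  }
  structure(list(par = par, dims = dims, nl = nl, task = ti$task,
                 outputs = ti$names, feature_names = colnames(X),
                 history = data.frame(epoch = seq_along(hist_loss),
                                      loss = hist_loss),
                 calibration = calibration,
                 fwd = fwd),
            class = "plain_mlp")
}

#' @export
predict.plain_mlp <- function(object, newdata,
                              type = c("response", "scores"), ...) {
  type <- match.arg(type)
  X <- feature_matrix(newdata)
  if (!identical(colnames(X), object$feature_names))
    stopf("feature layout of newdata does not match the fitted MLP")
  out <- object$fwd(object$par, X)$out
  rownames(out) <- newdata$sample_ids
  colnames(out) <- object$outputs
  if (object$task == "classification" && type == "response") {
    out <- softmax_rows(out)
  } else if (type == "response" && !is.null(object$calibration)) {
    out <- sweep(sweep(out, 2, object$calibration[2, ], "*"),
                 2, object$calibration[1, ], "+")
  }
  out
}

#' @export
print.plain_mlp <- function(x, ...) {
  cat(sprintf("plain_mlp (%s): layers %s, %s params\n", x$task,
              paste(x$dims, collapse = "-"),
              format(sum(vapply(x$par, length, 1L)), big.mark = ",")))
  invisible(x)
}

## metrics on a frozen test split for any model with a predict method
test_split_metrics <- function(model, test_ds, predict_fun = NULL) {
  preds <- if (is.null(predict_fun)) stats::predict(model, test_ds)
           else predict_fun(model, test_ds)
  fold_metrics(preds, test_ds$targets)
}

#' Ablation study
#'
#' Trains, on one shared train/test split, (1) the full pathway model,
#' (2) `n_repeats` size-matched random-rewired variants, and (3) the plain
#' MLP, all under identical training settings, and reports test metrics
#' per variant (R2/MAE/Pearson for regression; accuracy, macro-F1, AUROC,
#' AUPRC and companions for classification).
#'
#' @param ds a `multiomic_dataset` with targets.
#' @param config a [deepathnet_config()] for the pathway variants.
#' @param control a [train_control()] shared by all variants.
#' @param n_repeats random rewirings (default 10).
#' @param test_fraction held-out fraction.
#' @param mlp_hidden hidden widths of the plain MLP.
#' @param seed root seed (split, rewirings, model seeds derived from it).
#' @return data frame of class `ablation_result` (variant, rep, metric,
#'   value) with the split ids in `attr(, "split")`.
#' @export
run_ablation <- function(ds, config = deepathnet_config(),
                         control = train_control(), n_repeats = 10L,
                         test_fraction = 0.2, mlp_hidden = c(512L, 256L),
                         seed = 1L) {
  N <- length(ds$sample_ids)
  reg <- inherits(ds$targets, "response_matrix")
  set.seed(derive_seed(seed, "ablation-split"))
  test_ids <- sort(sample(ds$sample_ids, round(N * test_fraction)))
  rest <- setdiff(ds$sample_ids, test_ids)
  ## every variant trains with the same validation split when early
  ## stopping is requested
  val_ids <- character(0)
  if (!is.null(control$patience)) {
    set.seed(derive_seed(seed, "ablation-val"))
    val_ids <- sort(sample(rest, round(length(rest) * 0.2)))
  }
  train_ids <- setdiff(rest, val_ids)
  train_ds <- subset_dataset(ds, train_ids)
  val_ds <- if (length(val_ids)) subset_dataset(ds, val_ids) else NULL
  test_ds <- subset_dataset(ds, test_ids)

  res <- list()
  add <- function(variant, rep_i, mets) {
    res[[length(res) + 1L]] <<- data.frame(
      variant = variant, rep = rep_i, metric = names(mets),
      value = unname(mets), stringsAsFactors = FALSE)
  }

  cfg_full <- config
  cfg_full$seed <- derive_seed(seed, "full-init")
  fit_full <- deepathnet(train_ds, cfg_full, control, validation = val_ds,
                         calibrate = reg)
  add("full", 1L, test_split_metrics(fit_full, test_ds))

  for (rep_i in seq_len(n_repeats)) {
    rw <- rewire_pathways(ds$pathways,
                          seed = derive_seed(seed, sprintf("rewire-%d", rep_i)))
    cfg_r <- config
    cfg_r$seed <- derive_seed(seed, sprintf("rand-init-%d", rep_i))
    fit_r <- deepathnet(swap_pathways(train_ds, rw), cfg_r, control,
                        validation = if (is.null(val_ds)) NULL
                                     else swap_pathways(val_ds, rw),
                        calibrate = reg)
    add("random_pathways", rep_i,
        test_split_metrics(fit_r, swap_pathways(test_ds, rw)))
  }

  mlp <- plain_mlp(train_ds, hidden = mlp_hidden, control = control,
                   seed = derive_seed(seed, "mlp-init"),
                   validation = val_ds, calibrate = reg)
  add("plain_mlp", 1L, test_split_metrics(mlp, test_ds))

  out <- do.call(rbind, res)
  attr(out, "split") <- list(train = train_ids, val = val_ids,
                             test = test_ids)
  class(out) <- c("ablation_result", "data.frame")
  out
}

#' Down-sampling curve
#'
#' Freezes a test split first, then for every training fraction and seed
#' subsamples the training split, trains the full and the random-rewired
#' variant, and evaluates both on the fixed test set.  Reports per-run
#' values and the mean with 95% CI per (fraction, variant).
#'
#' @param ds a `multiomic_dataset` with targets.
#' @param config,control shared model/training settings.
#' @param fractions training fractions in (0, 1].
#' @param n_seeds subsample/initialization seeds per fraction.
#' @param test_fraction held-out fraction (frozen before subsampling).
#' @param metric metric tracked in the summary (default `"r2"` for
#'   regression, `"accuracy"` for classification).
#' @param seed root seed.
#' @return list of class `downsample_curve`: `runs` (fraction, variant,
#'   seed, metric, value) and `summary` (fraction, variant, mean, CI).
#' @export
downsample_curve <- function(ds, config = deepathnet_config(),
                             control = train_control(),
                             fractions = c(0.25, 0.5, 1),
                             n_seeds = 5L, test_fraction = 0.2,
                             metric = NULL, seed = 1L) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  metric <- metric %||%
    if (inherits(ds$targets, "response_matrix")) "r2" else "accuracy"
  N <- length(ds$sample_ids)
  reg <- inherits(ds$targets, "response_matrix")
  set.seed(derive_seed(seed, "downsample-test"))
  test_ids <- sort(sample(ds$sample_ids, round(N * test_fraction)))
  train_ids <- setdiff(ds$sample_ids, test_ids)
  test_ds <- subset_dataset(ds, test_ids)

  runs <- list()
  for (f in sort(fractions, decreasing = TRUE)) {
    n_sub <- round(length(train_ids) * f)
    if (n_sub < 2 * control$batch_size) {
      warnf("fraction %.2f yields %d training samples (< 2 * batch_size); skipped",
            f, n_sub)
      next
    }
    for (s in seq_len(n_seeds)) {
      set.seed(derive_seed(seed, sprintf("sub-%g-%d", f, s)))
      sub_ids <- sort(sample(train_ids, n_sub))
      ## validation carved inside the subsample so the training signal
      ## shrinks with the fraction, the test split stays frozen
      val_ds <- NULL
      fit_ids <- sub_ids
      if (!is.null(control$patience)) {
        set.seed(derive_seed(seed, sprintf("subval-%g-%d", f, s)))
        v_ids <- sort(sample(sub_ids, round(n_sub * 0.2)))
        fit_ids <- setdiff(sub_ids, v_ids)
        val_ds <- subset_dataset(ds, v_ids)
      }
      sub_ds <- subset_dataset(ds, fit_ids)
      cfg_f <- config; cfg_f$seed <- derive_seed(seed, sprintf("dsf-%g-%d", f, s))
      fit_f <- deepathnet(sub_ds, cfg_f, control, validation = val_ds,
                          calibrate = reg)
      mf <- test_split_metrics(fit_f, test_ds)
      rw <- rewire_pathways(ds$pathways,
                            seed = derive_seed(seed, sprintf("dsr-%d", s)))
      cfg_r <- config; cfg_r$seed <- derive_seed(seed, sprintf("dsri-%g-%d", f, s))
      fit_r <- deepathnet(swap_pathways(sub_ds, rw), cfg_r, control,
                          validation = if (is.null(val_ds)) NULL
                                       else swap_pathways(val_ds, rw),
                          calibrate = reg)
      mr <- test_split_metrics(fit_r, swap_pathways(test_ds, rw))
      runs[[length(runs) + 1L]] <- data.frame(
        fraction = f, variant = c("full", "random_pathways"), seed = s,
        metric = metric,
        value = c(mf[[metric]], mr[[metric]]), stringsAsFactors = FALSE)
    }
  }
  runs <- do.call(rbind, runs)
  if (is.null(runs)) stopf("no fraction was large enough to train on")
  key <- interaction(runs$fraction, runs$variant, drop = TRUE)
  summ <- do.call(rbind, lapply(split(runs, key), function(g) {
    ci <- mean_ci(g$value)
    data.frame(fraction = g$fraction[1], variant = g$variant[1],
               mean = ci[["mean"]], lower = ci[["lower"]],
               upper = ci[["upper"]], stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(runs = runs, summary = summ, metric = metric,
                 test_ids = test_ids),
            class = "downsample_curve")
}

#' @export
print.downsample_curve <- function(x, digits = 4, ...) {
  cat(sprintf("down-sampling curve (%s):\n", x$metric))
  s <- x$summary
  s[c("mean", "lower", "upper")] <- lapply(s[c("mean", "lower", "upper")],
                                           round, digits)
  print(s, row.names = FALSE)
  invisible(x)
}
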