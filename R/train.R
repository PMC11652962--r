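#' Masked mean squared error
#'
#' MSE over observed entries only; unobserved IC50 cells carry no gradient,
#' so samples with partial drug panels contribute exactly their measured
#' responses.
#'
#' @param pred,target batch x D matrices.
#' @param mask logical batch x D matrix, TRUE = observed.
#' @return scalar loss.
#' @export
masked_mse <- function(pred, target, mask) {
  stopifnot(identical(dim(pred), dim(target)), identical(dim(pred), dim(mask)))
  n <- sum(mask)
  if (n == 0) stopf("mask has no observed entries")
  sum(((pred - target)[mask])^2) / n
}

masked_mse_grad <- function(pred, target, mask) {
  n <- sum(mask)
  d <- pred - target
  d[!mask] <- 0
  2 * d / n
}

#' Multiclass cross-entropy
#'
#' Mean negative log softmax probability of the true class, stabilized by
#' max-subtraction.
#'
#' @param scores batch x C matrix of raw scores.
#' @param labels integer class indices in 1..C (or a factor).
#' @return scalar loss.
#' @export
cross_entropy <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels)
  C <- ncol(scores)
  if (C < 2) stopf("need >= 2 classes")
  if (any(labels < 1 | labels > C)) stopf("label outside 1..%d", C)
  m <- apply(scores, 1, max)
  lse <- m + log(rowSums(exp(scores - m)))
  true <- scores[cbind(seq_len(nrow(scores)), labels)]
  mean(lse - true)
}

cross_entropy_grad <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels)
  P <- softmax_rows(scores)
  P[cbind(seq_len(nrow(scores)), labels)] <-
    P[cbind(seq_len(nrow(scores)), labels)] - 1
  P / nrow(scores)
}

softmax_rows <- function(scores) {
  m <- apply(scores, 1, max)
  e <- exp(scores - m)
  e / rowSums(e)
}

#' Training control
#'
#' Optimization settings for [deepathnet()] and [plain_mlp()].  Adam with
#' learning rate 1e-4, batch size 32 and 100 epochs are the defaults;
#' `weight_decay` defaults to 0 so that encoder weights attached to
#' features that are zero for every sample are left untouched by training
#' (any decay would shrink them).
#'
#' @param epochs number of passes over the training set.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty added to the gradient (default 0).
#' @param patience optional early-stopping patience in epochs, used when a
#'   validation set is supplied to the fitter.
#' @param seed seed for shuffling and per-batch dropout masks.
#' @param verbose log per-epoch loss to stderr.
#' @return an object of class `train_control`.
#' @export
train_control <- function(epochs = 100L, batch_size = 32L,
                          learning_rate = 1e-4, weight_decay = 0,
                          patience = NULL, seed = 1L, verbose = FALSE) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            weight_decay >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 patience = patience, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_control")
}

target_info <- function(ds) {
  if (is.null(ds$targets)) stopf("dataset has no targets")
  if (inherits(ds$targets, "response_matrix")) {
    list(task = "regression", output_dim = ncol(ds$targets$values),
         names = colnames(ds$targets$values))
  } else {
    list(task = "classification", output_dim = nlevels(ds$targets),
         names = levels(ds$targets))
  }
}

#' Fit a pathway transformer model
#'
#' Trains the full architecture — per-pathway affine encoders, pathway
#' dropout, transformer blocks over pathway tokens, and an MLP head — by
#' minibatch Adam on the task loss: masked mean squared error over observed
#' IC50 entries for regression, cross-entropy for classification.  The
#' pathway dropout mask is redrawn for every batch.  Runs are fully
#' reproducible given `config$seed` (initialization) and `control$seed`
#' (shuffling and dropout).
#'
#' @param ds a `multiomic_dataset` with targets.
#' @param config a [deepathnet_config()]; task and output dimension are
#'   inferred from the dataset targets when not set.
#' @param control a [train_control()].
#' @param validation optional `multiomic_dataset` used for the validation
#'   loss trace and early stopping (with `control$patience`).
#' @param calibrate logical; for regression with a validation set, fit a
#'   per-drug linear recalibration (intercept and slope) of the predictions
#'   on the validation split and apply it in [predict.deepathnet()].
#'   Regularized training shrinks the spread of the raw predictions;
#'   recalibration restores the response scale without touching the test
#'   data.
#' @return a fitted object of class `deepathnet`, with components `history`
#'   (per-epoch loss data frame), `fitted`, and for regression `residuals`.
#' @seealso [predict.deepathnet()], [pathway_importance()], [repeated_cv()]
#' @examples
#' sim <- simulate_dataset(sim_config(n_samples = 60, n_pathways = 4,
#'                                    genes_per_pathway = 5, n_causal = 2,
#'                                    n_drugs = 2, seed = 7))
#' cfg <- deepathnet_config(embed_dim = 16, n_heads = 2, head_hidden = 16)
#' fit <- deepathnet(sim$dataset, cfg,
#'                   train_control(epochs = 3, verbose = FALSE))
#' fit
#' @export
deepathnet <- function(ds, config = deepathnet_config(),
                       control = train_control(), validation = NULL,
                       calibrate = FALSE) {
  stopifnot(inherits(ds, "multiomic_dataset"))
  ti <- target_info(ds)
  if (config$task != ti$task) {
    config$task <- ti$task
  }
  if (is.null(config$output_dim)) config$output_dim <- ti$output_dim
  if (config$output_dim != ti$output_dim)
    stopf("config output_dim (%d) does not match targets (%d)",
          config$output_dim, ti$output_dim)
  model <- deepathnet_init(config, ds$pathways, ds$modality_list)
  model$outputs <- ti$names

  A_full <- pathway_input_list(ds)
  N <- length(ds$sample_ids)
  reg <- ti$task == "regression"
  if (reg) {
    Y <- ds$targets$values
    Y[!ds$targets$observed] <- 0
    M <- ds$targets$observed
  } else {
    lab <- as.integer(ds$targets)
  }
  vset <- NULL
  if (!is.null(validation)) {
    vset <- list(A = pathway_input_list(validation),
                 targets = validation$targets)
  }

  st <- adam_init(model$par)
  par <- model$par
  cfg <- config
  hist_loss <- numeric(0)
  hist_val <- numeric(0)
  best_val <- Inf; best_par <- NULL; wait <- 0L

  set.seed(control$seed)
  for (ep in seq_len(control$epochs)) {
    ord <- sample.int(N)
    starts <- seq(1L, N, by = control$batch_size)
    ep_loss <- 0
    for (b in starts) {
      rows <- ord[b:min(b + control$batch_size - 1L, N)]
      A_b <- lapply(A_full, function(a) a[rows, , drop = FALSE])
      keep <- if (cfg$pathway_dropout > 0)
                stats::runif(length(A_b)) >= cfg$pathway_dropout
              else NULL
      keep_fac <- if (is.null(keep)) rep(1, length(A_b))
                  else as.numeric(keep) / (1 - cfg$pathway_dropout)
      if (reg) {
        mb <- M[rows, , drop = FALSE]
        if (!any(mb)) next
        res <- nn_fwdbwd_cpp(par, A_b, Y[rows, , drop = FALSE], mb + 0,
                             integer(0), 0L, keep_fac, cfg$embed_dim,
                             cfg$n_layers, cfg$n_heads,
                             length(cfg$head_hidden) + 1L,
                             as.integer(cfg$pooling == "flatten"))
      } else {
        res <- nn_fwdbwd_cpp(par, A_b, matrix(0, 0, 0), matrix(0, 0, 0),
                             lab[rows], 1L, keep_fac, cfg$embed_dim,
                             cfg$n_layers, cfg$n_heads,
                             length(cfg$head_hidden) + 1L,
                             as.integer(cfg$pooling == "flatten"))
      }
      loss <- res$loss
      if (!is.finite(loss))
        stopf("non-finite training loss at epoch %d (try a lower learning rate)", ep)
      upd <- adam_step(par, res$gr, st, control$learning_rate,
                       weight_decay = control$weight_decay)
      par <- upd$par; st <- upd$state
      ep_loss <- ep_loss + loss * length(rows)
    }
    hist_loss[ep] <- ep_loss / N
    if (!is.null(vset)) {
      vout <- nn_forward(par, cfg, vset$A)$out
      vl <- if (reg) {
        vy <- vset$targets$values; vm <- vset$targets$observed
        vy[!vm] <- 0
        masked_mse(vout, vy, vm)
      } else cross_entropy(vout, as.integer(vset$targets))
      hist_val[ep] <- vl
      if (!is.null(control$patience)) {
        if (vl < best_val - 1e-8) {
          best_val <- vl; best_par <- par; wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= control$patience) {
            dpn_log("early stop at epoch %d (best val %.5f)", ep, best_val,
                    verbose = control$verbose)
            par <- best_par
            break
          }
        }
      }
    }
    dpn_log("epoch %3d  loss %.5f%s", ep, hist_loss[ep],
            if (length(hist_val) >= ep) sprintf("  val %.5f", hist_val[ep]) else "",
            verbose = control$verbose)
  }

  if (!is.null(control$patience) && !is.null(best_par)) par <- best_par
  model$par <- par
  if (isTRUE(calibrate) && !is.null(validation) && reg) {
    pv <- nn_forward(par, cfg, vset$A)$out
    vy <- validation$targets$values
    vm <- validation$targets$observed
    model$calibration <- vapply(seq_len(ncol(pv)), function(j) {
      o <- vm[, j]
      if (sum(o) == 0) return(c(0, 1))
      if (sum(o) < 3 || stats::sd(pv[o, j]) == 0)
        return(c(mean(vy[o, j]), 0))
      cf <- stats::coef(stats::lm(vy[o, j] ~ pv[o, j]))
      if (any(!is.finite(cf))) c(mean(vy[o, j]), 0) else unname(cf)
    }, numeric(2))
  }
  model$history <- data.frame(epoch = seq_along(hist_loss), loss = hist_loss)
  if (length(hist_val)) model$history$val_loss <- hist_val[seq_along(hist_loss)]
  model$control <- control
  fitted <- nn_forward(par, cfg, A_full)$out
  rownames(fitted) <- ds$sample_ids
  colnames(fitted) <- ti$names
  if (reg) {
    model$fitted <- fitted
    res <- ds$targets$values - fitted
    res[!ds$targets$observed] <- NA_real_
    model$residuals <- res
  } else {
    model$fitted <- softmax_rows(fitted)
    colnames(model$fitted) <- ti$names
  }
  model
}

#' Predict from a fitted pathway transformer
#'
#' Evaluation-mode forward pass (dropout disabled), computed in batches.
#' For classification, `type = "response"` returns softmax probabilities
#' (rows sum to 1) and `type = "scores"` the raw head outputs; for
#' regression both return the predicted response matrix.
#'
#' @param object a `deepathnet` model.
#' @param newdata a `multiomic_dataset` wired like the model.
#' @param type `"response"` or `"scores"`.
#' @param batch_size forward batch size.
#' @param ... unused.
#' @return N x output_dim matrix.
#' @export
predict.deepathnet <- function(object, newdata, type = c("response", "scores"),
                               batch_size = 256L, ...) {
  type <- match.arg(type)
  check_wiring(object, newdata)
  A <- pathway_input_list(newdata)
  N <- nrow(A[[1]])
  out <- matrix(NA_real_, N, object$config$output_dim)
  for (b in seq(1L, N, by = batch_size)) {
    rows <- b:min(b + batch_size - 1L, N)
    A_b <- lapply(A, function(a) a[rows, , drop = FALSE])
    out[rows, ] <- nn_forward(object$par, object$config, A_b)$out
  }
  rownames(out) <- newdata$sample_ids
  colnames(out) <- object$outputs
  if (object$config$task == "classification" && type == "response") {
    out <- softmax_rows(out)
    colnames(out) <- object$outputs
  } else if (type == "response" && !is.null(object$calibration)) {
    out <- sweep(sweep(out, 2, object$calibration[2, ], "*"),
                 2, object$calibration[1, ], "+")
  }
  out
}

#' @export
summary.deepathnet <- function(object, ...) {
  cat(sprintf("Pathway transformer (%s)\n", object$config$task))
  cat(sprintf("  pathways: %d (sizes %d-%d), modalities: %s\n",
              length(object$pathways), min(lengths(object$pathways$genes)),
              max(lengths(object$pathways$genes)),
              paste(object$modality_list, collapse = ", ")))
  cat(sprintf("  embed_dim %d | %d transformer block(s) x %d heads | pooling %s\n",
              object$config$embed_dim, object$config$n_layers,
              object$config$n_heads, object$config$pooling))
  cat(sprintf("  parameters: %s\n", format(n_parameters(object), big.mark = ",")))
  if (!is.null(object$history)) {
    h <- object$history
    cat(sprintf("  trained %d epoch(s): loss %.5f -> %.5f\n",
                nrow(h), h$loss[1], h$loss[nrow(h)]))
  } else cat("  untrained\n")
  invisible(object)
}

#' @export
coef.deepathnet <- function(object, ...) object$par

#' @export
residuals.deepathnet <- function(object, ...) {
  if (is.null(object$residuals))
    stopf("residuals are available for fitted regression models only")
  object$residuals
}

#' @export
fitted.deepathnet <- function(object, ...) {
  if (is.null(object$fitted)) stopf("model is untrained")
  object$fitted
}

#' @export
plot.deepathnet <- function(x, ...) {
  if (is.null(x$history)) stopf("model is untrained")
  plot(x$history$epoch, x$history$loss, type = "l", xlab = "epoch",
       ylab = "training loss", main = "deepathnet training", ...)
  if (!is.null(x$history$val_loss)) {
    graphics::lines(x$history$epoch, x$history$val_loss, lty = 2)
    graphics::legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  }
  invisible(x)
}
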