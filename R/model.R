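#' Model configuration
#'
#' Architecture hyperparameters of the pathway transformer.  Defaults follow
#' the published architecture: 512-dimensional pathway embeddings, two
#' transformer blocks, and pathway dropout 0.5; head width, head count and
#' the transformer MLP expansion are conventional transformer defaults.
#'
#' @param embed_dim pathway embedding width d (default 512).  Each pathway
#'   encoder is a d x (m*n) affine map for m modalities and n member genes.
#' @param n_layers number of transformer blocks (default 2; 0 gives an
#'   encoder + head model with no attention, useful for diagnostics).
#' @param n_heads attention heads; must divide `embed_dim`.
#' @param mlp_hidden transformer MLP hidden width (default 4 * embed_dim).
#' @param pathway_dropout probability of zeroing a whole pathway token per
#'   training batch (default 0.5); survivors are rescaled by 1/(1-p)
#'   (inverted dropout) so evaluation needs no adjustment.
#' @param head_hidden integer vector of head MLP hidden widths (default:
#'   one hidden layer of width `embed_dim`, ReLU).
#' @param pooling `"mean"` (average over pathway tokens; keeps the head size
#'   independent of p and the model permutation-invariant in pathway order)
#'   or `"flatten"` (concatenate all tokens).
#' @param task `"regression"` (multi-drug IC50) or `"classification"`.
#' @param output_dim number of drugs or classes; may be left `NULL` and
#'   inferred from the dataset targets at fit time.
#' @param seed seed for parameter initialization.
#' @return an object of class `dpn_config`.
#' @export
deepathnet_config <- function(embed_dim = 512L, n_layers = 2L, n_heads = 8L,
                              mlp_hidden = 4L * embed_dim,
                              pathway_dropout = 0.5,
                              head_hidden = embed_dim,
                              pooling = c("mean", "flatten"),
                              task = c("regression", "classification"),
                              output_dim = NULL, seed = 1L) {
  pooling <- match.arg(pooling)
  task <- match.arg(task)
  if (!is_count(embed_dim) || !is_count(n_heads))
    stopf("embed_dim and n_heads must be positive integers")
  if (embed_dim %% n_heads != 0)
    stopf("embed_dim (%d) must be divisible by n_heads (%d)",
          embed_dim, n_heads)
  if (!(is.numeric(n_layers) && n_layers >= 0 && n_layers == floor(n_layers)))
    stopf("n_layers must be a non-negative integer")
  if (!(pathway_dropout >= 0 && pathway_dropout < 1))
    stopf("pathway_dropout must be in [0, 1)")
  if (!is.null(output_dim) && !is_count(output_dim))
    stopf("output_dim must be a positive integer")
  structure(list(
    embed_dim = as.integer(embed_dim), n_layers = as.integer(n_layers),
    n_heads = as.integer(n_heads), mlp_hidden = as.integer(mlp_hidden),
    pathway_dropout = pathway_dropout,
    head_hidden = as.integer(head_hidden), pooling = pooling,
    task = task,
    output_dim = if (is.null(output_dim)) NULL else as.integer(output_dim),
    seed = as.integer(seed)
  ), class = "dpn_config")
}

#' @export
print.dpn_config <- function(x, ...) {
  cat(sprintf(
    "dpn_config: d=%d, %d transformer block(s) x %d heads, mlp %d, dropout %.2f, pooling %s, task %s\n",
    x$embed_dim, x$n_layers, x$n_heads, x$mlp_hidden, x$pathway_dropout,
    x$pooling, x$task))
  invisible(x)
}

#' Initialize an untrained model
#'
#' Builds the per-pathway encoder weights (one d x (m*n_k) affine map per
#' pathway), the transformer blocks and the head, wired to a pathway
#' collection and a modality list.  Initialization is a fan-in-scaled
#' uniform scheme, fully determined by `config$seed`.
#'
#' @param config a [deepathnet_config()]; `output_dim` must be set.
#' @param pathways a `pathway_collection` fixing the pathway order and the
#'   encoder widths.
#' @param modality_list character vector of modality tags in input order.
#' @return an object of class `deepathnet` (untrained).
#' @export
deepathnet_init <- function(config, pathways, modality_list) {
  stopifnot(inherits(config, "dpn_config"),
            inherits(pathways, "pathway_collection"),
            length(modality_list) >= 1)
  if (is.null(config$output_dim))
    stopf("config$output_dim must be set before initialization")
  m <- length(modality_list)
  widths <- m * lengths(pathways$genes)
  set.seed(config$seed)
  par <- nn_init_params(config, widths)
  structure(list(
    par = par,
    config = config,
    pathways = pathways,
    modality_list = modality_list,
    widths = unname(widths),
    history = NULL,
    outputs = NULL
  ), class = "deepathnet")
}

#' @export
print.deepathnet <- function(x, ...) {
  cat(sprintf("deepathnet model (%s): %d pathways, %d modalities, d=%d, %d block(s), %s params%s\n",
              x$config$task, length(x$pathways), length(x$modality_list),
              x$config$embed_dim, x$config$n_layers,
              format(n_parameters(x), big.mark = ","),
              if (is.null(x$history)) " [untrained]" else ""))
  invisible(x)
}

#' Total parameter count
#' @param model a `deepathnet` model.
#' @return integer count of scalar parameters.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$par, length, 1L))
}

## check a dataset matches the model wiring
check_wiring <- function(model, ds) {
  if (!identical(ds$modality_list, model$modality_list))
    stopf("dataset modalities (%s) do not match model wiring (%s)",
          paste(ds$modality_list, collapse = ","),
          paste(model$modality_list, collapse = ","))
  if (!identical(ds$pathways$names, model$pathways$names) ||
      !identical(unname(lapply(ds$pathways$genes, identity)),
                 unname(lapply(model$pathways$genes, identity))))
    stopf("dataset pathway collection does not match model wiring")
  invisible(TRUE)
}

#' Encode one pathway's multiomic features
#'
#' The pathway encoder is the affine map `A %*% t(W) + B` projecting the
#' concatenated per-gene multiomic features of one pathway (width m*n) into
#' the d-dimensional pathway embedding; no nonlinearity is applied.
#'
#' @param A batch x (m*n) input matrix.
#' @param W d x (m*n) weight matrix.
#' @param b length-d bias.
#' @return batch x d embedding matrix.
#' @export
encode_pathway <- function(A, W, b) {
  if (ncol(A) != ncol(W))
    stopf("width mismatch: input has %d features, encoder expects %d",
          ncol(A), ncol(W))
  addb(tcrossprod(A, W), b)
}

#' Encode every pathway of a batch into the layer-0 tensor
#'
#' @param model a `deepathnet` model.
#' @param ds a `multiomic_dataset` wired like the model.
#' @param samples sample ids (default all).
#' @return N x d x p array of pathway embeddings (layer 0).
#' @export
encode_all_pathways <- function(model, ds, samples = NULL) {
  check_wiring(model, ds)
  A_list <- pathway_input_list(ds, samples)
  N <- nrow(A_list[[1]]); p <- length(A_list)
  H <- matrix(0, N * p, model$config$embed_dim)
  for (k in seq_len(p)) {
    idx <- (seq_len(N) - 1L) * p + k
    H[idx, ] <- encode_pathway(A_list[[k]],
                               model$par[[sprintf("enc%d.W", k)]],
                               model$par[[sprintf("enc%d.b", k)]])
  }
  flat_to_tensor(H, N, p)
}

#' Pathway-token dropout
#'
#' During training each pathway token (the whole d-vector, shared across the
#' batch) is independently zeroed with probability `p_drop`; survivors are
#' scaled by 1/(1-p_drop) (inverted dropout).  The mask is drawn once per
#' call, i.e. once per training batch.  In evaluation mode the input is
#' returned unchanged.
#'
#' @param x N x d x p tensor.
#' @param p_drop drop probability in [0, 1).
#' @param training logical.
#' @param mask optional logical keep-vector of length p (overrides drawing).
#' @return tensor of the same shape; the keep mask is attached as
#'   `attr(, "keep")` in training mode.
#' @export
pathway_dropout <- function(x, p_drop, training = FALSE, mask = NULL) {
  stopifnot(p_drop >= 0, p_drop < 1, length(dim(x)) == 3)
  if (!training || p_drop == 0) return(x)
  p <- dim(x)[3]
  if (is.null(mask)) mask <- stats::runif(p) >= p_drop
  fac <- as.numeric(mask) / (1 - p_drop)
  out <- x * rep(fac, each = dim(x)[1] * dim(x)[2])
  attr(out, "keep") <- mask
  out
}

#' Apply one transformer block (evaluation mode)
#'
#' Pre-norm residual block over the p pathway tokens of each sample:
#' `x + MHSA(LN(x))` followed by `+ MLP(LN(.))`, with GELU in the MLP.  No
#' positional encoding is used: pathways form an unordered set.
#'
#' @param model a `deepathnet` model.
#' @param x N x d x p tensor.
#' @param layer block index (1-based).
#' @return tensor of identical shape.
#' @export
transformer_block <- function(model, x, layer = 1L) {
  stopifnot(layer >= 1, layer <= model$config$n_layers)
  N <- dim(x)[1]; p <- dim(x)[3]
  Tm <- tensor_to_flat(x)
  res <- block_fwd(Tm, model$par, sprintf("blk%d.", layer), N, p,
                   model$config$n_heads)
  flat_to_tensor(res$out, N, p)
}

#' Map the final tensor to predictions
#'
#' Pools over the pathway axis (mean by default, flatten optional) and
#' applies the head MLP.  Outputs are raw scores; for classification the
#' softmax is applied by [predict.deepathnet()].
#'
#' @param model a `deepathnet` model.
#' @param x N x d x p tensor (after the last transformer block).
#' @return N x output_dim matrix of raw scores.
#' @export
predict_head <- function(model, x) {
  cfg <- model$config
  N <- dim(x)[1]; p <- dim(x)[3]
  Tm <- tensor_to_flat(x)
  if (cfg$pooling == "flatten") {
    b <- array(t(Tm), dim = c(cfg$embed_dim, p, N))
    X <- t(matrix(b, cfg$embed_dim * p, N))
  } else {
    X <- rowsum(Tm, rep(seq_len(N), each = p)) / p
  }
  nh <- length(cfg$head_hidden) + 1L
  for (i in seq_len(nh)) {
    X <- addb(X %*% model$par[[sprintf("head%d.W", i)]],
              model$par[[sprintf("head%d.b", i)]])
    if (i < nh) X <- pmax(X, 0)
  }
  X
}

#' Full forward pass
#'
#' Chains pathway encoding, pathway dropout (training mode only), the
#' transformer blocks and the prediction head.  Evaluation mode is
#' deterministic; training mode draws one dropout mask per call from the
#' current RNG state (or uses `drop_mask`).
#'
#' @param model a `deepathnet` model.
#' @param ds a wired `multiomic_dataset`.
#' @param samples sample ids (default all).
#' @param training logical.
#' @param drop_mask optional logical keep-vector of length p.
#' @return N x output_dim matrix of raw scores.
#' @export
model_forward <- function(model, ds, samples = NULL, training = FALSE,
                          drop_mask = NULL) {
  check_wiring(model, ds)
  A_list <- pathway_input_list(ds, samples)
  nn_forward(model$par, model$config, A_list, training = training,
             drop_mask = drop_mask)$out
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file holding the config, the pathway wiring
#' (names and gene sets), the modality list and all parameter arrays.
#' Loading verifies the wiring signature against a supplied pathway
#' collection.
#'
#' @param model a `deepathnet` model.
#' @param path file path.
#' @export
save_deepathnet <- function(model, path) {
  stopifnot(inherits(model, "deepathnet"))
  saveRDS(unclass(model), path, compress = FALSE)
  invisible(path)
}

#' @rdname save_deepathnet
#' @param pathways optional `pathway_collection` to verify the checkpoint
#'   wiring against (names and gene sets must match exactly).
#' @export
load_deepathnet <- function(path, pathways = NULL) {
  obj <- readRDS(path)
  model <- structure(obj, class = "deepathnet")
  if (!is.null(pathways)) {
    if (!identical(model$pathways$names, pathways$names) ||
        !identical(unname(model$pathways$genes), unname(pathways$genes)))
      stopf("checkpoint wiring does not match the supplied pathway collection")
  }
  model
}
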