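## Post-hoc attribution: epsilon-rule layer-wise relevance propagation down
## to the pathway tokens, and permutation-sampling Shapley values over
## gene-by-modality input features.

## epsilon-stabilized denominator: z + eps * sign(z), sign(0) -> +1
stab <- function(z, eps) z + eps * ifelse(z >= 0, 1, -1)

## relevance through a linear layer z = a %*% W (+ b): R_a = a * (s %*% t(W))
relprop_linear <- function(R, a, W, z, eps) {
  s <- R / stab(z, eps)
  a * (s %*% t(W))
}

#' Pathway-level relevance by epsilon-LRP
#'
#' Backpropagates the raw score of one output (a drug or a class) through
#' the head MLP and the transformer blocks down to the layer-0 pathway
#' tokens using the epsilon rule.  Attention weights are treated as
#' constants (relevance flows through the value path) and layer
#' normalization is relevance-transparent; both are standard conventions
#' for LRP on transformers, so conservation holds only approximately once
#' attention is involved (it is exact, up to epsilon, on the bias-free
#' MLP-only path).  Nonlinear activations pass relevance unchanged.
#'
#' @param model a fitted `deepathnet` model.
#' @param ds a wired `multiomic_dataset`.
#' @param target output index (or drug/class name).
#' @param samples sample ids (default all).
#' @param eps stabilizer of the epsilon rule.
#' @return N x p matrix of signed per-pathway relevances (token relevances
#'   summed over the embedding axis); columns named by pathway.
#' @export
lrp_relevance <- function(model, ds, target = 1L, samples = NULL,
                          eps = 1e-6) {
  check_wiring(model, ds)
  cfg <- model$config
  if (is.character(target)) target <- match(target, model$outputs)
  if (is.na(target) || target < 1 || target > cfg$output_dim)
    stopf("target index out of range 1..%d", cfg$output_dim)
  A_list <- pathway_input_list(ds, samples)
  fw <- nn_forward(model$par, cfg, A_list, keep_cache = TRUE)
  cache <- fw$cache
  N <- cache$N; p <- cache$p; d <- cfg$embed_dim
  par <- model$par

  ## start from the target output score
  R <- matrix(0, N, cfg$output_dim)
  R[, target] <- fw$out[, target]

  ## head MLP (ReLU passes relevance unchanged)
  nh <- length(cfg$head_hidden) + 1L
  for (i in rev(seq_len(nh))) {
    R <- relprop_linear(R, cache$hin[[i]], par[[sprintf("head%d.W", i)]],
                        cache$hpre[[i]], eps)
  }
  ## pooling
  if (cfg$pooling == "flatten") {
    R_T <- matrix(0, N * p, d)
    for (k in seq_len(p)) {
      idx <- (seq_len(N) - 1L) * p + k
      R_T[idx, ] <- R[, ((k - 1L) * d + 1L):(k * d), drop = FALSE]
    }
  } else {
    grp <- rep(seq_len(N), each = p)
    s_pool <- R / stab(cache$pooled, eps)
    R_T <- (cache$tokens / p) * s_pool[grp, , drop = FALSE]
  }
  ## transformer blocks in reverse
  for (l in rev(seq_len(cfg$n_layers))) {
    bc <- cache$blocks[[l]]
    pre <- sprintf("blk%d.", l)
    ## out = X2 + M : split by contribution
    sr <- R_T / stab(bc$out, eps)
    R_X2 <- bc$X2 * sr
    R_M <- bc$M * sr
    ## MLP branch: M = gelu(X3 W1 + b1) W2 + b2, LN2 transparent
    R_Hh <- relprop_linear(R_M, bc$Hh, par[[paste0(pre, "W2")]], bc$M, eps)
    R_X3 <- relprop_linear(R_Hh, bc$X3, par[[paste0(pre, "W1")]], bc$pre1, eps)
    R_X2 <- R_X2 + R_X3
    ## X2 = Tm + attn_out
    sr2 <- R_X2 / stab(bc$X2, eps)
    R_Tm <- bc$Tm * sr2
    R_att <- bc$attn_out * sr2
    ## attention: out proj, then token mixing with frozen weights, then V proj
    R_O <- relprop_linear(R_att, bc$O, par[[paste0(pre, "Wo")]], bc$attn_out, eps)
    dh <- d %/% cfg$n_heads
    R_V <- matrix(0, N * p, d)
    for (s in seq_len(N)) {
      rs <- ((s - 1L) * p + 1L):(s * p)
      for (h in seq_len(cfg$n_heads)) {
        ch <- ((h - 1L) * dh + 1L):(h * dh)
        A <- bc$attn[, , (s - 1L) * cfg$n_heads + h]
        sO <- R_O[rs, ch, drop = FALSE] / stab(bc$O[rs, ch, drop = FALSE], eps)
        R_V[rs, ch] <- bc$V[rs, ch, drop = FALSE] * crossprod(A, sO)
      }
    }
    R_X1 <- relprop_linear(R_V, bc$X1, par[[paste0(pre, "Wv")]], bc$V, eps)
    R_T <- R_Tm + R_X1  # LN1 transparent
  }
  ## dropout is identity in evaluation mode; sum token relevance over d
  rel <- matrix(0, N, p)
  for (k in seq_len(p)) {
    idx <- (seq_len(N) - 1L) * p + k
    rel[, k] <- rowSums(R_T[idx, , drop = FALSE])
  }
  colnames(rel) <- model$pathways$names
  if (is.null(samples)) rownames(rel) <- ds$sample_ids else rownames(rel) <- samples
  rel
}

#' Pathway importance report
#'
#' Mean absolute per-sample LRP relevance over the evaluation samples, one
#' score per pathway; deterministic given the dataset.
#'
#' @param model fitted `deepathnet`.
#' @param ds evaluation `multiomic_dataset`.
#' @param target output index or name.
#' @param samples sample ids (default all).
#' @param eps epsilon stabilizer.
#' @return `importance_report` data frame (pathway, score), sorted
#'   decreasing, with attributes `level = "pathway"`, `target`,
#'   `n_samples`, and the signed per-sample matrix in `attr(, "relevance")`.
#' @export
pathway_importance <- function(model, ds, target = 1L, samples = NULL,
                               eps = 1e-6) {
  if (length(samples %||% ds$sample_ids) == 0) stopf("no evaluation samples")
  rel <- lrp_relevance(model, ds, target = target, samples = samples, eps = eps)
  score <- colMeans(abs(rel))
  rep_df <- data.frame(pathway = model$pathways$names, score = unname(score),
                       stringsAsFactors = FALSE)
  rep_df <- rep_df[order(-rep_df$score), ]
  rownames(rep_df) <- NULL
  structure(rep_df, class = c("importance_report", "data.frame"),
            level = "pathway", target = target, n_samples = nrow(rel),
            relevance = rel)
}

#' @export
print.importance_report <- function(x, n = 10, ...) {
  cat(sprintf("%s-level importance (target %s, %d sample(s)):\n",
              attr(x, "level"), format(attr(x, "target")), attr(x, "n_samples")))
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat(sprintf("... %d more rows\n", nrow(x) - n))
  invisible(x)
}

#' Permutation-sampling Shapley attribution
#'
#' Model-agnostic Shapley estimate for groups of input features: for each
#' sampled permutation of the groups, the marginal change in `f` from
#' switching a group from its background values to its true values is
#' recorded and averaged.  When all permutations of the groups are covered
#' (`n_perm >= factorial(n_groups)`, at most 8 groups) the full enumeration
#' is used and the estimate is exact, satisfying efficiency, symmetry and
#' the null-player axiom.
#'
#' @param f vectorized model function: takes a matrix of rows-as-inputs,
#'   returns a numeric vector of scores.
#' @param x numeric input vector to explain.
#' @param background numeric vector of reference values (same length).
#' @param groups list of disjoint index vectors partitioning
#'   `seq_along(x)`; default one group per feature.
#' @param n_perm number of sampled permutations.
#' @param seed RNG seed for permutation sampling.
#' @return numeric vector of Shapley values, one per group, with
#'   `attr(, "exact")` indicating full enumeration.
#' @export
shapley_attribution <- function(f, x, background, groups = NULL,
                                n_perm = 100L, seed = 1L) {
  stopifnot(length(x) == length(background))
  if (is.null(groups)) groups <- as.list(seq_along(x))
  idx <- unlist(groups)
  if (anyDuplicated(idx)) stopf("groups overlap")
  if (!setequal(idx, seq_along(x)))
    stopf("groups must partition the feature indices")
  G <- length(groups)
  exact <- G <= 8 && factorial(G) <= n_perm
  perms <- if (exact) all_permutations(G)
           else {
             set.seed(seed)
             lapply(seq_len(n_perm), function(i) sample.int(G))
           }
  P <- length(perms)
  ## build all evaluation points: per permutation, G+1 cumulative inserts
  pts <- matrix(rep(background, each = P * (G + 1L)), P * (G + 1L),
                length(x))
  row_i <- 0L
  for (pm in perms) {
    cur <- background
    row_i <- row_i + 1L
    pts[row_i, ] <- cur
    for (g in pm) {
      cur[groups[[g]]] <- x[groups[[g]]]
      row_i <- row_i + 1L
      pts[row_i, ] <- cur
    }
  }
  vals <- f(pts)
  if (length(vals) != nrow(pts)) stopf("f must return one value per row")
  phi <- numeric(G)
  row_i <- 0L
  for (pm in perms) {
    base <- vals[row_i + 1L]
    for (j in seq_len(G)) {
      phi[pm[j]] <- phi[pm[j]] + (vals[row_i + j + 1L] - vals[row_i + j])
    }
    row_i <- row_i + G + 1L
  }
  phi <- phi / P
  names(phi) <- names(groups)
  attr(phi, "exact") <- exact
  phi
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    sub <- all_permutations(n - 1L)
    out <- c(out, lapply(sub, function(pm) c(i, setdiff(seq_len(n), i)[pm])))
  }
  out
}

## model function over flat gene-major feature rows for one output
feature_predict_fun <- function(model, ds, target) {
  if (is.character(target)) target <- match(target, model$outputs)
  cols <- lapply(seq_along(ds$pathways$genes), function(k)
    pathway_feature_cols(ds, k))
  function(X) {
    A_list <- lapply(cols, function(cc) X[, cc, drop = FALSE])
    nn_forward(model$par, model$config, A_list)$out[, target]
  }
}

#' Gene-by-modality importance report
#'
#' Mean absolute Shapley attribution across a sampled evaluation subset,
#' one group per (gene, modality) input feature, so each gene's total
#' importance decomposes into per-modality contributions (the stacked-bar
#' structure of omic-level importance plots).
#'
#' @param model fitted `deepathnet`.
#' @param ds evaluation `multiomic_dataset`.
#' @param target output index or name.
#' @param n_samples number of evaluation samples to attribute (clamped to
#'   the available count with a warning).
#' @param n_perm permutations per sample.
#' @param background `"mean"` (per-feature mean over the evaluation set) or
#'   `"zeros"`.
#' @param seed RNG seed.
#' @return `importance_report` data frame (gene, modality, score) with
#'   per-gene totals in `attr(, "gene_totals")`.
#' @export
gene_importance <- function(model, ds, target = 1L, n_samples = 20L,
                            n_perm = 30L, background = c("mean", "zeros"),
                            seed = 1L) {
  check_wiring(model, ds)
  background <- match.arg(background)
  F <- feature_matrix(ds)
  N <- nrow(F)
  if (n_samples > N) {
    warnf("n_samples (%d) exceeds available samples (%d); clamped",
          n_samples, N)
    n_samples <- N
  }
  set.seed(derive_seed(seed, "gene-importance-sample"))
  rows <- sort(sample.int(N, n_samples))
  bg <- if (background == "mean") colMeans(F) else numeric(ncol(F))
  f <- feature_predict_fun(model, ds, target)
  phis <- matrix(0, n_samples, ncol(F))
  for (i in seq_len(n_samples)) {
    phis[i, ] <- shapley_attribution(f, F[rows[i], ], bg, n_perm = n_perm,
                                     seed = derive_seed(seed, sprintf("perm-%d", i)))
  }
  score <- colMeans(abs(phis))
  exact <- ncol(F) <= 8 && factorial(ncol(F)) <= n_perm
  parts <- strsplit(colnames(F), ".", fixed = TRUE)
  gene <- vapply(parts, `[[`, "", 1L)
  modality <- vapply(parts, `[[`, "", 2L)
  rep_df <- data.frame(gene = gene, modality = modality, score = score,
                       stringsAsFactors = FALSE)
  totals <- tapply(rep_df$score, rep_df$gene, sum)
  rep_df <- rep_df[order(-totals[rep_df$gene], rep_df$gene, rep_df$modality), ]
  rownames(rep_df) <- NULL
  structure(rep_df, class = c("importance_report", "data.frame"),
            level = "gene", target = target, n_samples = n_samples,
            n_perm = n_perm, exact = exact,
            gene_totals = sort(totals, decreasing = TRUE))
}

#' Top-k entities of an importance report
#' @param report an `importance_report`.
#' @param k how many entities.
#' @return for pathway level, the top-k rows; for gene level, rows of the
#'   top-k genes by total importance (all modalities).
#' @export
top_features <- function(report, k = 5L) {
  if (attr(report, "level") == "pathway") return(utils::head(report, k))
  top <- names(utils::head(attr(report, "gene_totals"), k))
  report[report$gene %in% top, ]
}

#' Write an importance report as TSV plus JSON metadata
#' @param report an `importance_report`.
#' @param tsv_path output TSV; metadata JSON is written alongside as
#'   `<tsv_path>.meta.json`.
#' @export
write_importance_report <- function(report, tsv_path) {
  utils::write.table(as.data.frame(report), tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- list(level = attr(report, "level"),
               target = attr(report, "target"),
               n_samples = attr(report, "n_samples"),
               n_perm = attr(report, "n_perm"),
               exact = attr(report, "exact"))
  jsonlite::write_json(meta, paste0(tsv_path, ".meta.json"),
                       auto_unbox = TRUE)
  invisible(tsv_path)
}
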