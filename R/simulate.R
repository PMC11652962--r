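#' Simulation configuration
#'
#' Defines a multiomic dataset with known causal pathway structure: latent
#' standard-normal pathway activities drive gene-level features in every
#' modality, and a subset of causal pathways (plus one pathway-pathway
#' interaction) drives the drug responses or class labels.  Defaults give
#' 600 samples, 30 disjoint pathways of 15 genes, three modalities
#' (mutation, CNV, RNA), 6 causal pathways, unit loading and unit noise.
#'
#' @param n_samples number of samples.
#' @param n_pathways number of pathways (disjoint gene sets).
#' @param genes_per_pathway genes per pathway.
#' @param modalities subset of `c("mutation", "CNV", "RNA", "protein")`.
#' @param n_causal number of causal pathways (the first `n_causal`).
#' @param effect_size mutation logit slope beta on the pathway activity.
#' @param loading linear loading lambda of RNA on the pathway activity
#'   (CNV uses lambda/2; protein tracks RNA with coefficient 0.8).
#' @param noise_sd residual standard deviation sigma for continuous
#'   features and responses.
#' @param n_drugs number of drugs (regression task).
#' @param n_classes number of classes (classification task).
#' @param task `"regression"` or `"classification"`.
#' @param missing_modality_fraction fraction of (gene, modality) pairs
#'   deleted from the written matrices, exercising zero-fill.
#' @param missing_response_fraction fraction of response entries masked.
#' @param temperature softmax temperature for label noise (0 = argmax).
#' @param seed root seed; every sub-draw uses a derived sub-stream.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 600L, n_pathways = 30L,
                       genes_per_pathway = 15L,
                       modalities = c("mutation", "CNV", "RNA"),
                       n_causal = 6L, effect_size = 1, loading = 1,
                       noise_sd = 1, n_drugs = 8L, n_classes = 4L,
                       task = c("regression", "classification"),
                       missing_modality_fraction = 0.05,
                       missing_response_fraction = 0.1,
                       temperature = 0.5, seed = 1L) {
  task <- match.arg(task)
  stopifnot(n_causal <= n_pathways, noise_sd > 0,
            missing_modality_fraction >= 0, missing_modality_fraction < 1,
            missing_response_fraction >= 0, missing_response_fraction < 1,
            all(modalities %in% MODALITIES))
  structure(as.list(environment()), class = "sim_config")
}

#' Latent pathway activities
#'
#' @param cfg a [sim_config()].
#' @return n_samples x n_pathways matrix of i.i.d. standard normals, with
#'   sample and pathway names.
#' @export
simulate_pathway_activities <- function(cfg) {
  set.seed(derive_seed(cfg$seed, "activities"))
  Z <- matrix(stats::rnorm(cfg$n_samples * cfg$n_pathways),
              cfg$n_samples, cfg$n_pathways)
  rownames(Z) <- sprintf("S%04d", seq_len(cfg$n_samples))
  colnames(Z) <- sprintf("P%02d", seq_len(cfg$n_pathways))
  Z
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Simulate multiomic matrices from pathway activities
#'
#' Pathways own disjoint gene sets.  For gene g in pathway k with activity
#' Z_k: RNA = lambda * Z_k + N(0, sigma^2); protein = 0.8 * RNA +
#' N(0, sigma^2); CNV = (lambda/2) * Z_k + N(0, 1); mutation ~
#' Bernoulli(sigmoid(beta * Z_k - 2)) (the -2 offset keeps mutations
#' sparse).  A `missing_modality_fraction` of (gene, modality) pairs is
#' deleted to exercise the zero-fill path.
#'
#' @param Z activity matrix from [simulate_pathway_activities()].
#' @param cfg the same [sim_config()].
#' @return list: `omics` (list of `omic_matrix` in `cfg$modalities` order)
#'   and `pathways` (a `pathway_collection`).
#' @export
simulate_omics <- function(Z, cfg) {
  set.seed(derive_seed(cfg$seed, "omics"))
  n <- nrow(Z); p <- ncol(Z); gpp <- cfg$genes_per_pathway
  G <- p * gpp
  genes <- sprintf("G%04d", seq_len(G))
  gene_pathway <- rep(seq_len(p), each = gpp)
  Zg <- Z[, gene_pathway, drop = FALSE]  # n x G, activity of owning pathway

  lam <- cfg$loading; sg <- cfg$noise_sd; beta <- cfg$effect_size
  RNA <- lam * Zg + matrix(stats::rnorm(n * G, sd = sg), n, G)
  protein <- 0.8 * RNA + matrix(stats::rnorm(n * G, sd = sg), n, G)
  CNV <- (lam / 2) * Zg + matrix(stats::rnorm(n * G), n, G)
  mutation <- matrix(stats::rbinom(n * G, 1, sigmoid(beta * Zg - 2)), n, G)
  layers <- list(mutation = mutation, CNV = CNV, RNA = RNA,
                 protein = protein)
  for (nm in names(layers)) dimnames(layers[[nm]]) <- list(rownames(Z), genes)

  drop <- matrix(stats::runif(G * length(cfg$modalities)) <
                   cfg$missing_modality_fraction,
                 G, length(cfg$modalities))
  omics <- lapply(seq_along(cfg$modalities), function(j) {
    v <- layers[[cfg$modalities[j]]]
    keep <- !drop[, j]
    if (!any(keep)) keep[1] <- TRUE
    omic_matrix(v[, keep, drop = FALSE], cfg$modalities[j], verbose = FALSE)
  })
  pw <- split(genes, gene_pathway)
  names(pw) <- colnames(Z)
  list(omics = omics,
       pathways = pathway_collection(pw,
                                     descriptions = sprintf("synthetic pathway %d", seq_len(p))))
}

#' Simulate multi-drug responses
#'
#' For each drug, the response is a linear combination of the causal
#' pathway activities (weights drawn N(0,1), exactly zero elsewhere) plus
#' one shared multiplicative interaction 0.5 * Z_k1 * Z_k2 between the
#' first two causal pathways — a pathway-pathway interaction the attention
#' stage can learn — plus N(0, sigma^2) noise.  A fraction of entries is
#' masked as unobserved.
#'
#' @param Z activity matrix.
#' @param cfg the [sim_config()].
#' @return list: `response` (a `response_matrix`) and `truth` (list with
#'   `Z`, `causal`, `weights`, `interaction`, `seed`); the truth suffices
#'   to recompute the noiseless responses.
#' @export
simulate_drug_response <- function(Z, cfg) {
  set.seed(derive_seed(cfg$seed, "response"))
  p <- ncol(Z); D <- cfg$n_drugs
  causal <- seq_len(cfg$n_causal)
  W <- matrix(0, p, D, dimnames = list(colnames(Z), sprintf("D%02d", seq_len(D))))
  W[causal, ] <- stats::rnorm(length(causal) * D)
  inter <- if (length(causal) >= 2) causal[1:2] else c(causal[1], causal[1])
  signal <- Z %*% W + 0.5 * Z[, inter[1]] * Z[, inter[2]]
  y <- signal + matrix(stats::rnorm(nrow(Z) * D, sd = cfg$noise_sd), nrow(Z), D)
  dimnames(y) <- dimnames(signal)
  if (cfg$missing_response_fraction > 0) {
    miss <- matrix(stats::runif(length(y)) < cfg$missing_response_fraction,
                   nrow(y), ncol(y))
    y[miss] <- NA_real_
  }
  list(response = response_matrix(y),
       truth = list(Z = Z, causal = causal, weights = W,
                    interaction = inter, seed = cfg$seed))
}

#' Simulate class labels
#'
#' Class scores are class-specific linear combinations of the causal
#' pathway activities; labels are drawn from the softmax of
#' scores/temperature (argmax when `temperature = 0`).
#'
#' @param Z activity matrix.
#' @param cfg the [sim_config()] (`n_classes >= 2`).
#' @return list: `labels` (a `label_vector`) and `truth` (list with `Z`,
#'   `causal`, `class_weights`, `seed`).
#' @export
simulate_class_labels <- function(Z, cfg) {
  if (cfg$n_classes < 2) stopf("n_classes must be >= 2")
  set.seed(derive_seed(cfg$seed, "labels"))
  causal <- seq_len(cfg$n_causal)
  C <- matrix(stats::rnorm(cfg$n_classes * length(causal)),
              cfg$n_classes, length(causal))
  scores <- Z[, causal, drop = FALSE] %*% t(C)
  cls <- sprintf("class%02d", seq_len(cfg$n_classes))
  if (cfg$temperature <= 0) {
    lab <- cls[max.col(scores, ties.method = "first")]
  } else {
    P <- softmax_rows(scores / cfg$temperature)
    lab <- cls[apply(P, 1, function(pr) sample.int(length(pr), 1, prob = pr))]
  }
  list(labels = label_vector(stats::setNames(lab, rownames(Z))),
       truth = list(Z = Z, causal = causal, class_weights = C,
                    seed = cfg$seed))
}

#' One-stop synthetic dataset
#'
#' Draws activities, omics and targets, and assembles everything into a
#' model-ready `multiomic_dataset`.
#'
#' @param cfg a [sim_config()].
#' @return list: `dataset` (assembled `multiomic_dataset`), `omics`,
#'   `pathways`, `targets`, `truth`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  Z <- simulate_pathway_activities(cfg)
  om <- simulate_omics(Z, cfg)
  if (cfg$task == "regression") {
    tg <- simulate_drug_response(Z, cfg)
    targets <- tg$response
  } else {
    tg <- simulate_class_labels(Z, cfg)
    targets <- tg$labels
  }
  ds <- suppressWarnings(
    assemble_dataset(om$omics, om$pathways, targets, verbose = FALSE))
  list(dataset = ds, omics = om$omics, pathways = om$pathways,
       targets = targets, truth = tg$truth)
}

#' Write a simulated dataset to disk
#'
#' Emits one TSV per modality, the GMT pathway file, the target table and
#' a truth JSON, all readable back by the package's readers.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (om in sim$omics) {
    f <- file.path(dir, paste0(om$modality, ".tsv"))
    write_omic_matrix(om, f)
    paths[om$modality] <- f
  }
  g <- file.path(dir, "pathways.gmt")
  write_gmt(sim$pathways, g)
  paths["pathways"] <- g
  tf <- file.path(dir, "targets.tsv")
  if (inherits(sim$targets, "response_matrix")) {
    df <- data.frame(sample_id = rownames(sim$targets$values),
                     sim$targets$values, check.names = FALSE)
    utils::write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
  } else {
    utils::write.table(
      data.frame(sample_id = names(sim$targets),
                 label = as.character(sim$targets)),
      tf, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  paths["targets"] <- tf
  tj <- file.path(dir, "truth.json")
  truth <- sim$truth
  jsonlite::write_json(
    list(causal = truth$causal, seed = truth$seed,
         interaction = truth$interaction,
         weights = truth$weights, class_weights = truth$class_weights,
         Z = truth$Z),
    tj, digits = NA, matrix = "rowmajor")
  paths["truth"] <- tj
  invisible(paths)
}
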