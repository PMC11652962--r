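## Readers, validators and assembly of multiomic matrices, GMT gene sets and
## prediction targets into a model-ready dataset.

MODALITIES <- c("mutation", "CNV", "RNA", "protein")

#' Construct an omic matrix
#'
#' An omic matrix holds one molecular data layer (mutation calls, copy
#' number, RNA abundance, protein intensity, ...) as a samples-by-genes
#' numeric matrix.  Mutation layers are restricted to values in \{0, 1\}.
#' Non-finite cells (NA/NaN) are treated as missing measurements and
#' replaced by zero, matching the zero-insertion convention the model uses
#' for absent modalities; the number of replaced cells is reported.
#'
#' @param values numeric matrix, rows = samples, columns = genes, with
#'   unique row and column names.
#' @param modality one of `"mutation"`, `"CNV"`, `"RNA"`, `"protein"`, or
#'   any other label for a continuous layer.
#' @param verbose report zero-filled cell counts.
#' @return an object of class `omic_matrix`.
#' @export
omic_matrix <- function(values, modality, verbose = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("omic matrix needs sample row names and gene column names")
  rownames(values) <- trimws(rownames(values))
  colnames(values) <- trimws(colnames(values))
  if (anyDuplicated(rownames(values)))
    stopf("duplicate sample ids: %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]),
                collapse = ", "))
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup))
    stopf("duplicate gene columns: %s", paste(unique(dup), collapse = ", "))
  bad <- !is.finite(values)
  if (any(bad)) {
    values[bad] <- 0
    dpn_log("omic_matrix [%s]: zero-filled %d non-finite cell(s)",
            modality, sum(bad), verbose = verbose)
  }
  if (identical(modality, "mutation")) {
    nb <- which(!(values %in% c(0, 1)))
    if (length(nb)) {
      i <- arrayInd(nb[1], dim(values))
      stopf("mutation values must be 0/1; first offending cell sample '%s', gene '%s' (value %g)",
            rownames(values)[i[1]], colnames(values)[i[2]], values[nb[1]])
    }
  }
  structure(list(modality = modality, values = values),
            class = "omic_matrix")
}

#' @export
print.omic_matrix <- function(x, ...) {
  cat(sprintf("omic_matrix [%s]: %d samples x %d genes\n",
              x$modality, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.omic_matrix <- function(x) dim(x$values)

#' Read an omic matrix from delimited text
#'
#' Expects a header row of gene symbols, first column `sample_id`, and one
#' row per sample.  The delimiter is inferred from the file extension
#' (`.csv` = comma, otherwise tab).
#'
#' @param path file path.
#' @param modality modality tag (see [omic_matrix()]).
#' @param verbose report zero-filled counts.
#' @return an `omic_matrix`.
#' @export
read_omic_matrix <- function(path, modality, verbose = TRUE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  ## data-frame subsetting silently uniquifies duplicated column names, so
  ## duplicates must be caught from the raw header
  hdr <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  if (length(hdr) < 2) stopf("malformed header in '%s'", path)
  gcols <- trimws(hdr[-1])
  if (anyDuplicated(gcols))
    stopf("duplicate gene columns in '%s': %s", path,
          paste(unique(gcols[duplicated(gcols)]), collapse = ", "))
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE, comment.char = ""),
    error = function(e) stopf("cannot parse '%s': %s", path, conditionMessage(e)))
  if (ncol(df) < 2)
    stopf("malformed header in '%s': need a sample id column plus >= 1 gene", path)
  samples <- trimws(as.character(df[[1]]))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stopf("non-numeric values in '%s'", path)
  rownames(m) <- samples
  omic_matrix(m, modality, verbose = verbose)
}

#' Write an omic matrix as TSV
#'
#' Inverse of [read_omic_matrix()]; values round-trip exactly (full
#' precision is written).
#'
#' @param x an `omic_matrix`.
#' @param path output file.
#' @export
write_omic_matrix <- function(x, path) {
  stopifnot(inherits(x, "omic_matrix"))
  df <- data.frame(sample_id = rownames(x$values),
                   format(x$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`.  Within-line
#' duplicate genes are removed (first occurrence kept); duplicate pathway
#' names are an error.
#'
#' @param path GMT file path.
#' @return a `pathway_collection`: ordered named gene sets plus the union
#'   gene universe.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("'%s' contains no gene sets", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stopf("GMT parse error at line %d of '%s': fewer than 3 fields",
          which(nf < 3)[1], path)
  nm <- trimws(vapply(fields, `[[`, "", 1L))
  if (anyDuplicated(nm))
    stopf("duplicate pathway name(s): %s",
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  desc <- vapply(fields, `[[`, "", 2L)
  genes <- lapply(fields, function(f) {
    g <- trimws(f[-(1:2)])
    g <- g[nzchar(g)]
    unique(g)
  })
  if (any(lengths(genes) == 0)) stopf("empty gene set: %s", nm[lengths(genes) == 0][1])
  names(genes) <- nm
  pathway_collection(genes, descriptions = desc)
}

#' Construct a pathway collection
#'
#' @param genes named list of character vectors (gene symbols); names are
#'   pathway names.
#' @param descriptions optional character vector of the same length.
#' @return a `pathway_collection`.
#' @export
pathway_collection <- function(genes, descriptions = NULL) {
  stopifnot(is.list(genes), !is.null(names(genes)))
  if (anyDuplicated(names(genes))) stopf("pathway names must be unique")
  genes <- lapply(genes, function(g) unique(trimws(as.character(g))))
  if (any(lengths(genes) == 0)) stopf("every gene set must be non-empty")
  structure(list(
    names = names(genes),
    descriptions = descriptions %||% rep("na", length(genes)),
    genes = genes,
    gene_universe = sort(unique(unlist(genes, use.names = FALSE)))
  ), class = "pathway_collection")
}

#' @export
length.pathway_collection <- function(x) length(x$genes)

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("pathway_collection: %d pathways, %d genes in universe\n",
              length(x), length(x$gene_universe)))
  cat(sprintf("  sizes: min %d / median %g / max %d\n",
              min(lengths(x$genes)), stats::median(lengths(x$genes)),
              max(lengths(x$genes))))
  invisible(x)
}

#' Write a pathway collection in GMT format
#' @param x a `pathway_collection`.
#' @param path output file.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "pathway_collection"))
  lines <- vapply(seq_along(x$genes), function(i)
    paste(c(x$names[i], x$descriptions[i], x$genes[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read prediction targets
#'
#' Regression targets are a samples-by-drugs TSV of IC50 values with blanks
#' marking unobserved entries; classification targets a two-column
#' `sample_id<TAB>label` table.  Class labels are mapped onto the
#' lexicographically sorted class list.  Drugs with no observed response are
#' dropped with a warning.
#'
#' @param path file path.
#' @param task `"regression"` or `"classification"`.
#' @return for regression a list with class `response_matrix` (`values`
#'   matrix, logical `observed` mask); for classification a factor with
#'   class `label_vector` and sample ids as names.
#' @export
read_targets <- function(path, task = c("regression", "classification")) {
  task <- match.arg(task)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  ids <- trimws(as.character(df[[1]]))
  if (anyDuplicated(ids))
    stopf("repeated sample id(s) in '%s': %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (task == "regression") {
    y <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(y) <- "double"
    rownames(y) <- ids
    response_matrix(y)
  } else {
    if (ncol(df) != 2) stopf("classification targets need exactly 2 columns")
    label_vector(stats::setNames(as.character(df[[2]]), ids))
  }
}

#' Construct a drug-response matrix with an observed mask
#' @param values samples-by-drugs numeric matrix; NA marks unobserved.
#' @return a `response_matrix` (list: `values`, `observed`).
#' @export
response_matrix <- function(values) {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  observed <- is.finite(values)
  values[!observed] <- NA_real_
  empty <- colSums(observed) == 0
  if (any(empty)) {
    warnf("dropping drug(s) with no observed response: %s",
          paste(colnames(values)[empty], collapse = ", "))
    values <- values[, !empty, drop = FALSE]
    observed <- observed[, !empty, drop = FALSE]
  }
  if (!ncol(values)) stopf("no drug has any observed response")
  structure(list(values = values, observed = observed),
            class = "response_matrix")
}

#' Construct a class-label vector
#' @param labels named character vector (names = sample ids); the class list
#'   is the lexicographically sorted set of labels.
#' @return a named factor with class `label_vector`.
#' @export
label_vector <- function(labels) {
  stopifnot(!is.null(names(labels)))
  cls <- sort(unique(as.character(labels)))
  if (length(cls) < 2) stopf("classification needs >= 2 classes, got %d", length(cls))
  structure(factor(as.character(labels), levels = cls),
            names = names(labels), class = c("label_vector", "factor"))
}

#' Assemble a model-ready multiomic dataset
#'
#' Aligns all modalities and the targets to the (sorted) intersection of
#' their sample ids and indexes every pathway gene against every modality.
#' A pathway gene missing from a modality is marked absent and contributes
#' an exact zero to the model input; genes missing from every modality stay
#' in the wiring as all-zero inputs, so the network architecture depends
#' only on the pathway file.
#'
#' @param matrices list of `omic_matrix` objects (order defines the
#'   per-gene feature order).
#' @param pathways a `pathway_collection`.
#' @param targets a `response_matrix`, `label_vector`, or NULL (explanation
#'   and simulation workflows may carry targets separately).
#' @param verbose report alignment summary.
#' @return a `multiomic_dataset`.
#' @export
assemble_dataset <- function(matrices, pathways, targets = NULL,
                             verbose = TRUE) {
  stopifnot(length(matrices) >= 1,
            all(vapply(matrices, inherits, TRUE, "omic_matrix")),
            inherits(pathways, "pathway_collection"))
  modality_list <- vapply(matrices, `[[`, "", "modality")
  if (anyDuplicated(modality_list)) stopf("duplicate modality tags")
  names(matrices) <- modality_list

  ids <- Reduce(intersect, lapply(matrices, function(m) rownames(m$values)))
  if (!is.null(targets)) {
    tids <- if (inherits(targets, "response_matrix")) rownames(targets$values)
            else names(targets)
    ids <- intersect(ids, tids)
  }
  if (!length(ids)) stopf("empty sample intersection across modalities/targets")
  ids <- sort(ids)

  omics <- lapply(matrices, function(m) m$values[ids, , drop = FALSE])

  genes <- pathways$gene_universe
  gene_index <- lapply(omics, function(v) {
    idx <- match(genes, colnames(v))
    stats::setNames(idx, genes)
  })

  absent_everywhere <- Reduce(`&`, lapply(gene_index, is.na))
  dead <- vapply(pathways$genes, function(g) all(absent_everywhere[g]), TRUE)
  if (any(dead))
    warnf("pathway(s) with no measured gene in any modality (kept, all-zero input): %s",
          paste(pathways$names[dead], collapse = ", "))

  if (!is.null(targets)) {
    if (inherits(targets, "response_matrix")) {
      targets <- response_matrix(targets$values[ids, , drop = FALSE])
    } else {
      targets <- label_vector(stats::setNames(as.character(targets[ids]), ids))
    }
  }
  dpn_log("assembled dataset: %d samples, %d modalities, %d pathways, %d wired genes",
          length(ids), length(omics), length(pathways), length(genes),
          verbose = verbose)
  structure(list(
    sample_ids = ids,
    modality_list = unname(modality_list),
    omics = omics,
    gene_index = gene_index,
    pathways = pathways,
    targets = targets
  ), class = "multiomic_dataset")
}

#' @export
print.multiomic_dataset <- function(x, ...) {
  tt <- if (is.null(x$targets)) "none"
        else if (inherits(x$targets, "response_matrix"))
          sprintf("regression (%d drugs)", ncol(x$targets$values))
        else sprintf("classification (%d classes)", nlevels(x$targets))
  cat(sprintf("multiomic_dataset: %d samples | modalities: %s | %d pathways | targets: %s\n",
              length(x$sample_ids), paste(x$modality_list, collapse = ", "),
              length(x$pathways), tt))
  invisible(x)
}

n_modalities <- function(ds) length(ds$modality_list)

#' Per-gene concatenated input vector
#'
#' Returns the length-m feature vector for one gene of one sample, ordered
#' by the dataset's modality list; modalities in which the gene is absent
#' contribute an exact 0.
#'
#' @param ds a `multiomic_dataset`.
#' @param sample sample id.
#' @param gene gene symbol (must be wired, i.e. in the pathway universe).
#' @return numeric vector of length m, named by modality.
#' @export
gene_input_vector <- function(ds, sample, gene) {
  stopifnot(inherits(ds, "multiomic_dataset"))
  if (!gene %in% names(ds$gene_index[[1]]))
    stopf("gene '%s' is not wired into this dataset", gene)
  s <- match(sample, ds$sample_ids)
  if (is.na(s)) stopf("unknown sample '%s'", sample)
  out <- vapply(seq_along(ds$modality_list), function(m) {
    j <- ds$gene_index[[m]][[gene]]
    if (is.na(j)) 0 else ds$omics[[m]][s, j]
  }, 0)
  stats::setNames(out, ds$modality_list)
}

## Column indices of a pathway's genes inside the flat gene-major feature
## matrix (gene1.mod1 ... gene1.modm, gene2.mod1, ...).
pathway_feature_cols <- function(ds, k) {
  m <- n_modalities(ds)
  gpos <- match(ds$pathways$genes[[k]], names(ds$gene_index[[1]]))
  as.vector(t(outer(gpos - 1L, seq_len(m), function(g, j) g * m + j)))
}

## Flat N x (G*m) feature matrix over the wired gene universe, gene-major,
## with exact zeros for absent (gene, modality) pairs.  All model input
## matrices are column subsets of this.
feature_matrix <- function(ds, samples = NULL) {
  rows <- if (is.null(samples)) seq_along(ds$sample_ids)
          else match(samples, ds$sample_ids)
  if (anyNA(rows)) stopf("unknown sample id(s)")
  genes <- names(ds$gene_index[[1]])
  m <- n_modalities(ds)
  G <- length(genes)
  F <- matrix(0, length(rows), G * m)
  for (j in seq_len(m)) {
    idx <- ds$gene_index[[j]]
    present <- which(!is.na(idx))
    if (length(present))
      F[, (present - 1L) * m + j] <-
        ds$omics[[j]][rows, idx[present], drop = FALSE]
  }
  rownames(F) <- ds$sample_ids[rows]
  colnames(F) <- paste(rep(genes, each = m), rep(ds$modality_list, G), sep = ".")
  F
}

#' Per-pathway model input matrix
#'
#' Row s is the concatenation of [gene_input_vector()] over the pathway's
#' genes in collection order; width is m * n for m modalities and n genes.
#'
#' @param ds a `multiomic_dataset`.
#' @param pathway pathway name.
#' @param samples sample ids (default: all, in dataset order).
#' @return numeric matrix, samples by (m * n).
#' @export
pathway_input_matrix <- function(ds, pathway, samples = NULL) {
  stopifnot(inherits(ds, "multiomic_dataset"))
  k <- match(pathway, ds$pathways$names)
  if (is.na(k)) stopf("unknown pathway '%s'", pathway)
  F <- feature_matrix(ds, samples)
  F[, pathway_feature_cols(ds, k), drop = FALSE]
}

## All per-pathway input matrices at once (shared feature matrix build).
pathway_input_list <- function(ds, samples = NULL) {
  F <- feature_matrix(ds, samples)
  lapply(seq_along(ds$pathways$genes), function(k)
    F[, pathway_feature_cols(ds, k), drop = FALSE])
}

#' Subset a multiomic dataset by sample ids
#'
#' Returns the dataset restricted to `samples`, in the given order, with
#' targets subset consistently.  The pathway wiring and gene index are
#' unchanged, so models remain compatible across subsets.
#'
#' @param ds a `multiomic_dataset`.
#' @param samples character vector of sample ids (subset of
#'   `ds$sample_ids`).
#' @return a `multiomic_dataset`.
#' @export
subset_dataset <- function(ds, samples) {
  rows <- match(samples, ds$sample_ids)
  if (anyNA(rows)) stopf("unknown sample id(s) in subset")
  out <- ds
  out$sample_ids <- ds$sample_ids[rows]
  out$omics <- lapply(ds$omics, function(v) v[rows, , drop = FALSE])
  if (!is.null(ds$targets)) {
    if (inherits(ds$targets, "response_matrix")) {
      v <- ds$targets$values[rows, , drop = FALSE]
      out$targets <- structure(list(values = v, observed = is.finite(v)),
                               class = "response_matrix")
    } else {
      out$targets <- structure(
        factor(as.character(ds$targets[rows]), levels = levels(ds$targets)),
        names = ds$sample_ids[rows], class = c("label_vector", "factor"))
    }
  }
  out
}
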