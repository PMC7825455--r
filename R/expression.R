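#' Raw count matrix with feature and sample metadata
#'
#' Container for a feature-by-sample matrix of raw RNA-seq counts together
#' with feature biotypes (mRNA / lncRNA), sample stage labels
#' (GRI / MGI / RSI) and per-sample library sizes.
#'
#' @param counts Non-negative integer matrix, features in rows (unique
#'   rownames), samples in columns (colnames).
#' @param biotype Character vector, one of `"mRNA"`/`"lncRNA"` per feature,
#'   in row order or named by feature id.
#' @param stage Character/factor of stage labels per sample, in column
#'   order or named by sample id.
#' @param replicate Optional replicate labels per sample.
#' @param library_sizes Optional externally supplied library sizes; default
#'   is the column sums of `counts`.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, biotype, stage, replicate = NULL,
                         library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate feature ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (!is.integer(counts) && max(counts) <= .Machine$integer.max) {
    storage.mode(counts) <- "integer"
  }
  biotype <- .align_meta(biotype, rownames(counts), "biotype")
  if (!all(biotype %in% c("mRNA", "lncRNA"))) {
    stop("biotype must be 'mRNA' or 'lncRNA'")
  }
  stage <- .align_meta(as.character(stage), colnames(counts), "stage")
  if (is.null(replicate)) replicate <- ave(stage, stage, FUN = seq_along)
  replicate <- .align_meta(as.character(replicate), colnames(counts), "replicate")
  if (is.null(library_sizes)) {
    library_sizes <- colSums(counts)
  } else {
    library_sizes <- .align_meta(library_sizes, colnames(counts), "library_sizes")
  }
  structure(list(counts = counts,
                 feature_meta = data.frame(feature_id = rownames(counts),
                                           biotype = unname(biotype)),
                 samples = data.frame(sample_id = colnames(counts),
                                      stage = unname(stage),
                                      replicate = unname(replicate)),
                 library_sizes = library_sizes),
            class = "count_matrix")
}

.align_meta <- function(x, ids, what) {
  if (!is.null(names(x))) {
    if (!all(ids %in% names(x))) stop(what, " missing entries for some ids")
    x <- x[ids]
  } else if (length(x) != length(ids)) {
    stop(what, " must have one entry per id (got ", length(x),
         ", need ", length(ids), ")")
  }
  stats::setNames(x, ids)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d features (%d mRNA, %d lncRNA) x %d samples\n",
              nrow(x$counts), sum(x$feature_meta$biotype == "mRNA"),
              sum(x$feature_meta$biotype == "lncRNA"), ncol(x$counts)))
  cat("  stages:", paste(sprintf("%s(%d)", names(table(x$samples$stage)),
                                 table(x$samples$stage)), collapse = " "), "\n")
  invisible(x)
}

#' Counts per million
#'
#' `cpm[f, s] = counts[f, s] / library_size[s] * 1e6`. Library sizes default
#' to column totals of the matrix itself (the upstream mapped-read totals
#' are not available from a count matrix alone).
#'
#' @param cm A [count_matrix()].
#' @return An `expression_matrix` on the CPM scale.
#' @export
compute_cpm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  zero <- cm$library_sizes <= 0
  if (any(zero)) {
    stop("zero library size for sample(s): ",
         paste(names(cm$library_sizes)[zero], collapse = ", "))
  }
  values <- sweep(cm$counts, 2L, cm$library_sizes, "/") * 1e6
  structure(list(values = values, scale = "cpm",
                 feature_meta = cm$feature_meta, samples = cm$samples),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d x %d, scale = %s\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' Expressed-feature filter
#'
#' A feature is considered expressed when its CPM exceeds `threshold`
#' (strictly) in at least `min_libraries` libraries. Also tallies, per
#' stage, the features detected by the same rule restricted to that
#' stage's libraries.
#'
#' @param expr CPM-scale `expression_matrix`.
#' @param threshold CPM cutoff (strict `>`), default 0.5.
#' @param min_libraries Minimum number of libraries above the cutoff.
#' @return List with `keep` (named logical), `expressed` (feature ids),
#'   and `per_stage` (data frame of detected counts by stage and biotype).
#' @export
filter_expressed <- function(expr, threshold = 0.5, min_libraries = 1L) {
  .check_scale(expr, "cpm")
  hits <- expr$values > threshold
  keep <- rowSums(hits) >= min_libraries
  stages <- unique(expr$samples$stage)
  per_stage <- do.call(rbind, lapply(stages, function(st) {
    cols <- expr$samples$stage == st
    kept <- rowSums(hits[, cols, drop = FALSE]) >= min_libraries
    stats::aggregate(kept, list(biotype = expr$feature_meta$biotype),
                     FUN = sum) |>
      stats::setNames(c("biotype", "n_detected")) |>
      transform(stage = st)
  }))
  list(keep = keep, expressed = names(keep)[keep],
       per_stage = per_stage[, c("stage", "biotype", "n_detected")])
}

.check_scale <- function(expr, want) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (!identical(expr$scale, want)) {
    stop("expected an expression matrix on the '", want, "' scale, got '",
         expr$scale, "'")
  }
  invisible(expr)
}

#' Subset an expression or count matrix to a feature set
#' @param x An `expression_matrix` or [count_matrix()].
#' @param features Feature ids (or logical vector) to keep.
#' @return Object of the same class restricted to `features`.
#' @export
subset_features <- function(x, features) {
  if (is.logical(features)) features <- names(features)[features]
  if (inherits(x, "count_matrix")) {
    count_matrix(x$counts[features, , drop = FALSE],
                 stats::setNames(x$feature_meta$biotype, x$feature_meta$feature_id),
                 stats::setNames(x$samples$stage, x$samples$sample_id),
                 stats::setNames(x$samples$replicate, x$samples$sample_id),
                 x$library_sizes)
  } else if (inherits(x, "expression_matrix")) {
    x$values <- x$values[features, , drop = FALSE]
    x$feature_meta <- x$feature_meta[match(features, x$feature_meta$feature_id), ]
    x
  } else stop("unsupported object")
}

#' log2(CPM + 1) transform
#'
#' @param expr CPM-scale `expression_matrix`.
#' @return `expression_matrix` on the `log2cpm` scale.
#' @export
log_transform <- function(expr) {
  .check_scale(expr, "cpm")
  if (any(expr$values < 0)) stop("negative values cannot be log-transformed")
  expr$values <- log2(expr$values + 1)
  expr$scale <- "log2cpm"
  expr
}

#' Hierarchical clustering of samples
#'
#' Average-linkage clustering of samples on the distance
#' `1 - Pearson correlation` between log-scale expression columns.
#' Deterministic for a given input ordering (ties merge lowest index
#' first, the `stats::hclust` convention).
#'
#' @param expr log-scale `expression_matrix`.
#' @return An object of class `hclust`.
#' @export
sample_hclust <- function(expr) {
  .check_scale(expr, "log2cpm")
  if (ncol(expr$values) < 3L) stop("need >= 3 samples to cluster")
  sds <- apply(expr$values, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant expression column(s): ",
         paste(colnames(expr$values)[sds == 0], collapse = ", "))
  }
  d <- stats::as.dist(1 - stats::cor(expr$values))
  stats::hclust(d, method = "average")
}

#' Write a sample dendrogram in Newick format
#' @param hc An `hclust` tree from [sample_hclust()].
#' @param path Output file.
#' @export
write_dendrogram <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Principal component analysis of samples
#'
#' PCA of samples on log-scale expression, with features centered across
#' samples (no scaling). Components are limited by `min(n_samples - 1,
#' n_features)`.
#'
#' @param expr log-scale `expression_matrix`.
#' @param n_components Number of components to return (default: full rank).
#' @return List with `coords` (samples x components), `var_explained`
#'   (fractions, non-increasing) and `sdev`.
#' @export
sample_pca <- function(expr, n_components = NULL) {
  .check_scale(expr, "log2cpm")
  n <- ncol(expr$values)
  if (n < 2L) stop("need >= 2 samples for PCA")
  rank <- min(n - 1L, nrow(expr$values))
  if (is.null(n_components)) n_components <- rank
  if (n_components > rank) {
    stop("requested ", n_components, " components but rank is at most ", rank)
  }
  pc <- stats::prcomp(t(expr$values), center = TRUE, scale. = FALSE)
  total <- sum(pc$sdev^2)
  var_frac <- if (total > 0) pc$sdev^2 / total else rep(0, length(pc$sdev))
  idx <- seq_len(n_components)
  list(coords = pc$x[, idx, drop = FALSE],
       var_explained = var_frac[idx],
       sdev = pc$sdev[idx])
}
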