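#' Per-feature log2 fold change between two sample groups
#'
#' `log2((mean CPM_a + pseudo) / (mean CPM_b + pseudo))`, with group B the
#' reference (here typically the MGI stage).
#'
#' @param cm A [count_matrix()].
#' @param group_a,group_b Disjoint character vectors of sample ids.
#' @param pseudo Pseudocount added to each group mean CPM.
#' @return Named numeric vector of log2 fold changes.
#' @export
estimate_log2fc <- function(cm, group_a, group_b, pseudo = 0.5) {
  .check_groups(cm, group_a, group_b)
  cpm <- compute_cpm(cm)$values
  ma <- rowMeans(cpm[, group_a, drop = FALSE])
  mb <- rowMeans(cpm[, group_b, drop = FALSE])
  log2((ma + pseudo) / (mb + pseudo))
}

.check_groups <- function(cm, group_a, group_b) {
  stopifnot(inherits(cm, "count_matrix"))
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty")
  }
  all_ids <- colnames(cm$counts)
  missing <- setdiff(c(group_a, group_b), all_ids)
  if (length(missing)) stop("unknown sample id(s): ", paste(missing, collapse = ", "))
  if (length(intersect(group_a, group_b))) {
    stop("groups overlap: ", paste(intersect(group_a, group_b), collapse = ", "))
  }
  invisible(TRUE)
}

#' Negative-binomial Wald test for two-group differential expression
#'
#' Self-contained per-feature test. Counts are normalized by library-size
#' ratios (each column scaled to the mean library size of the tested
#' samples). For each feature the dispersion is estimated by method of
#' moments, \eqn{\phi = \max(0, (s^2 - \mu)/\mu^2)}, within each group and
#' pooled across the two groups weighted by degrees of freedom. Because a
#' per-feature moment estimate on a handful of replicates is very noisy,
#' it is moderated empirical-Bayes style: shrunk toward the common
#' (median) dispersion of reasonably expressed features with `prior_df`
#' pseudo-degrees of freedom, the same device the established count-model
#' packages use. The Wald statistic is the log2 fold change over its
#' delta-method standard error,
#' \eqn{Var(\bar x_g) = (\mu_g + \phi \mu_g^2)/n_g}, referred to a t
#' distribution with `n_a + n_b - 2 + prior_df` degrees of freedom
#' (residual plus prior information).
#'
#' Features with all-zero counts in both groups get `p = 1` by convention.
#'
#' @param cm A [count_matrix()].
#' @param group_a,group_b Disjoint sample-id vectors, each of size >= 2.
#' @param pseudo Pseudocount for the fold-change and delta-method scale.
#' @param prior_df Prior degrees of freedom for dispersion moderation.
#' @return Data frame: `feature_id`, `log2fc`, `p`.
#' @export
nb_test <- function(cm, group_a, group_b, pseudo = 0.5, prior_df = 10) {
  .check_groups(cm, group_a, group_b)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("need >= 2 samples per group for dispersion estimation")
  }
  ids <- c(group_a, group_b)
  libs <- cm$library_sizes[ids]
  norm <- sweep(cm$counts[, ids, drop = FALSE], 2L, libs / mean(libs), "/")
  xa <- norm[, group_a, drop = FALSE]
  xb <- norm[, group_b, drop = FALSE]
  na <- length(group_a); nb <- length(group_b)

  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1L, stats::var); vb <- apply(xb, 1L, stats::var)
  phi_a <- ifelse(ma > 0, (va - ma) / ma^2, 0)
  phi_b <- ifelse(mb > 0, (vb - mb) / mb^2, 0)
  df_res <- na + nb - 2
  phi_i <- pmax(0, ((na - 1) * phi_a + (nb - 1) * phi_b) / df_res)
  expressed <- ma + mb > 1            # common dispersion from non-trivial rows
  phi_common <- if (any(expressed)) stats::median(phi_i[expressed]) else 0
  phi <- (prior_df * phi_common + df_res * phi_i) / (prior_df + df_res)

  lfc <- log2((ma + pseudo) / (mb + pseudo))
  se2 <- (ma + phi * ma^2) / (na * (ma + pseudo)^2 * log(2)^2) +
         (mb + phi * mb^2) / (nb * (mb + pseudo)^2 * log(2)^2)
  tstat <- ifelse(se2 > 0, lfc / sqrt(se2), 0)
  p <- 2 * stats::pt(-abs(tstat), df = df_res + prior_df)
  p[ma == 0 & mb == 0] <- 1
  data.frame(feature_id = rownames(cm$counts), log2fc = unname(lfc),
             p = unname(p))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (q-values), order-preserving with respect to the
#' input.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Differential-expression calls at fixed thresholds
#'
#' A feature is called `up` when `log2fc > lfc_threshold` and
#' `q < q_threshold`, `down` when `log2fc < -lfc_threshold` and
#' `q < q_threshold`, else `ns`. Both inequalities are strict.
#'
#' @param results Data frame with columns `feature_id`, `log2fc`, `q` (and
#'   optionally `biotype`).
#' @param lfc_threshold Absolute log2 fold-change cutoff (default 1).
#' @param q_threshold FDR cutoff (default 0.1).
#' @return The input with a `call` column plus a `summary` attribute of
#'   up/down counts (by biotype when present).
#' @export
call_de <- function(results, lfc_threshold = 1, q_threshold = 0.1) {
  stopifnot(lfc_threshold > 0, q_threshold > 0,
            all(c("feature_id", "log2fc", "q") %in% names(results)))
  call <- ifelse(results$q < q_threshold & results$log2fc > lfc_threshold, "up",
          ifelse(results$q < q_threshold & results$log2fc < -lfc_threshold,
                 "down", "ns"))
  results$call <- factor(call, levels = c("up", "down", "ns"))
  by <- if ("biotype" %in% names(results)) {
    list(biotype = results$biotype, call = results$call)
  } else {
    list(call = results$call)
  }
  tab <- stats::aggregate(seq_len(nrow(results)), by, FUN = length)
  names(tab)[ncol(tab)] <- "n"
  attr(results, "summary") <- tab[tab$call != "ns", , drop = FALSE]
  results
}

#' One stage-versus-stage differential-expression contrast
#'
#' Runs [estimate_log2fc()], [nb_test()], [bh_fdr()] and [call_de()] for a
#' contrast of one stage against a reference stage (q-values computed
#' within the contrast). Returns one row per feature.
#'
#' @param cm A [count_matrix()].
#' @param stage_a Contrast stage (e.g. `"GRI"`).
#' @param stage_ref Reference stage (e.g. `"MGI"`).
#' @param lfc_threshold,q_threshold Call thresholds, see [call_de()].
#' @param pseudo Pseudocount.
#' @return Data frame `feature_id`, `biotype`, `log2fc`, `p`, `q`, `call`
#'   with the [call_de()] summary attribute; the contrast name is attached
#'   as attribute `contrast`.
#' @export
de_contrast <- function(cm, stage_a, stage_ref = "MGI",
                        lfc_threshold = 1, q_threshold = 0.1, pseudo = 0.5) {
  stopifnot(inherits(cm, "count_matrix"))
  ga <- cm$samples$sample_id[cm$samples$stage == stage_a]
  gb <- cm$samples$sample_id[cm$samples$stage == stage_ref]
  res <- nb_test(cm, ga, gb, pseudo = pseudo)
  res$log2fc <- unname(estimate_log2fc(cm, ga, gb, pseudo = pseudo))
  res$q <- bh_fdr(res$p)
  res$biotype <- cm$feature_meta$biotype[match(res$feature_id,
                                               cm$feature_meta$feature_id)]
  res <- call_de(res[, c("feature_id", "biotype", "log2fc", "p", "q")],
                 lfc_threshold, q_threshold)
  attr(res, "contrast") <- paste0(stage_a, "-", stage_ref)
  res
}
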