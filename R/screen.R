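#' Pearson correlation test
#'
#' Product-moment correlation with the exact t-transform p-value:
#' \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}}, two-sided on `n - 2` degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, non-constant.
#' @param alpha Significance level for the `significant` flag.
#' @return A `correlation_result` list: `r`, `t_stat`, `df`, `p`,
#'   `direction` (positive/negative), `significant`.
#' @export
pearson_test <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need n >= 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  pearson_from_summary(r, n, alpha)
}

#' Pearson test from a reported correlation and sample size
#'
#' Recomputes the t statistic and two-sided p-value from summary values
#' (e.g. a published `r` with known `n`).
#'
#' @param r Correlation coefficient in `[-1, 1]`.
#' @param n Sample size, `>= 3`.
#' @param alpha Significance level.
#' @return A `correlation_result`, as in [pearson_test()].
#' @export
pearson_from_summary <- function(r, n, alpha = 0.05) {
  stopifnot(abs(r) <= 1, n >= 3L)
  df <- n - 2L
  t_stat <- if (abs(r) == 1) sign(r) * Inf else r * sqrt(df) / sqrt(1 - r^2)
  p <- 2 * stats::pt(-abs(t_stat), df)
  structure(list(r = r, t_stat = t_stat, df = df, p = p,
                 direction = if (r >= 0) "positive" else "negative",
                 significant = p < alpha),
            class = "correlation_result")
}

#' Correlate a candidate lncRNA against a gene panel
#'
#' One Pearson test per panel gene against the candidate's expression row,
#' ranked by p-value, with counts of significant positive and negative
#' correlates at `alpha`.
#'
#' @param expr Numeric matrix with features in rows (rownames are ids) and
#'   samples in columns, or an `expression_matrix`.
#' @param candidate_id Row id of the candidate lncRNA (must not be in the
#'   panel).
#' @param panel_ids Row ids of the panel genes.
#' @param alpha Significance level.
#' @return List: `results` (data frame `gene_id`, `r`, `t_stat`, `df`,
#'   `p`, `direction`, `significant`, ranked by p), `n_sig_positive`,
#'   `n_sig_negative`.
#' @export
correlate_panel <- function(expr, candidate_id, panel_ids, alpha = 0.05) {
  if (inherits(expr, "expression_matrix")) expr <- expr$values
  stopifnot(is.matrix(expr))
  if (candidate_id %in% panel_ids) {
    stop("candidate '", candidate_id, "' must not be part of the panel")
  }
  missing <- setdiff(c(candidate_id, panel_ids), rownames(expr))
  if (length(missing)) stop("id(s) not in matrix: ", paste(missing, collapse = ", "))
  if (length(panel_ids) == 0L) {
    return(list(results = data.frame(gene_id = character(), r = numeric(),
                                     t_stat = numeric(), df = integer(),
                                     p = numeric(), direction = character(),
                                     significant = logical()),
                n_sig_positive = 0L, n_sig_negative = 0L))
  }
  cand <- expr[candidate_id, ]
  rows <- lapply(panel_ids, function(g) {
    ct <- pearson_test(cand, expr[g, ], alpha)
    data.frame(gene_id = g, r = ct$r, t_stat = ct$t_stat, df = ct$df,
               p = ct$p, direction = ct$direction, significant = ct$significant)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  list(results = res,
       n_sig_positive = sum(res$significant & res$direction == "positive"),
       n_sig_negative = sum(res$significant & res$direction == "negative"))
}

#' Relative quantification by the 2^-ddCt method
#'
#' \eqn{2^{-((Ct_{target,sample} - Ct_{ref,sample}) -
#' (Ct_{target,calibrator} - Ct_{ref,calibrator}))}}. Shifting all four Ct
#' values by a constant leaves the result unchanged.
#'
#' @param ct_target_sample,ct_ref_sample Ct of the target and reference
#'   (housekeeping) gene in the sample of interest.
#' @param ct_target_calibrator,ct_ref_calibrator Same in the calibrator.
#' @return Relative quantity (1 when there is no change); vectorized.
#' @export
ddct_quantify <- function(ct_target_sample, ct_ref_sample,
                          ct_target_calibrator, ct_ref_calibrator) {
  cts <- cbind(ct_target_sample, ct_ref_sample,
               ct_target_calibrator, ct_ref_calibrator)
  if (any(!is.finite(cts))) stop("Ct values must be finite")
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}

# --- miRNA seed matching ----------------------------------------------------

.norm_seq <- function(seq, what) {
  s <- toupper(seq)
  s <- chartr("U", "T", s)
  if (grepl("[^ACGT]", s)) {
    stop("invalid character(s) in ", what, " sequence (allowed: A, C, G, U/T)")
  }
  s
}

.revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

#' Canonical miRNA seed-match site scan
#'
#' Scans a (lnc)RNA sequence for the canonical seed-complementary site
#' classes of a miRNA. With miRNA positions numbered 5' to 3', the target
#' site (read 5' to 3') is the reverse complement of:
#' positions 2-7 (**6mer**), positions 2-8 (**7mer-m8**), positions 2-7
#' followed by an A opposite position 1 (**7mer-A1**), or positions 2-8
#' followed by that A (**8mer**). U and T are equivalent; overlapping
#' occurrences are all reported. By default each matched locus is reported
#' once with its maximal class (an 8mer site contains 7mer-m8, 7mer-A1 and
#' 6mer matches); set `collapse = FALSE` to report every class at every
#' position.
#'
#' @param lnc_seq Target sequence (length >= 8), RNA or DNA alphabet.
#' @param mirna_seq miRNA sequence (length >= 8), 5' to 3'.
#' @param collapse Report only the maximal class per locus (default TRUE).
#' @return Data frame `position` (0-based start of the site in the
#'   target), `site_class`, `match` (the matched target subsequence, DNA
#'   alphabet).
#' @export
seed_match_scan <- function(lnc_seq, mirna_seq, collapse = TRUE) {
  lnc <- .norm_seq(lnc_seq, "lncRNA")
  mir <- .norm_seq(mirna_seq, "miRNA")
  if (nchar(lnc) < 8L) stop("target sequence must be >= 8 nt")
  if (nchar(mir) < 8L) stop("miRNA sequence must be >= 8 nt")

  seed27 <- substr(mir, 2L, 7L)
  seed28 <- substr(mir, 2L, 8L)
  sites <- list(
    `8mer`      = paste0(.revcomp(seed28), "A"),
    `7mer-m8`   = .revcomp(seed28),
    `7mer-A1`   = paste0(.revcomp(seed27), "A"),
    `6mer`      = .revcomp(seed27))

  hits <- do.call(rbind, lapply(names(sites), function(cls) {
    pat <- sites[[cls]]
    pos <- .find_all(lnc, pat)
    if (length(pos) == 0L) return(NULL)
    data.frame(position = pos - 1L, site_class = cls, match = pat,
               end = pos - 1L + nchar(pat))
  }))
  if (is.null(hits)) {
    return(data.frame(position = integer(), site_class = character(),
                      match = character()))
  }
  prio <- c(`8mer` = 1L, `7mer-m8` = 2L, `7mer-A1` = 3L, `6mer` = 4L)
  hits <- hits[order(prio[hits$site_class], hits$position), , drop = FALSE]
  if (collapse) {
    keep <- rep(TRUE, nrow(hits))
    for (i in seq_len(nrow(hits))) {
      if (!keep[i]) next
      within <- hits$position >= hits$position[i] & hits$end <= hits$end[i] &
        prio[hits$site_class] > prio[hits$site_class[i]]
      keep[within] <- FALSE
    }
    hits <- hits[keep, , drop = FALSE]
  }
  hits <- hits[order(hits$position, prio[hits$site_class]), , drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("position", "site_class", "match")]
}

# all (overlapping) occurrences of fixed pattern, 1-based starts
.find_all <- function(s, pat) {
  out <- integer()
  from <- 1L
  repeat {
    hit <- regexpr(pat, substr(s, from, nchar(s)), fixed = TRUE)
    if (hit == -1L) break
    out <- c(out, from + as.integer(hit) - 1L)
    from <- from + as.integer(hit)
  }
  out
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson shuffle: returns sequences with exactly the same
#' dinucleotide (and hence mononucleotide) composition as the input, by
#' sampling random Eulerian walks on the dinucleotide transition
#' multigraph. Seeded and deterministic.
#'
#' @param seq Input sequence (RNA or DNA alphabet).
#' @param n Number of shuffles.
#' @param seed Integer seed.
#' @return Character vector of `n` shuffled sequences (DNA alphabet).
#' @export
dinucleotide_shuffle <- function(seq, n = 1L, seed = 1L) {
  s <- strsplit(.norm_seq(seq, "input"), "")[[1]]
  L <- length(s)
  if (L < 3L) return(rep(paste(s, collapse = ""), n))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  first <- s[1L]; last <- s[L]
  edges <- split(s[-1L], s[-L])          # outgoing edge targets per vertex
  verts <- names(edges)
  nonterm <- setdiff(verts, last)
  vapply(seq_len(n), function(i) {
    # pick, for every non-terminal vertex, the edge traversed last; a valid
    # Eulerian walk order exists iff those edges form an in-tree to `last`
    repeat {
      last_edge <- lapply(edges[nonterm],
                          function(tg) tg[sample.int(length(tg), 1L)])
      if (.is_intree(last_edge, last)) break
    }
    queues <- lapply(verts, function(v) {
      tg <- edges[[v]]
      if (!v %in% nonterm) return(tg[sample.int(length(tg))])
      le <- last_edge[[v]]
      rest <- tg[-match(le, tg)]
      c(if (length(rest)) rest[sample.int(length(rest))], le)
    })
    names(queues) <- verts
    walk <- character(L)
    walk[1L] <- first
    ptr <- stats::setNames(rep(1L, length(verts)), verts)
    cur <- first
    for (j in 2:L) {
      nxt <- queues[[cur]][ptr[[cur]]]
      ptr[[cur]] <- ptr[[cur]] + 1L
      walk[j] <- nxt
      cur <- nxt
    }
    paste(walk, collapse = "")
  }, character(1L))
}

# do the selected last-edges lead every non-terminal vertex to `last`?
.is_intree <- function(last_edge, last) {
  for (v in names(last_edge)) {
    cur <- v
    for (step in seq_len(length(last_edge) + 1L)) {
      cur <- last_edge[[cur]]
      if (is.null(cur) || identical(cur, last)) break
    }
    if (!identical(cur, last)) return(FALSE)
  }
  TRUE
}

#' Permutation null for seed-site counts
#'
#' Counts seed-match sites in dinucleotide-shuffled versions of the target
#' sequence, giving an empirical null for the observed site count.
#'
#' @param lnc_seq,mirna_seq As in [seed_match_scan()].
#' @param n_shuffles Number of shuffles.
#' @param seed Integer seed.
#' @param collapse Passed to [seed_match_scan()].
#' @return List: `observed` site count, `null` (vector of shuffle counts),
#'   `p` (permutation p-value, add-one corrected).
#' @export
seed_match_null <- function(lnc_seq, mirna_seq, n_shuffles = 1000L, seed = 1L,
                            collapse = TRUE) {
  observed <- nrow(seed_match_scan(lnc_seq, mirna_seq, collapse = collapse))
  shuffles <- dinucleotide_shuffle(lnc_seq, n = n_shuffles, seed = seed)
  null <- vapply(shuffles, function(s) {
    nrow(seed_match_scan(s, mirna_seq, collapse = collapse))
  }, integer(1L), USE.NAMES = FALSE)
  list(observed = observed, null = null,
       p = (1 + sum(null >= observed)) / (1 + n_shuffles))
}
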