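# Independent oracles used across the suite. Each deliberately avoids the
# code path it checks.

# bracketing bisection on a function of t; assumes f(lo) and f(hi) straddle 0
bisect_root <- function(f, lo, hi, tol = 1e-9, max_iter = 200L) {
  flo <- f(lo); fhi <- f(hi)
  stopifnot(is.finite(flo), is.finite(fhi), flo * fhi <= 0)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0 || (hi - lo) / 2 < tol) return(mid)
    if (flo * fm < 0) { hi <- mid; fhi <- fm } else { lo <- mid; flo <- fm }
  }
  (lo + hi) / 2
}

# numeric inflection roots from the analytic derivatives: bisection brackets
# derived from the (large, known-crossing) u-interval mapped to t
numeric_inflections <- function(model) {
  k <- model$k; b <- model$b
  t_of_u <- function(u) log(b / u) / k
  # generous u brackets around each family's crossings
  brackets <- switch(model$family,
    logistic        = list(MGI = c(0.2, 5), GRI = c(2.5, 50), RSI = c(0.01, 0.9)),
    gompertz        = list(MGI = c(0.2, 2.2), GRI = c(1.5, 40), RSI = c(0.01, 0.9)),
    von_bertalanffy = list(MGI = c(0.05, 0.7), GRI = c(0.35, 0.99), RSI = c(0.001, 0.3)))
  res <- sapply(names(brackets), function(nm) {
    ord <- if (nm == "MGI") 2L else 3L
    uu <- brackets[[nm]]
    lo <- t_of_u(max(uu)); hi <- t_of_u(min(uu))   # u decreasing in t
    bisect_root(function(t) growth_rate(model, t, order = ord), lo, hi,
                tol = 1e-10)
  })
  res
}

# Benjamini-Hochberg by its definition: q_i = min_{j: p_(j) >= p_(i)} p_(j)*m/j
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(pmin(ps[i:m] * m / (i:m), 1))
  }, numeric(1))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# all-pairs cis-window oracle on 0-based half-open intervals
cis_brute <- function(lncrnas, genes, window) {
  out <- list()
  for (i in seq_len(nrow(lncrnas))) {
    for (j in seq_len(nrow(genes))) {
      if (lncrnas$chrom[i] != genes$chrom[j]) next
      gap <- max(genes$start[j] - lncrnas$end[i],
                 lncrnas$start[i] - genes$end[j], 0L)
      if (gap <= window) {
        out[[length(out) + 1L]] <- data.frame(lncrna_id = lncrnas$id[i],
                                              gene_id = genes$id[j],
                                              distance = gap)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(lncrna_id = character(), gene_id = character(),
                      distance = integer()))
  }
  do.call(rbind, out)
}

sort_pairs <- function(df) {
  df <- df[order(df$lncrna_id, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# random toy annotation (overlaps allowed), 0-based half-open
random_annotation <- function(n_lnc, n_gene, chroms = c("chr1", "chr2"),
                              span = 5e5) {
  mk <- function(n, prefix, biotype) {
    start <- sample.int(span, n)
    data.frame(chrom = sample(chroms, n, replace = TRUE),
               start = start, end = start + sample(100:20000, n, replace = TRUE),
               id = sprintf("%s_%03d", prefix, seq_len(n)), strand = "+",
               biotype = biotype)
  }
  list(lncrnas = mk(n_lnc, "lnc", "lncRNA"), genes = mk(n_gene, "gene", "mRNA"))
}

# mean silhouette width on euclidean distances, computed from first principles
silhouette_mean <- function(coords, labels) {
  d <- as.matrix(stats::dist(coords))
  sil <- vapply(seq_len(nrow(coords)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(coords)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}

dinuc_counts <- function(s) {
  v <- strsplit(s, "")[[1]]
  tab <- table(paste0(v[-length(v)], v[-1]))
  tab[order(names(tab))]
}
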