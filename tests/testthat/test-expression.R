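# small deterministic count matrix used by several blocks
toy_counts <- function() {
  cnt <- matrix(c(5L, 0L, 995L,
                  10L, 0L, 1990L,
                  0L, 0L, 0L) * 1L, nrow = 3, byrow = TRUE,
                dimnames = list(c("gene_1", "gene_2", "lnc_1"),
                                c("s1", "s2", "s3")))
  count_matrix(cnt, c("mRNA", "mRNA", "lncRNA"), c("GRI", "MGI", "RSI"),
               library_sizes = c(s1 = 1000, s2 = 2000, s3 = 4000))
}

test_that("CPM is counts over library size times a million", {
  cnt <- matrix(c(5L, 0L, 995L), ncol = 1,
                dimnames = list(paste0("f", 1:3), "s1"))
  cm <- count_matrix(cnt, rep("mRNA", 3), "GRI")
  cpm <- compute_cpm(cm)
  expect_equal(unname(cpm$values[, 1]), c(5000, 0, 995000))
  expect_equal(sum(cpm$values[, 1]), 1e6, tolerance = 1e-9)
  # all-zero feature stays all-zero
  cm2 <- toy_counts()
  expect_true(all(compute_cpm(cm2)$values["lnc_1", ] == 0))
  # brute-force recomputation on a seeded synthetic matrix
  sim <- simulate_counts(sim_config(seed = 9,
                                    counts = list(n_mrna = 50, n_lncrna = 20)))
  cpm3 <- compute_cpm(sim$counts)$values
  brute <- sim$counts$counts
  for (j in seq_len(ncol(brute))) {
    brute[, j] <- brute[, j] / sum(sim$counts$counts[, j]) * 1e6
  }
  expect_equal(cpm3, brute, tolerance = 1e-12)
  # CPM columns sum to one million when library sizes are column sums
  expect_equal(unname(colSums(cpm3)), rep(1e6, ncol(cpm3)), tolerance = 1e-6)
})

test_that("zero library sizes are rejected with the offending sample named", {
  cnt <- matrix(0:3, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  cm <- count_matrix(cnt, c("mRNA", "mRNA"), c("GRI", "MGI"),
                     library_sizes = c(s1 = 0, s2 = 10))
  expect_error(compute_cpm(cm), "s1")
})

test_that("count_matrix validates ids, integerness and metadata", {
  cnt <- matrix(1L, 2, 2, dimnames = list(c("a", "a"), c("s1", "s2")))
  expect_error(count_matrix(cnt, c("mRNA", "mRNA"), c("GRI", "MGI")),
               "duplicate feature")
  cnt2 <- matrix(c(1.5, 1, 1, 1), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(count_matrix(cnt2, c("mRNA", "mRNA"), c("GRI", "MGI")),
               "non-negative integers")
  cnt3 <- matrix(1L, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(count_matrix(cnt3, c("mRNA", "weird"), c("GRI", "MGI")),
               "biotype")
})

test_that("CPM matches the edgeR reference implementation", {
  sim <- simulate_counts(sim_config(seed = 4,
                                    counts = list(n_mrna = 80, n_lncrna = 40)))
  ours <- compute_cpm(sim$counts)$values
  theirs <- edgeR::cpm(sim$counts$counts)
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("expressed filter is strict, per-library, and monotone", {
  sim <- simulate_counts(sim_config(seed = 2))
  cpm <- compute_cpm(sim$counts)
  filt <- filter_expressed(cpm)
  # brute-force scan oracle
  brute <- apply(cpm$values, 1L, function(x) sum(x > 0.5) >= 1)
  expect_equal(filt$keep, brute)
  # a feature above threshold in exactly one of nine libraries is kept
  vals <- matrix(0, 1, 9, dimnames = list("f1", paste0("s", 1:9)))
  vals[1, 5] <- 0.6
  ex <- structure(list(values = vals, scale = "cpm",
                       feature_meta = data.frame(feature_id = "f1",
                                                 biotype = "mRNA"),
                       samples = data.frame(sample_id = paste0("s", 1:9),
                                            stage = rep(c("GRI", "MGI", "RSI"),
                                                        each = 3),
                                            replicate = rep(1:3, 3))),
                  class = "expression_matrix")
  expect_equal(filter_expressed(ex)$expressed, "f1")
  # exactly at the threshold everywhere -> dropped (strict >)
  ex$values[1, ] <- 0.5
  expect_length(filter_expressed(ex)$expressed, 0)
  # raising the threshold never adds features
  k1 <- filter_expressed(cpm, threshold = 0.5)$keep
  k2 <- filter_expressed(cpm, threshold = 2)$keep
  expect_true(all(!k1[k2] == FALSE))   # k2 implies k1
  expect_true(all(k2 <= k1))
  # log-scale input is a scale mismatch
  expect_error(filter_expressed(log_transform(cpm)), "scale")
})

test_that("per-stage detection applies the same rule within each stage", {
  sim <- simulate_counts(sim_config(seed = 2,
                                    counts = list(n_mrna = 60, n_lncrna = 30)))
  cpm <- compute_cpm(sim$counts)
  per_stage <- filter_expressed(cpm)$per_stage
  for (st in c("GRI", "MGI", "RSI")) {
    cols <- cpm$samples$stage == st
    for (bt in c("mRNA", "lncRNA")) {
      rows <- cpm$feature_meta$biotype == bt
      brute <- sum(rowSums(cpm$values[rows, cols, drop = FALSE] > 0.5) >= 1)
      got <- per_stage$n_detected[per_stage$stage == st &
                                    per_stage$biotype == bt]
      expect_equal(got, brute)
    }
  }
})

test_that("log transform is log2(x + 1) on CPM only", {
  cpm <- compute_cpm(toy_counts())
  lg <- log_transform(cpm)
  expect_equal(lg$scale, "log2cpm")
  expect_equal(lg$values, log2(cpm$values + 1), tolerance = 1e-12)
  expect_equal(log2(0 + 1), 0)
  expect_equal(log2(1e6 + 1), 19.93157, tolerance = 1e-6)
  expect_error(log_transform(lg), "scale")
  bad <- cpm; bad$values[1, 1] <- -1
  expect_error(log_transform(bad), "negative")
})

test_that("sample clustering merges identical samples first and splits GRI off", {
  # three identical samples plus one orthogonal profile
  set.seed(8)
  base <- rnorm(50, 5, 2)
  vals <- cbind(a = base, b = base + rnorm(50, sd = 1e-3),
                c = base + rnorm(50, sd = 1e-3), d = rev(base))
  rownames(vals) <- paste0("f", 1:50)
  ex <- structure(list(values = vals, scale = "log2cpm",
                       feature_meta = data.frame(feature_id = rownames(vals),
                                                 biotype = "mRNA"),
                       samples = data.frame(sample_id = colnames(vals),
                                            stage = c("GRI", "GRI", "MGI", "RSI"),
                                            replicate = 1:4)),
                  class = "expression_matrix")
  hc <- sample_hclust(ex)
  # the odd sample 'd' is alone on its side of the root split
  expect_equal(hc$labels[stats::cutree(hc, 2) == stats::cutree(hc, 2)[["d"]]],
               "d")
  # deterministic under duplication of the feature set
  ex2 <- ex; ex2$values <- rbind(vals, vals)
  rownames(ex2$values) <- paste0("f", 1:100)
  ex2$feature_meta <- data.frame(feature_id = rownames(ex2$values),
                                 biotype = "mRNA")
  expect_equal(sample_hclust(ex2)$merge, hc$merge)
  # stage-structured counts with MGI/RSI closer together: GRI splits at root
  sim <- simulate_counts(sim_config(seed = 21))
  lg <- log_transform(compute_cpm(sim$counts))
  hc2 <- sample_hclust(lg)
  k2 <- stats::cutree(hc2, 2)
  gri <- grepl("^GRI", names(k2))
  expect_true(length(unique(k2[gri])) == 1 &&
                length(unique(k2[!gri])) == 1 &&
                k2[gri][1] != k2[!gri][1])
  # constant column is an undefined correlation
  ex3 <- ex; ex3$values[, 1] <- 3
  expect_error(sample_hclust(ex3), "constant")
})

test_that("sample PCA separates stages and respects rank bounds", {
  sim <- simulate_counts(sim_config(seed = 13))
  lg <- log_transform(compute_cpm(sim$counts))
  pca <- sample_pca(lg)
  expect_true(all(diff(pca$var_explained) <= 1e-12))
  expect_lte(sum(pca$var_explained), 1 + 1e-9)
  expect_lte(ncol(pca$coords), ncol(lg$values) - 1L)
  expect_error(sample_pca(lg, n_components = 20), "rank")
  # three stages, three replicates: groups separate in the first two PCs
  sil <- silhouette_mean(pca$coords[, 1:2], lg$samples$stage)
  expect_gt(sil, 0.5)
  # centered coordinates reproduce pairwise sample distances in full rank
  d_coords <- stats::dist(pca$coords)
  d_data <- stats::dist(t(lg$values))
  expect_equal(as.numeric(d_coords), as.numeric(d_data), tolerance = 1e-8)
})
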