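#' Simulation configuration
#'
#' Bundles the parameters of all synthetic generators. The defaults mirror
#' the study design the workflow targets: 126 animals weighed at 19
#' timepoints from birth to 400 days around a Von Bertalanffy truth with
#' 5% multiplicative noise; a 3-stage x 3-replicate negative-binomial
#' count matrix with a 10% DE fraction at |log2FC| = 2 and lncRNA
#' abundance shifted below mRNA; toy annotations planting lncRNA-gene
#' gaps that straddle the 100-kb window; and a 47-sample latent-factor
#' panel with 6 positive and 4 negative true correlates at |r| ~ 0.6.
#'
#' @param seed Integer master seed.
#' @param growth,counts,annotation,panel Named lists overriding individual
#'   defaults (partial lists are merged).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, growth = list(), counts = list(),
                       annotation = list(), panel = list()) {
  defaults <- list(
    growth = list(family = "von_bertalanffy", A = 174.607, b = 0.852,
                  k = 0.006, n_animals = 126L,
                  timepoints = round(seq(0, 400, length.out = 19L)),
                  cv_noise = 0.05),
    counts = list(n_mrna = 2000L, n_lncrna = 1000L,
                  stages = c("GRI", "MGI", "RSI"), reps_per_stage = 3L,
                  baseline_log2_mean = 5, baseline_log2_sd = 2,
                  nb_dispersion = 0.05, de_fraction = 0.1,
                  log2fc_effect = 2, lncrna_abundance_shift = 2,
                  gri_de_share = 0.6, libsize_jitter = 0.2),
    annotation = list(n_chroms = 3L, chrom_length = 5e6, gene_length = 2000L,
                      lnc_length = 800L, n_pairs = 24L, window = 100000L),
    panel = list(n_pos = 6L, n_neg = 4L, target_r = 0.6, n_samples = 47L,
                 candidate_noise_sd = 0.2))
  cfg <- list(seed = as.integer(seed),
              growth = utils::modifyList(defaults$growth, growth),
              counts = utils::modifyList(defaults$counts, counts),
              annotation = utils::modifyList(defaults$annotation, annotation),
              panel = utils::modifyList(defaults$panel, panel))
  stopifnot(cfg$growth$cv_noise >= 0,
            cfg$counts$de_fraction >= 0, cfg$counts$de_fraction <= 1,
            cfg$counts$nb_dispersion >= 0)
  structure(cfg, class = "sim_config")
}

#' Simulate longitudinal body-weight records
#'
#' Draws `w_ij = y(t_j) * (1 + e_ij)` for each animal i and timepoint j,
#' with `y` the configured true growth model and `e_ij` Gaussian with
#' standard deviation `cv_noise` (multiplicative noise), truncated so that
#' weights stay positive. Weights at age 0 for a Von Bertalanffy truth are
#' small but positive when `b < 1`. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return List: `records` (data frame `animal_id`, `age`, `weight`) and
#'   `model` (the generating [growth_model()]).
#' @export
simulate_body_weights <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$growth
  if (g$cv_noise >= 1) stop("cv_noise must be < 1")
  model <- growth_model(g$family, g$A, g$b, g$k)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  truth <- predict_weight(model, g$timepoints)
  n <- g$n_animals
  records <- do.call(rbind, lapply(seq_along(g$timepoints), function(j) {
    eps <- stats::rnorm(n, sd = g$cv_noise)
    eps <- pmax(eps, -0.99)               # keep weights > 0
    data.frame(animal_id = sprintf("animal_%03d", seq_len(n)),
               age = g$timepoints[j],
               weight = pmax(truth[j] * (1 + eps), 1e-6))
  }))
  rownames(records) <- NULL
  list(records = records, model = model)
}

#' Simulate a stage-structured negative-binomial count matrix
#'
#' Per-feature baseline means are log-normal (log2 scale), with lncRNA
#' baselines shifted down by `lncrna_abundance_shift` log2 units. A
#' `de_fraction` of features is differentially expressed against the MGI
#' reference: each DE feature is assigned to the GRI contrast (with
#' probability `gri_de_share`) or the RSI contrast, with effect
#' `+/- log2fc_effect`. Counts are negative binomial with dispersion
#' `nb_dispersion` (Poisson when 0); per-sample sequencing depth varies
#' uniformly by `+/- libsize_jitter`.
#'
#' @param config A [sim_config()].
#' @return List: `counts` (a [count_matrix()]) and `truth` (data frame
#'   `feature_id`, `biotype`, `is_de`, `contrast`, `true_log2fc`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cc <- config$counts
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 1L)

  n_feat <- cc$n_mrna + cc$n_lncrna
  biotype <- rep(c("mRNA", "lncRNA"), c(cc$n_mrna, cc$n_lncrna))
  ids <- sprintf("%s_%05d", ifelse(biotype == "mRNA", "gene", "lnc"),
                 seq_len(n_feat))
  base_log2 <- stats::rnorm(n_feat, cc$baseline_log2_mean, cc$baseline_log2_sd) -
    ifelse(biotype == "lncRNA", cc$lncrna_abundance_shift, 0)

  n_de <- round(cc$de_fraction * n_feat)
  de_idx <- sample.int(n_feat, n_de)
  contrast <- rep(NA_character_, n_feat)
  contrast[de_idx] <- ifelse(stats::runif(n_de) < cc$gri_de_share, "GRI", "RSI")
  sign_de <- rep(0, n_feat)
  sign_de[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE)
  true_lfc <- sign_de * cc$log2fc_effect

  stages <- rep(cc$stages, each = cc$reps_per_stage)
  sample_ids <- paste0(stages, "_", sequence(rep(cc$reps_per_stage,
                                                 length(cc$stages))))
  depth <- stats::runif(length(sample_ids), 1 - cc$libsize_jitter,
                        1 + cc$libsize_jitter)

  mu_stage <- function(stage) {
    shift <- ifelse(!is.na(contrast) & contrast == stage, true_lfc, 0)
    2^(base_log2 + shift)
  }
  counts <- matrix(0L, n_feat, length(sample_ids),
                   dimnames = list(ids, sample_ids))
  for (s in seq_along(sample_ids)) {
    mu <- mu_stage(stages[s]) * depth[s]
    counts[, s] <- if (cc$nb_dispersion > 0) {
      stats::rnbinom(n_feat, mu = mu, size = 1 / cc$nb_dispersion)
    } else {
      stats::rpois(n_feat, mu)
    }
  }
  cm <- count_matrix(counts, biotype, stages)
  truth <- data.frame(feature_id = ids, biotype = biotype,
                      is_de = seq_len(n_feat) %in% de_idx,
                      contrast = contrast, true_log2fc = true_lfc)
  list(counts = cm, truth = truth)
}

#' Simulate a toy genomic annotation with known cis pairs
#'
#' Plants lncRNA-gene pairs at controlled gaps — always including 0
#' (overlap handled as gap 0 by convention of adjacent placement),
#' `window - 1`, `window` and `window + 1` — padded far apart so that no
#' unintended pair falls inside the window. Returns the ground-truth pair
#' list (gaps `<= window` only).
#'
#' @param config A [sim_config()].
#' @return List: `lncrnas`, `genes` (feature data frames as from
#'   [read_annotation()]) and `truth_pairs` (`lncrna_id`, `gene_id`,
#'   `distance`).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  an <- config$annotation
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 2L)

  fixed_gaps <- c(0L, an$window - 1L, an$window, an$window + 1L)
  n_extra <- max(0L, an$n_pairs - length(fixed_gaps))
  gaps <- c(fixed_gaps,
            sample.int(3L * an$window, n_extra))   # 1 .. 3*window
  chroms <- paste0("chr", 1 + (seq_along(gaps) - 1) %% an$n_chroms)
  spacing <- 2L * an$window + 10000L               # isolates cassettes

  lnc <- gene <- truth <- vector("list", length(gaps))
  offset <- stats::setNames(rep(0L, an$n_chroms),
                            paste0("chr", seq_len(an$n_chroms)))
  for (i in seq_along(gaps)) {
    ch <- chroms[i]
    start <- offset[[ch]] + spacing
    lnc_start <- start
    lnc_end <- lnc_start + an$lnc_length
    gene_start <- lnc_end + gaps[i]
    gene_end <- gene_start + an$gene_length
    if (gene_end > an$chrom_length) {
      stop("annotation overflow: chromosome ", ch, " too short for ",
           length(gaps), " pair cassettes")
    }
    offset[[ch]] <- gene_end
    lnc[[i]] <- data.frame(chrom = ch, start = lnc_start, end = lnc_end,
                           id = sprintf("lnc_%03d", i), strand = "+",
                           biotype = "lncRNA")
    gene[[i]] <- data.frame(chrom = ch, start = gene_start, end = gene_end,
                            id = sprintf("gene_%03d", i),
                            strand = sample(c("+", "-"), 1L),
                            biotype = "mRNA")
    if (gaps[i] <= an$window) {
      truth[[i]] <- data.frame(lncrna_id = sprintf("lnc_%03d", i),
                               gene_id = sprintf("gene_%03d", i),
                               distance = gaps[i])
    }
  }
  list(lncrnas = do.call(rbind, lnc),
       genes = do.call(rbind, gene),
       truth_pairs = do.call(rbind, truth[!vapply(truth, is.null, TRUE)]))
}

#' Simulate a latent-factor correlated expression panel
#'
#' The candidate row is a standard-normal latent factor plus Gaussian
#' noise (`candidate_noise_sd`); each positive panel gene is
#' `+lambda * latent + noise` and each negative gene `-lambda * latent +
#' noise`, with `lambda` solved so the population correlation with the
#' candidate equals `target_r` exactly.
#'
#' @param config A [sim_config()].
#' @return List: `expr` (matrix, rows `candidate`, `pos_*`, `neg_*`;
#'   columns samples) and `truth` (data frame `gene_id`, `direction`,
#'   `target_r`).
#' @export
simulate_correlated_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pn <- config$panel
  if (abs(pn$target_r) >= 1) stop("target_r must satisfy |r| < 1")
  r_adj <- pn$target_r * sqrt(1 + pn$candidate_noise_sd^2)
  if (abs(r_adj) >= 1) {
    stop("target_r unattainable with candidate_noise_sd = ",
         pn$candidate_noise_sd)
  }
  lambda <- r_adj / sqrt(1 - r_adj^2)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 3L)

  n <- pn$n_samples
  latent <- stats::rnorm(n)
  candidate <- latent + stats::rnorm(n, sd = pn$candidate_noise_sd)
  pos <- t(vapply(seq_len(pn$n_pos),
                  function(i) lambda * latent + stats::rnorm(n),
                  numeric(n)))
  neg <- t(vapply(seq_len(pn$n_neg),
                  function(i) -lambda * latent + stats::rnorm(n),
                  numeric(n)))
  expr <- rbind(candidate = candidate, pos, neg)
  ids <- c("candidate",
           if (pn$n_pos) sprintf("pos_%02d", seq_len(pn$n_pos)),
           if (pn$n_neg) sprintf("neg_%02d", seq_len(pn$n_neg)))
  rownames(expr) <- ids
  colnames(expr) <- sprintf("sample_%02d", seq_len(n))
  truth <- data.frame(gene_id = ids[-1L],
                      direction = rep(c("positive", "negative"),
                                      c(pn$n_pos, pn$n_neg)),
                      target_r = rep(c(pn$target_r, -pn$target_r),
                                     c(pn$n_pos, pn$n_neg)))
  list(expr = expr, truth = truth)
}

#' Simulate a candidate lncRNA sequence with planted miRNA seed sites
#'
#' Generates a random-composition RNA sequence of the given length and
#' plants a chosen seed-site class for the miRNA at fixed positions.
#'
#' @param mirna_seq miRNA sequence (5'->3').
#' @param length Sequence length (default 316 nt, a typical short lncRNA).
#' @param positions 0-based positions at which to plant sites.
#' @param site_class Class to plant.
#' @param seed Integer seed.
#' @return Character DNA-alphabet sequence.
#' @export
simulate_lncrna_sequence <- function(mirna_seq, length = 316L,
                                     positions = integer(),
                                     site_class = "8mer", seed = 1L) {
  mir <- .norm_seq(mirna_seq, "miRNA")
  site <- switch(site_class,
                 `8mer` = paste0(.revcomp(substr(mir, 2L, 8L)), "A"),
                 `7mer-m8` = .revcomp(substr(mir, 2L, 8L)),
                 `7mer-A1` = paste0(.revcomp(substr(mir, 2L, 7L)), "A"),
                 `6mer` = .revcomp(substr(mir, 2L, 7L)),
                 stop("unknown site class: ", site_class))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  s <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  for (p in positions) {
    stopifnot(p >= 0, p + nchar(site) <= length)
    s[(p + 1):(p + nchar(site))] <- strsplit(site, "")[[1]]
  }
  paste(s, collapse = "")
}
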