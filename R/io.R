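#' Read body-weight records from CSV
#'
#' Expects a header `animal_id,age_days,weight_kg`.
#'
#' @param path CSV file.
#' @return Data frame `animal_id`, `age`, `weight` (days / kg).
#' @export
read_weights <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "age_days", "weight_kg")
  if (!all(need %in% names(df))) {
    stop("weights file ", path, " must have header columns ",
         paste(need, collapse = ", "))
  }
  out <- data.frame(animal_id = as.character(df$animal_id),
                    age = as.numeric(df$age_days),
                    weight = as.numeric(df$weight_kg))
  .check_weight_records(out)
}

#' Write body-weight records to CSV
#' @param records Data frame `animal_id`, `age`, `weight`.
#' @param path Output CSV.
#' @export
write_weights <- function(records, path) {
  utils::write.csv(data.frame(animal_id = records$animal_id,
                              age_days = records$age,
                              weight_kg = records$weight),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a count matrix and its metadata from TSV files
#'
#' @param counts_path TSV, first column `feature_id`, remaining columns
#'   integer counts per sample.
#' @param feature_meta_path TSV with columns `feature_id`, `biotype`.
#' @param sample_sheet_path TSV with columns `sample_id`, `stage`,
#'   `replicate`.
#' @return A [count_matrix()].
#' @export
read_counts <- function(counts_path, feature_meta_path, sample_sheet_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1L] != "feature_id") {
    stop("counts file ", counts_path, ": first column must be 'feature_id'")
  }
  if (anyDuplicated(tab$feature_id)) {
    stop("counts file ", counts_path, ": duplicate feature id(s): ",
         paste(unique(tab$feature_id[duplicated(tab$feature_id)]),
               collapse = ", "))
  }
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(mat) || any(mat != round(mat)) || any(mat < 0)) {
    stop("counts file ", counts_path, ": counts must be non-negative integers")
  }
  storage.mode(mat) <- "integer"
  rownames(mat) <- tab$feature_id

  fm <- utils::read.delim(feature_meta_path, stringsAsFactors = FALSE)
  if (!all(c("feature_id", "biotype") %in% names(fm))) {
    stop("feature metadata ", feature_meta_path,
         " must have columns feature_id, biotype")
  }
  ss <- utils::read.delim(sample_sheet_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "stage", "replicate") %in% names(ss))) {
    stop("sample sheet ", sample_sheet_path,
         " must have columns sample_id, stage, replicate")
  }
  count_matrix(mat,
               stats::setNames(fm$biotype, fm$feature_id),
               stats::setNames(ss$stage, ss$sample_id),
               stats::setNames(as.character(ss$replicate), ss$sample_id))
}

#' Write a count matrix and its metadata to TSV files
#' @param cm A [count_matrix()].
#' @param counts_path,feature_meta_path,sample_sheet_path Output TSVs.
#' @export
write_counts <- function(cm, counts_path, feature_meta_path,
                         sample_sheet_path) {
  stopifnot(inherits(cm, "count_matrix"))
  tab <- data.frame(feature_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE)
  utils::write.table(tab, counts_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(cm$feature_meta, feature_meta_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(cm$samples, sample_sheet_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(counts_path)
}

#' Write genomic features as BED6+1
#' @param feats Feature data frame (`chrom`, `start`, `end`, `id`,
#'   `strand`, `biotype`).
#' @param path Output BED file.
#' @export
write_annotation <- function(feats, path) {
  bed <- data.frame(feats$chrom, feats$start, feats$end, feats$id, 0L,
                    feats$strand, feats$biotype)
  utils::write.table(bed, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a generic result table as TSV
#' @param df Data frame.
#' @param path Output file.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full staged-transcriptome workflow on synthetic inputs
#'
#' End-to-end orchestration: simulate (or load) body weights, fit the
#' three sigmoid families and select the best, derive the inflection
#' report; simulate counts, filter to expressed features, run both
#' stage-versus-MGI contrasts; assign cis targets of DE lncRNAs on the
#' toy annotation; and screen the correlated candidate panel. Each
#' stage's tables are written under `out_dir` before the next stage runs.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @return Invisible list bundle with all stage results.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  write <- !is.null(out_dir)
  if (write && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)

  # growth staging
  sim_w <- simulate_body_weights(config)
  fits <- lapply(c("logistic", "gompertz", "von_bertalanffy"),
                 function(fam) fit_growth_model(sim_w$records, fam,
                                                seed = config$seed))
  best <- select_best_model(fits)
  report <- inflection_points(best$model)
  if (write) {
    write_weights(sim_w$records, path("body_weights.csv"))
    write_growth_report(report, path("growth_report.json"))
  }

  # expression profiling
  sim_c <- simulate_counts(config)
  cpm <- compute_cpm(sim_c$counts)
  filt <- filter_expressed(cpm)
  expressed_cm <- subset_features(sim_c$counts, filt$keep)
  logexpr <- log_transform(compute_cpm(expressed_cm))
  hc <- sample_hclust(logexpr)
  pca <- sample_pca(logexpr, n_components = 2L)
  if (write) {
    write_tsv(filt$per_stage, path("detected_per_stage.tsv"))
    write_dendrogram(hc, path("sample_dendrogram.nwk"))
    write_tsv(data.frame(sample_id = rownames(pca$coords), pca$coords),
              path("pca_coordinates.tsv"))
  }

  # differential expression, both contrasts against MGI
  de <- lapply(c("GRI", "RSI"), function(st) {
    res <- de_contrast(expressed_cm, st, "MGI")
    if (write) write_tsv(res, path(sprintf("de_%s_vs_MGI.tsv", st)))
    res
  })
  names(de) <- c("GRI-MGI", "RSI-MGI")
  de_summary <- lapply(de, attr, "summary")

  # cis targets of DE lncRNAs (toy annotation; membership by id prefix is
  # synthetic-only, real runs supply matched annotations)
  sim_a <- simulate_annotation(config)
  cis <- find_cis_targets(sim_a$lncrnas, sim_a$genes,
                          window = config$annotation$window)
  if (write) write_tsv(cis, path("cis_targets.tsv"))

  # candidate screen
  sim_p <- simulate_correlated_panel(config)
  screen <- correlate_panel(sim_p$expr, "candidate",
                            setdiff(rownames(sim_p$expr), "candidate"))
  if (write) write_tsv(screen$results, path("candidate_panel.tsv"))

  if (write) {
    summary_json <- list(
      seed = config$seed,
      growth = list(best_family = best$model$family,
                    r_squared = best$r_squared,
                    t_MGI = report$t_MGI, t_GRI = report$t_GRI,
                    t_RSI = report$t_RSI,
                    max_rate_g_per_day = report$max_rate_g_per_day),
      n_expressed = length(filt$expressed),
      de_summary = de_summary,
      n_cis_pairs = nrow(cis),
      panel = list(n_sig_positive = screen$n_sig_positive,
                   n_sig_negative = screen$n_sig_negative))
    writeLines(jsonlite::toJSON(summary_json, auto_unbox = TRUE, digits = NA),
               path("pipeline_summary.json"))
  }

  invisible(list(weights = sim_w, fits = fits, best = best, report = report,
                 counts = sim_c, filter = filt, hclust = hc, pca = pca,
                 de = de, annotation = sim_a, cis = cis,
                 panel = sim_p, screen = screen))
}
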