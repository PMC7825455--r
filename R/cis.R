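#' Read a BED6+1 genomic annotation
#'
#' Reads features from a BED-like file with seven tab-separated columns:
#' chrom, start, end (0-based half-open), name, score, strand, biotype
#' (mRNA or lncRNA). Malformed lines are reported with their line numbers.
#'
#' @param path BED6+1 file.
#' @return Data frame of validated features: `chrom`, `start`, `end`,
#'   `id`, `strand`, `biotype`.
#' @export
read_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      id = character(), strand = character(),
                      biotype = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 7L)
  if (length(bad)) {
    stop("parse error in ", path, ": expected 7 tab-separated columns at line(s) ",
         paste(bad, collapse = ", "))
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad)) {
    stop("parse error in ", path, ": invalid interval (need 0 <= start < end) ",
         "at line(s) ", paste(bad, collapse = ", "))
  }
  if (!all(m[, 6L] %in% c("+", "-", "."))) {
    stop("parse error in ", path, ": strand must be '+', '-' or '.'")
  }
  if (!all(m[, 7L] %in% c("mRNA", "lncRNA"))) {
    stop("parse error in ", path, ": biotype must be 'mRNA' or 'lncRNA'")
  }
  feats <- data.frame(chrom = m[, 1L], start = start, end = end,
                      id = m[, 4L], strand = m[, 6L], biotype = m[, 7L])
  for (bt in unique(feats$biotype)) {
    ids <- feats$id[feats$biotype == bt]
    if (anyDuplicated(ids)) {
      stop("duplicate ", bt, " id(s): ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
  }
  feats
}

.as_granges <- function(feats) {
  GenomicRanges::GRanges(
    seqnames = feats$chrom,
    ranges = IRanges::IRanges(start = feats$start + 1L, end = feats$end),
    strand = "*")
}

#' lncRNA cis-target assignment by genomic window
#'
#' Pairs each lncRNA with every protein-coding gene on the same chromosome
#' whose interval gap is at most `window` bases (100 kb by default).
#' Distance is the number of bases strictly between the nearest interval
#' ends; overlapping or adjacent intervals have distance 0. Strand is
#' ignored (cis regulation is considered in both orientations). The
#' boundary is inclusive: a gap of exactly `window` still pairs.
#'
#' @param lncrnas,genes Feature data frames as from [read_annotation()]
#'   (`chrom`, `start`, `end`, `id`; 0-based half-open).
#' @param window Maximum gap in bp, `>= 0`.
#' @return Data frame `lncrna_id`, `gene_id`, `distance`, ordered by
#'   lncRNA then gene.
#' @export
find_cis_targets <- function(lncrnas, genes, window = 100000L) {
  stopifnot(window >= 0)
  empty <- data.frame(lncrna_id = character(), gene_id = character(),
                      distance = integer())
  if (nrow(lncrnas) == 0L || nrow(genes) == 0L) return(empty)
  lgr <- .as_granges(lncrnas)
  ggr <- .as_granges(genes)
  hits <- GenomicRanges::findOverlaps(lgr, ggr, maxgap = window,
                                      ignore.strand = TRUE)
  if (length(hits) == 0L) return(empty)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  d <- GenomicRanges::distance(lgr[qh], ggr[sh])
  keep <- !is.na(d) & d <= window
  out <- data.frame(lncrna_id = lncrnas$id[qh[keep]],
                    gene_id = genes$id[sh[keep]],
                    distance = as.integer(d[keep]))
  out[order(match(out$lncrna_id, lncrnas$id), match(out$gene_id, genes$id)), ,
      drop = FALSE] |> `rownames<-`(NULL)
}
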