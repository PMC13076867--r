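#' Read replication-initiation zones from a scored BED file
#'
#' BED5 (or wider): chrom, start, end, name, score; the score column holds
#' the replication-initiation score.
#'
#' @param path Path to a BED file with at least 5 columns.
#' @return Data frame: chrom, start, end, name, score (sorted by position).
#' @export
read_scored_bed <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  ncol <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  if (ncol < 5) stop("scored BED requires >= 5 columns (score in column 5)")
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$score) || any(is.na(gr$score)))
    stop("missing score column in ", path)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   name = if (!is.null(gr$name)) gr$name else
                     sprintf("zone%d", seq_along(gr)),
                   score = as.numeric(gr$score),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop("zone with start >= end in ", path)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write zones as scored BED
#' @param zones Zone data frame (chrom, start, end, name, score).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scored_bed <- function(zones, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%s", zones$chrom,
                   as.integer(zones$start), as.integer(zones$end),
                   zones$name, format(zones$score, trim = TRUE,
                                      scientific = FALSE))
  writeLines(lines, path)
  invisible(path)
}

#' Mean nascent signal over zones, per condition
#'
#' Zones are strandless: both strands are summed. Signal is the mean
#' normalized value per bp over the zone.
#'
#' @param zones Zone data frame.
#' @param covs Named list of `stranded_coverage`, one per condition
#'   (spike-scaled).
#' @return `zones` with one `signal_<condition>` column per condition.
#' @export
quantify_zone_signal <- function(zones, covs) {
  stopifnot(is.list(covs), !is.null(names(covs)))
  for (cond in names(covs)) {
    cov <- covs[[cond]]
    vals <- vapply(seq_len(nrow(zones)), function(i) {
      z <- zones[i, ]
      if (!z$chrom %in% names(cov$chrom_lengths) ||
          z$start >= cov$chrom_lengths[[z$chrom]]) {
        warning("zone ", z$name, " outside coverage extent; signal 0")
        return(0)
      }
      region_signal_mean(cov, z$chrom, "both", z$start, z$end)
    }, numeric(1))
    zones[[paste0("signal_", cond)]] <- vals
  }
  zones
}

#' Classify zones as polymerase-affected or not
#'
#' A zone is affected (`P-A`) when log2(signal at the treated condition /
#' signal at baseline) is strictly greater than `cutoff_log2`; otherwise
#' `P-NA`. Zones with a zero baseline are `unscored`. Classification is
#' invariant under any rescaling applied equally to both conditions.
#'
#' @param zones Output of [quantify_zone_signal()].
#' @param cond_t,cond_0 Condition labels (column suffixes) for treated and
#'   baseline signals.
#' @param cutoff_log2 Log2-ratio cutoff (strict).
#' @return `zones` with `log2_ratio` and `label` columns.
#' @export
classify_pa_pna <- function(zones, cond_t, cond_0, cutoff_log2 = log2(1.25)) {
  st <- zones[[paste0("signal_", cond_t)]]
  s0 <- zones[[paste0("signal_", cond_0)]]
  if (is.null(st) || is.null(s0))
    stop("zones lack signal columns for '", cond_t, "' / '", cond_0, "'")
  ratio <- ifelse(s0 > 0, log2(st / s0), NA_real_)
  zones$log2_ratio <- ratio
  zones$label <- ifelse(!(s0 > 0), "unscored",
                        ifelse(ratio > cutoff_log2, "P-A", "P-NA"))
  zones
}

#' Distance from each zone to the closest gene
#'
#' Minimum edge-to-edge gap to any gene on either strand; 0 when zone and
#' gene overlap. Zones on a chromosome with no genes get `NA` and a flag.
#'
#' @param zones Zone data frame.
#' @param genes A gene table.
#' @return `zones` with `distance_to_closest_gene` and `size` columns.
#' @export
zone_gene_distance <- function(zones, genes) {
  dist <- rep(NA_real_, nrow(zones))
  for (i in seq_len(nrow(zones))) {
    z <- zones[i, ]
    same <- genes$chrom == z$chrom
    if (!any(same)) next
    gap <- pmax(genes$start[same] - z$end, z$start - genes$end[same], 0)
    dist[i] <- min(gap)
  }
  if (anyNA(dist)) warning(sum(is.na(dist)),
                           " zone(s) on chromosomes without genes")
  zones$distance_to_closest_gene <- dist
  zones$size <- zones$end - zones$start
  zones
}

#' High-confidence perturbed zones
#'
#' Zones with a replication-initiation score strictly above `score_min` and
#' a treated/baseline signal ratio strictly above `fold_min`.
#'
#' @param zones Output of [classify_pa_pna()] (needs `log2_ratio`).
#' @param score_min Strict score lower bound.
#' @param fold_min Strict fold-change lower bound (linear scale).
#' @return The retained zone subset.
#' @export
high_confidence_perturbed <- function(zones, score_min = 10, fold_min = 2) {
  if (is.null(zones$log2_ratio)) stop("zones lack a log2_ratio column")
  keep <- !is.na(zones$log2_ratio) & zones$score > score_min &
    2^zones$log2_ratio > fold_min
  out <- zones[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
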