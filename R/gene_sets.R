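#' Expressed-gene universe
#'
#' @param genes A gene table with an `expression` column.
#' @param min_expression Minimum expression (inclusive).
#' @return The subset of `genes` with `expression >= min_expression`.
#' @export
select_expressed <- function(genes, min_expression = 1) {
  keep <- !is.na(genes$expression) & genes$expression >= min_expression
  if (!any(keep)) warning("no gene passes the expression threshold")
  out <- genes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Non-overlapping, highly expressed gene universe
#'
#' Retains genes that are (i) separated by at least `min_separation` bp from
#' any other gene (either strand) on both flanks, (ii) longer than
#' `min_length`, and (iii) covered above `min_density` (strict) in both the
#' gene body and the termination region, in both conditions. The separation
#' filter is symmetric: two genes closer than the threshold both fail.
#'
#' @param genes A gene table.
#' @param cov_a,cov_b Normalized `stranded_coverage` for the two conditions.
#' @param min_separation Minimum flank clearance, bp.
#' @param min_length Minimum gene length, bp.
#' @param min_density Strict lower bound on mean normalized signal per bp.
#' @param dog_length Termination-region length past the TES, bp.
#' @return The retained subset of `genes`, with a `filters` attribute
#'   recording the thresholds (provenance).
#' @export
select_nonoverlapping <- function(genes, cov_a, cov_b,
                                  min_separation = 2500,
                                  min_length = 2000,
                                  min_density = 50,
                                  dog_length = 2500) {
  n <- nrow(genes)
  sep_ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    same <- genes$chrom == genes$chrom[i]
    same[i] <- FALSE
    if (!any(same)) next
    gap_left <- genes$start[i] - genes$end[same]
    gap_right <- genes$start[same] - genes$end[i]
    gap <- pmax(gap_left, gap_right)  # negative when overlapping
    if (any(gap < min_separation)) sep_ok[i] <- FALSE
  }
  len_ok <- gene_length(genes) > min_length
  dens_ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    g <- genes[i, ]
    body <- sort(c(g$start, g$end))
    dog <- dog_window(g, dog_length)
    for (cov in list(cov_a, cov_b)) {
      if (!g$chrom %in% names(cov$chrom_lengths))
        stop("gene ", g$gene_id, " has no coverage")
      vals <- c(region_signal_mean(cov, g$chrom, g$strand, body[1], body[2]),
                region_signal_mean(cov, g$chrom, g$strand, dog[1], dog[2]))
      if (!all(vals > min_density)) dens_ok[i] <- FALSE
    }
  }
  keep <- sep_ok & len_ok & dens_ok
  out <- genes[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filters") <- list(min_separation = min_separation,
                               min_length = min_length,
                               min_density = min_density,
                               dog_length = dog_length)
  out
}

# strand-aware termination window [TES, TES + dog_length) in genomic coords
dog_window <- function(gene, dog_length = 2500) {
  if (gene$strand == "+") c(gene$end, gene$end + dog_length)
  else c(gene$start - dog_length, gene$start)
}

#' Strand-aware last exons
#'
#' The biological final exon of each gene with at least two exons and length
#' above `min_length`; single-exon (or short) genes are silently filtered.
#'
#' @param genes A gene table with exon blocks.
#' @param min_length Minimum gene length, bp.
#' @return Data frame: gene_id, chrom, strand, start, end (the last exon).
#' @export
last_exons <- function(genes, min_length = 2000) {
  keep <- vapply(genes$exons, nrow, 0L) >= 2L & gene_length(genes) > min_length
  g <- genes[keep, , drop = FALSE]
  out <- lapply(seq_len(nrow(g)), function(i) {
    ex <- g$exons[[i]]
    j <- if (g$strand[i] == "+") nrow(ex) else 1L
    data.frame(gene_id = g$gene_id[i], chrom = g$chrom[i],
               strand = g$strand[i], start = ex[j, "start"],
               end = ex[j, "end"], stringsAsFactors = FALSE)
  })
  if (!length(out))
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = numeric(),
                      end = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
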