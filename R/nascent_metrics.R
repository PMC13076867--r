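#' Mean normalized signal density over a region
#'
#' Sum of signal in the region, optionally library-normalized, divided by
#' region length. Spike-scaled tracks pass their applied scale through
#' unchanged (no further normalization).
#'
#' @param cov A `stranded_coverage`.
#' @param chrom Chromosome.
#' @param start,end Region, 0-based half-open.
#' @param strand `"+"`, `"-"` or `"both"` (strands summed).
#' @param library_total If not `NULL`, counts are scaled to
#'   `per / library_total`.
#' @param per Reference depth for library normalization.
#' @return Normalized signal per bp (a single number).
#' @export
quantify_region <- function(cov, chrom, start, end, strand = "+",
                            library_total = NULL, per = 1e8) {
  if (end <= start) stop("empty region: start >= end")
  d <- region_signal_mean(cov, chrom, strand, start = start, end = end)
  if (!is.null(library_total)) d <- library_normalize(d, library_total, per)
  d
}

#' Termination index
#'
#' TI = log2(downstream density / body density), with the downstream-of-gene
#' window extending `dog_length` bp 3' of the biological TES on the gene's
#' strand and both densities length-normalized. Sense-strand signal only.
#' When the body density is zero the call is unclassifiable (`ti = NA`);
#' when only the downstream density is zero, `ti = -Inf` and the call is
#' flagged.
#'
#' @param cov A `stranded_coverage` (any normalization state; a global
#'   factor cancels in the ratio).
#' @param genes A gene table.
#' @param dog_length Downstream window length, bp.
#' @param library_total Optional library size for density normalization
#'   (cancels in TI; kept so densities are reported on the stated scale).
#' @return Data frame: gene_id, body_density, dog_density, ti, flagged.
#' @export
termination_index <- function(cov, genes, dog_length = 2500,
                              library_total = NULL) {
  n <- nrow(genes)
  body_d <- dog_d <- ti <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    g <- genes[i, ]
    if (gene_length(g) <= 0) stop("gene body length must be positive")
    body <- sort(c(g$start, g$end))
    dog <- dog_window(g, dog_length)
    body_d[i] <- quantify_region(cov, g$chrom, body[1], body[2], g$strand,
                                 library_total)
    dog_d[i] <- quantify_region(cov, g$chrom, dog[1], dog[2], g$strand,
                                library_total)
    ti[i] <- if (body_d[i] > 0) log2(dog_d[i] / body_d[i]) else NA_real_
  }
  data.frame(gene_id = genes$gene_id, body_density = body_d,
             dog_density = dog_d, ti = ti,
             flagged = !is.finite(ti), stringsAsFactors = FALSE)
}

#' Classify termination dependence from a TI shift
#'
#' Genes whose TI increases by strictly more than `delta_threshold` between
#' control and perturbed conditions are called dependent-termination (NDT);
#' genes with both TIs finite but a smaller shift are independent (NIT);
#' genes with a non-finite TI in either condition are unclassified. No
#' default threshold is supplied: choose it from the expected effect size
#' (see [expected_delta_ti()]).
#'
#' @param ti_control,ti_perturbed Outputs of [termination_index()] on the
#'   two conditions (matched by `gene_id`).
#' @param delta_threshold Strict lower bound on `delta_ti` for an NDT call.
#' @return Data frame: gene_id, ti_control, ti_perturbed, delta_ti, class.
#' @export
classify_ndt_nit <- function(ti_control, ti_perturbed, delta_threshold) {
  if (missing(delta_threshold))
    stop("delta_threshold has no default; derive it from the effect size")
  m <- merge(ti_control[, c("gene_id", "ti")],
             ti_perturbed[, c("gene_id", "ti")],
             by = "gene_id", suffixes = c("_control", "_perturbed"))
  m$delta_ti <- m$ti_perturbed - m$ti_control
  ok <- is.finite(m$ti_control) & is.finite(m$ti_perturbed)
  m$class <- ifelse(!ok, "unclassified",
                    ifelse(m$delta_ti > delta_threshold, "NDT", "NIT"))
  m
}

#' Promoter-proximal pausing index
#'
#' Density over the promoter-proximal window `[TSS, TSS + pause_window)`
#' divided by density over the remaining gene body
#' `[TSS + pause_window, TES)`, strand-aware, sense-strand signal.
#'
#' @param cov A `stranded_coverage`.
#' @param genes A gene table.
#' @param pause_window Promoter-proximal window length, bp.
#' @return Data frame: gene_id, pause_density, body_density, pausing_index,
#'   flagged (zero body density).
#' @export
pausing_index <- function(cov, genes, pause_window = 300) {
  n <- nrow(genes)
  pd <- bd <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    g <- genes[i, ]
    if (gene_length(g) <= pause_window)
      stop("gene ", g$gene_id, " not longer than the pause window")
    if (g$strand == "+") {
      pw <- c(g$start, g$start + pause_window)
      body <- c(g$start + pause_window, g$end)
    } else {
      pw <- c(g$end - pause_window, g$end)
      body <- c(g$start, g$end - pause_window)
    }
    pd[i] <- quantify_region(cov, g$chrom, pw[1], pw[2], g$strand)
    bd[i] <- quantify_region(cov, g$chrom, body[1], body[2], g$strand)
  }
  data.frame(gene_id = genes$gene_id, pause_density = pd, body_density = bd,
             pausing_index = ifelse(bd > 0, pd / bd, NA_real_),
             flagged = !(bd > 0), stringsAsFactors = FALSE)
}

# mean signal of a region split into n equal body bins, 5'->3'
scaled_body_means <- function(cov, chrom, strand, start, end, n_bins) {
  edges <- start + (end - start) * (0:n_bins) / n_bins
  v <- vapply(seq_len(n_bins), function(j)
    region_signal_mean(cov, chrom, strand, edges[j], edges[j + 1L]),
    numeric(1))
  if (strand == "-") rev(v) else v
}

#' Elongation-index profile (synthesis / occupancy)
#'
#' Each gene body is scaled to `n_bins` bins; the per-bin elongation index
#' is mean(synthesis track) / mean(occupancy track) (e.g., TT-seq over
#' POINT-seq). Bins with a zero denominator are masked (NA). The aggregate
#' profile is the per-bin mean over genes, ignoring masked bins. Genes
#' shorter than `n_bins * min_bin_bp` are excluded with a warning.
#'
#' @param tt Synthesis-weighted `stranded_coverage` (numerator).
#' @param point Occupancy `stranded_coverage` (denominator), on the same
#'   normalization footing as `tt` per condition.
#' @param genes A gene table.
#' @param n_bins Number of scaled body bins.
#' @param min_bin_bp Minimum bp per scaled bin.
#' @return A list of class `elongation_profile`: `matrix` (genes x bins),
#'   `profile` (aggregate per-bin mean), `genes` (ids used).
#' @export
elongation_index_profile <- function(tt, point, genes, n_bins = 40,
                                     min_bin_bp = 10) {
  ok <- gene_length(genes) >= n_bins * min_bin_bp
  if (any(!ok))
    warning(sum(!ok), " gene(s) shorter than ", n_bins * min_bin_bp,
            " bp excluded from the elongation profile")
  g <- genes[ok, , drop = FALSE]
  mat <- matrix(NA_real_, nrow(g), n_bins,
                dimnames = list(g$gene_id, NULL))
  for (i in seq_len(nrow(g))) {
    num <- scaled_body_means(tt, g$chrom[i], g$strand[i], g$start[i],
                             g$end[i], n_bins)
    den <- scaled_body_means(point, g$chrom[i], g$strand[i], g$start[i],
                             g$end[i], n_bins)
    ei <- ifelse(den > 0, num / den, NA_real_)
    mat[i, ] <- ei
  }
  profile <- colMeans(mat, na.rm = TRUE)
  profile[!is.finite(profile)] <- NA_real_
  structure(list(matrix = mat, profile = profile, genes = g$gene_id),
            class = "elongation_profile")
}

#' @export
print.elongation_profile <- function(x, ...) {
  cat("elongation_profile: ", nrow(x$matrix), " genes x ", ncol(x$matrix),
      " scaled bins; aggregate median ",
      signif(stats::median(x$profile, na.rm = TRUE), 4), "\n", sep = "")
  invisible(x)
}

read_has_gap <- function(reads) {
  if (!is.null(reads$gapped)) return(as.logical(reads$gapped))
  grepl(",", reads$blocks, fixed = TRUE)
}

#' Splicing efficiency over units
#'
#' For each unit (gene or junction window), reads overlapping the unit on
#' the matching strand are counted; those whose alignment carries a gap
#' (spliced reads) are related to the total. Units with no overlapping
#' reads are flagged with undefined efficiency.
#'
#' @param reads Read records with `chrom`, `start`, `end`, `strand` and
#'   either a logical `gapped` column or a `blocks` string (a comma marks a
#'   gap).
#' @param units Data frame of unit intervals: `unit_id` (or `gene_id`),
#'   `chrom`, `strand`, `start`, `end`.
#' @return Data frame: unit_id, spliced_reads, total_reads, efficiency,
#'   flagged.
#' @export
splicing_efficiency <- function(reads, units) {
  id_col <- if ("unit_id" %in% names(units)) "unit_id" else "gene_id"
  gap <- read_has_gap(reads)
  n <- nrow(units)
  spliced <- total <- integer(n)
  for (i in seq_len(n)) {
    u <- units[i, ]
    hit <- reads$chrom == u$chrom & reads$strand == u$strand &
      reads$start < u$end & reads$end > u$start
    total[i] <- sum(hit)
    spliced[i] <- sum(hit & gap)
  }
  data.frame(unit_id = units[[id_col]], spliced_reads = spliced,
             total_reads = total,
             efficiency = ifelse(total > 0, spliced / total, NA_real_),
             flagged = total == 0, stringsAsFactors = FALSE)
}

#' Scaled metagene matrix and mean profile
#'
#' Each region's body is linearly rescaled to `body_bins` bins, flanked by
#' `up_bins` and `down_bins` fixed-width bins of `flank_bin_width` bp.
#' Minus-strand rows are reversed so that column 1 is always the biological
#' 5' end. The mean profile is the unweighted column mean over regions.
#' Regions shorter than one body bin are excluded.
#'
#' @param cov A `stranded_coverage`.
#' @param regions Data frame with `chrom`, `start`, `end`, `strand`.
#' @param body_bins Number of scaled body bins.
#' @param up_bins,down_bins Fixed-width flank bin counts.
#' @param flank_bin_width Flank bin width, bp.
#' @return A list of class `metagene`: `matrix`
#'   (regions x (up+body+down) bins), `profile` (column means), and the bin
#'   geometry.
#' @export
metagene_matrix <- function(cov, regions, body_bins = 400, up_bins = 250,
                            down_bins = 250, flank_bin_width = 10) {
  keep <- (regions$end - regions$start) >= body_bins
  regions <- regions[keep, , drop = FALSE]
  total_bins <- up_bins + body_bins + down_bins
  mat <- matrix(NA_real_, nrow(regions), total_bins)
  fw <- flank_bin_width
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    body <- scaled_body_means(cov, r$chrom, r$strand, r$start, r$end,
                              body_bins)
    up5 <- down3 <- numeric(0)
    if (up_bins > 0) {
      if (r$strand == "+") {
        edges <- r$start - fw * (up_bins:0)
        up5 <- vapply(seq_len(up_bins), function(j) region_signal_mean(
          cov, r$chrom, r$strand, edges[j], edges[j + 1L]), numeric(1))
      } else {
        edges <- r$end + fw * (0:up_bins)
        up5 <- rev(vapply(seq_len(up_bins), function(j) region_signal_mean(
          cov, r$chrom, r$strand, edges[j], edges[j + 1L]), numeric(1)))
      }
    }
    if (down_bins > 0) {
      if (r$strand == "+") {
        edges <- r$end + fw * (0:down_bins)
        down3 <- vapply(seq_len(down_bins), function(j) region_signal_mean(
          cov, r$chrom, r$strand, edges[j], edges[j + 1L]), numeric(1))
      } else {
        edges <- r$start - fw * (down_bins:0)
        down3 <- rev(vapply(seq_len(down_bins), function(j)
          region_signal_mean(cov, r$chrom, r$strand, edges[j], edges[j + 1L]),
          numeric(1)))
      }
    }
    mat[i, ] <- c(up5, body, down3)
  }
  structure(list(matrix = mat, profile = colMeans(mat, na.rm = TRUE),
                 up_bins = up_bins, body_bins = body_bins,
                 down_bins = down_bins, flank_bin_width = flank_bin_width),
            class = "metagene")
}

#' @export
print.metagene <- function(x, ...) {
  cat("metagene: ", nrow(x$matrix), " regions, ",
      x$up_bins, " + ", x$body_bins, " + ", x$down_bins, " bins\n", sep = "")
  invisible(x)
}
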