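#' Strand-specific binned coverage
#'
#' A `stranded_coverage` object holds per-chromosome, per-strand signal on a
#' fixed bin grid. Values are per-bp signal densities (bedGraph semantics), so
#' the signal mass of a bin is `value * bin_extent`. The same bin grid is used
#' for both strands of a chromosome, and the normalization state of the track
#' (`"raw"`, `"per100M"` or `"spike-scaled"`) is carried along with every
#' scaling factor that has been applied.
#'
#' @param bin_width Bin width in bp (positive integer).
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#' @return An object of class `stranded_coverage`.
#' @export
stranded_coverage <- function(bin_width, chrom_lengths) {
  if (length(bin_width) != 1L || !is.finite(bin_width) || bin_width <= 0)
    stop("bin_width must be a single positive number")
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  bin_width <- as.integer(bin_width)
  values <- lapply(chrom_lengths, function(len) {
    n <- ceiling(len / bin_width)
    list(`+` = numeric(n), `-` = numeric(n))
  })
  structure(
    list(bin_width = bin_width,
         chrom_lengths = chrom_lengths,
         values = values,
         norm_state = "raw",
         factors = numeric(0)),
    class = "stranded_coverage")
}

#' @export
print.stranded_coverage <- function(x, ...) {
  cat("stranded_coverage: ", length(x$chrom_lengths), " chromosome(s), ",
      "bin width ", x$bin_width, " bp, state '", x$norm_state, "'\n", sep = "")
  for (chrom in names(x$chrom_lengths)) {
    cat("  ", chrom, ": ", x$chrom_lengths[[chrom]], " bp, ",
        length(x$values[[chrom]][["+"]]), " bins\n", sep = "")
  }
  if (length(x$factors))
    cat("  factors applied:", paste(signif(x$factors, 6), collapse = ", "), "\n")
  invisible(x)
}

check_strand <- function(strand) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  strand
}

#' Replace the signal of one (chromosome, strand) track
#'
#' @param cov A `stranded_coverage`.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param values Numeric vector, one value per bin of the chromosome grid.
#' @return The modified `stranded_coverage`.
#' @export
set_track <- function(cov, chrom, strand, values) {
  check_strand(strand)
  if (!chrom %in% names(cov$chrom_lengths)) stop("unknown chromosome: ", chrom)
  n <- length(cov$values[[chrom]][[strand]])
  if (length(values) != n)
    stop("expected ", n, " bin values for ", chrom, ", got ", length(values))
  if (any(!is.finite(values))) stop("coverage values must be finite")
  cov$values[[chrom]][[strand]] <- as.numeric(values)
  cov
}

# extent of each bin in bp (last bin may be clipped by the chromosome end)
bin_extents <- function(cov, chrom) {
  len <- cov$chrom_lengths[[chrom]]
  n <- length(cov$values[[chrom]][["+"]])
  ext <- rep(cov$bin_width, n)
  ext[n] <- len - (n - 1L) * cov$bin_width
  ext
}

# Sum of signal mass (value * bp) over genomic [start, end), one strand.
# Partial bins contribute value * overlap. Regions outside the data are 0.
region_signal_sum <- function(cov, chrom, strand, start, end) {
  check_strand(strand)
  if (end <= start) stop("empty region: start >= end")
  if (!chrom %in% names(cov$chrom_lengths)) return(0)
  len <- cov$chrom_lengths[[chrom]]
  start <- max(start, 0)
  end <- min(end, len)
  if (end <= start) return(0)
  bw <- cov$bin_width
  v <- cov$values[[chrom]][[strand]]
  b0 <- floor(start / bw)
  b1 <- floor((end - 1) / bw)
  idx <- seq.int(b0, b1)
  lo <- pmax(start, idx * bw)
  hi <- pmin(end, (idx + 1) * bw)
  sum(v[idx + 1L] * (hi - lo))
}

# Mean per-bp signal over [start, end) for one strand or both summed.
region_signal_mean <- function(cov, chrom, strand = c("+", "-", "both"),
                               start, end) {
  strand <- match.arg(strand)
  if (strand == "both") {
    s <- region_signal_sum(cov, chrom, "+", start, end) +
      region_signal_sum(cov, chrom, "-", start, end)
  } else {
    s <- region_signal_sum(cov, chrom, strand, start, end)
  }
  s / (end - start)
}

#' Scale every bin of a coverage track by a constant
#'
#' Records the applied factor and updates the normalization state exactly once
#' per applied factor.
#'
#' @param cov A `stranded_coverage`.
#' @param scale Positive multiplicative factor.
#' @param state New normalization state label
#'   (`"per100M"` or `"spike-scaled"`).
#' @return The scaled `stranded_coverage`.
#' @export
scale_coverage <- function(cov, scale, state = c("spike-scaled", "per100M")) {
  state <- match.arg(state)
  if (!is.finite(scale) || scale <= 0) stop("scale must be positive and finite")
  for (chrom in names(cov$values))
    for (strand in c("+", "-"))
      cov$values[[chrom]][[strand]] <- cov$values[[chrom]][[strand]] * scale
  cov$factors <- c(cov$factors, scale)
  cov$norm_state <- state
  cov
}

#' Read a bedGraph file onto a bin grid
#'
#' Intervals (0-based, half-open, as in the format) are rasterized onto the
#' grid with length-weighted means, so total signal mass is conserved. The
#' file must be sorted and non-overlapping per chromosome and all values must
#' be non-negative.
#'
#' @param path Path to a bedGraph file.
#' @param strand Which strand of the track the file represents.
#' @param bin_width Bin width in bp for the grid.
#' @param chrom_lengths Named lengths of the chromosomes. If `NULL`, the
#'   farthest interval end per chromosome is used.
#' @param into Optionally an existing `stranded_coverage` whose other strand
#'   is already filled; the file is added onto its grid.
#' @return A `stranded_coverage` with `norm_state = "raw"`.
#' @export
read_bedgraph <- function(path, strand, bin_width = 100,
                          chrom_lengths = NULL, into = NULL) {
  check_strand(strand)
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) && any(gr$score < 0))
    stop("negative coverage value in ", path)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   value = gr$score)
  if (!is.null(into)) {
    cov <- into
  } else {
    if (is.null(chrom_lengths)) {
      if (!nrow(df)) stop("empty bedGraph and no chrom_lengths given")
      chrom_lengths <- vapply(split(df$end, df$chrom), max, numeric(1))
    }
    cov <- stranded_coverage(bin_width, chrom_lengths)
  }
  for (chrom in unique(df$chrom)) {
    d <- df[df$chrom == chrom, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)]))
      stop("overlapping bedGraph intervals on ", chrom)
    if (!chrom %in% names(cov$chrom_lengths)) next
    cov$values[[chrom]][[strand]] <-
      rasterize_intervals(d, cov$chrom_lengths[[chrom]], cov$bin_width)
  }
  cov$norm_state <- "raw"
  cov
}

# value-weighted rasterization of sorted, non-overlapping intervals;
# per-bp Rle -> binned means keeps signal mass exact
rasterize_intervals <- function(d, chrom_len, bin_width) {
  n_bins <- ceiling(chrom_len / bin_width)
  keep <- d$start < chrom_len & d$end > 0
  d <- d[keep, , drop = FALSE]
  if (!nrow(d)) return(numeric(n_bins))
  d$end <- pmin(d$end, chrom_len)
  d$start <- pmax(d$start, 0)
  ir <- IRanges::IRanges(start = d$start + 1L, end = d$end)
  rle <- IRanges::coverage(ir, weight = d$value, width = chrom_len)
  bin_start <- seq.int(1L, by = bin_width, length.out = n_bins)
  bin_end <- pmin(bin_start + bin_width - 1L, chrom_len)
  v <- IRanges::Views(rle, start = bin_start, end = bin_end)
  as.numeric(IRanges::viewSums(v)) / (bin_end - bin_start + 1)
}

#' Write one strand of a coverage track as bedGraph
#'
#' Adjacent bins with equal values are merged into runs, so
#' `write_bedgraph(read_bedgraph(f))` reproduces `f` up to run-length merging.
#'
#' @param cov A `stranded_coverage`.
#' @param path Output path.
#' @param strand Which strand to write.
#' @param drop_zero Omit zero-valued runs (bedGraph convention).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(cov, path, strand, drop_zero = TRUE) {
  check_strand(strand)
  recs <- list()
  for (chrom in names(cov$chrom_lengths)) {
    v <- cov$values[[chrom]][[strand]]
    if (!length(v)) next
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- c(0L, ends_bin[-length(ends_bin)])
    start <- starts_bin * cov$bin_width
    end <- pmin(ends_bin * cov$bin_width, cov$chrom_lengths[[chrom]])
    keep <- if (drop_zero) r$values != 0 else rep(TRUE, length(r$values))
    if (!any(keep)) next
    recs[[chrom]] <- data.frame(chrom = chrom, start = start[keep],
                                end = end[keep], value = r$values[keep])
  }
  df <- if (length(recs)) do.call(rbind, recs) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               value = numeric())
  lines <- sprintf("%s\t%d\t%d\t%s", df$chrom, as.integer(df$start),
                   as.integer(df$end), format(df$value, trim = TRUE,
                                              scientific = FALSE))
  writeLines(lines, path)
  invisible(path)
}
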