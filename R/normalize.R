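#' Spike-in normalization factor
#'
#' The factor is the spike read share, spike / (endogenous + spike); tracks
#' are multiplied by its reciprocal (`scale`) so that conditions with equal
#' spike recovery end up on a common absolute scale.
#'
#' @param spike_reads Spike-in (e.g., SIRV) read count.
#' @param endogenous_reads Endogenous (e.g., human) read count.
#' @return A list of class `spike_normalization`: `spike_reads`,
#'   `endogenous_reads`, `factor`, `scale` (`= 1/factor`).
#' @export
spike_factor <- function(spike_reads, endogenous_reads) {
  if (spike_reads <= 0 || endogenous_reads <= 0)
    stop("spike and endogenous read counts must both be positive")
  f <- spike_reads / (endogenous_reads + spike_reads)
  structure(list(spike_reads = spike_reads,
                 endogenous_reads = endogenous_reads,
                 factor = f, scale = 1 / f),
            class = "spike_normalization")
}

#' @export
print.spike_normalization <- function(x, ...) {
  cat("spike normalization: factor ", signif(x$factor, 6),
      " (scale ", signif(x$scale, 6), ") from ", x$spike_reads,
      " spike / ", x$endogenous_reads, " endogenous reads\n", sep = "")
  invisible(x)
}

#' Apply spike-in scaling to a coverage track
#'
#' @param cov A raw `stranded_coverage`.
#' @param norm A `spike_normalization` from [spike_factor()].
#' @return The track multiplied by `norm$scale`, with
#'   `norm_state = "spike-scaled"`.
#' @export
apply_spike_scaling <- function(cov, norm) {
  stopifnot(inherits(norm, "spike_normalization"))
  scale_coverage(cov, norm$scale, "spike-scaled")
}

#' Library-size normalization of region counts
#'
#' @param counts Raw region read counts.
#' @param total_reads Library size (mapped reads).
#' @param per Reference depth (default 100 million).
#' @return `counts * per / total_reads`.
#' @export
library_normalize <- function(counts, total_reads, per = 1e8) {
  if (length(total_reads) != 1L || total_reads <= 0)
    stop("total_reads must be a single positive count")
  counts * per / total_reads
}

#' Subsampling fractions that equalize library depth
#'
#' Every sample is subsampled to the depth of the smallest library.
#'
#' @param totals Per-sample read totals (optionally named).
#' @return Keep fractions in (0, 1], `min(totals)/totals`.
#' @export
subsample_to_smallest <- function(totals) {
  if (any(totals <= 0)) stop("all library totals must be positive")
  min(totals) / totals
}

#' ChIP spike-in scaling factors from a peak quantification table
#'
#' Spike-chromatin peak densities (count per bp per library read) are
#' averaged over the retained (condition-overlapping) peaks; the factor for
#' the non-reference condition is density(ref)/density(other), the reference
#' being fixed at 1, so that multiplying the other condition's track by its
#' factor equalizes spike densities.
#'
#' @param peaks Data frame with columns `start`, `end`, `count_ref`,
#'   `count_other`, `libsize_ref`, `libsize_other` (one row per retained
#'   peak).
#' @return A list of class `chip_spike_factor`: per-condition `density` and
#'   `factor` (reference = 1).
#' @export
chip_spike_factor <- function(peaks) {
  need <- c("start", "end", "count_ref", "count_other",
            "libsize_ref", "libsize_other")
  if (!all(need %in% names(peaks)))
    stop("peak table must have columns: ", paste(need, collapse = ", "))
  if (!nrow(peaks)) stop("empty overlap peak set")
  len <- peaks$end - peaks$start
  if (any(len <= 0)) stop("peak with non-positive length")
  d_ref <- mean(peaks$count_ref / (len * peaks$libsize_ref))
  d_other <- mean(peaks$count_other / (len * peaks$libsize_other))
  if (d_other <= 0 || d_ref <= 0) stop("non-positive spike peak density")
  structure(list(density = c(ref = d_ref, other = d_other),
                 factor = c(ref = 1, other = d_ref / d_other)),
            class = "chip_spike_factor")
}

#' @export
print.chip_spike_factor <- function(x, ...) {
  cat("ChIP spike factors (reference = 1): other =",
      signif(x$factor[["other"]], 6), "\n")
  invisible(x)
}
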