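#' Binned replication (BrdU-IP / input) track
#'
#' Holds per-bin BrdU-IP counts `CB`, input counts `CI`, and the derived
#' quantities: totals-normalized `NB = CB/sum(CB)` and `NI = CI/sum(CI)`
#' (normalization totals are taken over all bins, before any masking),
#' enrichment `EB = NB/NI` on valid bins (input count at least
#' `min_input`), and optionally a smoothed enrichment.
#'
#' @param cb Integer-like vector of BrdU-IP counts per bin.
#' @param ci Input counts per bin, same length.
#' @param bin_width Bin width, bp.
#' @param chrom Chromosome name.
#' @return An object of class `brdu_track` with elements `cb`, `ci`,
#'   `bin_width`, `chrom` (derived fields are added by
#'   [brdu_enrichment()]).
#' @export
brdu_track <- function(cb, ci, bin_width = 1000, chrom = "chr") {
  if (length(cb) != length(ci)) stop("cb and ci must have equal length")
  if (any(cb < 0) || any(ci < 0)) stop("counts must be non-negative")
  structure(list(cb = as.numeric(cb), ci = as.numeric(ci),
                 bin_width = bin_width, chrom = chrom),
            class = "brdu_track")
}

#' @export
print.brdu_track <- function(x, ...) {
  cat("brdu_track: ", length(x$cb), " bins of ", x$bin_width, " bp",
      if (!is.null(x$eb)) sprintf(", %d valid (CI >= %d)",
                                  sum(x$valid), x$min_input), "\n", sep = "")
  invisible(x)
}

#' Bin reads by midpoint
#'
#' Each read contributes one count to the bin containing its midpoint
#' (`floor((start + end)/2)`) on a half-open grid,
#' bin index `floor(mid / bin_width)`.
#'
#' @param reads Data frame with `start`, `end` (0-based half-open bp).
#' @param bin_width Bin width, bp.
#' @param n_bins Number of bins (reads beyond the grid are an error).
#' @return Integer vector of per-bin counts summing to `nrow(reads)`.
#' @export
bin_read_centers <- function(reads, bin_width = 1000, n_bins) {
  mid <- floor((reads$start + reads$end) / 2)
  idx <- floor(mid / bin_width)
  if (any(mid < 0) || any(idx >= n_bins))
    stop("read outside chromosome bounds")
  tabulate(idx + 1L, nbins = n_bins)
}

#' BrdU enrichment with input filtering
#'
#' Bins whose input count is below `min_input` are masked. `NB` and `NI`
#' are computed from grand totals over all bins (masking applies only to
#' the enrichment), and `EB = NB/NI` on valid bins.
#'
#' @param track A [brdu_track()].
#' @param min_input Minimum input count for a valid bin.
#' @return The track with `nb`, `ni`, `valid`, `eb` (NA on masked bins) and
#'   `min_input` fields.
#' @export
brdu_enrichment <- function(track, min_input = 5) {
  stopifnot(inherits(track, "brdu_track"))
  if (sum(track$cb) <= 0 || sum(track$ci) <= 0)
    stop("both BrdU and input tracks need positive totals")
  valid <- track$ci >= min_input
  if (!any(valid)) stop("all bins fall below the input minimum")
  track$nb <- track$cb / sum(track$cb)
  track$ni <- track$ci / sum(track$ci)
  track$valid <- valid
  track$eb <- ifelse(valid & track$ni > 0, track$nb / track$ni, NA_real_)
  track$min_input <- min_input
  track
}

#' Moving-average smoothing over 2m + 1 bins
#'
#' Each bin becomes the mean of itself and the `m` bins on either side. At
#' track edges, and across masked (`NA`) bins, the mean is taken over the
#' available valid bins in the window (shrink-to-available, no padding);
#' windows with no valid bin stay `NA`.
#'
#' @param values Numeric vector (NA marks masked bins).
#' @param m Half-width in bins.
#' @return Smoothed vector of the same length.
#' @export
smooth_moving_average <- function(values, m = 10) {
  n <- length(values)
  ok <- !is.na(values)
  v <- ifelse(ok, values, 0)
  cs <- c(0, cumsum(v))
  ck <- c(0, cumsum(as.numeric(ok)))
  lo <- pmax(seq_len(n) - m, 1L)
  hi <- pmin(seq_len(n) + m, n)
  s <- cs[hi + 1L] - cs[lo]
  k <- ck[hi + 1L] - ck[lo]
  out <- ifelse(k > 0, s / k, NA_real_)
  out
}

#' Condition subtraction and delta-zone calling
#'
#' Computes the per-bin difference `a - b` and segments it into maximal
#' runs of bins strictly above `+background` (plus zones) or strictly below
#' `-background` (minus zones); bins with `|delta| <= background`, and
#' masked bins, are excluded as noise. Swapping the condition order swaps
#' the plus and minus zone sets exactly.
#'
#' @param a,b Numeric per-bin tracks on the same grid (e.g., smoothed
#'   enrichments); NA marks masked bins.
#' @param background Half-width of the excluded noise band, in the track's
#'   native units.
#' @param bin_width Bin width, bp (used to express zones in bp).
#' @return A list of class `delta_zones`: `delta`, `plus_zones` and
#'   `minus_zones` (data frames with bin and bp bounds), `background`,
#'   `bin_width`.
#' @export
subtract_conditions <- function(a, b, background = 10, bin_width = 1000) {
  if (length(a) != length(b)) stop("mismatched bin grids")
  delta <- a - b
  sign_code <- ifelse(is.na(delta), 0,
                      ifelse(delta > background, 1,
                             ifelse(delta < -background, -1, 0)))
  zones_of <- function(code) {
    r <- rle(sign_code == code)
    ends <- cumsum(r$lengths)
    starts <- c(1L, ends[-length(ends)] + 1L)
    keep <- r$values
    data.frame(start_bin = starts[keep], end_bin = ends[keep],
               start = (starts[keep] - 1L) * bin_width,
               end = ends[keep] * bin_width)
  }
  structure(list(delta = delta,
                 plus_zones = zones_of(1L),
                 minus_zones = zones_of(-1L),
                 background = background, bin_width = bin_width),
            class = "delta_zones")
}

#' @export
print.delta_zones <- function(x, ...) {
  cat("delta_zones: ", nrow(x$plus_zones), " plus / ",
      nrow(x$minus_zones), " minus zone(s), band +/-", x$background,
      "\n", sep = "")
  invisible(x)
}

#' Per-gene readthrough delta downstream of the TES
#'
#' Mean difference (perturbed minus control) of nascent signal over the
#' strand-aware window `[TES + offset[1], TES + offset[2])`.
#'
#' @param point_perturbed,point_control Spike-scaled `stranded_coverage`.
#' @param genes A gene table.
#' @param window Offsets from the TES, bp (default the 2.5-5 kb
#'   downstream-of-gene band).
#' @return Data frame: gene_id, chrom, win_start, win_end, delta.
#' @export
dog_delta_point <- function(point_perturbed, point_control, genes,
                            window = c(2500, 5000)) {
  n <- nrow(genes)
  delta <- ws <- we <- rep(NA_real_, n)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    g <- genes[i, ]
    tes <- gene_tes(g)
    if (g$strand == "+") {
      a <- tes + window[1]; b <- tes + window[2]
    } else {
      a <- tes - window[2]; b <- tes - window[1]
    }
    len <- point_control$chrom_lengths[[g$chrom]]
    if (a < 0 || b > len) { keep[i] <- FALSE; next }
    dp <- region_signal_mean(point_perturbed, g$chrom, g$strand, a, b)
    dc <- region_signal_mean(point_control, g$chrom, g$strand, a, b)
    delta[i] <- dp - dc
    ws[i] <- a; we[i] <- b
  }
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    win_start = ws, win_end = we, delta = delta,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratify per-gene windows by replication delta zones
#'
#' Each gene's downstream window is assigned to the group of the zone it
#' overlaps: `"plus"`, `"minus"`, or `"unassigned"` when it overlaps zones
#' of both signs or none.
#'
#' @param deltas Output of [dog_delta_point()].
#' @param zone_set A `delta_zones` from [subtract_conditions()].
#' @return `deltas` with a `group` column.
#' @export
stratify_by_zones <- function(deltas, zone_set) {
  overlaps_any <- function(a, b, z)
    nrow(z) > 0 && any(a < z$end & b > z$start)
  grp <- vapply(seq_len(nrow(deltas)), function(i) {
    a <- deltas$win_start[i]; b <- deltas$win_end[i]
    p <- overlaps_any(a, b, zone_set$plus_zones)
    m <- overlaps_any(a, b, zone_set$minus_zones)
    if (p && !m) "plus" else if (m && !p) "minus" else "unassigned"
  }, "")
  deltas$group <- grp
  deltas
}

#' Brunner-Munzel rank test of stochastic equality
#'
#' Tests whether P(X < Y) + 0.5 P(X = Y) differs from one half. The
#' estimator is computed from mid-ranks (ties get half weight); the
#' studentized statistic uses the rank-based variance estimates of Brunner
#' and Munzel with Welch-type degrees of freedom, and a two-sided p-value
#' from the t reference distribution.
#'
#' @param x,y Numeric samples (at least two values each).
#' @return An object of class `htest` with `estimate` (the stochastic
#'   superiority estimate), `statistic`, `parameter` (df) and `p.value`.
#' @export
brunner_munzel <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("both samples need at least 2 values")
  r <- rank(c(x, y))
  rx <- r[seq_len(n1)]; ry <- r[n1 + seq_len(n2)]
  mx <- mean(rx); my <- mean(ry)
  p_hat <- (my - (n2 + 1) / 2) / n1
  # rank-based variance estimates (mid-ranks handle ties with half weight)
  sx2 <- sum((rx - rank(x) - mx + (n1 + 1) / 2)^2) / (n1 - 1)
  sy2 <- sum((ry - rank(y) - my + (n2 + 1) / 2)^2) / (n2 - 1)
  var_term <- n1 * sx2 + n2 * sy2
  if (var_term <= 0)
    stop("degenerate variance: all pairwise comparisons identical; ",
         "use an exact or permutation test instead")
  stat <- n1 * n2 * (my - mx) / ((n1 + n2) * sqrt(var_term))
  df <- var_term^2 /
    ((n1 * sx2)^2 / (n1 - 1) + (n2 * sy2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(stat), df)
  structure(list(statistic = c(statistic = stat),
                 parameter = c(df = df),
                 p.value = p,
                 estimate = c("P(X<Y) + .5 P(X=Y)" = p_hat),
                 alternative = "two.sided",
                 method = "Brunner-Munzel test",
                 data.name = paste(deparse(substitute(x)), "and",
                                   deparse(substitute(y)))),
            class = "htest")
}
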