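#' Select genes suitable for inhibition-wave calling
#'
#' Retains genes longer than `min_length` whose read density over the
#' promoter-proximal interval `[TSS + 1 kb, TSS + 20 kb)` (strand-aware)
#' drops by strictly more than `min_reduction` upon treatment. Genes with
#' zero untreated proximal density are excluded with a flag.
#'
#' @param cov_untreated,cov_treated `stranded_coverage` on the same
#'   normalization footing.
#' @param genes A gene table.
#' @param min_length Strict minimum gene length, bp.
#' @param proximal_window Offsets from the TSS (bp) bounding the proximal
#'   interval.
#' @param min_reduction Strict minimum fractional density reduction.
#' @return The retained subset of `genes`, with a `wave_filter` attribute
#'   data frame recording per-gene length, reduction and pass flags.
#' @export
filter_wave_genes <- function(cov_untreated, cov_treated, genes,
                              min_length = 60000,
                              proximal_window = c(1000, 20000),
                              min_reduction = 0.70) {
  n <- nrow(genes)
  red <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    g <- genes[i, ]
    if (g$strand == "+") {
      a <- g$start + proximal_window[1]; b <- g$start + proximal_window[2]
    } else {
      a <- g$end - proximal_window[2]; b <- g$end - proximal_window[1]
    }
    d0 <- region_signal_mean(cov_untreated, g$chrom, g$strand, a, b)
    d1 <- region_signal_mean(cov_treated, g$chrom, g$strand, a, b)
    red[i] <- if (d0 > 0) 1 - d1 / d0 else NA_real_
  }
  len_ok <- gene_length(genes) > min_length
  red_ok <- !is.na(red) & red > min_reduction
  flags <- data.frame(gene_id = genes$gene_id,
                      length = gene_length(genes),
                      reduction = red,
                      length_pass = len_ok, reduction_pass = red_ok)
  out <- genes[len_ok & red_ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "wave_filter") <- flags
  out
}

# exhaustive two-segment least-squares breakpoint on cumulative sums, O(n);
# returns 0-based breakpoint index k (segments [1..k], [k+1..n]) and RSS gain
best_breakpoint <- function(v) {
  n <- length(v)
  cs <- cumsum(v)
  cs2 <- cumsum(v^2)
  k <- seq_len(n - 1L)
  s1 <- cs[k]; s2 <- cs[n] - cs[k]
  # RSS = sum(v^2) - s1^2/k - s2^2/(n-k); only the subtracted part varies
  gain <- s1^2 / k + s2^2 / (n - k)
  gmax <- max(gain)
  # near-ties are re-scored with the direct residual formula so that exact
  # ties (common on integer-valued tracks) resolve identically to an
  # exhaustive scan: smallest breakpoint with minimal RSS
  cand <- which(gain >= gmax - 1e-8 * max(abs(gmax), 1))
  if (length(cand) > 1L) {
    rss <- vapply(cand, function(kk) {
      a <- v[seq_len(kk)]; b <- v[(kk + 1L):n]
      sum((a - mean(a))^2) + sum((b - mean(b))^2)
    }, numeric(1))
    kbest <- cand[which.min(rss)]
    rss1 <- min(rss)
  } else {
    kbest <- cand
    rss1 <- cs2[n] - gain[kbest]
  }
  rss0 <- cs2[n] - cs[n]^2 / n
  list(k = kbest, rss_single = rss0, rss_split = rss1)
}

#' Call the inhibition-wave transition point of one gene
#'
#' Fits a two-segment piecewise-constant model to the treated coverage
#' binned at `bin_width` from TSS to TES (strand-aware, 5' to 3') by
#' exhaustive least-squares scan over all candidate breakpoints, with ties
#' broken toward the smallest position. The front position is the distance
#' of the breakpoint from the TSS. Degenerate fits (no residual improvement
#' over a single segment) and fits at either extreme candidate are flagged
#' as uncalled.
#'
#' @param cov_treated A `stranded_coverage` of the treated time point.
#' @param gene One-row gene table.
#' @param bin_width Calling resolution, bp.
#' @return A list: `front_position` (bp from TSS, `NA` if uncalled),
#'   `called`, `reason` (`"ok"`, `"degenerate"` or `"extreme"`).
#' @export
call_transition_point <- function(cov_treated, gene, bin_width = 1000) {
  len <- gene_length(gene)
  n <- floor(len / bin_width)
  if (n < 4L) stop("fewer than 4 bins: gene too short for calling")
  # per-bin means in transcription order
  v <- vapply(seq_len(n), function(j) {
    if (gene$strand == "+") {
      a <- gene$start + (j - 1) * bin_width
    } else {
      a <- gene$end - j * bin_width
    }
    region_signal_mean(cov_treated, gene$chrom, gene$strand, a, a + bin_width)
  }, numeric(1))
  bp <- best_breakpoint(v)
  tol <- 1e-12 * max(bp$rss_single, 1)
  if (bp$rss_single - bp$rss_split <= tol)
    return(list(front_position = NA_real_, called = FALSE,
                reason = "degenerate"))
  if (bp$k == 1L || bp$k == n - 1L)
    return(list(front_position = NA_real_, called = FALSE,
                reason = "extreme"))
  list(front_position = bp$k * bin_width, called = TRUE, reason = "ok")
}

#' Call transition points for a gene set
#'
#' @param cov_treated Treated `stranded_coverage`.
#' @param genes A gene table (typically from [filter_wave_genes()]).
#' @param bin_width Calling resolution, bp.
#' @return Data frame: gene_id, front_position, called, reason.
#' @export
call_transition_points <- function(cov_treated, genes, bin_width = 1000) {
  calls <- lapply(seq_len(nrow(genes)), function(i)
    call_transition_point(cov_treated, genes[i, ], bin_width))
  data.frame(gene_id = genes$gene_id,
             front_position = vapply(calls, `[[`, 0, "front_position"),
             called = vapply(calls, `[[`, TRUE, "called"),
             reason = vapply(calls, `[[`, "", "reason"),
             stringsAsFactors = FALSE)
}

#' Elongation rate from a called front
#'
#' @param front_position Front distance from TSS, bp (may be a vector).
#' @param treatment_minutes Treatment duration, minutes.
#' @return Rate in kb/min; 0-bp fronts give rate 0.
#' @export
estimate_rate <- function(front_position, treatment_minutes) {
  if (treatment_minutes <= 0) stop("treatment_minutes must be positive")
  front_position / 1000 / treatment_minutes
}

#' Replicate-consistent transition calls
#'
#' Keeps genes whose called front positions in two replicates differ by at
#' most `max_discrepancy` bp; genes missing or uncalled in either replicate
#' are dropped.
#'
#' @param calls_rep1,calls_rep2 Outputs of [call_transition_points()].
#' @param max_discrepancy Tolerance, bp.
#' @return Data frame of retained genes: gene_id, front_rep1, front_rep2,
#'   front_mean, discrepancy.
#' @export
replicate_consistency <- function(calls_rep1, calls_rep2,
                                  max_discrepancy = 2000) {
  m <- merge(calls_rep1[calls_rep1$called, c("gene_id", "front_position")],
             calls_rep2[calls_rep2$called, c("gene_id", "front_position")],
             by = "gene_id", suffixes = c("_rep1", "_rep2"))
  m$discrepancy <- abs(m$front_position_rep1 - m$front_position_rep2)
  m <- m[m$discrepancy <= max_discrepancy, , drop = FALSE]
  m$front_mean <- (m$front_position_rep1 + m$front_position_rep2) / 2
  rownames(m) <- NULL
  m
}
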