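#' Simulation scenario
#'
#' A `sim_scenario` bundles every parameter of the synthetic-data generator
#' and a seed, so that each generator is a pure function of
#' (scenario, condition): the same scenario always yields byte-identical
#' output. The generator emulates strand-specific nascent coverage with a
#' promoter pause peak, a uniform gene-body plateau and a post-TES decay;
#' a perturbed condition in which a known subset of genes reads through the
#' termination site as a plateau of `readthrough_amplitude` times the body
#' density over `readthrough_extension` bp; CDK9-inhibition waves advancing
#' at `elongation_rate_v` kb/min; junction reads with a planted spliced
#' fraction; intergenic replication-initiation zones at controlled distances
#' from gene ends; and 1-kb binned BrdU-IP/input counts with alternating
#' early/late replication domains.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_genes Number of genes to place.
#' @param gene_length Gene length in bp (constant across genes).
#' @param gap_range Range (bp) of intergenic gaps between consecutive genes.
#' @param bin_width Coverage bin width in bp.
#' @param pause_height Promoter pause peak height, fold over body density.
#' @param pause_width Width of the pause peak window at the TSS, bp.
#' @param body_density Expected gene-body signal, reads per bp.
#' @param background_density Uniform intergenic background, reads per bp.
#' @param dog_decay_length Exponential decay length of post-TES signal, bp.
#' @param dog_decay_cutoff Distance past which post-TES decay is truncated
#'   to zero, bp.
#' @param readthrough_extension Length of the readthrough plateau planted in
#'   the perturbed condition, bp.
#' @param readthrough_amplitude Plateau height as a fraction of body density.
#' @param planted_fraction Fraction of genes given the readthrough defect in
#'   the perturbed condition.
#' @param elongation_rate_v Elongation rate in kb/min for inhibition waves.
#' @param nvp2_times Treated time points, minutes.
#' @param residual_fraction Residual signal fraction behind the wave front.
#' @param spike_fraction Fraction of total reads from the spike-in set.
#' @param spliced_fraction Probability that a junction read is spliced.
#' @param n_junction_reads Junction reads to simulate in total.
#' @param read_length Simulated read length, bp.
#' @param ri_gap_near Range (bp) of TES-to-zone gaps for zones planted
#'   inside readthrough reach; zones beyond reach are placed so that they
#'   clear the readthrough plateau plus decay cutoff of both genes flanking
#'   the intergenic gap.
#' @param ri_gap_fixed If not `NULL`, place every zone at exactly this gap.
#' @param ri_width_range Zone width range, bp.
#' @param ri_score_meanlog,ri_score_sdlog Log-normal RI score parameters.
#' @param replication_domain_length Length of alternating early/late
#'   replication domains, bp.
#' @param early_weight Fold enrichment of BrdU incorporation in early
#'   domains over late domains.
#' @param ci_mean,cb_mean Mean input and BrdU-IP counts per 1-kb bin.
#' @param brdu_attenuation Multiplier on perturbed-condition BrdU counts in
#'   bins downstream of readthrough-defective genes.
#' @param brdu_late_boost Multiplier on perturbed-condition BrdU counts in
#'   late-domain bins.
#' @param conflict_window Length (bp) of the downstream-of-TES region whose
#'   replication is attenuated in the perturbed condition.
#' @param noise_model `"poisson"` for count noise, `"none"` for exact
#'   expected values (closed-form tests).
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(seed = 1L,
                         n_genes = 20L,
                         gene_length = 100000,
                         gap_range = c(32000, 45000),
                         bin_width = 100,
                         pause_height = 10,
                         pause_width = 250,
                         body_density = 0.5,
                         background_density = 0.005,
                         dog_decay_length = 500,
                         dog_decay_cutoff = 3000,
                         readthrough_extension = 10000,
                         readthrough_amplitude = 0.5,
                         planted_fraction = 0.5,
                         elongation_rate_v = 2,
                         nvp2_times = 30,
                         residual_fraction = 0.1,
                         spike_fraction = 0.1,
                         spliced_fraction = 0.7,
                         n_junction_reads = 10000L,
                         read_length = 100,
                         ri_gap_near = c(500, 2000),
                         ri_gap_fixed = NULL,
                         ri_width_range = c(2000, 4000),
                         ri_score_meanlog = log(20),
                         ri_score_sdlog = 1,
                         replication_domain_length = 100000,
                         early_weight = 3,
                         ci_mean = 50,
                         cb_mean = 50,
                         brdu_attenuation = 0.4,
                         brdu_late_boost = 1.5,
                         conflict_window = 20000,
                         noise_model = c("poisson", "none")) {
  noise_model <- match.arg(noise_model)
  sc <- as.list(environment())
  fracs <- c(readthrough_amplitude = readthrough_amplitude,
             planted_fraction = planted_fraction,
             residual_fraction = residual_fraction,
             spike_fraction = spike_fraction,
             spliced_fraction = spliced_fraction)
  if (any(fracs < 0 | fracs > 1))
    stop("fractions must lie in [0, 1]: ",
         paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", "))
  if (elongation_rate_v <= 0 || body_density <= 0 || bin_width <= 0)
    stop("rates, densities and bin widths must be positive")
  structure(sc, class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("sim_scenario: seed ", x$seed, ", ", x$n_genes, " genes of ",
      x$gene_length, " bp, noise '", x$noise_model, "'\n", sep = "")
  cat("  readthrough: amplitude ", x$readthrough_amplitude, " over ",
      x$readthrough_extension, " bp in ",
      round(100 * x$planted_fraction), "% of genes\n", sep = "")
  cat("  elongation: ", x$elongation_rate_v, " kb/min at t = ",
      paste(x$nvp2_times, collapse = ", "), " min\n", sep = "")
  invisible(x)
}

# Evaluate code under a derived seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

scenario_chrom <- "chrS"

# add `value` per-bp over genomic [a, b) to a per-bin density vector,
# length-weighted on partial bins; touches only the overlapped bins
add_density <- function(lambda, a, b, value, bin_width, chrom_len) {
  a <- max(a, 0); b <- min(b, chrom_len)
  if (b <= a) return(lambda)
  i0 <- floor(a / bin_width); i1 <- floor((b - 1) / bin_width)
  bs <- (i0:i1) * bin_width
  ext <- pmin(bin_width, chrom_len - bs)
  lo <- pmax(bs, a); hi <- pmin(bs + bin_width, b)
  idx <- (i0:i1) + 1L
  lambda[idx] <- lambda[idx] + value * (hi - lo) / ext
  lambda
}

#' Simulate a gene annotation and replication-initiation zones
#'
#' Genes of fixed length are laid out on one chromosome with intergenic gaps
#' drawn from `gap_range`, alternating strands. A deterministic
#' `planted_fraction` of genes carries the readthrough defect (column
#' `planted`). One intergenic RI zone is placed downstream of each gene's
#' TES, either within readthrough reach (`ri_gap_near`, fully inside the
#' would-be readthrough plateau) or beyond it, each with probability one
#' half. Because alternating strands make consecutive TESs face shared
#' (convergent) intergenic gaps, beyond-reach zones are placed to clear the
#' readthrough plateau plus decay cutoff of *both* flanking genes, so the
#' `planted_invaded` tag (near zone of a defect-carrying gene) is exact
#' ground truth for invasion. Scores are drawn log-normally.
#'
#' @param scenario A [sim_scenario()].
#' @return A list with elements `genes` (gene table with `planted` column),
#'   `zones` (data frame: chrom, start, end, name, score, gene_id, gap,
#'   planted_invaded) and `chrom_lengths`.
#' @export
simulate_genome <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  with_seed(scenario$seed, {
    n <- scenario$n_genes
    bw <- scenario$bin_width
    # genes snapped to the coverage bin grid so noise-free profiles are
    # exactly piecewise-constant on bins
    gaps <- floor(stats::runif(n + 1L, scenario$gap_range[1],
                               scenario$gap_range[2] + 1) / bw) * bw
    glen <- rep(floor(scenario$gene_length / bw) * bw, n)
    start <- cumsum(gaps[seq_len(n)]) + cumsum(c(0, glen[-n]))
    end <- start + glen
    chrom_len <- end[n] + gaps[n + 1L]
    clear <- scenario$readthrough_extension + scenario$dog_decay_cutoff
    if (is.null(scenario$ri_gap_fixed) &&
        scenario$gap_range[1] < 2 * clear + scenario$ri_width_range[2] + 500)
      stop("infeasible packing: intergenic gaps too small to place ",
           "replication zones clear of readthrough reach")
    strand <- rep(c("+", "-"), length.out = n)
    planted <- seq_len(n) <= round(scenario$planted_fraction * n)
    genes <- new_gene_table(sprintf("g%03d", seq_len(n)), scenario_chrom,
                            strand, start, end,
                            exons = make_exon_blocks(start, end),
                            expression = rep(100, n))
    genes$planted <- planted

    near <- stats::runif(n) < 0.5
    width <- floor(stats::runif(n, scenario$ri_width_range[1],
                                scenario$ri_width_range[2]))
    # the convergent intergenic gap this gene's TES faces
    conv_gap <- ifelse(strand == "+", gaps[seq_len(n) + 1L], gaps[seq_len(n)])
    if (!is.null(scenario$ri_gap_fixed)) {
      gap <- rep(scenario$ri_gap_fixed, n)
    } else {
      far_lo <- rep(clear, n)
      far_hi <- conv_gap - clear - width
      gap <- ifelse(near,
                    floor(stats::runif(n, scenario$ri_gap_near[1],
                                       scenario$ri_gap_near[2])),
                    floor(far_lo + stats::runif(n) * (far_hi - far_lo)))
    }
    tes <- gene_tes(genes)
    zstart <- ifelse(strand == "+", tes + gap, tes - gap - width)
    zend <- zstart + width
    score <- stats::rlnorm(n, scenario$ri_score_meanlog,
                           scenario$ri_score_sdlog)
    reach <- gap + width <= scenario$readthrough_extension
    zones <- data.frame(chrom = scenario_chrom, start = zstart, end = zend,
                        name = sprintf("z%03d", seq_len(n)),
                        score = score, gene_id = genes$gene_id,
                        gap = gap,
                        planted_invaded = planted & reach,
                        stringsAsFactors = FALSE)
    zones <- zones[zones$start >= 0 & zones$end <= chrom_len, , drop = FALSE]
    zones <- zones[order(zones$start), , drop = FALSE]
    rownames(zones) <- NULL
    list(genes = genes, zones = zones,
         chrom_lengths = stats::setNames(chrom_len, scenario_chrom))
  })
}

# two exons separated by a central intron (for junction-read simulation)
make_exon_blocks <- function(start, end) {
  Map(function(s, e) {
    l <- e - s
    e1 <- floor(l * 0.3)
    i <- floor(l * 0.4)
    cbind(start = c(s, s + e1 + i), end = c(s + e1, e))
  }, start, end)
}

# expected sense-strand signal (reads/bp) for one gene over chromosome bins
gene_profile <- function(bins_start, bin_width, chrom_len, gene, scenario,
                         readthrough) {
  lambda <- numeric(length(bins_start))
  add_interval <- function(lambda, a, b, value)
    add_density(lambda, a, b, value, bin_width, chrom_len)
  s <- gene$start; e <- gene$end
  bd <- scenario$body_density
  lambda <- add_interval(lambda, s, e, bd)
  if (gene$strand == "+") {
    pw <- c(s, s + scenario$pause_width)
  } else {
    pw <- c(e - scenario$pause_width, e)
  }
  lambda <- add_interval(lambda, pw[1], pw[2], (scenario$pause_height - 1) * bd)
  # downstream-of-gene signal: plateau (if readthrough) then truncated decay
  dog0 <- if (readthrough) scenario$readthrough_extension else 0
  amp <- if (readthrough) scenario$readthrough_amplitude * bd else bd
  if (readthrough) {
    if (gene$strand == "+") {
      lambda <- add_interval(lambda, e, e + dog0, amp)
    } else {
      lambda <- add_interval(lambda, s - dog0, s, amp)
    }
  }
  # decay sampled at bin resolution from the plateau end
  L <- scenario$dog_decay_length
  cutoff <- scenario$dog_decay_cutoff
  nd <- ceiling(cutoff / bin_width)
  d <- (seq_len(nd) - 0.5) * bin_width
  dec <- amp * exp(-d / L)
  dec[d > cutoff] <- 0
  for (k in seq_len(nd)) {
    if (gene$strand == "+") {
      a <- e + dog0 + (k - 1) * bin_width
      lambda <- add_interval(lambda, a, a + bin_width, dec[k])
    } else {
      a <- s - dog0 - k * bin_width
      lambda <- add_interval(lambda, a, a + bin_width, dec[k])
    }
  }
  lambda
}

# materialize per-bin expected densities into observed values per noise model
observe <- function(lambda, extents, noise_model) {
  if (noise_model == "none") return(lambda)
  stats::rpois(length(lambda), lambda * extents) / extents
}

#' Simulate nascent (POINT-seq-like) coverage
#'
#' Control genes carry a pause peak, a uniform body and a truncated
#' exponential post-TES decay; in the perturbed condition, genes with
#' `planted = TRUE` additionally read through the TES as a plateau of
#' `readthrough_amplitude` x body density over `readthrough_extension` bp
#' before decaying. A uniform both-strand background is added everywhere.
#' Poisson noise (per bin, mean = density x bin extent) is applied unless
#' the scenario's noise model is `"none"`. Spike-in and endogenous read
#' tallies consistent with `spike_fraction` are returned alongside.
#'
#' @param genome Output of [simulate_genome()].
#' @param scenario The [sim_scenario()].
#' @param condition `"control"` or `"perturbed"`.
#' @return A list: `coverage` (raw `stranded_coverage`), `spike_reads`,
#'   `endogenous_reads`.
#' @export
simulate_point_coverage <- function(genome, scenario,
                                    condition = c("control", "perturbed")) {
  condition <- match.arg(condition)
  genes <- genome$genes
  chrom_len <- genome$chrom_lengths[[scenario_chrom]]
  cov <- stranded_coverage(scenario$bin_width, genome$chrom_lengths)
  bins_start <- (seq_along(cov$values[[scenario_chrom]][["+"]]) - 1) *
    scenario$bin_width
  ext <- bin_extents(cov, scenario_chrom)
  lam <- list(`+` = rep(scenario$background_density, length(bins_start)),
              `-` = rep(scenario$background_density, length(bins_start)))
  planted <- if (!is.null(genes$planted)) genes$planted else
    rep(TRUE, nrow(genes))
  for (i in seq_len(nrow(genes))) {
    rt <- condition == "perturbed" && planted[i]
    lam[[genes$strand[i]]] <- lam[[genes$strand[i]]] +
      gene_profile(bins_start, scenario$bin_width, chrom_len,
                   genes[i, ], scenario, rt) -
      0  # background already included once
  }
  seed_off <- if (condition == "control") 101L else 102L
  with_seed(scenario$seed + seed_off, {
    for (strand in c("+", "-"))
      cov <- set_track(cov, scenario_chrom, strand,
                       observe(lam[[strand]], ext, scenario$noise_model))
    mass <- sum((cov$values[[scenario_chrom]][["+"]] +
                   cov$values[[scenario_chrom]][["-"]]) * ext)
    endo <- max(1L, round(mass))
    sf <- scenario$spike_fraction
    spike_mean <- endo * sf / (1 - sf)
    spike <- if (scenario$noise_model == "none") max(1L, round(spike_mean))
      else max(1L, stats::rpois(1L, spike_mean))
    list(coverage = cov, spike_reads = spike, endogenous_reads = endo)
  })
}

#' Simulate a CDK9-inhibition (NVP-2) time course
#'
#' The untreated track is the uniform gene body (plus background). At a
#' treated time point `t`, signal within `[TSS, TSS + v t]` (strand-aware)
#' is suppressed to `residual_fraction` of the body density and left intact
#' beyond, modeling the clearing wave behind inhibited promoters. The true
#' front position per gene and time, `min(v t, gene length)`, is recorded.
#'
#' @param genome Output of [simulate_genome()].
#' @param scenario The [sim_scenario()]; uses `elongation_rate_v` (kb/min)
#'   and `nvp2_times` (minutes).
#' @return A list: `untreated` (`stranded_coverage`), `treated` (named list
#'   of `stranded_coverage`, one per time point), `truth` (data frame
#'   gene_id, time_min, front_bp).
#' @export
simulate_tt_timecourse <- function(genome, scenario) {
  genes <- genome$genes
  chrom_len <- genome$chrom_lengths[[scenario_chrom]]
  bw <- scenario$bin_width
  n_bins <- ceiling(chrom_len / bw)
  bins_start <- (seq_len(n_bins) - 1) * bw
  base <- list(`+` = rep(scenario$background_density, n_bins),
               `-` = rep(scenario$background_density, n_bins))
  add_body <- function(lam, gene, a, b, value)
    add_density(lam, a, b, value, bw, chrom_len)
  for (i in seq_len(nrow(genes)))
    base[[genes$strand[i]]] <- add_body(base[[genes$strand[i]]], genes[i, ],
                                        genes$start[i], genes$end[i],
                                        scenario$body_density)
  make_cov <- function(lam, seed_off) {
    cov <- stranded_coverage(bw, genome$chrom_lengths)
    ext <- bin_extents(cov, scenario_chrom)
    with_seed(scenario$seed + seed_off, {
      for (strand in c("+", "-"))
        cov <- set_track(cov, scenario_chrom, strand,
                         observe(lam[[strand]], ext, scenario$noise_model))
      cov
    })
  }
  untreated <- make_cov(base, 201L)
  treated <- list()
  truth <- NULL
  for (ti in seq_along(scenario$nvp2_times)) {
    t_min <- scenario$nvp2_times[ti]
    lam <- base
    fronts <- numeric(nrow(genes))
    depth <- scenario$elongation_rate_v * 1000 * t_min
    for (i in seq_len(nrow(genes))) {
      front <- min(depth, gene_length(genes[i, ]))
      fronts[i] <- front
      # subtract the suppressed share over the cleared interval
      cut <- (1 - scenario$residual_fraction) * scenario$body_density
      if (genes$strand[i] == "+") {
        a <- genes$start[i]; b <- genes$start[i] + front
      } else {
        a <- genes$end[i] - front; b <- genes$end[i]
      }
      lam[[genes$strand[i]]] <- add_body(lam[[genes$strand[i]]], genes[i, ],
                                         a, b, -cut)
    }
    treated[[sprintf("t%g", t_min)]] <- make_cov(lam, 201L + ti)
    truth <- rbind(truth, data.frame(gene_id = genes$gene_id,
                                     time_min = t_min, front_bp = fronts))
  }
  list(untreated = untreated, treated = treated, truth = truth)
}

#' Simulate junction-spanning reads with planted spliced fraction
#'
#' Reads are placed across exon-exon junctions; each is spliced (carries two
#' blocks flanking the intron, i.e., a gapped alignment) with probability
#' `spliced_fraction`, otherwise it runs contiguously from the exon into the
#' intron. With noise model `"none"` the spliced count per junction is the
#' deterministic rounded expectation (enumeration mode), making the pooled
#' efficiency exact.
#'
#' @param genome Output of [simulate_genome()].
#' @param scenario The [sim_scenario()].
#' @return A data frame of read records: read_id, chrom, strand, start, end,
#'   blocks (`"s-e,s-e"` string), gapped, gene_id.
#' @export
simulate_junction_reads <- function(genome, scenario) {
  genes <- genome$genes
  multi <- vapply(genes$exons, nrow, 0L) >= 2L
  if (!any(multi)) {
    warning("no genes with >= 2 exons; no junction reads simulated")
    return(data.frame())
  }
  if (any(!multi))
    warning(sum(!multi), " single-exon gene(s) skipped for junction reads")
  genes <- genes[multi, , drop = FALSE]
  n <- scenario$n_junction_reads
  rl <- scenario$read_length
  with_seed(scenario$seed + 301L, {
    gi <- sort(rep_len(seq_len(nrow(genes)), n))
    per_gene <- tabulate(gi, nbins = nrow(genes))
    out <- vector("list", nrow(genes))
    for (g in seq_len(nrow(genes))) {
      m <- per_gene[g]
      if (!m) next
      ex <- genes$exons[[g]]
      # first junction in transcription order (strand-aware)
      j <- if (genes$strand[g] == "+") 1L else nrow(ex) - 1L
      don_end <- ex[j, "end"]      # genomic end of upstream-exon block
      acc_start <- ex[j + 1L, "start"]
      a <- pmin(pmax(floor(stats::runif(m, 10, rl - 10)), 10), rl - 10)
      gapped <- if (scenario$noise_model == "none") {
        seq_len(m) <= round(scenario$spliced_fraction * m)
      } else {
        stats::runif(m) < scenario$spliced_fraction
      }
      b <- rl - a
      start <- ifelse(gapped, don_end - a, don_end - a)
      end <- ifelse(gapped, acc_start + b, don_end + b)
      blocks <- ifelse(
        gapped,
        sprintf("%d-%d,%d-%d", as.integer(don_end - a), as.integer(don_end),
                as.integer(acc_start), as.integer(acc_start + b)),
        sprintf("%d-%d", as.integer(start), as.integer(end)))
      out[[g]] <- data.frame(chrom = genes$chrom[g],
                             strand = genes$strand[g],
                             start = start, end = end, blocks = blocks,
                             gapped = gapped, gene_id = genes$gene_id[g],
                             stringsAsFactors = FALSE)
    }
    reads <- do.call(rbind, out)
    reads <- cbind(read_id = sprintf("r%06d", seq_len(nrow(reads))), reads)
    rownames(reads) <- NULL
    reads
  })
}

#' Simulate 1-kb binned BrdU-IP and input counts
#'
#' Input counts are uniform with mean `ci_mean`. BrdU-IP counts follow
#' alternating early/late replication domains (early domains enriched
#' `early_weight`-fold). In the perturbed condition, bins within
#' `conflict_window` bp downstream of readthrough-defective (planted) genes
#' have their BrdU counts multiplied by `brdu_attenuation` (replication
#' suppressed by invading polymerase) and late-domain bins by
#' `brdu_late_boost` (compensatory late firing).
#'
#' @param genome Output of [simulate_genome()].
#' @param scenario The [sim_scenario()].
#' @param condition `"control"` or `"perturbed"`.
#' @param bin_width Bin width in bp (1 kb by convention).
#' @return A `brdu_track` (see [brdu_track()]) with the true per-bin labels
#'   attached as attributes `domain` (early/late) and `conflict` (logical).
#' @export
simulate_brdu_counts <- function(genome, scenario,
                                 condition = c("control", "perturbed"),
                                 bin_width = 1000) {
  condition <- match.arg(condition)
  chrom_len <- genome$chrom_lengths[[scenario_chrom]]
  n <- ceiling(chrom_len / bin_width)
  mid <- (seq_len(n) - 0.5) * bin_width
  early <- (floor(mid / scenario$replication_domain_length) %% 2) == 0
  cb_mu <- ifelse(early, scenario$early_weight, 1) * scenario$cb_mean
  ci_mu <- rep(scenario$ci_mean, n)
  conflict <- rep(FALSE, n)
  genes <- genome$genes
  planted <- if (!is.null(genes$planted)) genes$planted else
    rep(TRUE, nrow(genes))
  for (i in which(planted)) {
    tes <- gene_tes(genes[i, ])
    if (genes$strand[i] == "+") {
      a <- tes; b <- tes + scenario$conflict_window
    } else {
      a <- tes - scenario$conflict_window; b <- tes
    }
    conflict <- conflict | (mid >= a & mid < b)
  }
  if (condition == "perturbed") {
    cb_mu[conflict] <- cb_mu[conflict] * scenario$brdu_attenuation
    cb_mu[!early] <- cb_mu[!early] * scenario$brdu_late_boost
  }
  seed_off <- if (condition == "control") 401L else 402L
  with_seed(scenario$seed + seed_off, {
    if (scenario$noise_model == "none") {
      cb <- cb_mu; ci <- ci_mu
    } else {
      cb <- stats::rpois(n, cb_mu); ci <- stats::rpois(n, ci_mu)
    }
    tr <- brdu_track(cb, ci, bin_width = bin_width, chrom = scenario_chrom)
    attr(tr, "domain") <- ifelse(early, "early", "late")
    attr(tr, "conflict") <- conflict
    tr
  })
}

#' Expected termination-index shift of the planted readthrough defect
#'
#' Closed-form expected control and perturbed downstream-of-gene densities
#' under the scenario's profile (truncated exponential decay vs readthrough
#' plateau), giving the expected difference in termination index for a
#' planted gene. Useful for setting a recovery classification threshold at
#' a stated fraction of the known effect size.
#'
#' @param scenario A [sim_scenario()].
#' @param dog_length Downstream window length, bp.
#' @return A list: `dog_control`, `dog_perturbed` (reads/bp) and `delta_ti`.
#' @export
expected_delta_ti <- function(scenario, dog_length = 2500) {
  L <- scenario$dog_decay_length
  bd <- scenario$body_density
  cutoff <- min(scenario$dog_decay_cutoff, dog_length)
  decay_mass <- bd * L * (1 - exp(-cutoff / L))
  dog_c <- decay_mass / dog_length + scenario$background_density
  amp <- scenario$readthrough_amplitude * bd
  ext <- scenario$readthrough_extension
  if (ext >= dog_length) {
    dog_p <- amp + scenario$background_density
  } else {
    tail_cut <- min(scenario$dog_decay_cutoff, dog_length - ext)
    dog_p <- (amp * ext + amp * L * (1 - exp(-tail_cut / L))) / dog_length +
      scenario$background_density
  }
  list(dog_control = dog_c, dog_perturbed = dog_p,
       delta_ti = log2(dog_p / dog_c))
}
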