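#' Run configuration
#'
#' All thresholds of the pipeline in one validated list, with defaults at
#' the conventional analysis values: 2.5-kb termination window, log2(1.25)
#' zone cutoff, input minimum 5, smoothing half-width 10, +/-10 noise band,
#' 60-kb / 70%-reduction wave filters. Round-trips losslessly through YAML.
#'
#' @param seed Integer seed for the simulation scenario.
#' @param outdir Output directory for [run_pipeline()].
#' @param dog_length Termination-region length, bp.
#' @param pa_cutoff_log2 Zone classification cutoff, log2 units.
#' @param min_input Minimum input count per valid replication bin.
#' @param smoothing_m Moving-average half-width, bins.
#' @param background_band Excluded half-band on the replication delta
#'   track.
#' @param wave_min_length,wave_min_reduction,wave_proximal_window
#'   Inhibition-wave gene filters (bp, fraction, bp offsets from TSS).
#' @param rate_bin_width Transition-calling resolution, bp.
#' @param delta_ti_fraction Fraction of the expected planted TI shift used
#'   as the NDT classification threshold.
#' @param scenario Named list of [sim_scenario()] overrides.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, outdir = "polterm_out",
                       dog_length = 2500,
                       pa_cutoff_log2 = log2(1.25),
                       min_input = 5,
                       smoothing_m = 10,
                       background_band = 10,
                       wave_min_length = 60000,
                       wave_min_reduction = 0.70,
                       wave_proximal_window = c(1000, 20000),
                       rate_bin_width = 1000,
                       delta_ti_fraction = 0.5,
                       scenario = list()) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(cfg$seed)
  num <- c("dog_length", "pa_cutoff_log2", "min_input", "smoothing_m",
           "background_band", "wave_min_length", "wave_min_reduction",
           "wave_proximal_window", "rate_bin_width", "delta_ti_fraction")
  for (f in num) cfg[[f]] <- as.numeric(cfg[[f]])
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  pos <- c("dog_length", "min_input", "smoothing_m", "background_band",
           "wave_min_length", "rate_bin_width")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop("config field '", f, "' must be positive")
  if (!is.null(cfg$scenario$bin_width) && cfg$scenario$bin_width <= 0)
    stop("config field 'scenario$bin_width' must be positive")
  if (cfg$wave_min_reduction < 0 || cfg$wave_min_reduction > 1)
    stop("wave_min_reduction must lie in [0, 1]")
  invisible(cfg)
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @return For `read_run_config`, a `run_config`; for `write_run_config`,
#'   `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param cfg A `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15L)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic pipeline
#'
#' Executes simulate, normalize, metrics, zones, rate and brdu stages (or a
#' subset) on the configured scenario, writing one TSV/BED per result plus
#' a manifest recording the seed, thresholds and stage outputs. Identical
#' configurations (including seed) produce byte-identical outputs.
#'
#' @param cfg A [run_config()].
#' @param stages Character subset of
#'   `c("simulate", "normalize", "metrics", "zones", "rate", "brdu")`.
#' @return Invisibly, a list of result objects per stage (also written
#'   under `cfg$outdir`).
#' @export
run_pipeline <- function(cfg, stages = c("simulate", "normalize", "metrics",
                                         "zones", "rate", "brdu")) {
  stopifnot(inherits(cfg, "run_config"))
  all_stages <- c("simulate", "normalize", "metrics", "zones", "rate", "brdu")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- c(sprintf("polterm %s", as.character(utils::packageVersion("polterm"))),
                sprintf("seed\t%d", cfg$seed),
                sprintf("dog_length\t%g", cfg$dog_length),
                sprintf("pa_cutoff_log2\t%.10g", cfg$pa_cutoff_log2),
                sprintf("min_input\t%g", cfg$min_input),
                sprintf("smoothing_m\t%g", cfg$smoothing_m),
                sprintf("background_band\t%g", cfg$background_band))
  out_file <- function(name) file.path(cfg$outdir, name)
  emit <- function(stage, name) {
    manifest <<- c(manifest, sprintf("output\t%s\t%s", stage, name))
    out_file(name)
  }
  res <- list()

  sc <- do.call(sim_scenario, c(list(seed = cfg$seed), cfg$scenario))
  genome <- simulate_genome(sc)
  point <- list(control = simulate_point_coverage(genome, sc, "control"),
                perturbed = simulate_point_coverage(genome, sc, "perturbed"))

  if ("simulate" %in% stages) {
    write_gene_table(genome$genes, emit("simulate", "genes.tsv"))
    write_scored_bed(genome$zones, emit("simulate", "zones.bed"))
    write_tsv(genome$zones[, c("name", "gene_id", "gap", "planted_invaded")],
              emit("simulate", "truth_zones.tsv"))
    for (cond in names(point))
      for (strand in c("+", "-"))
        write_bedgraph(point[[cond]]$coverage,
                       emit("simulate", sprintf("point_%s_%s.bedgraph", cond,
                                                if (strand == "+") "fwd"
                                                else "rev")),
                       strand)
    res$simulate <- list(scenario = sc, genome = genome)
  }

  norm <- lapply(point, function(p)
    spike_factor(p$spike_reads, p$endogenous_reads))
  scaled <- Map(function(p, nf) apply_spike_scaling(p$coverage, nf),
                point, norm)
  if ("normalize" %in% stages) {
    nf_tab <- data.frame(condition = names(norm),
                         spike_reads = vapply(norm, `[[`, 0, "spike_reads"),
                         endogenous_reads = vapply(norm, `[[`, 0,
                                                   "endogenous_reads"),
                         factor = vapply(norm, `[[`, 0, "factor"),
                         scale = vapply(norm, `[[`, 0, "scale"))
    write_tsv(nf_tab, emit("normalize", "spike_factors.tsv"))
    res$normalize <- norm
  }

  if ("metrics" %in% stages) {
    ti_c <- termination_index(scaled$control, genome$genes, cfg$dog_length)
    ti_p <- termination_index(scaled$perturbed, genome$genes, cfg$dog_length)
    thr <- cfg$delta_ti_fraction * expected_delta_ti(sc, cfg$dog_length)$delta_ti
    cls <- classify_ndt_nit(ti_c, ti_p, thr)
    write_tsv(ti_c, emit("metrics", "ti_control.tsv"))
    write_tsv(ti_p, emit("metrics", "ti_perturbed.tsv"))
    write_tsv(cls, emit("metrics", "ti_comparison.tsv"))
    pi_c <- pausing_index(scaled$control, genome$genes)
    write_tsv(pi_c, emit("metrics", "pausing.tsv"))
    reads <- simulate_junction_reads(genome, sc)
    spl <- splicing_efficiency(reads, stats::setNames(
      genome$genes[, c("gene_id", "chrom", "strand", "start", "end")],
      c("unit_id", "chrom", "strand", "start", "end")))
    write_tsv(spl, emit("metrics", "splicing.tsv"))
    res$metrics <- list(ti_control = ti_c, ti_perturbed = ti_p,
                        classes = cls, pausing = pi_c, splicing = spl)
  }

  if ("zones" %in% stages) {
    z <- quantify_zone_signal(genome$zones,
                              list(control = scaled$control,
                                   perturbed = scaled$perturbed))
    z <- classify_pa_pna(z, "perturbed", "control", cfg$pa_cutoff_log2)
    z <- zone_gene_distance(z, genome$genes)
    write_tsv(z, emit("zones", "zones_classified.tsv"))
    res$zones <- z
  }

  if ("rate" %in% stages) {
    tt <- simulate_tt_timecourse(genome, sc)
    t_lab <- names(tt$treated)[1]
    t_min <- sc$nvp2_times[1]
    wave <- filter_wave_genes(tt$untreated, tt$treated[[t_lab]],
                              genome$genes, cfg$wave_min_length,
                              cfg$wave_proximal_window,
                              cfg$wave_min_reduction)
    calls <- call_transition_points(tt$treated[[t_lab]], wave,
                                    cfg$rate_bin_width)
    calls$rate_kb_min <- estimate_rate(calls$front_position, t_min)
    write_tsv(calls, emit("rate", "transition_calls.tsv"))
    res$rate <- list(timecourse = tt, calls = calls)
  }

  if ("brdu" %in% stages) {
    br <- lapply(c(control = "control", perturbed = "perturbed"),
                 function(cond) {
                   tr <- simulate_brdu_counts(genome, sc, cond)
                   tr <- brdu_enrichment(tr, cfg$min_input)
                   tr$eb_smooth <- smooth_moving_average(tr$eb,
                                                         cfg$smoothing_m)
                   tr
                 })
    dz <- subtract_conditions(br$perturbed$eb_smooth, br$control$eb_smooth,
                              cfg$background_band / 100,
                              br$control$bin_width)
    deltas <- dog_delta_point(scaled$perturbed, scaled$control, genome$genes,
                              c(cfg$dog_length, 2 * cfg$dog_length))
    strat <- stratify_by_zones(deltas, dz)
    write_tsv(data.frame(bin = seq_along(dz$delta), delta = dz$delta),
              emit("brdu", "brdu_delta.tsv"))
    write_tsv(strat, emit("brdu", "dog_delta_by_zone.tsv"))
    bm <- NULL
    gm <- strat$delta[strat$group == "minus"]
    gp <- strat$delta[strat$group == "plus"]
    if (length(gm) >= 2 && length(gp) >= 2) {
      bm <- tryCatch(brunner_munzel(gm, gp), error = function(e) NULL)
    }
    if (!is.null(bm)) {
      write_tsv(data.frame(estimate = unname(bm$estimate),
                           statistic = unname(bm$statistic),
                           df = unname(bm$parameter),
                           p_value = bm$p.value),
                emit("brdu", "brunner_munzel.tsv"))
    }
    res$brdu <- list(tracks = br, delta_zones = dz, stratified = strat,
                     test = bm)
  }

  writeLines(manifest, out_file("manifest.txt"))
  invisible(res)
}
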