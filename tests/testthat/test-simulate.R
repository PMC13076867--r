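test_that("genome simulation is deterministic and respects spacing", {
  sc <- sim_scenario(seed = 5, n_genes = 20)
  g1 <- simulate_genome(sc)
  g2 <- simulate_genome(sc)
  expect_identical(g1, g2)
  genes <- g1$genes
  ord <- order(genes$start)
  gaps <- genes$start[ord][-1] - genes$end[ord][-nrow(genes)]
  expect_true(all(gaps >= sc$gap_range[1]))
  expect_equal(nrow(genes), 20)
  expect_equal(nrow(g1$zones), 20)
  # zones are intergenic: no overlap with any gene
  for (i in seq_len(nrow(g1$zones)))
    expect_false(any(g1$zones$start[i] < genes$end &
                       g1$zones$end[i] > genes$start))
})

test_that("fixed zone placement puts every zone at the stated gap", {
  sc <- sim_scenario(seed = 3, n_genes = 10, ri_gap_fixed = 3000)
  g <- simulate_genome(sc)
  expect_true(all(g$zones$gap == 3000))
  tes <- gene_tes(g$genes)[match(g$zones$gene_id, g$genes$gene_id)]
  strand <- g$genes$strand[match(g$zones$gene_id, g$genes$gene_id)]
  off <- ifelse(strand == "+", g$zones$start - tes, tes - g$zones$end)
  expect_true(all(off == 3000))
})

test_that("infeasible zone packing is rejected", {
  sc <- sim_scenario(seed = 1, gap_range = c(5000, 6000))
  expect_error(simulate_genome(sc), "infeasible packing")
})

test_that("noise-free nascent coverage has the constructed shape", {
  sc <- tiny_scenario()
  g <- simulate_genome(sc)
  ctrl <- simulate_point_coverage(g, sc, "control")
  gene <- g$genes[1, ]
  body_mid <- sort(c(gene$start, gene$end))
  # gene-body plateau at body density (plus background)
  mid_d <- region_signal_mean(ctrl$coverage, gene$chrom, gene$strand,
                              body_mid[1] + 5000, body_mid[2] - 5000)
  expect_equal(mid_d, sc$body_density + sc$background_density,
               tolerance = 1e-10)
  # pause peak: pause_height-fold body density just downstream of the TSS
  tss <- gene_tss(gene)
  pw <- if (gene$strand == "+") c(tss, tss + 200) else c(tss - 200, tss)
  pk <- region_signal_mean(ctrl$coverage, gene$chrom, gene$strand,
                           pw[1], pw[2])
  expect_equal(pk, sc$pause_height * sc$body_density + sc$background_density,
               tolerance = 1e-10)
  # the boxcar conserves its mass even where it straddles a bin boundary
  pm <- if (gene$strand == "+") c(tss, tss + 300) else c(tss - 300, tss)
  mass <- region_signal_sum(ctrl$coverage, gene$chrom, gene$strand,
                            pm[1], pm[2])
  expect_equal(mass, (sc$body_density + sc$background_density) * 300 +
                 (sc$pause_height - 1) * sc$body_density * sc$pause_width,
               tolerance = 1e-8)
  # post-TES decay: signal at TES + 2500 far below body; TI negative
  ti <- termination_index(ctrl$coverage, g$genes)
  expect_true(all(ti$ti < 0))
})

test_that("planted readthrough sets the downstream density ratio", {
  sc <- tiny_scenario(planted_fraction = 1)
  g <- simulate_genome(sc)
  pert <- simulate_point_coverage(g, sc, "perturbed")
  gene <- g$genes[1, ]
  tes <- gene_tes(gene)
  win <- if (gene$strand == "+") c(tes, tes + sc$readthrough_extension) else
    c(tes - sc$readthrough_extension, tes)
  dog_d <- region_signal_mean(pert$coverage, gene$chrom, gene$strand,
                              win[1], win[2]) - sc$background_density
  body <- sort(c(gene$start, gene$end))
  body_d <- region_signal_mean(pert$coverage, gene$chrom, gene$strand,
                               body[1] + 5000, body[2] - 5000) -
    sc$background_density
  expect_equal(dog_d / body_d, sc$readthrough_amplitude, tolerance = 0.02)
})

test_that("Poisson coverage recovers body density within sampling error", {
  sc <- sim_scenario(seed = 8, n_genes = 100, gene_length = 20000,
                     readthrough_extension = 5000, dog_decay_cutoff = 1500,
                     noise_model = "poisson")
  g <- simulate_genome(sc)
  ctrl <- simulate_point_coverage(g, sc, "control")
  means <- vapply(seq_len(nrow(g$genes)), function(i) {
    gene <- g$genes[i, ]
    region_signal_mean(ctrl$coverage, gene$chrom, gene$strand,
                       gene$start + 2000, gene$end - 2000)
  }, numeric(1))
  mu <- sc$body_density + sc$background_density
  # mean of ~16k-bp windows over 100 genes: SE = sqrt(mu / total bp)
  se <- sqrt(mu / (100 * 16000))
  expect_lt(abs(mean(means) - mu), 3 * se)
})

test_that("inhibition waves suppress exactly up to v*t and clamp", {
  sc <- tiny_scenario(nvp2_times = c(0.5, 30))
  g <- simulate_genome(sc)
  tt <- simulate_tt_timecourse(g, sc)
  # 30 min at 2 kb/min = 60 kb > 20-kb genes: fully suppressed
  tr <- tt$truth
  expect_true(all(tr$front_bp[tr$time_min == 30] == sc$gene_length))
  # 0.5 min = 1 kb front
  expect_true(all(tr$front_bp[tr$time_min == 0.5] == 1000))
  gene <- g$genes[1, ]
  tss <- gene_tss(gene)
  a <- if (gene$strand == "+") c(tss, tss + 1000) else c(tss - 1000, tss)
  sup <- region_signal_mean(tt$treated[["t0.5"]], gene$chrom, gene$strand,
                            a[1], a[2])
  expect_equal(sup, sc$residual_fraction * sc$body_density +
                 sc$background_density, tolerance = 1e-10)
  b <- if (gene$strand == "+") c(tss + 1000, tss + 2000) else
    c(tss - 2000, tss - 1000)
  intact <- region_signal_mean(tt$treated[["t0.5"]], gene$chrom, gene$strand,
                               b[1], b[2])
  expect_equal(intact, sc$body_density + sc$background_density,
               tolerance = 1e-10)
})

test_that("zero treatment time reproduces the untreated track", {
  sc <- tiny_scenario(nvp2_times = 0)
  g <- simulate_genome(sc)
  tt <- simulate_tt_timecourse(g, sc)
  expect_equal(tt$treated[["t0"]]$values, tt$untreated$values)
})

test_that("junction reads carry the planted spliced fraction", {
  sc <- tiny_scenario()  # enumeration mode
  g <- simulate_genome(sc)
  reads <- simulate_junction_reads(g, sc)
  expect_equal(mean(reads$gapped), sc$spliced_fraction, tolerance = 1e-3)
  # gapped reads carry two blocks flanking the intron
  expect_true(all(grepl(",", reads$blocks[reads$gapped])))
  expect_false(any(grepl(",", reads$blocks[!reads$gapped])))
  # stochastic mode: binomial sampling oracle at n = 10,000
  scp <- tiny_scenario(noise_model = "poisson")
  rp <- simulate_junction_reads(simulate_genome(scp), scp)
  p <- scp$spliced_fraction
  se <- sqrt(p * (1 - p) / nrow(rp))
  expect_lt(abs(mean(rp$gapped) - p), 4 * se)
  # determinism
  rp2 <- simulate_junction_reads(simulate_genome(scp), scp)
  expect_identical(rp, rp2)
})

test_that("spliced_fraction = 1 makes every junction read gapped", {
  sc <- tiny_scenario(spliced_fraction = 1)
  reads <- simulate_junction_reads(simulate_genome(sc), sc)
  expect_true(all(reads$gapped))
})

test_that("BrdU counts reflect replication timing structure", {
  # uniform timing, control: EB ~ 1 everywhere
  sc <- sim_scenario(seed = 13, n_genes = 10, early_weight = 1)
  g <- simulate_genome(sc)
  tr <- brdu_enrichment(simulate_brdu_counts(g, sc, "control"))
  smoothed <- smooth_moving_average(tr$eb, m = 10)
  expect_lt(median(abs(smoothed[tr$valid] - 1), na.rm = TRUE), 0.1)
  # 3x early enrichment recovered in the EB ratio
  sc3 <- sim_scenario(seed = 13, n_genes = 10, early_weight = 3)
  g3 <- simulate_genome(sc3)
  t3 <- brdu_enrichment(simulate_brdu_counts(g3, sc3, "control"))
  early <- attr(t3, "domain") == "early"
  ratio <- mean(t3$eb[early & t3$valid]) / mean(t3$eb[!early & t3$valid])
  expect_equal(ratio, 3, tolerance = 0.1)
  # determinism
  expect_identical(simulate_brdu_counts(g3, sc3, "control")$cb, t3$cb)
})

test_that("single-exon genes are skipped for junction reads with warning", {
  sc <- tiny_scenario()
  g <- simulate_genome(sc)
  g$genes$exons[[1]] <- cbind(start = g$genes$start[1], end = g$genes$end[1])
  expect_warning(reads <- simulate_junction_reads(g, sc), "single-exon")
  expect_false(g$genes$gene_id[1] %in% reads$gene_id)
  g$genes$exons <- lapply(seq_len(nrow(g$genes)), function(i)
    cbind(start = g$genes$start[i], end = g$genes$end[i]))
  expect_warning(r0 <- simulate_junction_reads(g, sc), "no genes")
  expect_equal(nrow(r0), 0)
})
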