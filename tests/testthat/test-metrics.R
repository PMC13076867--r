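test_that("region quantification matches the worked density", {
  # 1000 raw counts over 2500 bp at library 5e7 -> 0.8 per bp
  cov <- stranded_coverage(100, c(chr1 = 10000))
  v <- numeric(100)
  v[1:25] <- 0.4  # 0.4/bp * 2500 bp = 1000 counts
  cov <- set_track(cov, "chr1", "+", v)
  d <- quantify_region(cov, "chr1", 0, 2500, "+", library_total = 5e7)
  expect_equal(d, 0.8)
  # region fully outside the data -> 0
  expect_equal(quantify_region(cov, "chr1", 20000, 21000, "+"), 0)
  expect_error(quantify_region(cov, "chr1", 500, 500, "+"), "empty region")
})

test_that("density is invariant to bin refinement on piecewise tracks", {
  for (bw in c(10, 50, 250)) {
    cov <- stranded_coverage(bw, c(chr1 = 10000))
    n <- ceiling(10000 / bw)
    v <- rep(c(1, 3), length.out = n)  # piecewise constant on every grid
    cov <- set_track(cov, "chr1", "+", rep(2, n))
    expect_equal(quantify_region(cov, "chr1", 1234, 8766, "+"), 2)
  }
})

test_that("termination index closed forms hold", {
  g <- one_gene(10000, 50000, "+")
  # uniform track: body density = dog density -> TI = 0
  cov <- uniform_coverage(3, len = 100000)
  expect_equal(termination_index(cov, g)$ti, 0)
  # body 0.4, dog 0.1 -> TI = -2
  cov2 <- stranded_coverage(100, c(chr1 = 100000))
  v <- numeric(1000)
  v[(10000 / 100 + 1):(50000 / 100)] <- 0.4
  v[(50000 / 100 + 1):(52500 / 100)] <- 0.1
  cov2 <- set_track(cov2, "chr1", "+", v)
  ti <- termination_index(cov2, g)
  expect_equal(ti$body_density, 0.4)
  expect_equal(ti$dog_density, 0.1)
  expect_equal(ti$ti, -2)
  # strand symmetry: mirrored minus-strand gene gives the same TI
  gm <- one_gene(50000, 90000, "-", gene_id = "gB")
  vm <- numeric(1000)
  vm[(50000 / 100 + 1):(90000 / 100)] <- 0.4
  vm[(47500 / 100 + 1):(50000 / 100)] <- 0.1
  covm <- set_track(stranded_coverage(100, c(chr1 = 100000)), "chr1", "-", vm)
  expect_equal(termination_index(covm, gm)$ti, -2)
})

test_that("TI is invariant under global track rescaling", {
  g <- one_gene(10000, 50000, "+")
  cov <- stranded_coverage(100, c(chr1 = 100000))
  set.seed(77)
  v <- rexp(1000) + 0.1
  cov <- set_track(cov, "chr1", "+", v)
  ti0 <- termination_index(cov, g)$ti
  for (s in rexp(100) + 0.01) {
    ti_s <- termination_index(scale_coverage(cov, s), g)$ti
    expect_equal(ti_s, ti0, tolerance = 1e-12)
  }
})

test_that("zero-density genes are flagged, not imputed", {
  g <- one_gene(10000, 50000, "+")
  cov <- stranded_coverage(100, c(chr1 = 100000))
  v <- numeric(1000)
  v[(10000 / 100 + 1):(50000 / 100)] <- 1  # body only, empty DoG
  cov <- set_track(cov, "chr1", "+", v)
  ti <- termination_index(cov, g)
  expect_true(ti$flagged)
  expect_equal(ti$ti, -Inf)
  # zero body -> unclassifiable NA
  empty <- stranded_coverage(100, c(chr1 = 100000))
  ti0 <- termination_index(empty, g)
  expect_true(is.na(ti0$ti))
})

test_that("NDT/NIT classification uses a strict threshold", {
  tc <- data.frame(gene_id = c("a", "b", "c"), ti = c(-2, -2, NA))
  tp <- data.frame(gene_id = c("a", "b", "c"), ti = c(0, -1, 1))
  cls <- classify_ndt_nit(tc, tp, delta_threshold = 1)
  expect_equal(cls$class[cls$gene_id == "a"], "NDT")   # delta 2 > 1
  expect_equal(cls$class[cls$gene_id == "b"], "NIT")   # delta 1, boundary
  expect_equal(cls$class[cls$gene_id == "c"], "unclassified")
  expect_error(classify_ndt_nit(tc, tp), "no default")
})

test_that("pausing index ratios promoter window to body", {
  g <- one_gene(10000, 50000, "+")
  cov <- uniform_coverage(2, len = 100000)
  expect_equal(pausing_index(cov, g)$pausing_index, 1)
  # 10x boxcar over the pause window
  v <- rep(2, 1000)
  v[(10000 / 100 + 1):(10300 / 100)] <- 20
  cov10 <- set_track(stranded_coverage(100, c(chr1 = 100000)),
                     "chr1", "+", v)
  expect_equal(pausing_index(cov10, g)$pausing_index, 10)
  # simulated pause height recovered (noise-free)
  sc <- tiny_scenario(pause_width = 300)
  gg <- simulate_genome(sc)
  ctrl <- simulate_point_coverage(gg, sc, "control")
  pi_all <- pausing_index(ctrl$coverage, gg$genes, pause_window = 300)
  h_exp <- (sc$pause_height * sc$body_density + sc$background_density) /
    (sc$body_density + sc$background_density)
  expect_equal(pi_all$pausing_index, rep(h_exp, nrow(gg$genes)),
               tolerance = 0.05)
})

test_that("elongation index is the per-bin synthesis/occupancy ratio", {
  g <- one_gene(10000, 50000, "+")
  tt <- uniform_coverage(4, len = 100000)
  point <- uniform_coverage(2, len = 100000)
  ep <- elongation_index_profile(tt, point, g)
  expect_equal(unname(ep$profile), rep(2, 40))
  # zero-denominator bin masked, others unaffected
  v <- rep(2, 1000)
  v[(10000 / 100 + 1):(11000 / 100)] <- 0  # first body bin of 40
  point0 <- set_track(stranded_coverage(100, c(chr1 = 100000)),
                      "chr1", "+", v)
  ep0 <- elongation_index_profile(tt, point0, g)
  expect_true(is.na(ep0$matrix[1, 1]))
  expect_equal(unname(ep0$profile[-1]), rep(2, 39))
  # halved occupancy at constant synthesis doubles EI
  point_half <- uniform_coverage(1, len = 100000)
  ep_half <- elongation_index_profile(tt, point_half, g)
  expect_equal(unname(ep_half$profile / ep$profile), rep(2, 40),
               tolerance = 1e-10)
})

test_that("splicing efficiency counts gapped reads per unit", {
  unit <- data.frame(unit_id = "u1", chrom = "chr1", strand = "+",
                     start = 0, end = 1000)
  reads <- data.frame(chrom = "chr1", strand = "+",
                      start = seq(0, 900, by = 100), end = seq(50, 950, 100),
                      gapped = rep(c(TRUE, FALSE), c(7, 3)))
  se <- splicing_efficiency(reads, unit)
  expect_equal(se$efficiency, 0.7)
  reads$gapped <- TRUE
  expect_equal(splicing_efficiency(reads, unit)$efficiency, 1)
  # unit with no overlapping reads is flagged
  far <- data.frame(unit_id = "u2", chrom = "chr1", strand = "+",
                    start = 5000, end = 6000)
  se2 <- splicing_efficiency(reads, far)
  expect_true(se2$flagged)
  expect_true(is.na(se2$efficiency))
  # strand-matched: antisense reads are not counted
  reads$strand <- "-"
  expect_true(splicing_efficiency(reads, unit)$flagged)
})

test_that("planted spliced fraction is recovered from simulated reads", {
  sc <- tiny_scenario()  # enumeration mode: exact
  g <- simulate_genome(sc)
  reads <- simulate_junction_reads(g, sc)
  units <- g$genes[, c("gene_id", "chrom", "strand", "start", "end")]
  se <- splicing_efficiency(reads, units)
  pooled <- sum(se$spliced_reads) / sum(se$total_reads)
  expect_equal(pooled, sc$spliced_fraction, tolerance = 1e-3)
})

test_that("metagene matrices have exact geometry and strand symmetry", {
  cov <- uniform_coverage(5, len = 100000)
  reg <- data.frame(chrom = "chr1", start = c(20000, 60000),
                    end = c(24000, 64000), strand = c("+", "-"))
  mg <- metagene_matrix(cov, reg, body_bins = 40, up_bins = 25,
                        down_bins = 25, flank_bin_width = 10)
  expect_equal(dim(mg$matrix), c(2, 90))
  expect_equal(unname(mg$profile), rep(5, 90))  # flat input -> flat profile
  # a minus-strand region and its mirrored plus twin give identical rows
  len <- 100000
  set.seed(42)
  v <- rexp(1000)
  covp <- set_track(stranded_coverage(100, c(chr1 = len)), "chr1", "+", v)
  covm <- set_track(stranded_coverage(100, c(chr1 = len)), "chr1", "-",
                    rev(v))
  regp <- data.frame(chrom = "chr1", start = 20000, end = 24000,
                     strand = "+")
  regm <- data.frame(chrom = "chr1", start = len - 24000,
                     end = len - 20000, strand = "-")
  mp <- metagene_matrix(covp, regp, 40, 25, 25, 10)
  mm <- metagene_matrix(covm, regm, 40, 25, 25, 10)
  expect_equal(mp$matrix, mm$matrix)
})

test_that("genes too short for the scaled profile are excluded loudly", {
  tt <- uniform_coverage(4, len = 100000)
  point <- uniform_coverage(2, len = 100000)
  genes <- rbind(one_gene(10000, 50000, "+", gene_id = "ok"),
                 one_gene(60000, 60200, "+", gene_id = "tiny"))
  expect_warning(ep <- elongation_index_profile(tt, point, genes),
                 "excluded")
  expect_equal(ep$genes, "ok")
})
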