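test_that("read midpoints land on the half-open bin grid", {
  reads <- data.frame(start = c(100, 900, 0), end = c(300, 1100, 2000))
  counts <- bin_read_centers(reads, bin_width = 1000, n_bins = 3)
  # midpoints 200 -> bin 1, 1000 -> bin 2, 1000 -> bin 2
  expect_equal(counts, c(1L, 2L, 0L))
  expect_equal(sum(counts), nrow(reads))  # conservation
  expect_error(bin_read_centers(data.frame(start = 5000, end = 5200),
                                1000, 3), "outside chromosome")
})

test_that("enrichment follows the totals-normalized ratio with masking", {
  tr <- brdu_enrichment(brdu_track(cb = c(10, 20), ci = c(10, 10)))
  expect_equal(tr$nb, c(1 / 3, 2 / 3))
  expect_equal(tr$ni, c(0.5, 0.5))
  expect_equal(tr$eb, c(2 / 3, 4 / 3))
  # a bin with input below the minimum is masked but still normalizes totals
  tr2 <- brdu_enrichment(brdu_track(cb = c(10, 20, 30), ci = c(10, 4, 10)))
  expect_true(is.na(tr2$eb[2]))
  expect_equal(tr2$nb, c(10, 20, 30) / 60)
  expect_equal(tr2$ni, c(10, 4, 10) / 24)
  # CB proportional to CI -> EB identically 1
  tr3 <- brdu_enrichment(brdu_track(cb = c(30, 60, 90), ci = c(10, 20, 30)))
  expect_equal(tr3$eb, rep(1, 3))
  # EB invariant under separate rescaling of either total
  tr4 <- brdu_enrichment(brdu_track(cb = 7 * c(10, 20), ci = c(10, 10)))
  expect_equal(tr4$eb, tr$eb)
  expect_error(brdu_enrichment(brdu_track(c(1, 1), c(1, 1)), min_input = 5),
               "below the input minimum")
})

test_that("moving-average smoothing has exact impulse and edge behavior", {
  # constant track unchanged
  expect_equal(smooth_moving_average(rep(3, 50), m = 10), rep(3, 50))
  # unit impulse spreads to 21 bins of 1/21
  v <- numeric(60)
  v[30] <- 1
  s <- smooth_moving_average(v, m = 10)
  expect_equal(s[20:40], rep(1 / 21, 21))
  expect_equal(s[c(19, 41)], c(0, 0))
  # edge windows shrink to the available bins
  v2 <- c(rep(1, 11), rep(0, 39))
  s2 <- smooth_moving_average(v2, m = 10)
  expect_equal(s2[1], mean(v2[1:11]))  # only 11 bins available
  # masked bins are excluded from the window mean
  v3 <- rep(2, 30)
  v3[15] <- NA
  expect_equal(smooth_moving_average(v3, m = 5), rep(2, 30))
})

test_that("condition subtraction calls antisymmetric delta zones", {
  dz <- subtract_conditions(c(15, -12, 3), c(0, 0, 0), background = 10,
                            bin_width = 1000)
  expect_equal(nrow(dz$plus_zones), 1)
  expect_equal(nrow(dz$minus_zones), 1)
  expect_equal(dz$plus_zones$start_bin, 1)
  expect_equal(dz$minus_zones$start_bin, 2)
  # +10 exactly is inside the excluded band
  dz10 <- subtract_conditions(c(10, -10), c(0, 0), background = 10)
  expect_equal(nrow(dz10$plus_zones) + nrow(dz10$minus_zones), 0)
  # swapping conditions swaps zone sets exactly
  a <- c(15, -12, 3, 40, -40, 0)
  b <- c(0, 3, -8, 11, 2, 0)
  d1 <- subtract_conditions(a, b)
  d2 <- subtract_conditions(b, a)
  expect_equal(d1$plus_zones, d2$minus_zones)
  expect_equal(d1$minus_zones, d2$plus_zones)
  expect_error(subtract_conditions(1:3, 1:4), "mismatched")
})

test_that("downstream delta separates planted readthrough genes", {
  sc <- sim_scenario(seed = 31, n_genes = 10, noise_model = "none")
  g <- simulate_genome(sc)
  ctrl <- simulate_point_coverage(g, sc, "control")
  pert <- simulate_point_coverage(g, sc, "perturbed")
  # identical tracks -> all-zero deltas
  d0 <- dog_delta_point(ctrl$coverage, ctrl$coverage, g$genes)
  expect_equal(d0$delta, rep(0, nrow(d0)))
  d <- dog_delta_point(pert$coverage, ctrl$coverage, g$genes)
  m <- merge(d, g$genes[, c("gene_id", "planted")])
  # noise-free separation is perfect (AUROC 1)
  expect_gt(min(m$delta[m$planted]), max(m$delta[!m$planted]))
})

test_that("uniform offset in the window shifts delta by that offset", {
  g <- one_gene(10000, 50000, "+")
  a <- uniform_coverage(3, len = 100000)
  b <- uniform_coverage(2, len = 100000)
  d <- dog_delta_point(a, b, g)
  expect_equal(d$delta, 1)
})

test_that("window-zone stratification partitions the gene set", {
  deltas <- data.frame(gene_id = c("a", "b", "c"),
                       win_start = c(500, 4500, 9500),
                       win_end = c(900, 4900, 9900))
  zs <- subtract_conditions(c(20, rep(0, 3), -20, rep(0, 5)),
                            numeric(10), background = 10, bin_width = 1000)
  out <- stratify_by_zones(deltas, zs)
  expect_equal(out$group, c("plus", "minus", "unassigned"))
  expect_equal(sum(table(out$group)), nrow(deltas))
})

test_that("Brunner-Munzel estimator matches exhaustive pair counting", {
  bm <- brunner_munzel(c(1, 3, 5), c(2, 4, 6))
  expect_equal(unname(bm$estimate), 6 / 9)
  # exchangeable identical samples -> exactly 1/2
  x <- c(1, 2, 2, 3, 7)
  expect_equal(unname(brunner_munzel(x, x)$estimate), 0.5)
  # exhaustive pairwise oracle on many small tie-rich fixtures
  set.seed(404)
  for (r in 1:50) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- sample(1:4, n1, replace = TRUE)
    y <- sample(1:4, n2, replace = TRUE)
    p_impl <- tryCatch(unname(brunner_munzel(x, y)$estimate),
                       error = function(e) NA_real_)
    if (!is.na(p_impl)) expect_equal(p_impl, pairwise_p_hat(x, y))
  }
  expect_error(brunner_munzel(c(1, 1), c(2, 2)), "degenerate")
  expect_error(brunner_munzel(1, c(1, 2)), "at least 2")
})

test_that("planted termination defects concentrate in minus zones", {
  sc <- sim_scenario(seed = 17, n_genes = 40)
  g <- simulate_genome(sc)
  ctrl <- simulate_point_coverage(g, sc, "control")
  pert <- simulate_point_coverage(g, sc, "perturbed")
  bc <- brdu_enrichment(simulate_brdu_counts(g, sc, "control"))
  bp <- brdu_enrichment(simulate_brdu_counts(g, sc, "perturbed"))
  dz <- subtract_conditions(100 * smooth_moving_average(bp$eb),
                            100 * smooth_moving_average(bc$eb),
                            background = 10, bin_width = bc$bin_width)
  d <- dog_delta_point(pert$coverage, ctrl$coverage, g$genes)
  st <- stratify_by_zones(d, dz)
  m <- merge(st, g$genes[, c("gene_id", "planted")])
  # genes with the planted defect are enriched in BrdU-depleted (minus)
  # zones relative to the rest (smoothing spreads zone edges ~m bins, so
  # some unplanted neighbors are swept in; enrichment, not purity)
  expect_gt(mean(m$planted[m$group == "minus"]),
            mean(m$planted[m$group != "minus"]))
  expect_gt(mean(m$planted[m$group == "minus"]), 0.5)
  gm <- st$delta[st$group == "minus"]
  gp <- st$delta[st$group == "plus"]
  bm <- brunner_munzel(gp, gm)
  expect_lt(bm$p.value, 0.01)
  expect_gt(unname(bm$estimate), 0.5)  # minus-zone deltas larger
})
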