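# shared fixture builders (everything is generated in code)

# a uniform single-chromosome coverage track, same value on the given strands
uniform_coverage <- function(value, len = 100000, bin_width = 100,
                             strands = c("+", "-"), chrom = "chr1") {
  cov <- stranded_coverage(bin_width, setNames(len, chrom))
  n <- ceiling(len / bin_width)
  for (s in strands) cov <- set_track(cov, chrom, s, rep(value, n))
  cov
}

# one + strand gene on chr1 with a simple two-exon structure
one_gene <- function(start = 10000, end = 50000, strand = "+",
                     chrom = "chr1", gene_id = "gA") {
  l <- end - start
  ex <- cbind(start = c(start, start + floor(l * 0.7)),
              end = c(start + floor(l * 0.3), end))
  g <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                  start = start, end = end, expression = 10,
                  stringsAsFactors = FALSE)
  g$exons <- list(ex)
  g
}

# brute-force two-segment least-squares breakpoint (independent oracle)
brute_breakpoint <- function(v) {
  n <- length(v)
  best <- Inf
  bk <- NA_integer_
  for (k in seq_len(n - 1L)) {
    a <- v[seq_len(k)]; b <- v[(k + 1L):n]
    rss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (rss < best) {
      best <- rss
      bk <- k
    }
  }
  bk
}

# exhaustive pairwise stochastic-superiority estimate (independent oracle)
pairwise_p_hat <- function(x, y) {
  cmp <- outer(x, y, function(a, b) (a < b) + 0.5 * (a == b))
  mean(cmp)
}

tiny_scenario <- function(noise_model = "none", ...) {
  sim_scenario(seed = 42, n_genes = 6, gene_length = 20000,
               readthrough_extension = 5000, dog_decay_cutoff = 1500,
               conflict_window = 8000, noise_model = noise_model, ...)
}
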