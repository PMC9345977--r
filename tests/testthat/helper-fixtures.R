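# Fixture builders and independent oracles shared across the test files.

# tiny genotype matrix with evenly spaced loci on one chromosome
toy_geno <- function(dosages, chrom = "chr1", spacing = 100,
                     start = 100, pos = NULL,
                     sample_ids = paste0("s", seq_len(nrow(dosages)))) {
  p <- ncol(dosages)
  if (is.null(pos)) pos <- start + spacing * (seq_len(p) - 1)
  geno_matrix(dosages,
              data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T"),
              sample_ids)
}

# Weir & Cockerham (1984) theta, transcribed equation by equation for an
# arbitrary number of populations, with explicit loops. Serves as the
# independent oracle for the vectorised two-population implementation.
wc_oracle <- function(pops) {
  r <- length(pops)
  n <- vapply(pops, length, numeric(1))          # diploids per population
  p <- vapply(pops, function(g) sum(g) / (2 * length(g)), numeric(1))
  h <- vapply(pops, function(g) mean(g == 1), numeric(1))
  n_bar <- 0
  for (i in seq_len(r)) n_bar <- n_bar + n[i] / r
  n_c <- 0
  for (i in seq_len(r)) n_c <- n_c + n[i]^2
  n_c <- (r * n_bar - n_c / (r * n_bar)) / (r - 1)
  p_bar <- 0
  for (i in seq_len(r)) p_bar <- p_bar + n[i] * p[i] / (r * n_bar)
  s2 <- 0
  for (i in seq_len(r)) s2 <- s2 + n[i] * (p[i] - p_bar)^2 / ((r - 1) * n_bar)
  h_bar <- 0
  for (i in seq_len(r)) h_bar <- h_bar + n[i] * h[i] / (r * n_bar)
  a <- n_bar / n_c *
    (s2 - 1 / (n_bar - 1) *
       (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4))
  b <- n_bar / (n_bar - 1) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
       (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  c <- h_bar / 2
  if (a + b + c == 0) return(list(a = a, b = b, c = c, theta = NA_real_))
  list(a = a, b = b, c = c, theta = a / (a + b + c))
}

# brute-force CSS from the definition, without the matrix machinery:
# raw Euclidean/SNP-count distances, no MDS shortcut (MDS is
# distance-preserving here, so the values must agree)
css_oracle <- function(dosages, g1, g2) {
  d <- as.matrix(stats::dist(dosages)) / ncol(dosages)
  m <- length(g1); n <- length(g2)
  between <- mean(d[g1, g2])
  w1 <- 0; k <- 0
  for (i in g1) for (j in g1) if (i < j) { w1 <- w1 + d[i, j]; k <- k + 1 }
  w1 <- if (k) w1 / k else 0
  w2 <- 0; k <- 0
  for (i in g2) for (j in g2) if (i < j) { w2 <- w2 + d[i, j]; k <- k + 1 }
  w2 <- if (k) w2 / k else 0
  between - (m * w1 + n * w2) / (m + n)
}

# neutral two-group, two-stratum genotype fixture for permutation tests
neutral_contrast_sim <- function(seed, n_chrom = 2, snps = 5000) {
  cfg <- sim_config(seed = seed, n_chromosomes = n_chrom,
                    snps_per_chromosome = snps,
                    prop_parallel_loci = 0,
                    polygenic_trait_params = list(n_loci = 0, effect_sd = 0,
                                                  residual_sd = 15),
                    n_outgroup = 0)
  simulate_radiation(cfg)
}

css_groups <- function(sim) {
  ing <- sim$samples[sim$samples$ecomorph != "Outgroup", ]
  list(group1 = ing$sample[ing$ecomorph == "Balchen"],
       group2 = ing$sample[ing$ecomorph == "Albeli"],
       strata = split(ing$sample, ing$lake))
}
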