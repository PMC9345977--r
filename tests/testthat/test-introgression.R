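test_that("f4 matches direct arithmetic and its exchange identities", {
  # two SNPs: (1,0,1,0) and (0,0,1,0) -> mean(1*1, 0*1) = 0.5
  pa <- c(1, 0); pb <- c(0, 0); pc <- c(1, 1); pd <- c(0, 0)
  expect_equal(f4_stat(pa, pb, pc, pd), 0.5)
  expect_equal(f4_stat(pb, pa, pc, pd), -0.5)        # antisymmetry in (A,B)
  expect_equal(f4_stat(pa, pb, pd, pc), -0.5)        # antisymmetry in (C,D)
  expect_equal(f4_stat(pc, pd, pa, pb), 0.5)         # pair exchange
  expect_equal(f4_stat(pa, pa, pc, pd), 0)           # p_A = p_B
  expect_error(f4_stat(NA, 1, 1, 0), "no SNP")
})

test_that("the three quartet arrangements sum to zero (Fisher identity)", {
  set.seed(24)
  p <- matrix(runif(4 * 500), ncol = 4)
  s <- f4_stat(p[, 1], p[, 2], p[, 3], p[, 4]) +
    f4_stat(p[, 1], p[, 3], p[, 4], p[, 2]) +
    f4_stat(p[, 1], p[, 4], p[, 2], p[, 3])
  expect_lt(abs(s), 1e-12)
})

test_that("topology contrast returns the generating scenario", {
  verdicts <- function(mode) {
    vapply(1:10, function(sd) {
      cfg <- sim_config(seed = sd, n_chromosomes = 2,
                        snps_per_chromosome = 3000, origin_mode = mode,
                        polygenic_trait_params = list(n_loci = 0,
                                                      effect_sd = 0,
                                                      residual_sd = 15))
      sim <- simulate_radiation(cfg)
      fr <- allele_freqs(sim$genotypes, group_samples(sim$samples, "species"))
      topology_contrast(fr, "Balchen_Lake1", "Albeli_Lake1",
                        "Balchen_Lake2", "Albeli_Lake2")$verdict
    }, character(1))
  }
  expect_gte(sum(verdicts("parallel") == "parallel within-lake origin"), 9)
  expect_gte(sum(verdicts("single") == "single ecomorph origin"), 9)
})

test_that("topology contrast on identical populations is indeterminate", {
  f <- matrix(0.5, 100, 4, dimnames = list(NULL, c("b1", "a1", "b2", "a2")))
  out <- topology_contrast(f, "b1", "a1", "b2", "a2")
  expect_equal(out$f4_sympatric, 0)
  expect_equal(out$f4_ecomorph, 0)
  expect_equal(out$verdict, "indeterminate")
  expect_error(topology_contrast(f, "b1", "b1", "b2", "a2"), "distinct")
})

test_that("D and the f4-admixture ratio match direct arithmetic", {
  # single site (0, 1, 1, 0): ABBA = 1, BABA = 0 -> D = 1
  r <- d_and_f4ratio(0, 1, 1, 0)
  expect_equal(r$d, 1)
  expect_equal(r$f, 1)     # denominator substitutes C for B: also 1
  # p_B = p_A everywhere -> D = 0, f = 0
  pa <- runif(50)
  r2 <- d_and_f4ratio(pa, pa, runif(50), rep(0.1, 50))
  expect_equal(r2$d, 0)
  expect_equal(r2$f, 0)
  # |D| <= 1 on random frequency tables
  set.seed(25)
  for (i in 1:20) {
    p <- matrix(runif(4 * 100), ncol = 4)
    d <- d_and_f4ratio(p[, 1], p[, 2], p[, 3], p[, 4])$d
    expect_lte(abs(d), 1)
  }
})

test_that("f4-admixture ratio recovers the simulated admixture fraction", {
  fs <- vapply(1:3, function(sd) {
    ev <- list(list(donor_lake = "Lake1", recipient_species = "Albeli_Lake3",
                    tract_fraction = 0.2, tract_length_bp = 50000))
    cfg <- sim_config(seed = sd, n_chromosomes = 10,
                      snps_per_chromosome = 5000,
                      prop_parallel_loci = 0,
                      polygenic_trait_params = list(n_loci = 0,
                                                    effect_sd = 0,
                                                    residual_sd = 15),
                      introgression_events = ev)
    sim <- simulate_radiation(cfg)
    fr <- allele_freqs(sim$genotypes, group_samples(sim$samples, "species"))
    d_and_f4ratio(fr[, "Balchen_Lake3"], fr[, "Albeli_Lake3"],
                  fr[, "Albeli_Lake1"], fr[, "Outgroup"], n_c = 6)$f
  }, numeric(1))
  expect_lt(abs(mean(fs) - 0.2), 0.05)
})

test_that("block jackknife Z is calibrated and handles degenerate variance", {
  # constant per-block statistic -> SE 0 -> infinite Z with a warning
  expect_warning(z0 <- jackknife_z(rep(1, 100), rep(2, 100)), "SE is zero")
  expect_equal(z0$estimate, 0.5)
  expect_true(is.infinite(z0$z))
  # null calibration: i.i.d. Gaussian numerator, true value 0
  set.seed(26)
  zs <- replicate(200, jackknife_z(rnorm(2000), rep(1, 2000))$z)
  expect_gt(stats::ks.test(zs, "pnorm")$p.value, 0.01)
  # doubling the block count changes the SE only modestly on smooth data
  set.seed(27)
  num <- rnorm(4000, 0.1, 1)
  se20 <- jackknife_z(num, rep(1, 4000), 20)$se
  se40 <- jackknife_z(num, rep(1, 4000), 40)$se
  expect_lt(abs(se40 - se20) / se20, 0.2)
  expect_error(jackknife_z(1:10, 1:10, 1), "two blocks")
  expect_error(jackknife_z(1:3, 1:3, 5), "fewer sites")
})

test_that("Bonferroni Z threshold reproduces the printed values", {
  expect_equal(as.numeric(bonferroni_z_threshold(0.01, 1910)), 4.41)
  expect_equal(as.numeric(bonferroni_z_threshold(0.05, 1)), 1.64)
  expect_equal(as.numeric(bonferroni_z_threshold(0.5, 1)), 0)
})

test_that("fbranch on a 4-tip tree reduces to the single f4 ratio", {
  set.seed(28)
  n <- 2000
  f <- cbind(A = runif(n), B = runif(n), C = runif(n), O = runif(n))
  fb <- fbranch("(((A,B),C),O);", f, outgroup = "O")
  direct <- d_and_f4ratio(f[, "A"], f[, "B"], f[, "C"], f[, "O"])$f
  expect_equal(fb$fb["B", "C"], max(direct, 0), ignore_attr = TRUE)
  # cells violating the topology are untestable
  expect_true(is.na(fb$fb["B", "A"]))   # C inside the sister clade
  expect_true(is.na(fb$fb["A", "B"]))
  expect_error(fbranch("((A,B),(C,O));", f, outgroup = "O"),
               "direct child of the root")
})

test_that("fbranch pinpoints a simulated donor/recipient pair", {
  ev <- list(list(donor_lake = "Lake1", recipient_species = "Albeli_Lake3",
                  tract_fraction = 0.2, tract_length_bp = 50000))
  cfg <- sim_config(seed = 29, n_chromosomes = 10,
                    snps_per_chromosome = 5000, prop_parallel_loci = 0,
                    polygenic_trait_params = list(n_loci = 0, effect_sd = 0,
                                                  residual_sd = 15),
                    introgression_events = ev)
  sim <- simulate_radiation(cfg)
  grp <- group_samples(sim$samples, "species")
  fr <- allele_freqs(sim$genotypes, grp)
  fb <- fbranch(sim$truth$tree, fr, outgroup = "Outgroup",
                sample_sizes = 2 * lengths(grp))
  tab <- fb$table[!is.na(fb$table$fb) & fb$table$significant, ]
  expect_gt(nrow(tab), 0)
  top <- tab[which.max(tab$fb), ]
  # the f4-ratio is symmetric in who donated, so the top cell may come out
  # in either orientation of the simulated Lake1 <-> Albeli_Lake3 event
  lake1_side <- c("Albeli_Lake1", "Balchen_Lake1",
                  "mrca(Albeli_Lake1+Balchen_Lake1)")
  forward <- top$branch == "Albeli_Lake3" && top$donor %in% lake1_side
  reverse <- top$branch %in% lake1_side && top$donor == "Albeli_Lake3"
  expect_true(forward || reverse)
  # and every significant cell involves the two partners
  expect_true(all(tab$branch %in% c("Albeli_Lake3", lake1_side)))
})

test_that("fbranch under the null stays within the Bonferroni expectation", {
  sig <- vapply(1:5, function(sd) {
    cfg <- sim_config(seed = sd + 100, n_chromosomes = 2,
                      snps_per_chromosome = 2500, prop_parallel_loci = 0,
                      polygenic_trait_params = list(n_loci = 0, effect_sd = 0,
                                                    residual_sd = 15))
    sim <- simulate_radiation(cfg)
    grp <- group_samples(sim$samples, "species")
    fr <- allele_freqs(sim$genotypes, grp)
    fb <- fbranch(sim$truth$tree, fr, outgroup = "Outgroup",
                  sample_sizes = 2 * lengths(grp))
    sum(fb$significant, na.rm = TRUE)
  }, numeric(1))
  # family-wise alpha 0.01 per seed: expected false positives ~ 0.05 overall
  expect_lte(sum(sig), 1)
})
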