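test_that("css_window matches hand evaluation on toy cases", {
  # all individuals identical -> all distances zero -> CSS 0
  expect_equal(css_window(matrix(1L, 8, 5), 1:4, 5:8), 0)
  # single SNP, group1 {0,0}, group2 {2,2}: between mean 2, within 0
  expect_equal(css_window(matrix(c(0, 0, 2, 2), ncol = 1), 1:2, 3:4), 2)
  # a 3+3 instance against the brute-force definition
  set.seed(11)
  d <- matrix(sample(0:2, 6 * 40, TRUE), 6)
  expect_equal(css_window(d, 1:3, 4:6), css_oracle(d, 1:3, 4:6),
               tolerance = 1e-8)
  expect_error(css_window(d, 1, 2:6), "at least two")
  expect_error(css_window(d[, 0], 1:3, 4:6), "zero SNPs")
})

test_that("CSS is invariant to SNP order and to swapping group labels", {
  set.seed(12)
  d <- matrix(sample(0:2, 8 * 30, TRUE), 8)
  ref <- css_window(d, 1:4, 5:8)
  expect_equal(css_window(d[, sample(30)], 1:4, 5:8), ref, tolerance = 1e-8)
  expect_equal(css_window(d, 5:8, 1:4), ref, tolerance = 1e-8)
})

test_that("label-shuffled CSS on neutral data is centred at zero", {
  sim <- neutral_contrast_sim(13, n_chrom = 1, snps = 3000)
  grp <- css_groups(sim)
  ids <- c(grp$group1, grp$group2)
  idx <- match(ids, sim$genotypes$sample_ids)
  set.seed(1)
  vals <- replicate(300, {
    sh <- sample(ids)
    g1 <- match(sh[1:12], ids)
    css_window(sim$genotypes$dosages[idx, 1:100], g1, setdiff(1:24, g1))
  })
  expect_lt(abs(mean(vals)), 2 * stats::sd(vals) / sqrt(length(vals)))
})

test_that("stratified permutation p-values follow the add-one rule", {
  # 4 strata of 3+3 (160,000 distinct assignments) with a perfectly
  # separating signal: the observed CSS tops every sampled permutation, so
  # the add-one estimator gives exactly 1/(N + 1)
  set.seed(14)
  noise <- matrix(sample(0:2, 24 * 10, TRUE), 24)
  signal <- matrix(rep(rep(c(0L, 2L), each = 3, times = 4), 20), 24)
  g <- toy_geno(cbind(signal, noise), spacing = 100)
  ids <- paste0("s", 1:24)
  grp1 <- ids[rep(0:3 * 6, each = 3) + 1:3]        # the dosage-0 triplets
  grp2 <- setdiff(ids, grp1)
  strata <- split(ids, rep(1:4, each = 6))
  des <- css_design(grp1, grp2, strata, n_permutations = 999,
                    min_snps = 10, mode = "sampled", seed = 3)
  res <- css_scan(g, make_windows(g, 50000), des)
  expect_equal(res$p_perm, 1 / 1000)
  expect_gt(res$p_perm, 0)   # the add-one rule forbids p = 0
})

test_that("exact enumeration agrees with sampling within binomial error", {
  # 2 strata of 3+3: 20^2 = 400 distinct stratified assignments
  sim <- neutral_contrast_sim(15, n_chrom = 1, snps = 2000)
  grp <- css_groups(sim)
  two <- c("Lake1", "Lake2")
  g1 <- grp$group1[grp$group1 %in% unlist(grp$strata[two])]
  g2 <- grp$group2[grp$group2 %in% unlist(grp$strata[two])]
  w <- make_windows(sim$genotypes)
  des_e <- css_design(g1, g2, grp$strata[two], mode = "exact", seed = 5)
  des_s <- css_design(g1, g2, grp$strata[two], n_permutations = 2000,
                      mode = "sampled", seed = 5)
  expect_equal(radscan:::stratified_assignment_count(des_e), 400)
  pe <- css_scan(sim$genotypes, w, des_e)$p_perm
  ps <- css_scan(sim$genotypes, w, des_s)$p_perm
  tol <- 3 * sqrt(pe * (1 - pe) / 2000) + 2 / 2000
  expect_true(all(abs(pe - ps) <= tol))
})

test_that("windows below the SNP-count floor never appear in output", {
  set.seed(16)
  d <- matrix(sample(0:2, 8 * 47, TRUE), 8)
  # 23 SNPs in window 0, 24 in window 1
  pos <- c(seq(100, by = 10, length.out = 23),
           seq(50001, by = 10, length.out = 24))
  g <- toy_geno(d, pos = pos)
  ids <- paste0("s", 1:8)
  des <- css_design(ids[1:4], ids[5:8],
                    strata = list(l1 = ids[c(1, 2, 5, 6)],
                                  l2 = ids[c(3, 4, 7, 8)]),
                    n_permutations = 99, mode = "sampled")
  res <- css_scan(g, make_windows(g), des)
  expect_equal(nrow(res), 1)
  expect_equal(res$n_snps, 24)
  expect_equal(res$start, 50000)
})

test_that("css_design validates strata", {
  ids <- paste0("s", 1:8)
  expect_error(css_design(ids[1:4], ids[5:8],
                          strata = list(l1 = ids[1:4], l2 = ids[5:8])),
               "all its samples in one group")
  expect_error(css_design(ids[1:4], ids[4:8],
                          strata = list(l = ids)), "overlap")
})

test_that("Benjamini-Hochberg q-values match hand computation", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.02, 0.7, 0.4, 1)
  expect_equal(fdr_adjust(p, "storey", pi0 = 1), fdr_adjust(p))
  q <- fdr_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p
  expect_error(fdr_adjust(numeric(0)), "empty")
  expect_error(fdr_adjust(c(0.5, 0)), "lie in")
})

test_that("outlier-window PCA separates simulated ecomorph clusters", {
  cfg <- sim_config(seed = 17, n_chromosomes = 2, snps_per_chromosome = 2000)
  sim <- simulate_radiation(cfg)
  grp <- css_groups(sim)
  w <- make_windows(sim$genotypes)
  par_win <- unique(w$snp_window[sim$truth$loci$class == "parallel"])
  ing <- sim$samples$sample[sim$samples$ecomorph != "Outgroup"]
  gi <- subset_geno(sim$genotypes, samples = ing)
  pca <- outlier_pca(gi, w, par_win)
  pc1 <- pca$scores[, 1]
  lab <- sim$samples$ecomorph[match(rownames(pca$scores),
                                    sim$samples$sample)]
  # silhouette of the two ecomorph clusters along PC1
  sil <- vapply(seq_along(pc1), function(i) {
    own <- mean(abs(pc1[i] - pc1[lab == lab[i]][-match(i, which(lab == lab[i]))]))
    oth <- mean(abs(pc1[i] - pc1[lab != lab[i]]))
    (oth - own) / max(own, oth)
  }, numeric(1))
  expect_gt(mean(sil, na.rm = TRUE), 0.5)
  expect_lte(sum(pca$var_explained), 1 + 1e-8)
})

test_that("duplicate samples get identical PCA scores", {
  set.seed(18)
  d <- matrix(sample(0:2, 6 * 200, TRUE), 6)
  d <- rbind(d, d[1, ])   # duplicate of sample 1
  g <- toy_geno(d, spacing = 1000)
  w <- make_windows(g)
  pca <- outlier_pca(g, w, seq_len(nrow(w$windows)), ld_r2_max = 1)
  expect_equal(pca$scores[1, ], pca$scores[7, ], tolerance = 1e-8)
})

test_that("trait regression recovers exact and null relationships", {
  set.seed(19)
  x <- rnorm(50)
  out <- trait_regression(x, 2 * x)
  expect_equal(out$r_squared, 1)
  expect_equal(out$slope, 2)
  # independent trait at n = 90: mean R^2 ~ 1/(n-1)
  r2 <- replicate(300, trait_regression(rnorm(90), rnorm(90))$r_squared)
  expect_equal(mean(r2), 1 / 89, tolerance = 0.25)
  # permuted trait: p-values roughly uniform
  p <- replicate(300, trait_regression(x, sample(2 * x))$p_value)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.001)
  expect_error(trait_regression(rep(1, 10), rnorm(10)), "zero variance")
  # stratified fits are appended
  out2 <- trait_regression(x, 2 * x, strata = rep(c("a", "b"), 25))
  expect_equal(nrow(out2), 3)
})
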