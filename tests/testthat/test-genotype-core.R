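test_that("VCF round-trips through write_vcf/read_vcf", {
  g <- toy_geno(matrix(c(0L, 1L, 2L, 2L, 1L, 0L), nrow = 2, byrow = TRUE))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g, path)
  g2 <- read_vcf(path)
  expect_identical(g2$dosages, g$dosages)
  expect_identical(g2$loci$pos, g$loci$pos)
  expect_identical(g2$sample_ids, g$sample_ids)
})

test_that("read_vcf rejects multiallelic records, missing GT and unsorted input", {
  path <- withr::local_tempfile(fileext = ".vcf")
  head <- c("##fileformat=VCFv4.2",
            "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb")
  writeLines(c(head,
               "chr1\t100\t.\tA\tT,G\t.\tPASS\t.\tGT\t0/0\t0/1"), path)
  expect_error(read_vcf(path), "multiallelic.*chr1:100")
  writeLines(c(head,
               "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t./.\t0/1"), path)
  expect_error(read_vcf(path), "missing|unparseable")
  writeLines(c(head,
               "chr1\t200\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1",
               "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1"), path)
  expect_error(read_vcf(path), "not coordinate-sorted")
})

test_that("phased and unphased genotypes give the same dosages", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb",
               "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0|1\t1|1"), path)
  g <- read_vcf(path)
  expect_equal(as.vector(g$dosages), c(1L, 2L))
})

test_that("filter_mac drops monomorphic loci and respects min_mac", {
  # locus 1 monomorphic in subset, locus 2 one heterozygote, locus 3 common
  d <- rbind(c(0L, 1L, 2L),
             c(0L, 0L, 1L),
             c(2L, 2L, 2L))  # sample s3 outside the subset
  g <- toy_geno(d)
  out <- filter_mac(g, subset = c("s1", "s2"), min_mac = 1)
  expect_equal(out$loci$pos, g$loci$pos[2:3])
  expect_equal(n_snps(filter_mac(g, min_mac = 0)), 3)  # identity
  expect_error(filter_mac(g, subset = "nope"), "unknown sample")
  expect_error(filter_mac(g, subset = character(0)), "nonempty")
})

test_that("window assignment follows the floor((pos-1)/size) convention", {
  g <- toy_geno(matrix(0:1, 2, 3), pos = c(1L, 50000L, 50001L))
  w <- make_windows(g, 50000)
  expect_equal(w$snp_window, c(1L, 1L, 2L))       # 50,000 in window 0
  expect_equal(w$windows$start, c(0, 50000))
  expect_equal(w$windows$end, c(50000, 100000))
})

test_that("every SNP falls in exactly one window and counts sum up", {
  sim <- neutral_contrast_sim(5, n_chrom = 3, snps = 500)
  w <- make_windows(sim$genotypes)
  expect_false(anyNA(w$snp_window))
  expect_equal(sum(w$windows$n_snps), n_snps(sim$genotypes))
  # chromosomes absent from the loci get no windows
  expect_setequal(unique(w$windows$chrom), unique(sim$genotypes$loci$chrom))
})

test_that("allele_freqs matches a direct recount and stays in [0,1]", {
  d <- rbind(c(2L, 0L), c(1L, 0L), c(0L, 2L))
  g <- toy_geno(d)
  f <- allele_freqs(g, list(one = "s1", trio = c("s1", "s2", "s3")))
  expect_equal(f[, "one"], c(1, 0))          # single sample, dosage 2 -> 1
  expect_equal(unname(f[1, "trio"]), 0.5)    # dosages {0,1,2} -> 0.5
  # recount oracle on a random 8-sample instance
  set.seed(1)
  d2 <- matrix(sample(0:2, 8 * 20, TRUE), 8)
  g2 <- toy_geno(d2)
  grp <- list(a = c("s1", "s3", "s8"), b = paste0("s", 1:8))
  f2 <- allele_freqs(g2, grp)
  manual <- sapply(grp, function(ids) {
    apply(d2[match(ids, g2$sample_ids), , drop = FALSE], 2, sum) /
      (2 * length(ids))
  })
  expect_equal(unname(f2), unname(manual))
  expect_true(all(f2 >= 0 & f2 <= 1))
  expect_error(allele_freqs(g2, list(a = character(0))), "empty group")
})

test_that("Balding-Nichols lake frequencies average to the ancestral value", {
  # one lake drawn around p0 = 0.3; mean over many draws within binomial bound
  set.seed(42)
  p <- radscan:::rbeta_bn(rep(0.3, 500), 0.1)
  expect_lt(abs(mean(p) - 0.3), 0.03)
})

test_that("ld_prune removes duplicates, keeps independents, is idempotent", {
  set.seed(7)
  base <- matrix(sample(0:2, 200 * 50, TRUE, prob = c(.25, .5, .25)), 200)
  dup <- cbind(base[, 1], base)               # exact duplicate column
  g <- toy_geno(dup, spacing = 10)
  kept <- ld_prune(g, window_bp = 50000, r2_max = 0.95)
  expect_false(all(c(1, 2) %in% kept))        # one copy of the duplicate
  expect_true(2 %in% kept == FALSE || 1 %in% kept == FALSE)
  # mutually independent SNPs at n = 200: >= 99% retained
  g2 <- toy_geno(base, spacing = 10)
  kept2 <- ld_prune(g2, window_bp = 50000, r2_max = 0.95)
  expect_gte(length(kept2) / ncol(base), 0.99)
  # r2_max = 1 keeps everything
  expect_equal(ld_prune(g, window_bp = 50000, r2_max = 1),
               seq_len(ncol(dup)))
  # idempotent: pruning the pruned set changes nothing
  g3 <- subset_geno(g, snps = kept)
  expect_equal(ld_prune(g3, window_bp = 50000, r2_max = 0.95),
               seq_len(n_snps(g3)))
  # postcondition: no retained pair within the window exceeds the threshold
  sub <- g$dosages[, kept]
  r2 <- cor(sub)^2
  close_pairs <- abs(outer(g$loci$pos[kept], g$loci$pos[kept], "-")) < 50000
  diag(close_pairs) <- FALSE
  expect_true(all(r2[close_pairs] <= 0.95 + 1e-9))
})

test_that("interval overlap uses half-open 1-bp semantics and matches brute force", {
  win <- data.frame(chrom = "chr1", start = 0, end = 50000)
  expect_equal(nrow(interval_overlap(
    win, data.frame(chrom = "chr1", start = 49999, end = 60000))), 1)
  expect_equal(nrow(interval_overlap(
    win, data.frame(chrom = "chr1", start = 50000, end = 60000))), 0)
  # quadratic oracle on a toy set
  wins <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                     start = c(0, 100, 0), end = c(100, 200, 100))
  feats <- data.frame(chrom = c("chr1", "chr2"),
                      start = c(50, 500), end = c(150, 600),
                      name = c("g1", "g2"))
  got <- interval_overlap(wins, feats)
  brute <- expand.grid(w = 1:3, f = 1:2)
  brute$hit <- mapply(function(w, f) {
    wins$chrom[w] == feats$chrom[f] &&
      max(wins$start[w], feats$start[f]) < min(wins$end[w], feats$end[f])
  }, brute$w, brute$f)
  expect_setequal(paste(got$window, got$feature),
                  paste(brute$w, brute$f)[brute$hit])
  expect_error(interval_overlap(
    win, data.frame(chrom = "chr1", start = 10, end = 10)), "malformed")
})

test_that("BED and GFF3 readers agree on coordinate conversion", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tgeneA", bed)
  b <- read_bed(bed)
  expect_equal(c(b$start, b$end), c(100, 200))
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=geneA"), gff)
  g <- read_gff3(gff)
  expect_equal(c(g$start, g$end), c(100, 200))  # same interval as the BED
})
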