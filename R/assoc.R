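#' Bonferroni -log10(p) significance threshold
#'
#' `-log10(alpha / n_snps)`, the genome-wide line drawn on a Manhattan plot,
#' reported to two decimals (raw value in attribute `"raw"`).
#'
#' @param alpha family-wise significance level.
#' @param n_snps number of SNPs tested.
#' @return Threshold on the -log10(p) scale, rounded to 2 decimals.
#' @export
bonferroni_threshold <- function(alpha, n_snps) {
  stopifnot(alpha > 0, alpha <= 1, n_snps >= 1)
  raw <- -log10(alpha / n_snps)
  out <- round(raw, 2)
  attr(out, "raw") <- raw
  out
}

#' LD-considerate significance threshold
#'
#' Bonferroni threshold computed over the effective number of tests: the
#' count of SNPs surviving LD pruning (pairs with r-squared above `r2_max`
#' within `window_bp` windows collapsed to one representative).
#'
#' @param g a `geno_matrix`.
#' @param alpha family-wise significance level.
#' @param window_bp,r2_max pruning parameters (defaults 50 kb, 0.95).
#' @return list with `n_effective` and `threshold` (-log10 scale, 2 dp,
#'   raw value in its `"raw"` attribute).
#' @export
ld_considerate_threshold <- function(g, alpha = 0.05, window_bp = 50000,
                                     r2_max = 0.95) {
  kept <- ld_prune(g, window_bp = window_bp, r2_max = r2_max)
  list(n_effective = length(kept),
       threshold = bonferroni_threshold(alpha, length(kept)))
}

#' Percent variance explained by a single SNP
#'
#' PVE = (2 beta^2 MAF (1 - MAF)) /
#'       (2 beta^2 MAF (1 - MAF) + se_beta^2 2 N MAF (1 - MAF)),
#' computed from a SNP's effect size, its standard error, the minor allele
#' frequency and the sample size. Monotone increasing in |beta| and
#' decreasing in se_beta; lies in [0, 1).
#'
#' @param beta SNP effect size (trait units per allele).
#' @param se_beta standard error of `beta`.
#' @param maf minor allele frequency, strictly inside (0, 1).
#' @param n sample size.
#' @return Fraction of phenotypic variance explained.
#' @export
pve <- function(beta, se_beta, maf, n) {
  if (any(maf <= 0 | maf >= 1)) stop("maf must lie strictly in (0, 1)")
  stopifnot(n >= 1)
  num <- 2 * beta^2 * maf * (1 - maf)
  num / (num + se_beta^2 * 2 * n * maf * (1 - maf))
}

#' Per-group allele frequency profile at one SNP
#'
#' Reports the alt-allele frequency of each group at a focal SNP alongside
#' the group's mean trait value — the display used to show a large-effect
#' locus tracking an ecomorph-graded trait.
#'
#' @param g a `geno_matrix`.
#' @param samples metadata data.frame (see [read_sample_table()]).
#' @param chrom,pos coordinates of the SNP.
#' @param grouping metadata column(s) to group by: `"ecomorph"` (default) or
#'   e.g. `c("ecomorph", "lake")`.
#' @param trait metadata column holding the trait (default
#'   `"gill_raker_count"`).
#' @return data.frame with `group`, `n`, `freq`, `trait_mean`.
#' @export
group_allele_freqs <- function(g, samples, chrom, pos,
                               grouping = "ecomorph",
                               trait = "gill_raker_count") {
  snp <- which(g$loci$chrom == chrom & g$loci$pos == pos)
  if (length(snp) != 1) stop("SNP ", chrom, ":", pos, " not found")
  groups <- group_samples(samples, by = grouping,
                          restrict = g$sample_ids)
  if (any(lengths(groups) == 0)) stop("empty group")
  freq <- vapply(groups, function(ids) {
    mean(g$dosages[sample_index(g, ids), snp]) / 2
  }, numeric(1))
  tmean <- vapply(groups, function(ids) {
    mean(samples[[trait]][match(ids, samples$sample)])
  }, numeric(1))
  data.frame(group = names(groups), n = lengths(groups), freq = freq,
             trait_mean = tmean, row.names = NULL, stringsAsFactors = FALSE)
}

#' Single-locus association scan (ordinary least squares)
#'
#' Per-SNP OLS of the trait on alt-allele dosage, optionally adjusting for
#' covariates (e.g. principal components), with the Wald p-value of the
#' dosage slope. Binary traits are handled by the same linear scoring.
#' Monomorphic SNPs are skipped. This is a plumbing-grade scan for
#' synthetic-data testing, not a mixed-model GWAS: its output schema matches
#' what [pve()] consumes.
#'
#' @param g a `geno_matrix`.
#' @param trait named numeric vector (names = sample ids) or a vector
#'   aligned with `g$sample_ids`; must be complete.
#' @param covariates optional numeric matrix of covariates (rows aligned
#'   with the samples used).
#' @return data.frame: `chrom`, `pos`, `beta`, `se_beta`, `p`, `maf`, `n`.
#' @export
simple_assoc_scan <- function(g, trait, covariates = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  if (!is.null(names(trait))) {
    trait <- trait[g$sample_ids]
  }
  if (length(trait) != length(g$sample_ids) || anyNA(trait)) {
    stop("trait must be complete and cover every sample")
  }
  n <- length(trait)
  x <- g$dosages
  # residualise trait and dosages on intercept + covariates
  z <- cbind(rep(1, n), covariates)
  qz <- qr(z)
  y_r <- stats::residuals(stats::lm.fit(z, trait))
  x_r <- x - z %*% qr.coef(qz, x)
  ssx <- colSums(x_r^2)
  poly <- ssx > 1e-12
  if (!any(poly)) stop("all SNPs are monomorphic")
  df <- n - ncol(z) - 1
  if (df < 1) stop("not enough samples for the model")
  beta <- as.vector(crossprod(x_r[, poly, drop = FALSE], y_r)) / ssx[poly]
  rss <- sum(y_r^2) - beta^2 * ssx[poly]
  rss <- pmax(rss, 0)
  sigma2 <- rss / df
  se <- sqrt(sigma2 / ssx[poly])
  tstat <- beta / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  f <- colMeans(x[, poly, drop = FALSE]) / 2
  data.frame(chrom = g$loci$chrom[poly], pos = g$loci$pos[poly],
             beta = beta, se_beta = se, p = p,
             maf = pmin(f, 1 - f), n = n, stringsAsFactors = FALSE)
}
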