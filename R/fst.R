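#' Weir-Cockerham variance components per SNP for two populations
#'
#' Implements the Weir & Cockerham (1984) two-level estimator from genotype
#' counts, including the observed-heterozygosity term: per SNP the
#' among-population (a), among-individual-within-population (b) and
#' within-individual (c) components are returned together with
#' theta = a / (a + b + c). Theta may be negative; SNPs with
#' a + b + c = 0 (no variation) are returned as `NA` theta.
#'
#' @param g a `geno_matrix`.
#' @param pop1,pop2 sample ids of the two populations (each >= 2 diploids).
#' @return data.frame, one row per SNP: `chrom`, `pos`, `a`, `b`, `c`,
#'   `theta`.
#' @export
wc_fst <- function(g, pop1, pop2) {
  stopifnot(inherits(g, "geno_matrix"))
  i1 <- sample_index(g, pop1)
  i2 <- sample_index(g, pop2)
  if (length(i1) < 2 || length(i2) < 2) {
    stop("each population needs at least two diploid individuals")
  }
  d1 <- g$dosages[i1, , drop = FALSE]
  d2 <- g$dosages[i2, , drop = FALSE]
  comp <- wc_components(colMeans(d1) / 2, colMeans(d2) / 2,
                        colMeans(d1 == 1), colMeans(d2 == 1),
                        length(i1), length(i2))
  data.frame(chrom = g$loci$chrom, pos = g$loci$pos,
             a = comp$a, b = comp$b, c = comp$c, theta = comp$theta,
             stringsAsFactors = FALSE)
}

# vectorised W&C (1984) components for r = 2 populations; p = alt freq,
# h = observed het proportion, n = diploid counts
wc_components <- function(p1, p2, h1, h2, n1, n2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  tot <- a + b + c
  theta <- ifelse(abs(tot) < 1e-300, NA_real_, a / tot)
  list(a = a, b = b, c = c, theta = theta)
}

#' Windowed Weir-Cockerham F_ST between two populations
#'
#' Per window the ratio-of-sums ("weighted") estimate
#' `sum(a) / sum(a + b + c)` and the mean of per-SNP theta are reported.
#' SNPs with undefined theta are excluded from both (with a message);
#' negative per-SNP components are retained in the sums, matching the
#' estimator's definition. Windows with fewer than `min_snps` usable SNPs
#' are removed.
#'
#' @param g a `geno_matrix` (apply [filter_mac()] over the union of the two
#'   populations first, mirroring a `--mac 1` pre-filter).
#' @param windows a `window_set`.
#' @param pop1,pop2 sample ids.
#' @param min_snps minimum usable SNPs per window (default 10).
#' @return data.frame: `chrom`, `start`, `end`, `n_snps`, `fst_weighted`,
#'   `fst_mean`, with attribute `window_index` giving the retained rows of
#'   `windows$windows`.
#' @export
windowed_fst <- function(g, windows, pop1, pop2, min_snps = 10) {
  stopifnot(inherits(windows, "window_set"))
  per_snp <- wc_fst(g, pop1, pop2)
  usable <- !is.na(per_snp$theta)
  if (any(!usable)) {
    message(sum(!usable), " SNP(s) with undefined theta skipped")
  }
  wid <- windows$snp_window
  nw <- nrow(windows$windows)
  sum_by <- function(x) {
    out <- numeric(nw)
    t <- tapply(x, wid, sum)
    out[as.integer(names(t))] <- t
    out
  }
  au <- ifelse(usable, per_snp$a, 0)
  tu <- ifelse(usable, per_snp$a + per_snp$b + per_snp$c, 0)
  thu <- ifelse(usable, per_snp$theta, 0)
  n_use <- sum_by(as.numeric(usable))
  a_sum <- sum_by(au)
  t_sum <- sum_by(tu)
  th_sum <- sum_by(thu)
  keep <- which(n_use >= min_snps)
  if (length(keep) == 0) stop("no window has at least ", min_snps, " SNPs")
  out <- data.frame(
    chrom = windows$windows$chrom[keep],
    start = windows$windows$start[keep],
    end = windows$windows$end[keep],
    n_snps = as.integer(n_use[keep]),
    fst_weighted = a_sum[keep] / t_sum[keep],
    fst_mean = th_sum[keep] / n_use[keep],
    stringsAsFactors = FALSE
  )
  attr(out, "window_index") <- keep
  out
}

#' Top-percentile F_ST outlier windows
#'
#' Flags the `ceiling(fraction * W)` windows with the highest weighted F_ST;
#' ties are broken by genomic order (earlier windows kept first).
#'
#' @param records data.frame from [windowed_fst()].
#' @param fraction outlier fraction (default 0.01, the top percentile).
#' @param rank_by `"fst_weighted"` (default) or `"fst_mean"`.
#' @return The input with an added logical `outlier` column.
#' @export
top_percentile_outliers <- function(records, fraction = 0.01,
                                    rank_by = c("fst_weighted", "fst_mean")) {
  rank_by <- match.arg(rank_by)
  if (nrow(records) == 0) stop("empty record set")
  k <- ceiling(fraction * nrow(records))
  ord <- order(-records[[rank_by]], records$chrom, records$start)
  records$outlier <- FALSE
  records$outlier[ord[seq_len(k)]] <- TRUE
  records
}

#' Expected count of outlier windows shared by chance across k lakes
#'
#' With an outlier fraction q applied independently in each of L lakes over
#' the same W windows, the expected number of windows that are outliers in a
#' given set of k lakes is q^k * W, and summing over the C(L, k) lake
#' combinations gives `q^k * W * choose(L, k)`.
#'
#' @param q outlier fraction per scan.
#' @param W total window count.
#' @param L number of lakes (independent scans).
#' @param k number of lakes sharing (2 <= k <= L).
#' @return Expected shared-window count.
#' @export
expected_overlap <- function(q, W, L, k) {
  if (k > L) stop("k cannot exceed L")
  if (k < 2) stop("sharing requires k >= 2")
  q^k * W * choose(L, k)
}

#' Observed vs expected sharing of outlier windows across lakes
#'
#' @param outlier_sets named list (one element per lake) of window
#'   identifiers (integer indices into a common window grid, or any common
#'   key such as `"chrom:start"`).
#' @param W total number of windows in the common grid.
#' @param q outlier fraction used in each scan (default 0.01).
#' @return data.frame with one row per k in 2..L: `k`, `observed_exact`
#'   (windows in exactly k sets), `observed_at_least` (windows in >= k
#'   sets; the headline count), and `expected` from [expected_overlap()].
#' @export
shared_outlier_windows <- function(outlier_sets, W, q = 0.01) {
  L <- length(outlier_sets)
  if (L < 2) stop("need at least two outlier sets")
  tab <- table(unlist(lapply(outlier_sets, unique)))
  ks <- 2:L
  data.frame(
    k = ks,
    observed_exact = vapply(ks, function(k) sum(tab == k), numeric(1)),
    observed_at_least = vapply(ks, function(k) sum(tab >= k), numeric(1)),
    expected = vapply(ks, function(k) expected_overlap(q, W, L, k),
                      numeric(1))
  )
}
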