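#' Cluster separation score for one window
#'
#' Pairwise distances between individuals are Euclidean distances of their
#' dosage vectors divided by the window's SNP count. Individuals are embedded
#' by classical multidimensional scaling retaining all positive-eigenvalue
#' axes (distance-preserving for this metric) and the score is
#'
#' CSS = mean between-group distance
#'       - (m * mean within-group-1 + n * mean within-group-2) / (m + n)
#'
#' where within-group means use the 2 / (k (k - 1)) pair normalisation. The
#' score is invariant to SNP column order and to swapping the group labels.
#'
#' @param dosages numeric matrix, individuals x SNPs, for one window.
#' @param group1,group2 row indices (or logical masks) of the two groups;
#'   each must contain at least two individuals.
#' @return The CSS score (a single number; 0 when all individuals coincide).
#' @export
css_window <- function(dosages, group1, group2) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) < 1) stop("window has zero SNPs")
  idx1 <- if (is.logical(group1)) which(group1) else as.integer(group1)
  idx2 <- if (is.logical(group2)) which(group2) else as.integer(group2)
  m <- length(idx1); n <- length(idx2)
  if (m < 2 || n < 2) stop("each group needs at least two individuals")
  if (length(intersect(idx1, idx2))) stop("groups overlap")
  sub <- dosages[c(idx1, idx2), , drop = FALSE]
  d0 <- stats::dist(sub) / ncol(dosages)
  if (max(d0) == 0) return(0)
  # distance-preserving MDS embedding (all positive-eigenvalue axes)
  k <- min(nrow(sub) - 1, ncol(sub))
  mds <- suppressWarnings(stats::cmdscale(d0, k = k, eig = TRUE))
  coords <- mds$points[, mds$eig[seq_len(ncol(mds$points))] > 1e-12,
                       drop = FALSE]
  d <- as.matrix(stats::dist(coords))
  g1 <- seq_len(m); g2 <- m + seq_len(n)
  between <- mean(d[g1, g2])
  within1 <- sum(d[g1, g1]) / (m * (m - 1))   # = mean over unordered pairs
  within2 <- sum(d[g2, g2]) / (n * (n - 1))
  between - (m * within1 + n * within2) / (m + n)
}

#' Define a two-group contrast with lake strata for the CSS scan
#'
#' @param group1,group2 sample ids of the two ecomorph groups.
#' @param strata named list mapping stratum label (lake) to the sample ids it
#'   contains; the strata must partition the union of the groups and every
#'   stratum must contain members of both groups (otherwise the stratified
#'   shuffle could not exchange labels there).
#' @param n_permutations permutations for the sampled null (default 1e5).
#' @param min_snps windows with fewer SNPs are dropped (default 24).
#' @param fdr_level outlier cut-off on the q-value (default 0.01).
#' @param mode `"auto"` picks exact enumeration when the stratified
#'   assignment count is at most `exact_max`, else Monte-Carlo sampling;
#'   `"exact"` and `"sampled"` force one engine.
#' @param exact_max assignment-count ceiling for automatic exact enumeration.
#' @param seed RNG seed for the sampled engine.
#' @return A list of class `css_design`.
#' @export
css_design <- function(group1, group2, strata,
                       n_permutations = 100000, min_snps = 24,
                       fdr_level = 0.01,
                       mode = c("auto", "sampled", "exact"),
                       exact_max = 200000, seed = 1) {
  mode <- match.arg(mode)
  all_ids <- c(group1, group2)
  if (anyDuplicated(all_ids)) stop("groups overlap or contain duplicates")
  if (!setequal(unlist(strata), all_ids)) {
    stop("strata must partition the union of group1 and group2")
  }
  for (s in names(strata)) {
    ids <- strata[[s]]
    if (!any(ids %in% group1) || !any(ids %in% group2)) {
      stop("stratum '", s, "' has all its samples in one group")
    }
  }
  structure(list(group1 = group1, group2 = group2, strata = strata,
                 n_permutations = n_permutations, min_snps = min_snps,
                 fdr_level = fdr_level, mode = mode, exact_max = exact_max,
                 seed = as.integer(seed)),
            class = "css_design")
}

# number of distinct stratified assignments (product of per-stratum
# binomial coefficients)
stratified_assignment_count <- function(design) {
  prod(vapply(design$strata, function(ids) {
    choose(length(ids), sum(ids %in% design$group1))
  }, numeric(1)))
}

# assignment matrix: one column per permutation, TRUE = sample plays group1.
# Row order follows `ids`. Column 1 is the observed assignment.
stratified_assignments <- function(design, ids, exact) {
  obs <- ids %in% design$group1
  strata_idx <- lapply(design$strata, function(s) match(s, ids))
  m_per <- lapply(strata_idx, function(ix) sum(obs[ix]))
  if (exact) {
    per_stratum <- mapply(function(ix, m) {
      utils::combn(length(ix), m, simplify = FALSE)
    }, strata_idx, m_per, SIMPLIFY = FALSE)
    grid <- expand.grid(lapply(per_stratum, seq_along))
    n_tot <- nrow(grid)
    out <- matrix(FALSE, length(ids), n_tot)
    for (s in seq_along(strata_idx)) {
      ix <- strata_idx[[s]]
      choices <- vapply(per_stratum[[s]], function(ch) ix[ch],
                        integer(m_per[[s]]))
      choices <- matrix(choices, nrow = m_per[[s]])
      rows <- as.vector(choices[, grid[, s], drop = FALSE])
      cols <- rep(seq_len(n_tot), each = m_per[[s]])
      out[cbind(rows, cols)] <- TRUE
    }
    out
  } else {
    n <- design$n_permutations
    out <- matrix(FALSE, length(ids), n + 1)
    out[, 1] <- obs
    for (j in seq_len(n) + 1) {
      for (s in seq_along(strata_idx)) {
        ix <- strata_idx[[s]]
        out[sample(ix, m_per[[s]]), j] <- TRUE
      }
    }
    out
  }
}

# pair-weight matrix turning a pair-distance vector into CSS scores:
# css = t(D_pairs) %*% W  for each assignment column
css_pair_weights <- function(assign, pair_i, pair_j, m, n) {
  a_i <- assign[pair_i, , drop = FALSE]
  a_j <- assign[pair_j, , drop = FALSE]
  between <- a_i != a_j
  within1 <- a_i & a_j
  w_b <- 1 / (m * n)
  w_1 <- -(m / (m + n)) * 2 / (m * (m - 1))
  w_2 <- -(n / (m + n)) * 2 / (n * (n - 1))
  between * w_b + within1 * w_1 + (!between & !within1) * w_2
}

#' Windowed CSS scan with a stratified permutation null
#'
#' For every window with at least `min_snps` SNPs the cluster separation
#' score is computed between the two groups, and its significance assessed
#' against a null in which group labels are reshuffled within each stratum
#' (lake), preserving per-stratum group counts and hence the population
#' structure. One shared permutation set is evaluated against all windows.
#' Sampled p-values use the add-one rule, p = (1 + #\{perm >= obs\}) /
#' (1 + N), so p is never zero; in exact mode every distinct stratified
#' assignment is enumerated and p is the exact tail proportion. Q-values are
#' computed with [fdr_adjust()] and windows with q <= `fdr_level` are flagged
#' as outliers.
#'
#' @param g a `geno_matrix`.
#' @param windows a `window_set` from [make_windows()].
#' @param design a [css_design()].
#' @return data.frame (one row per retained window): `chrom`, `start`,
#'   `end`, `n_snps`, `css`, `p_perm`, `q_value`, `outlier`. The permutation
#'   engine and seed are recorded in attributes `engine`, `n_perm`, `seed`.
#' @export
css_scan <- function(g, windows, design) {
  stopifnot(inherits(g, "geno_matrix"), inherits(windows, "window_set"),
            inherits(design, "css_design"))
  ids <- c(design$group1, design$group2)
  ridx <- sample_index(g, ids)
  m <- length(design$group1); n <- length(design$group2)
  if (m < 2 || n < 2) stop("each group needs at least two individuals")
  keep <- which(windows$windows$n_snps >= design$min_snps)
  if (length(keep) == 0) {
    stop("no window has at least ", design$min_snps, " SNPs")
  }
  n_count <- stratified_assignment_count(design)
  exact <- switch(design$mode,
                  exact = TRUE, sampled = FALSE,
                  auto = n_count <= design$exact_max)
  set.seed(design$seed)
  assign <- stratified_assignments(design, ids, exact)

  pairs <- utils::combn(length(ids), 2)
  pair_i <- pairs[1, ]; pair_j <- pairs[2, ]

  # per-window pair-distance rows (Euclidean / SNP count; MDS-preserved)
  dmat <- matrix(0, length(keep), ncol(pairs))
  for (w in seq_along(keep)) {
    snps <- which(windows$snp_window == keep[w])
    sub <- g$dosages[ridx, snps, drop = FALSE]
    dmat[w, ] <- as.vector(stats::dist(sub)) / length(snps)
  }

  obs_w <- css_pair_weights(
    matrix(ids %in% design$group1, ncol = 1), pair_i, pair_j, m, n)
  obs <- as.vector(dmat %*% obs_w)

  # evaluate permutation columns in chunks to bound memory
  n_cols <- ncol(assign)
  ge_count <- integer(length(keep))
  chunk <- 20000L
  first_col <- if (exact) 1L else 2L   # sampled: col 1 is the observed labels
  cols <- seq(first_col, n_cols)
  for (start in seq(1, length(cols), by = chunk)) {
    cc <- cols[start:min(start + chunk - 1, length(cols))]
    w <- css_pair_weights(assign[, cc, drop = FALSE], pair_i, pair_j, m, n)
    perm <- dmat %*% w
    ge_count <- ge_count + rowSums(perm >= obs - 1e-12)
  }
  if (exact) {
    p <- ge_count / n_count
    engine <- "exact"
    n_perm <- n_count
  } else {
    p <- (1 + ge_count) / (1 + design$n_permutations)
    engine <- "sampled"
    n_perm <- design$n_permutations
  }
  q <- fdr_adjust(p)
  out <- data.frame(
    chrom = windows$windows$chrom[keep],
    start = windows$windows$start[keep],
    end = windows$windows$end[keep],
    n_snps = windows$windows$n_snps[keep],
    css = obs, p_perm = p, q_value = q,
    outlier = q <= design$fdr_level,
    stringsAsFactors = FALSE
  )
  attr(out, "engine") <- engine
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- design$seed
  attr(out, "window_index") <- keep
  out
}

#' FDR adjustment of permutation p-values
#'
#' Benjamini-Hochberg by default; `method = "storey"` additionally estimates
#' the null proportion pi0 on a lambda grid (0.05-0.95) with cubic-spline
#' smoothing and scales the BH values by it (Storey q-values). With pi0
#' forced to 1 the two methods coincide. Output is monotone non-decreasing
#' in p.
#'
#' @param p p-values in (0, 1].
#' @param method `"BH"` or `"storey"`.
#' @param pi0 optional fixed null proportion overriding the estimate.
#' @return q-values, same length as `p`.
#' @export
fdr_adjust <- function(p, method = c("BH", "storey"), pi0 = NULL) {
  method <- match.arg(method)
  if (length(p) == 0) stop("empty p-value vector")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  bh <- stats::p.adjust(p, method = "BH")
  if (method == "BH") return(bh)
  if (is.null(pi0)) {
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
  }
  pi0 <- min(max(pi0, 1e-8), 1)
  pmin(pi0 * bh, 1)
}

#' PCA of samples restricted to outlier-window SNPs
#'
#' SNPs are restricted to the given outlier windows, LD-pruned, mean-centred
#' and decomposed by singular values. Each PC's sign is fixed so that its
#' loading sum is non-negative, making scores reproducible.
#'
#' @param g a `geno_matrix` (typically all samples, not only those used to
#'   call the outliers).
#' @param windows the `window_set` used in the scan.
#' @param outlier_windows integer indices into `windows$windows` (e.g. the
#'   `window_index` attribute of a scan result subset to `outlier == TRUE`).
#' @param ld_window_bp,ld_r2_max LD-pruning parameters applied to the
#'   outlier-window SNPs before the decomposition.
#' @return list with `scores` (samples x PCs), `var_explained`, and
#'   `snp_index` (retained SNP columns of `g`).
#' @export
outlier_pca <- function(g, windows, outlier_windows,
                        ld_window_bp = 50000, ld_r2_max = 0.1) {
  stopifnot(inherits(g, "geno_matrix"), inherits(windows, "window_set"))
  if (length(outlier_windows) < 1) stop("no outlier windows supplied")
  snps <- which(windows$snp_window %in% outlier_windows)
  if (length(snps) < 2) stop("fewer than 2 SNPs fall in the outlier windows")
  sub <- subset_geno(g, snps = snps)
  kept <- ld_prune(sub, window_bp = ld_window_bp, r2_max = ld_r2_max)
  x <- scale(sub$dosages[, kept, drop = FALSE], center = TRUE, scale = FALSE)
  sv <- svd(x)
  flip <- ifelse(colSums(sv$v) < 0, -1, 1)
  scores <- sweep(sv$u %*% diag(sv$d, nrow = length(sv$d)), 2, flip, `*`)
  rownames(scores) <- g$sample_ids
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  list(scores = scores,
       var_explained = sv$d^2 / sum(sv$d^2),
       snp_index = snps[kept])
}

#' Regress a trait on a principal component
#'
#' Ordinary least squares with the overall F-test p-value; when `strata` is
#' supplied, per-stratum fits are appended (e.g. per lake system).
#'
#' @param pc_scores numeric predictor (e.g. PC1 scores).
#' @param trait numeric response, same length.
#' @param strata optional factor of stratum labels for stratified fits.
#' @return data.frame with `group`, `n`, `slope`, `r_squared`, `p_value`.
#' @export
trait_regression <- function(pc_scores, trait, strata = NULL) {
  fit_one <- function(x, y, label) {
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3) {
      return(data.frame(group = label, n = length(x), slope = NA_real_,
                        r_squared = NA_real_, p_value = NA_real_))
    }
    if (stats::var(x) == 0) stop("zero variance in predictor (", label, ")")
    fit <- stats::lm(y ~ x)
    s <- summary(fit)
    pv <- stats::pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                    lower.tail = FALSE)
    data.frame(group = label, n = length(x),
               slope = unname(stats::coef(fit)[2]),
               r_squared = s$r.squared, p_value = unname(pv))
  }
  out <- fit_one(pc_scores, trait, "all")
  if (!is.null(strata)) {
    for (s in unique(as.character(strata))) {
      sel <- as.character(strata) == s
      out <- rbind(out, fit_one(pc_scores[sel], trait[sel], s))
    }
  }
  rownames(out) <- NULL
  out
}
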