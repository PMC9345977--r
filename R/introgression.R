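#' Four-taxon F4 statistic
#'
#' Mean over SNPs of (p_A - p_B)(p_C - p_D). Antisymmetric in each pair and
#' symmetric under swapping the pairs; the three distinct quartet
#' arrangements sum to zero at every SNP set.
#'
#' @param p_a,p_b,p_c,p_d per-SNP allele frequencies (equal length).
#' @return F4 value.
#' @export
f4_stat <- function(p_a, p_b, p_c, p_d) {
  ok <- stats::complete.cases(p_a, p_b, p_c, p_d)
  if (!any(ok)) stop("no SNP with all four frequencies defined")
  mean((p_a[ok] - p_b[ok]) * (p_c[ok] - p_d[ok]))
}

#' F4 topology contrast for two sympatric ecomorph pairs
#'
#' Compares the two four-taxon arrangements of a pair of lakes each holding
#' the two contrast ecomorphs. F4_1 places the sympatric pair of lake 1
#' against the sympatric pair of lake 2, ((B1, A1), (B2, A2)): correlated
#' allele frequencies here indicate a single ecomorph origin followed by
#' sorting into lakes. F4_2 places same-ecomorph species together,
#' ((B1, B2), (A1, A2)): correlated frequencies here reflect shared
#' within-lake history, i.e. truly sympatric pairs. Where |F4_1| < |F4_2|
#' the parallel within-lake origin is supported.
#'
#' @param freqs numeric matrix (SNPs x populations) with named columns.
#' @param balchen1,albeli1 column names of the two ecomorphs in lake 1.
#' @param balchen2,albeli2 column names of the two ecomorphs in lake 2.
#' @return list with `f4_sympatric` (F4_1), `f4_ecomorph` (F4_2), and
#'   `verdict`: `"parallel within-lake origin"`, `"single ecomorph origin"`,
#'   or `"indeterminate"` when the magnitudes coincide.
#' @export
topology_contrast <- function(freqs, balchen1, albeli1, balchen2, albeli2) {
  pops <- c(balchen1, albeli1, balchen2, albeli2)
  if (anyDuplicated(pops)) stop("the four populations must be distinct")
  if (!all(pops %in% colnames(freqs))) {
    stop("missing frequency column(s): ",
         paste(setdiff(pops, colnames(freqs)), collapse = ", "))
  }
  f4_1 <- f4_stat(freqs[, balchen1], freqs[, albeli1],
                  freqs[, balchen2], freqs[, albeli2])
  f4_2 <- f4_stat(freqs[, balchen1], freqs[, balchen2],
                  freqs[, albeli1], freqs[, albeli2])
  verdict <- if (abs(f4_1) < abs(f4_2)) {
    "parallel within-lake origin"
  } else if (abs(f4_1) > abs(f4_2)) {
    "single ecomorph origin"
  } else "indeterminate"
  list(f4_sympatric = f4_1, f4_ecomorph = f4_2, verdict = verdict)
}

# per-site ABBA/BABA building blocks for ((A, B), C, O).
# The f4-ratio denominator substitutes C for B (donor into itself); pC then
# enters squared, and with a finite sample of n_c haploid alleles
# E[pC^2] = p^2 + p(1-p)/n_c, so the unbiased pC^2 estimate
# pC^2 - pC(1-pC)/(n_c - 1) is used when n_c is supplied.
abba_baba_sites <- function(p_a, p_b, p_c, p_o, n_c = NULL) {
  abba <- (1 - p_a) * p_b * p_c * (1 - p_o)
  baba <- p_a * (1 - p_b) * p_c * (1 - p_o)
  pc2 <- if (!is.null(n_c) && is.finite(n_c)) {
    p_c^2 - p_c * (1 - p_c) / (n_c - 1)
  } else {
    p_c^2
  }
  den_f <- (pc2 - p_a * p_c) * (1 - p_o)
  list(num = abba - baba, den_d = abba + baba, den_f = den_f)
}

#' Patterson's D and the f4-admixture ratio
#'
#' For the relationship ((A, B), C) with outgroup O, per-site
#' ABBA = (1 - pA) pB pC (1 - pO) and BABA = pA (1 - pB) pC (1 - pO);
#' D = sum(ABBA - BABA) / sum(ABBA + BABA). The f4-admixture ratio divides
#' the same numerator by the donor-into-itself denominator in which C's
#' frequencies replace B's, estimating the admixture fraction from C into B.
#' Supplying `n_c` (the haploid sample size behind the C frequencies)
#' applies the unbiased small-sample correction to the squared pC term;
#' leave it `NULL` when the frequencies are population values.
#'
#' @param p_a,p_b,p_c,p_o per-SNP allele frequencies.
#' @param n_c optional haploid sample size of population C.
#' @return list with `d`, `f`, and the summed `num`, `den_d`, `den_f`
#'   (either ratio is `NA` when its denominator is zero).
#' @export
d_and_f4ratio <- function(p_a, p_b, p_c, p_o, n_c = NULL) {
  ok <- stats::complete.cases(p_a, p_b, p_c, p_o)
  if (!any(ok)) stop("no usable SNPs")
  s <- abba_baba_sites(p_a[ok], p_b[ok], p_c[ok], p_o[ok], n_c)
  num <- sum(s$num); den_d <- sum(s$den_d); den_f <- sum(s$den_f)
  d <- if (den_d == 0) NA_real_ else num / den_d
  f <- if (den_f == 0) NA_real_ else num / den_f
  list(d = d, f = f, num = num, den_d = den_d, den_f = den_f)
}

#' Delete-one-block jackknife Z-score for a ratio statistic
#'
#' Sites are grouped into `n_blocks` contiguous equal-count blocks; the
#' ratio sum(num)/sum(den) is recomputed with each block deleted and the
#' jackknife standard error SE^2 = (B-1)/B * sum((theta_j - mean)^2) yields
#' Z = estimate / SE. A degenerate SE of zero returns a signed infinite Z
#' with a warning.
#'
#' @param num,den per-site numerator and denominator streams (equal length,
#'   in genome order).
#' @param n_blocks number of contiguous blocks (default 20; must be >= 2 and
#'   <= number of sites).
#' @return list with `estimate`, `se`, `z`, `n_blocks`.
#' @export
jackknife_z <- function(num, den, n_blocks = 20) {
  stopifnot(length(num) == length(den))
  n <- length(num)
  if (n_blocks < 2) stop("need at least two blocks")
  if (n < n_blocks) stop("fewer sites than blocks")
  blk <- make_blocks(n, n_blocks)
  bn <- vapply(split(num, blk), sum, numeric(1))
  bd <- vapply(split(den, blk), sum, numeric(1))
  est <- sum(bn) / sum(bd)
  loo <- (sum(bn) - bn) / (sum(bd) - bd)
  se <- sqrt((n_blocks - 1) / n_blocks * sum((loo - mean(loo))^2))
  if (se == 0) {
    warning("jackknife SE is zero; Z reported as signed infinity")
    z <- sign(est) * Inf
    if (est == 0) z <- 0
  } else {
    z <- est / se
  }
  list(estimate = est, se = se, z = z, n_blocks = n_blocks)
}

# contiguous equal-count block labels 1..b for n sites
make_blocks <- function(n, b) {
  sizes <- rep(n %/% b, b)
  extra <- n %% b
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  rep(seq_len(b), times = sizes)
}

#' Bonferroni-corrected one-sided Z threshold
#'
#' The upper-tail standard-normal quantile of `alpha / n_tests`, reported to
#' two decimals: the Z-score a test statistic must exceed for one-sided
#' significance at family-wise level `alpha` over `n_tests` tests.
#'
#' @param alpha family-wise significance level in (0, 1).
#' @param n_tests number of tests (e.g. computable f-branch cells).
#' @return Z threshold rounded to 2 decimals (raw value in attribute
#'   `"raw"`).
#' @export
bonferroni_z_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  raw <- stats::qnorm(alpha / n_tests, lower.tail = FALSE)
  out <- round(raw, 2)
  attr(out, "raw") <- raw
  out
}

# ---- tree machinery -------------------------------------------------------

# validate rooted binary tree with the outgroup a direct child of the root;
# returns list(tree, root, outgroup_tip_index)
check_group_tree <- function(tree, outgroup) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object or Newick")
  if (!ape::is.binary(tree)) stop("tree must be fully resolved (binary)")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique")
  if (!outgroup %in% tree$tip.label) {
    stop("outgroup '", outgroup, "' is not a tip of the tree")
  }
  root <- ape::Ntip(tree) + 1
  og <- match(outgroup, tree$tip.label)
  root_children <- tree$edge[tree$edge[, 1] == root, 2]
  if (!og %in% root_children) {
    stop("outgroup must be a direct child of the root")
  }
  list(tree = tree, root = root, outgroup = og)
}

node_children <- function(tree, node) tree$edge[tree$edge[, 1] == node, 2]

node_tips <- function(tree, node) {
  nt <- ape::Ntip(tree)
  if (node <= nt) return(tree$tip.label[node])
  tree$tip.label[unlist(ape::prop.part(tree)[node - nt])]
}

node_label <- function(tree, node) {
  nt <- ape::Ntip(tree)
  if (node <= nt) return(tree$tip.label[node])
  tips <- node_tips(tree, node)
  paste0("mrca(", paste(sort(tips), collapse = "+"), ")")
}

#' Tree-guided excess allele-sharing: the f-branch matrix
#'
#' For every branch b of the rooted population tree (tips and internal
#' nodes, excluding the root and the outgroup) with sister clade a, and
#' every donor tip C outside both clades, the statistic
#' f_b(C) = median over recipients B in clade(b) of the minimum over
#' references A in clade(a) of the f4-admixture ratio f(A, B; C, O),
#' with negative values floored at zero. Combinations that violate the tree
#' topology (C inside clade(a) or clade(b), or C the outgroup) are marked
#' untestable (`NA`). Z-scores come from a delete-one-block jackknife of the
#' whole median-of-minima statistic, and cells with Z above the one-sided
#' Bonferroni threshold [bonferroni_z_threshold()] over the computable cells
#' are flagged significant.
#'
#' @param tree rooted binary `phylo` object or Newick string; tip labels
#'   must match the columns of `freqs`.
#' @param freqs numeric matrix, SNPs (in genome order) x population tips.
#' @param outgroup tip label of the outgroup.
#' @param n_blocks jackknife blocks (default 20).
#' @param sample_sizes optional named vector of haploid sample sizes per tip
#'   for the unbiased donor-denominator correction.
#' @param alpha family-wise level for the significance flags (default 0.01).
#' @return list of class `fbranch` with matrices `fb`, `z`, `significant`
#'   (branches x donors; `NA` marks untestable cells), the `threshold`,
#'   `n_testable`, and a long-format data.frame `table`.
#' @export
fbranch <- function(tree, freqs, outgroup, n_blocks = 20,
                    sample_sizes = NULL, alpha = 0.01) {
  ct <- check_group_tree(tree, outgroup)
  tree <- ct$tree
  tips <- tree$tip.label
  if (!all(tips %in% colnames(freqs))) {
    stop("missing frequency column(s): ",
         paste(setdiff(tips, colnames(freqs)), collapse = ", "))
  }
  nt <- ape::Ntip(tree)
  n_sites <- nrow(freqs)
  if (n_sites < n_blocks) stop("fewer SNPs than jackknife blocks")
  blk <- make_blocks(n_sites, n_blocks)
  p_o <- freqs[, outgroup]

  # per-(A,B,C) block sums of the f4-ratio numerator and denominator,
  # computed lazily and cached
  cache <- new.env(parent = emptyenv())
  trio_blocks <- function(a, b, c) {
    key <- paste(a, b, c, sep = "\r")
    if (!is.null(cache[[key]])) return(cache[[key]])
    n_c <- if (!is.null(sample_sizes)) sample_sizes[[c]] else NULL
    s <- abba_baba_sites(freqs[, a], freqs[, b], freqs[, c], p_o, n_c)
    v <- rbind(num = vapply(split(s$num, blk), sum, numeric(1)),
               den = vapply(split(s$den_f, blk), sum, numeric(1)))
    cache[[key]] <- v
    v
  }

  # branches: every node except the root, the outgroup tip, and the ingroup
  # root branch (whose sister is the outgroup, leaving no reference clade)
  all_nodes <- setdiff(seq_len(nt + tree$Nnode), c(ct$root, ct$outgroup))
  parent_of <- function(node) tree$edge[tree$edge[, 2] == node, 1]
  branches <- Filter(function(b) {
    par <- parent_of(b)
    sis <- setdiff(node_children(tree, par), b)
    !(par == ct$root) && length(sis) == 1
  }, all_nodes)
  donors <- setdiff(tips, outgroup)
  b_labels <- vapply(branches, function(b) node_label(tree, b), character(1))

  fb <- matrix(NA_real_, length(branches), length(donors),
               dimnames = list(b_labels, donors))
  zmat <- fb
  for (bi in seq_along(branches)) {
    b <- branches[[bi]]
    sis <- setdiff(node_children(tree, parent_of(b)), b)
    tips_b <- node_tips(tree, b)
    tips_a <- node_tips(tree, sis)
    for (c_tip in setdiff(donors, c(tips_b, tips_a))) {
      # full-data and leave-one-block-out f_b via cached block sums
      stat_from <- function(drop_block) {
        mins <- vapply(tips_b, function(B) {
          vals <- vapply(tips_a, function(A) {
            tb <- trio_blocks(A, B, c_tip)
            use <- if (is.na(drop_block)) seq_len(n_blocks) else
              setdiff(seq_len(n_blocks), drop_block)
            den <- sum(tb["den", use])
            if (den == 0) return(NA_real_)
            sum(tb["num", use]) / den
          }, numeric(1))
          if (all(is.na(vals))) NA_real_ else min(vals, na.rm = TRUE)
        }, numeric(1))
        if (all(is.na(mins))) NA_real_ else
          stats::median(mins, na.rm = TRUE)
      }
      full <- stat_from(NA)
      if (is.na(full)) next
      loo <- vapply(seq_len(n_blocks), stat_from, numeric(1))
      se <- sqrt((n_blocks - 1) / n_blocks *
                   sum((loo - mean(loo, na.rm = TRUE))^2, na.rm = TRUE))
      fb[bi, c_tip] <- max(full, 0)
      zmat[bi, c_tip] <- if (se == 0) {
        if (full > 0) Inf else 0
      } else full / se
    }
  }
  n_testable <- sum(!is.na(fb))
  threshold <- bonferroni_z_threshold(alpha, max(n_testable, 1))
  sig <- zmat > as.numeric(threshold)
  long <- data.frame(
    branch = rep(rownames(fb), times = ncol(fb)),
    donor = rep(colnames(fb), each = nrow(fb)),
    fb = as.vector(fb), z = as.vector(zmat),
    significant = as.vector(sig), stringsAsFactors = FALSE
  )
  structure(list(fb = fb, z = zmat, significant = sig,
                 threshold = threshold, n_testable = n_testable,
                 alpha = alpha, n_blocks = n_blocks, table = long),
            class = "fbranch")
}

#' @export
print.fbranch <- function(x, ...) {
  cat("fbranch matrix:", nrow(x$fb), "branches x", ncol(x$fb), "donors;",
      x$n_testable, "testable cells;",
      sum(x$significant, na.rm = TRUE), "significant at Z >",
      as.numeric(x$threshold), "\n")
  invisible(x)
}
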