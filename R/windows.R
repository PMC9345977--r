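#' Tile the genome into fixed-size windows
#'
#' Windows are tiled from the start of each chromosome in 0-based half-open
#' coordinates `[k*size, (k+1)*size)`; a SNP at 1-based VCF position p falls
#' in window `floor((p - 1) / size)`. Chromosomes are tiled up to the last
#' SNP they carry; chromosomes without SNPs get no windows. Every SNP belongs
#' to exactly one window.
#'
#' @param g a `geno_matrix`.
#' @param size_bp window size in bp (the scans in this package use 50000).
#' @return An object of class `window_set`: list with `windows` (data.frame
#'   `chrom`, `start`, `end`, `n_snps`), `snp_window` (window row index per
#'   SNP) and `size_bp`.
#' @export
make_windows <- function(g, size_bp = 50000) {
  stopifnot(inherits(g, "geno_matrix"), size_bp > 0)
  chroms <- unique(g$loci$chrom)
  win_list <- lapply(chroms, function(ch) {
    pos <- g$loci$pos[g$loci$chrom == ch]
    n_win <- floor((max(pos) - 1) / size_bp) + 1
    data.frame(chrom = ch,
               start = (seq_len(n_win) - 1) * size_bp,
               end = seq_len(n_win) * size_bp,
               stringsAsFactors = FALSE)
  })
  windows <- do.call(rbind, win_list)
  key_w <- paste(windows$chrom, windows$start %/% size_bp)
  key_s <- paste(g$loci$chrom, (g$loci$pos - 1) %/% size_bp)
  snp_window <- match(key_s, key_w)
  windows$n_snps <- tabulate(snp_window, nbins = nrow(windows))
  structure(list(windows = windows, snp_window = snp_window,
                 size_bp = size_bp),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat("window_set:", nrow(x$windows), "windows of", x$size_bp, "bp covering",
      sum(x$windows$n_snps), "SNPs\n")
  invisible(x)
}

windows_to_granges <- function(windows) {
  GenomicRanges::GRanges(
    seqnames = windows$chrom,
    ranges = IRanges::IRanges(start = windows$start + 1L,
                              end = windows$end)
  )
}

#' Read a BED file of features
#'
#' BED is 0-based half-open on disk; the returned data.frame keeps that
#' convention (`start` 0-based, `end` exclusive), matching the package's
#' internal window coordinates.
#'
#' @param path BED path.
#' @return data.frame with `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else
               paste0("feature_", seq_along(gr)),
             stringsAsFactors = FALSE)
}

#' Read gene intervals from a GFF3 file
#'
#' GFF3 coordinates are 1-based closed on disk; they are converted to the
#' package's 0-based half-open convention.
#'
#' @param path GFF3 path.
#' @param feature_type keep only records of this type (default `"gene"`;
#'   `NULL` keeps everything).
#' @return data.frame with `chrom`, `start`, `end`, `name`.
#' @export
read_gff3 <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path, format = "GFF3")
  if (!is.null(feature_type)) {
    gr <- gr[as.character(gr$type) %in% feature_type]
  }
  nm <- if (!is.null(gr$ID)) as.character(gr$ID) else
    paste0("feature_", seq_along(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = nm, stringsAsFactors = FALSE)
}

#' Overlap windows with feature intervals (minimum 1 bp)
#'
#' Both inputs are 0-based half-open data.frames (`chrom`, `start`, `end`);
#' a pair is reported when the intervals share at least one base.
#'
#' @param windows data.frame of windows (e.g. `window_set$windows`, possibly
#'   subset to outliers).
#' @param features data.frame of features, e.g. from [read_bed()] or
#'   [read_gff3()].
#' @return data.frame with `window` and `feature` row indices plus the
#'   coordinates and feature name of each overlapping pair.
#' @export
interval_overlap <- function(windows, features) {
  stopifnot(all(c("chrom", "start", "end") %in% names(windows)),
            all(c("chrom", "start", "end") %in% names(features)))
  if (any(windows$end <= windows$start) || any(features$end <= features$start)) {
    stop("malformed interval: end must exceed start (half-open coordinates)")
  }
  q <- windows_to_granges(windows)
  s <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start + 1L,
                              end = features$end)
  )
  hits <- GenomicRanges::findOverlaps(q, s, minoverlap = 1L)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  data.frame(window = qi, feature = si,
             chrom = windows$chrom[qi],
             window_start = windows$start[qi],
             window_end = windows$end[qi],
             feature_start = features$start[si],
             feature_end = features$end[si],
             feature_name = if ("name" %in% names(features))
               features$name[si] else as.character(si),
             stringsAsFactors = FALSE)
}

#' Greedy LD pruning of a genotype matrix
#'
#' Removes the later-positioned SNP of any pair closer than `window_bp` whose
#' squared Pearson correlation of dosages exceeds `r2_max`, scanning left to
#' right within each chromosome. After pruning, no retained pair within any
#' `window_bp` window has r-squared above the threshold. Deterministic,
#' order-stable and idempotent.
#'
#' @param g a `geno_matrix`.
#' @param window_bp window span in bp within which pairs are tested.
#' @param r2_max squared-correlation threshold in (0, 1].
#' @param samples optional sample ids over which correlations are computed.
#' @return Integer vector of retained SNP column indices.
#' @export
ld_prune <- function(g, window_bp = 50000, r2_max = 0.95, samples = NULL) {
  stopifnot(inherits(g, "geno_matrix"), r2_max > 0, r2_max <= 1)
  dos <- g$dosages
  if (!is.null(samples)) dos <- dos[sample_index(g, samples), , drop = FALSE]
  x <- scale(dos, center = TRUE, scale = FALSE)
  ss <- colSums(x^2)
  pos <- g$loci$pos
  chrom <- g$loci$chrom
  p <- ncol(x)
  keep <- logical(p)
  kept_idx <- integer(0)          # retained SNPs on the current chromosome
  cur_chrom <- ""
  lo <- 1L                        # first retained SNP still within range
  for (i in seq_len(p)) {
    if (chrom[i] != cur_chrom) {
      cur_chrom <- chrom[i]
      kept_idx <- integer(0)
      lo <- 1L
    }
    while (lo <= length(kept_idx) &&
           pos[i] - pos[kept_idx[lo]] >= window_bp) {
      lo <- lo + 1L
    }
    cand <- if (lo <= length(kept_idx))
      kept_idx[lo:length(kept_idx)] else integer(0)
    ok <- TRUE
    if (length(cand) && ss[i] > 0) {
      num <- as.vector(crossprod(x[, cand, drop = FALSE], x[, i]))
      denom <- ss[cand] * ss[i]
      r2 <- ifelse(denom > 0, num^2 / denom, 0)
      ok <- all(r2 <= r2_max + 1e-12)
    } else if (length(cand) && ss[i] == 0) {
      # monomorphic SNP: undefined correlation, treated as unlinked
      ok <- TRUE
    }
    if (ok) {
      keep[i] <- TRUE
      kept_idx <- c(kept_idx, i)
    }
  }
  which(keep)
}
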