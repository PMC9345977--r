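#' Construct a genotype matrix
#'
#' The central container of the package: a samples x SNPs matrix of alternate
#' allele dosages (0, 1, 2; no missing values) together with locus coordinates.
#' Loci must be sorted by (chromosome, position) with unique positions within
#' each chromosome, mirroring a sorted multi-sample VCF of biallelic SNPs.
#'
#' @param dosages integer matrix, samples in rows, SNPs in columns, values in
#'   \{0, 1, 2\}.
#' @param loci data.frame with columns `chrom`, `pos` (1-based, as in VCF),
#'   `ref`, `alt`; one row per SNP column of `dosages`.
#' @param sample_ids character vector of unique sample labels, one per row.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosages, loci, sample_ids) {
  dosages <- as.matrix(dosages)
  if (!is.numeric(dosages)) stop("dosages must be numeric")
  if (anyNA(dosages)) stop("missing genotypes are not allowed")
  if (!all(dosages %in% c(0L, 1L, 2L))) {
    stop("dosages must be 0, 1 or 2 (biallelic diploid alt-allele counts)")
  }
  storage.mode(dosages) <- "integer"
  loci <- as.data.frame(loci)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(loci))) {
    stop("loci must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(loci) != ncol(dosages)) {
    stop("loci rows (", nrow(loci), ") != dosage columns (", ncol(dosages), ")")
  }
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (length(sample_ids) != nrow(dosages)) {
    stop("sample_ids length != dosage rows")
  }
  loci$chrom <- as.character(loci$chrom)
  loci$pos <- as.integer(loci$pos)
  # sorted means: each chromosome forms one contiguous block (in order of
  # first appearance) with strictly increasing positions within it
  if (nrow(loci) > 0) {
    blocks <- rle(loci$chrom)
    if (anyDuplicated(blocks$values)) {
      stop("loci must be sorted by (chromosome, position): chromosome ",
           blocks$values[anyDuplicated(blocks$values)],
           " appears in non-contiguous blocks")
    }
    same_chrom <- loci$chrom[-1] == loci$chrom[-nrow(loci)]
    nondecr <- diff(loci$pos) > 0 | !same_chrom
    if (!all(nondecr)) {
      i <- which(!nondecr)[1] + 1
      if (loci$pos[i] == loci$pos[i - 1]) {
        stop("duplicate positions within a chromosome at ",
             loci$chrom[i], ":", loci$pos[i])
      }
      stop("loci must be sorted by (chromosome, position) near ",
           loci$chrom[i], ":", loci$pos[i])
    }
  }
  rownames(dosages) <- sample_ids
  structure(
    list(dosages = dosages, loci = loci,
         sample_ids = as.character(sample_ids)),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", length(x$sample_ids), "samples x",
      nrow(x$loci), "SNPs on", length(unique(x$loci$chrom)),
      "chromosome(s)\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' Number of SNPs in a genotype matrix
#' @param g a `geno_matrix`.
#' @return Integer SNP count.
#' @export
n_snps <- function(g) nrow(g$loci)

#' Subset a genotype matrix
#'
#' @param g a `geno_matrix`.
#' @param samples sample ids (or indices) to keep; default all.
#' @param snps SNP column indices (or logical mask) to keep; default all.
#' @return A `geno_matrix` restricted to the requested samples/SNPs.
#' @export
subset_geno <- function(g, samples = NULL, snps = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  ridx <- seq_along(g$sample_ids)
  if (!is.null(samples)) {
    if (is.character(samples)) {
      ridx <- match(samples, g$sample_ids)
      if (anyNA(ridx)) {
        stop("unknown sample id(s): ",
             paste(samples[is.na(ridx)], collapse = ", "))
      }
    } else ridx <- samples
  }
  cidx <- seq_len(n_snps(g))
  if (!is.null(snps)) {
    cidx <- if (is.logical(snps)) which(snps) else as.integer(snps)
  }
  geno_matrix(g$dosages[ridx, cidx, drop = FALSE],
              g$loci[cidx, , drop = FALSE],
              g$sample_ids[ridx])
}

sample_index <- function(g, ids) {
  idx <- match(ids, g$sample_ids)
  if (anyNA(idx)) {
    stop("unknown sample id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Read a biallelic SNP VCF into a genotype matrix
#'
#' Accepts VCFv4.x with a GT field for every sample. Records that are
#' multiallelic, carry missing genotypes, or are not coordinate-sorted are
#' rejected with a diagnostic naming the offending record; the scans in this
#' package assume complete genotypes (a `--max-missing 1`-style regime).
#'
#' @param path path to a VCF (plain or bgzipped).
#' @return A `geno_matrix`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {           # single record comes back as a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  if (nrow(fix) == 0) stop("no variant records in ", path)
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  bad <- grepl(",", alt) | is.na(alt) | alt == "."
  if (any(bad)) {
    i <- which(bad)[1]
    stop("multiallelic or ALT-less record at ", chrom[i], ":", pos[i],
         " (ALT = ", alt[i], "); only biallelic SNPs are supported")
  }
  same <- chrom[-1] == chrom[-length(chrom)]
  if (length(chrom) > 1 &&
      (any(!diff(pos) > 0 & same) || anyDuplicated(rle(chrom)$values))) {
    i <- which(!(diff(pos) > 0) & same)[1] + 1
    if (is.na(i)) i <- 1
    stop("VCF is not coordinate-sorted near record ", chrom[i], ":", pos[i])
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, names(gt)))
  if (is.null(gt) || ncol(gt) == 0) stop("VCF has no sample GT columns")
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean == "0/0"] <- 0L
  dos[clean == "0/1" | clean == "1/0"] <- 1L
  dos[clean == "1/1"] <- 2L
  if (anyNA(dos)) {
    i <- which(is.na(dos), arr.ind = TRUE)[1, ]
    stop("missing or unparseable GT '", gt[i[1], i[2]], "' for sample ",
         colnames(gt)[i[2]], " at ", chrom[i[1]], ":", pos[i[1]])
  }
  geno_matrix(t(dos),
              data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         stringsAsFactors = FALSE),
              colnames(gt))
}

#' Write a genotype matrix as a VCFv4.2 file (GT field only)
#'
#' @param g a `geno_matrix`.
#' @param path output path (plain text).
#' @param contig_lengths optional named vector of chromosome lengths for the
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path, contig_lengths = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=radscan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  if (!is.null(contig_lengths)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>",
                       names(contig_lengths), as.integer(contig_lengths)),
               con)
  }
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", g$sample_ids), collapse = "\t"), con)
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix(gt_code[g$dosages + 1L], nrow = nrow(g$dosages))
  body <- apply(gt, 2, paste, collapse = "\t")
  lines <- paste(g$loci$chrom, g$loci$pos, ".", g$loci$ref, g$loci$alt,
                 ".", "PASS", ".", "GT", body, sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-separated with columns `sample`, `lake`, `lake_system`, `species`,
#' `ecomorph`, `sex`, `standard_length_mm`, `gill_raker_count`.
#'
#' @param path TSV path.
#' @return data.frame with the columns above.
#' @export
read_sample_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample", "lake", "lake_system", "species", "ecomorph", "sex",
            "standard_length_mm", "gill_raker_count")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(tab$sample)) stop("duplicate sample ids in metadata")
  tab
}

#' Write a sample metadata table
#' @param samples data.frame as returned by [read_sample_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filter loci by minor allele count within a sample subset
#'
#' Retains loci whose minor allele count, computed over `subset`, is at least
#' `min_mac`. With `min_mac = 1` this drops loci monomorphic within the
#' subset, the usual pre-filter for pairwise differentiation scans.
#'
#' @param g a `geno_matrix`.
#' @param subset sample ids defining the counting population (default: all).
#' @param min_mac minimum minor allele count; `0` keeps everything.
#' @return A `geno_matrix` with the passing loci.
#' @export
filter_mac <- function(g, subset = NULL, min_mac = 1) {
  stopifnot(inherits(g, "geno_matrix"))
  if (is.null(subset)) subset <- g$sample_ids
  if (length(subset) == 0) stop("subset must be nonempty")
  idx <- sample_index(g, subset)
  ac <- colSums(g$dosages[idx, , drop = FALSE])
  an <- 2L * length(idx)
  mac <- pmin(ac, an - ac)
  subset_geno(g, snps = which(mac >= min_mac))
}

#' Per-group alternate allele frequencies
#'
#' @param g a `geno_matrix`.
#' @param groups named list mapping group label to sample ids (groups may
#'   overlap; every group must be nonempty).
#' @return Numeric matrix, SNPs x groups, of alt allele frequencies.
#' @export
allele_freqs <- function(g, groups) {
  stopifnot(inherits(g, "geno_matrix"), is.list(groups))
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("groups must be a named list")
  }
  out <- vapply(groups, function(ids) {
    if (length(ids) == 0) stop("empty group")
    idx <- sample_index(g, ids)
    colSums(g$dosages[idx, , drop = FALSE]) / (2 * length(idx))
  }, numeric(n_snps(g)))
  out <- matrix(out, nrow = n_snps(g),
                dimnames = list(NULL, names(groups)))
  out
}

#' Group samples by a metadata column
#'
#' @param samples metadata data.frame.
#' @param by column name (e.g. `"ecomorph"`, `"species"`, `"lake"`) or a
#'   character vector of columns to cross (joined by `_`).
#' @param restrict optional sample ids to restrict to.
#' @return Named list of sample-id vectors.
#' @export
group_samples <- function(samples, by = "species", restrict = NULL) {
  if (!all(by %in% names(samples))) {
    stop("unknown metadata column(s): ",
         paste(setdiff(by, names(samples)), collapse = ", "))
  }
  if (!is.null(restrict)) samples <- samples[samples$sample %in% restrict, ]
  key <- do.call(paste, c(samples[by], sep = "_"))
  split(samples$sample, key)
}
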