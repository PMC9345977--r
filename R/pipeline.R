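#' Default pipeline run configuration
#'
#' Returns the default parameter list used by [run_stage()]; values supplied
#' in `...` (or read from YAML via [read_run_config()]) override the
#' defaults. Parameter defaults follow the windowed-scan conventions used
#' throughout the package: 50 kb windows, minimum 24 SNPs per CSS window and
#' 10 per F_ST window, FDR level 0.01, top-percentile F_ST outliers,
#' 100,000 permutations, 20 jackknife blocks.
#'
#' @param ... named overrides.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    out_dir = "radscan_out",
    vcf = NULL, metadata = NULL, tree = NULL,
    window_bp = 50000, min_snps_css = 24, min_snps_fst = 10,
    fdr_level = 0.01, outlier_fraction = 0.01,
    n_permutations = 100000, permutation_mode = "auto",
    alpha_assoc = 0.05, alpha_fbranch = 0.01,
    n_blocks = 20, ld_r2_css_pca = 0.1, ld_r2_assoc = 0.95,
    contrast_ecomorphs = c("Balchen", "Albeli"),
    outgroup = "Outgroup",
    trait = "gill_raker_count",
    simulate = list(),
    seed = 1, force = FALSE
  )
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read a YAML run configuration
#' @param path YAML file; keys override [run_config()] defaults.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  clean <- unclass(cfg)
  clean$force <- NULL
  yaml::write_yaml(clean, tmp)
  unname(tools::md5sum(tmp))
}

log_line <- function(...) {
  kv <- paste(..., sep = "", collapse = " ")
  message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", kv)
}

write_manifest <- function(cfg, stage, outputs) {
  man <- list(stage = stage,
              config_hash = config_hash(cfg),
              seed = cfg$seed,
              version = as.character(utils::packageVersion("radscan")),
              outputs = outputs,
              checksums = as.list(tools::md5sum(
                file.path(cfg$out_dir, outputs))))
  names(man$checksums) <- outputs
  path <- file.path(cfg$out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

check_overwrite <- function(cfg, stage) {
  path <- file.path(cfg$out_dir, paste0(stage, "_manifest.json"))
  if (file.exists(path) && !isTRUE(cfg$force)) {
    old <- jsonlite::read_json(path)
    if (!identical(old$config_hash, config_hash(cfg))) {
      stop("existing '", stage, "' outputs were produced under a different ",
           "configuration (hash mismatch); rerun with force = TRUE to ",
           "overwrite")
    }
  }
}

write_tsv <- function(x, cfg, name) {
  utils::write.table(x, file.path(cfg$out_dir, name), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  name
}

load_inputs <- function(cfg) {
  for (f in c("vcf", "metadata")) {
    if (is.null(cfg[[f]])) stop("config field '", f, "' is required")
    if (!file.exists(cfg[[f]])) stop("missing input file: ", cfg[[f]])
  }
  list(g = read_vcf(cfg$vcf), samples = read_sample_table(cfg$metadata))
}

#' Run one pipeline stage
#'
#' Stages: `"simulate"` (synthetic radiation to VCF + metadata + truth),
#' `"css-scan"` (stratified-permutation CSS outlier scan + outlier-window
#' PCA + trait regressions), `"fst-scan"` (per-lake windowed Weir-Cockerham
#' F_ST, top-percentile outliers, cross-lake overlap summary),
#' `"f4-contrast"` (F4 topology contrasts for all lake pairs), `"fbranch"`
#' (tree-guided excess allele-sharing matrix), `"assoc-support"`
#' (association scan, significance thresholds, top-SNP PVE and per-ecomorph
#' frequency profile). Every stage writes TSV artifacts plus a JSON manifest
#' carrying the config hash, seed and package version; re-running with an
#' identical configuration reproduces identical outputs, and a stage refuses
#' to overwrite outputs from a different configuration unless
#' `force = TRUE`.
#'
#' @param stage stage name (see above).
#' @param cfg a [run_config()] (or path handled by [read_run_config()]).
#' @return Character vector of the files written (relative to
#'   `cfg$out_dir`), invisibly.
#' @export
run_stage <- function(stage = c("simulate", "css-scan", "fst-scan",
                                "f4-contrast", "fbranch", "assoc-support"),
                      cfg) {
  stage <- match.arg(stage)
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  check_overwrite(cfg, stage)
  log_line("stage=", stage, " seed=", cfg$seed, " out=", cfg$out_dir)
  outputs <- switch(
    stage,
    "simulate" = stage_simulate(cfg),
    "css-scan" = stage_css(cfg),
    "fst-scan" = stage_fst(cfg),
    "f4-contrast" = stage_f4(cfg),
    "fbranch" = stage_fbranch(cfg),
    "assoc-support" = stage_assoc(cfg)
  )
  write_manifest(cfg, stage, outputs)
  log_line("stage=", stage, " status=done files=", length(outputs))
  invisible(outputs)
}

stage_simulate <- function(cfg) {
  sc <- do.call(sim_config, c(cfg$simulate, list(seed = cfg$seed)))
  sim <- simulate_radiation(sc)
  vcf <- file.path(cfg$out_dir, "simulated.vcf")
  write_vcf(sim$genotypes, vcf,
            contig_lengths = stats::setNames(
              rep(sc$chrom_length_bp, sc$n_chromosomes),
              sprintf("chr%d", seq_len(sc$n_chromosomes))))
  write_sample_table(sim$samples, file.path(cfg$out_dir, "metadata.tsv"))
  write_truth(sim$truth, file.path(cfg$out_dir, "truth"))
  writeLines(sim$truth$tree, file.path(cfg$out_dir, "tree.nwk"))
  yaml::write_yaml(unclass(sc), file.path(cfg$out_dir, "sim_config.yaml"))
  c("simulated.vcf", "metadata.tsv", "tree.nwk", "sim_config.yaml")
}

contrast_groups <- function(samples, cfg) {
  eco <- cfg$contrast_ecomorphs
  in1 <- samples$sample[samples$ecomorph == eco[1]]
  in2 <- samples$sample[samples$ecomorph == eco[2]]
  if (!length(in1) || !length(in2)) {
    stop("contrast ecomorphs not found in metadata: ",
         paste(eco, collapse = " vs "))
  }
  strata <- split(c(in1, in2),
                  samples$lake[match(c(in1, in2), samples$sample)])
  list(group1 = in1, group2 = in2, strata = strata)
}

stage_css <- function(cfg) {
  inp <- load_inputs(cfg)
  grp <- contrast_groups(inp$samples, cfg)
  win <- make_windows(inp$g, cfg$window_bp)
  des <- css_design(grp$group1, grp$group2, grp$strata,
                    n_permutations = cfg$n_permutations,
                    min_snps = cfg$min_snps_css,
                    fdr_level = cfg$fdr_level,
                    mode = cfg$permutation_mode, seed = cfg$seed)
  res <- css_scan(inp$g, win, des)
  files <- write_tsv(res, cfg, "css_windows.tsv")
  if (any(res$outlier)) {
    out_win <- attr(res, "window_index")[res$outlier]
    ingroup <- inp$samples$sample[inp$samples$ecomorph != "Outgroup"]
    gi <- subset_geno(inp$g, samples = intersect(inp$g$sample_ids, ingroup))
    pca <- outlier_pca(gi, win, out_win, ld_window_bp = cfg$window_bp,
                       ld_r2_max = cfg$ld_r2_css_pca)
    scores <- data.frame(sample = rownames(pca$scores),
                         pca$scores[, seq_len(min(5, ncol(pca$scores))),
                                    drop = FALSE])
    files <- c(files, write_tsv(scores, cfg, "css_pca_scores.tsv"))
    meta <- inp$samples[match(scores$sample, inp$samples$sample), ]
    reg <- rbind(
      cbind(trait = "standard_length_mm",
            trait_regression(scores$PC1, meta$standard_length_mm,
                             meta$lake_system)),
      cbind(trait = "gill_raker_count",
            trait_regression(scores$PC1, meta$gill_raker_count,
                             meta$lake_system))
    )
    files <- c(files, write_tsv(reg, cfg, "css_trait_regressions.tsv"))
  }
  files
}

stage_fst <- function(cfg) {
  inp <- load_inputs(cfg)
  eco <- cfg$contrast_ecomorphs
  lakes <- setdiff(unique(inp$samples$lake), "Outgroup")
  win <- make_windows(inp$g, cfg$window_bp)
  files <- character(0)
  sets <- list()
  records <- list()
  for (lk in lakes) {
    sel <- inp$samples$lake == lk
    p1 <- inp$samples$sample[sel & inp$samples$ecomorph == eco[1]]
    p2 <- inp$samples$sample[sel & inp$samples$ecomorph == eco[2]]
    if (length(p1) < 2 || length(p2) < 2) next
    gsub_ <- filter_mac(inp$g, subset = c(p1, p2), min_mac = 1)
    wsub <- make_windows(gsub_, cfg$window_bp)
    rec <- windowed_fst(gsub_, wsub, p1, p2, min_snps = cfg$min_snps_fst)
    rec <- top_percentile_outliers(rec, cfg$outlier_fraction)
    records[[lk]] <- rec
    sets[[lk]] <- paste(rec$chrom, rec$start)[rec$outlier]
    files <- c(files, write_tsv(rec, cfg, paste0("fst_", lk, ".tsv")))
  }
  if (length(sets) >= 2) {
    W <- nrow(win$windows)
    ov <- shared_outlier_windows(sets, W, cfg$outlier_fraction)
    files <- c(files, write_tsv(ov, cfg, "fst_overlap_summary.tsv"))
  }
  files
}

stage_f4 <- function(cfg) {
  inp <- load_inputs(cfg)
  eco <- cfg$contrast_ecomorphs
  lakes <- setdiff(unique(inp$samples$lake), "Outgroup")
  groups <- group_samples(inp$samples, by = "species",
                          restrict = inp$g$sample_ids)
  freqs <- allele_freqs(inp$g, groups)
  rows <- list()
  for (i in seq_along(lakes)) for (j in seq_along(lakes)) {
    if (i >= j) next
    b1 <- paste(eco[1], lakes[i], sep = "_")
    a1 <- paste(eco[2], lakes[i], sep = "_")
    b2 <- paste(eco[1], lakes[j], sep = "_")
    a2 <- paste(eco[2], lakes[j], sep = "_")
    if (!all(c(b1, a1, b2, a2) %in% colnames(freqs))) next
    tc <- topology_contrast(freqs, b1, a1, b2, a2)
    rows[[length(rows) + 1]] <- data.frame(
      lake1 = lakes[i], lake2 = lakes[j],
      f4_sympatric = tc$f4_sympatric, f4_ecomorph = tc$f4_ecomorph,
      verdict = tc$verdict, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no complete lake pair found for the contrast")
  write_tsv(do.call(rbind, rows), cfg, "f4_contrasts.tsv")
}

stage_fbranch <- function(cfg) {
  inp <- load_inputs(cfg)
  if (is.null(cfg$tree) || !file.exists(cfg$tree)) {
    stop("config field 'tree' must point to a Newick file")
  }
  tree <- ape::read.tree(cfg$tree)
  groups <- group_samples(inp$samples, by = "species",
                          restrict = inp$g$sample_ids)
  groups <- groups[intersect(names(groups), tree$tip.label)]
  freqs <- allele_freqs(inp$g, groups)
  sizes <- 2 * lengths(groups)
  fb <- fbranch(tree, freqs, outgroup = cfg$outgroup,
                n_blocks = cfg$n_blocks, sample_sizes = sizes,
                alpha = cfg$alpha_fbranch)
  files <- write_tsv(fb$table, cfg, "fbranch_long.tsv")
  mat <- data.frame(branch = rownames(fb$fb), fb$fb, check.names = FALSE)
  c(files, write_tsv(mat, cfg, "fbranch_matrix.tsv"))
}

stage_assoc <- function(cfg) {
  inp <- load_inputs(cfg)
  ingroup <- inp$samples$sample[inp$samples$ecomorph != "Outgroup"]
  g <- subset_geno(inp$g, samples = intersect(inp$g$sample_ids, ingroup))
  g <- filter_mac(g, min_mac = 1)
  trait <- stats::setNames(inp$samples[[cfg$trait]], inp$samples$sample)
  scan <- simple_assoc_scan(g, trait[g$sample_ids])
  scan$minus_log10_p <- -log10(scan$p)
  files <- write_tsv(scan, cfg, "assoc_scan.tsv")
  strict <- bonferroni_threshold(cfg$alpha_assoc, nrow(scan))
  ldc <- ld_considerate_threshold(g, cfg$alpha_assoc,
                                  window_bp = cfg$window_bp,
                                  r2_max = cfg$ld_r2_assoc)
  top <- scan[which.min(scan$p), ]
  top_pve <- pve(top$beta, top$se_beta, top$maf, top$n)
  summary <- list(
    n_snps = nrow(scan),
    bonferroni_threshold = as.numeric(strict),
    n_effective = ldc$n_effective,
    ld_considerate_threshold = as.numeric(ldc$threshold),
    top_snp = list(chrom = top$chrom, pos = top$pos,
                   minus_log10_p = top$minus_log10_p, pve = top_pve)
  )
  jsonlite::write_json(summary, file.path(cfg$out_dir, "assoc_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  prof <- group_allele_freqs(g, inp$samples, top$chrom, top$pos,
                             grouping = "ecomorph", trait = cfg$trait)
  c(files, "assoc_summary.json",
    write_tsv(prof, cfg, "assoc_top_snp_profile.tsv"))
}
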