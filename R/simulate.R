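#' Configuration for a synthetic lake radiation
#'
#' Builds and validates the parameter set for [simulate_radiation()]. The
#' defaults emulate the sampling design of a parallel-divergence study of a
#' lake radiation: four lakes each holding a benthic/deep-bodied ecomorph
#' ("Balchen") and a zooplanktivorous shallow-bodied ecomorph ("Albeli"),
#' three diploid individuals per species (24 ingroup samples), genome-wide
#' lake-level drift under the Balding-Nichols model, a small fraction of loci
#' with parallel ecomorph-associated frequency shifts shared across lakes,
#' optional lake-specific divergent loci, one large-effect gill-raker locus,
#' polygenic control of standard length, and introgression tracts from a
#' donor lake into designated recipient species.
#'
#' Parallel and lake-specific loci are placed in contiguous blocks of
#' `divergent_block_snps` SNPs, emulating clustered divergence regions rather
#' than isolated SNPs.
#'
#' @param n_lakes number of lakes.
#' @param ecomorphs_per_lake list (length `n_lakes`) of ecomorph label
#'   vectors; each lake gets one species per listed ecomorph. Default:
#'   `c("Balchen", "Albeli")` in every lake.
#' @param n_per_species diploid individuals per species.
#' @param n_chromosomes,snps_per_chromosome,chrom_length_bp genome layout
#'   (default 4 chromosomes x 5000 SNPs over 2.5 Mb, i.e. ~100 SNPs per
#'   50 kb window).
#' @param fst_lake Balding-Nichols drift parameter between lakes, in [0, 1).
#' @param prop_parallel_loci fraction of SNPs with parallel ecomorph shifts.
#' @param parallel_shift allele-frequency delta between the two contrast
#'   ecomorphs at parallel loci (split +/- shift/2 around the lake frequency).
#' @param prop_lake_specific_loci fraction of SNPs divergent in one lake only.
#' @param lake_specific_shift frequency delta for lake-specific loci.
#' @param divergent_block_snps SNPs per contiguous divergent block.
#' @param large_effect_locus `NULL` or `list(chrom =, pos =, effect =)`
#'   giving the chromosome index, bp position (snapped to the nearest
#'   simulated SNP) and per-alt-allele effect in gill-raker units; the locus
#'   also receives ecomorph-graded allele frequencies (`large_effect_shift`).
#' @param large_effect_shift frequency range of the large-effect locus across
#'   ecomorphs, ordered by their gill-raker baselines.
#' @param polygenic_trait_params `list(n_loci =, effect_sd =, residual_sd =)`
#'   for standard length (mm).
#' @param introgression_events list of
#'   `list(donor_lake =, recipient_species =, tract_fraction =,
#'   tract_length_bp =)` entries.
#' @param origin_mode `"parallel"` (ecomorphs arise within each lake; the
#'   default) or `"single"` (one ancient ecomorph split predating the lakes,
#'   modelled as ecomorph-level Balding-Nichols drift with parameter
#'   `fst_ecomorph` followed by lake-level drift within each ecomorph).
#' @param fst_ecomorph drift between ecomorph lineages in `"single"` mode.
#' @param n_outgroup outgroup individuals (an independently drifted
#'   population used to polarise four-taxon statistics); 0 to omit.
#' @param fst_outgroup drift parameter of the outgroup population.
#' @param gill_raker_baseline named vector of ecomorph gill-raker baselines;
#'   the defaults order Balchen < Felchen < Albeli.
#' @param gill_raker_sd,gill_raker_min residual SD and floor of the count.
#' @param length_baseline named vector of ecomorph standard-length baselines
#'   (mm).
#' @param seed integer; fully determines the simulated output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_lakes = 4,
                       ecomorphs_per_lake = NULL,
                       n_per_species = 3,
                       n_chromosomes = 4,
                       snps_per_chromosome = 5000,
                       chrom_length_bp = 2500000,
                       fst_lake = 0.1,
                       prop_parallel_loci = 0.01,
                       parallel_shift = 0.8,
                       prop_lake_specific_loci = 0,
                       lake_specific_shift = 0.8,
                       divergent_block_snps = 50,
                       large_effect_locus = NULL,
                       large_effect_shift = 0.8,
                       polygenic_trait_params = list(n_loci = 100,
                                                     effect_sd = 2,
                                                     residual_sd = 15),
                       introgression_events = list(),
                       origin_mode = c("parallel", "single"),
                       fst_ecomorph = 0.1,
                       n_outgroup = 4,
                       fst_outgroup = 0.2,
                       gill_raker_baseline = c(Balchen = 26, Felchen = 28,
                                               Albeli = 30,
                                               `large-pelagic` = 28,
                                               `benthic-profundal` = 22,
                                               `pelagic-profundal` = 29,
                                               Outgroup = 28),
                       gill_raker_sd = 1.5,
                       gill_raker_min = 15,
                       length_baseline = c(Balchen = 450, Felchen = 350,
                                           Albeli = 250,
                                           `large-pelagic` = 480,
                                           `benthic-profundal` = 300,
                                           `pelagic-profundal` = 280,
                                           Outgroup = 350),
                       seed = 1) {
  origin_mode <- match.arg(origin_mode)
  if (is.null(ecomorphs_per_lake)) {
    ecomorphs_per_lake <- rep(list(c("Balchen", "Albeli")), n_lakes)
  }
  if (length(ecomorphs_per_lake) != n_lakes) {
    stop("ecomorphs_per_lake must have one entry per lake")
  }
  if (fst_lake < 0 || fst_lake >= 1) stop("fst_lake must be in [0, 1)")
  prop_poly <- polygenic_trait_params$n_loci /
    (n_chromosomes * snps_per_chromosome)
  if (prop_parallel_loci + prop_lake_specific_loci + prop_poly > 1) {
    stop("locus-class fractions exceed 1")
  }
  if (!is.null(large_effect_locus)) {
    stopifnot(all(c("chrom", "pos", "effect") %in% names(large_effect_locus)))
    if (large_effect_locus$chrom > n_chromosomes ||
        large_effect_locus$pos > chrom_length_bp) {
      stop("large_effect_locus lies outside the simulated genome")
    }
  }
  for (ev in introgression_events) {
    stopifnot(all(c("donor_lake", "recipient_species", "tract_fraction",
                    "tract_length_bp") %in% names(ev)))
    if (ev$tract_length_bp > chrom_length_bp) {
      stop("introgression tract length exceeds chromosome length")
    }
    if (ev$tract_fraction < 0 || ev$tract_fraction > 1) {
      stop("tract_fraction must be in [0, 1]")
    }
  }
  ecos <- unique(unlist(ecomorphs_per_lake))
  miss <- setdiff(c(ecos, "Outgroup"), names(gill_raker_baseline))
  if (length(miss)) stop("no gill-raker baseline for: ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(c(ecos, "Outgroup"), names(length_baseline))
  if (length(miss)) stop("no length baseline for: ",
                         paste(miss, collapse = ", "))
  structure(list(
    n_lakes = n_lakes, ecomorphs_per_lake = ecomorphs_per_lake,
    n_per_species = n_per_species, n_chromosomes = n_chromosomes,
    snps_per_chromosome = snps_per_chromosome,
    chrom_length_bp = chrom_length_bp, fst_lake = fst_lake,
    prop_parallel_loci = prop_parallel_loci,
    parallel_shift = parallel_shift,
    prop_lake_specific_loci = prop_lake_specific_loci,
    lake_specific_shift = lake_specific_shift,
    divergent_block_snps = divergent_block_snps,
    large_effect_locus = large_effect_locus,
    large_effect_shift = large_effect_shift,
    polygenic_trait_params = polygenic_trait_params,
    introgression_events = introgression_events,
    origin_mode = origin_mode, fst_ecomorph = fst_ecomorph,
    n_outgroup = n_outgroup, fst_outgroup = fst_outgroup,
    gill_raker_baseline = gill_raker_baseline,
    gill_raker_sd = gill_raker_sd, gill_raker_min = gill_raker_min,
    length_baseline = length_baseline, seed = as.integer(seed)
  ), class = "sim_config")
}

# Balding-Nichols draw: Beta(p(1-F)/F, (1-p)(1-F)/F) around ancestral p.
rbeta_bn <- function(p, f) {
  if (f <= 0) return(p)
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

# contiguous divergent blocks: sample non-overlapping runs of `block` SNPs
# within chromosomes; returns SNP indices
draw_blocks <- function(n_target, block, chrom_of, free) {
  picked <- integer(0)
  if (n_target <= 0) return(picked)
  n_blocks <- max(1, round(n_target / block))
  avail <- which(free)
  guard <- 0
  while (n_blocks > 0 && length(avail) > block && guard < 1000) {
    guard <- guard + 1
    s <- sample(avail, 1)
    run <- s:min(s + block - 1, length(chrom_of))
    run <- run[chrom_of[run] == chrom_of[s]]
    if (all(free[run])) {
      picked <- c(picked, run)
      free[run] <- FALSE
      avail <- which(free)
      n_blocks <- n_blocks - 1
    }
  }
  sort(picked)
}

#' Simulate a replicated lake-system radiation
#'
#' Ancestral allele frequencies are drawn from Beta(0.8, 0.8) truncated to
#' [0.05, 0.95]; lake frequencies drift from the ancestral frequency under
#' the Balding-Nichols model with parameter `fst_lake`; parallel loci shift
#' the two contrast ecomorphs by +/- `parallel_shift/2` with the same sign in
#' every lake (one global sign per locus, clipped to [0, 1]); lake-specific
#' loci apply the same shift in a single randomly chosen lake. Genotypes are
#' Binomial(2, p). The large-effect locus contributes additively to
#' gill-raker count; standard length is an ecomorph baseline plus a polygenic
#' score plus Gaussian noise. Introgression replaces recipient genotypes
#' within non-overlapping tracts with draws at the donor lake's frequencies.
#' A single RNG is seeded once from `config$seed`, so the seed fully
#' determines the output.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (a `geno_matrix`), `samples` (metadata
#'   data.frame), and `truth` (class `sim_truth`: per-SNP `loci` classes and
#'   effects, per-sample introgression `tracts`, per-sample `traits`, the
#'   population `tree` in Newick form, and the per-population frequency
#'   matrices used).
#' @export
simulate_radiation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  S <- cfg$n_chromosomes * cfg$snps_per_chromosome

  # 1. genome layout
  chrom_names <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
  pos_list <- lapply(seq_len(cfg$n_chromosomes), function(i) {
    sort(sample.int(cfg$chrom_length_bp, cfg$snps_per_chromosome))
  })
  loci <- data.frame(
    chrom = rep(chrom_names, each = cfg$snps_per_chromosome),
    pos = unlist(pos_list),
    ref = "A", alt = "T", stringsAsFactors = FALSE
  )
  chrom_of <- rep(seq_len(cfg$n_chromosomes), each = cfg$snps_per_chromosome)

  # 2. ancestral frequencies, truncated Beta(0.8, 0.8)
  p0 <- stats::rbeta(S, 0.8, 0.8)
  while (any(bad <- p0 < 0.05 | p0 > 0.95)) {
    p0[bad] <- stats::rbeta(sum(bad), 0.8, 0.8)
  }

  # 3. locus classes
  class <- rep("neutral", S)
  free <- rep(TRUE, S)
  le_idx <- NA_integer_
  if (!is.null(cfg$large_effect_locus)) {
    on_chrom <- which(chrom_of == cfg$large_effect_locus$chrom)
    le_idx <- on_chrom[which.min(abs(loci$pos[on_chrom] -
                                       cfg$large_effect_locus$pos))]
    class[le_idx] <- "large_effect"
    free[le_idx] <- FALSE
    p0[le_idx] <- 0.5
  }
  par_idx <- draw_blocks(round(cfg$prop_parallel_loci * S),
                         cfg$divergent_block_snps, chrom_of, free)
  class[par_idx] <- "parallel"
  free[par_idx] <- FALSE
  ls_idx <- draw_blocks(round(cfg$prop_lake_specific_loci * S),
                        cfg$divergent_block_snps, chrom_of, free)
  class[ls_idx] <- "lake_specific"
  free[ls_idx] <- FALSE
  n_poly <- cfg$polygenic_trait_params$n_loci
  poly_idx <- if (n_poly > 0) sort(sample(which(free), n_poly)) else integer(0)
  class[poly_idx] <- "polygenic"

  # 4. per-locus randomisation: parallel sign, lake-specific lake, effects
  par_sign <- rep(NA_integer_, S)
  par_sign[par_idx] <- sample(c(-1L, 1L), length(par_idx), replace = TRUE)
  ls_lake <- rep(NA_integer_, S)
  ls_lake[ls_idx] <- sample.int(cfg$n_lakes, length(ls_idx), replace = TRUE)
  ls_sign <- rep(NA_integer_, S)
  ls_sign[ls_idx] <- sample(c(-1L, 1L), length(ls_idx), replace = TRUE)
  poly_beta <- rep(0, S)
  poly_beta[poly_idx] <- stats::rnorm(n_poly, 0,
                                      cfg$polygenic_trait_params$effect_sd)

  # 5. population frequencies: lake base, then ecomorph adjustments
  lakes <- sprintf("Lake%d", seq_len(cfg$n_lakes))
  ecos_all <- unique(unlist(cfg$ecomorphs_per_lake))
  # the two contrast ecomorphs are the first two listed overall
  contrast <- ecos_all[seq_len(min(2, length(ecos_all)))]
  lake_base <- matrix(NA_real_, S, cfg$n_lakes,
                      dimnames = list(NULL, lakes))
  eco_anc <- NULL
  if (cfg$origin_mode == "single") {
    eco_anc <- vapply(ecos_all, function(e) rbeta_bn(p0, cfg$fst_ecomorph),
                      numeric(S))
  }
  for (l in seq_len(cfg$n_lakes)) {
    lake_base[, l] <- rbeta_bn(p0, cfg$fst_lake)
  }

  eco_dir <- function(eco) {
    # +1 for the second contrast ecomorph, -1 for the first, 0 otherwise
    if (length(contrast) < 2) return(0)
    if (eco == contrast[1]) -1 else if (eco == contrast[2]) 1 else 0
  }
  # gill-raker-graded frequency scaling of the large-effect locus in [-.5,.5]
  gr_base <- cfg$gill_raker_baseline
  le_scale <- function(eco) {
    b <- gr_base[intersect(c(ecos_all, "Outgroup"), names(gr_base))]
    if (max(b) == min(b)) return(0)
    (gr_base[[eco]] - min(b)) / (max(b) - min(b)) - 0.5
  }

  pop_freq <- function(lake_i, eco) {
    f <- if (cfg$origin_mode == "single") {
      rbeta_bn(eco_anc[, eco], cfg$fst_lake)
    } else {
      lake_base[, lake_i]
    }
    d <- eco_dir(eco)
    if (d != 0 && length(par_idx)) {
      f[par_idx] <- f[par_idx] +
        par_sign[par_idx] * d * cfg$parallel_shift / 2
    }
    if (d != 0 && length(ls_idx)) {
      sel <- ls_idx[ls_lake[ls_idx] == lake_i]
      f[sel] <- f[sel] + ls_sign[sel] * d * cfg$lake_specific_shift / 2
    }
    if (!is.na(le_idx)) {
      f[le_idx] <- f[le_idx] + cfg$large_effect_shift * le_scale(eco)
    }
    pmin(pmax(f, 0), 1)
  }

  # 6. samples and genotypes (fixed order: lake, then ecomorph, then rep)
  meta <- list()
  dos <- list()
  pop_freqs <- list()
  for (l in seq_len(cfg$n_lakes)) {
    for (eco in cfg$ecomorphs_per_lake[[l]]) {
      f <- pop_freq(l, eco)
      species <- paste(eco, lakes[l], sep = "_")
      pop_freqs[[species]] <- f
      for (k in seq_len(cfg$n_per_species)) {
        id <- sprintf("%s_%02d", species, k)
        meta[[id]] <- data.frame(
          sample = id, lake = lakes[l], lake_system = lakes[l],
          species = species, ecomorph = eco, stringsAsFactors = FALSE
        )
        dos[[id]] <- stats::rbinom(S, 2, f)
      }
    }
  }
  if (cfg$n_outgroup > 0) {
    f_out <- pmin(pmax(rbeta_bn(p0, cfg$fst_outgroup), 0), 1)
    pop_freqs[["Outgroup"]] <- f_out
    for (k in seq_len(cfg$n_outgroup)) {
      id <- sprintf("Outgroup_%02d", k)
      meta[[id]] <- data.frame(
        sample = id, lake = "Outgroup", lake_system = "Outgroup",
        species = "Outgroup", ecomorph = "Outgroup", stringsAsFactors = FALSE
      )
      dos[[id]] <- stats::rbinom(S, 2, f_out)
    }
  }
  samples <- do.call(rbind, meta)
  rownames(samples) <- NULL
  dosages <- do.call(rbind, dos)

  # 7. traits
  n_samp <- nrow(samples)
  samples$sex <- sample(c("M", "F"), n_samp, replace = TRUE)
  le_eff <- if (!is.na(le_idx)) cfg$large_effect_locus$effect else 0
  le_dos <- if (!is.na(le_idx)) dosages[, le_idx] else rep(0, n_samp)
  raker <- cfg$gill_raker_baseline[samples$ecomorph] + le_eff * le_dos +
    stats::rnorm(n_samp, 0, cfg$gill_raker_sd)
  samples$gill_raker_count <- pmax(round(raker), cfg$gill_raker_min)
  poly_score <- as.vector(dosages %*% poly_beta) - sum(2 * p0 * poly_beta)
  samples$standard_length_mm <- round(
    cfg$length_baseline[samples$ecomorph] + poly_score +
      stats::rnorm(n_samp, 0, cfg$polygenic_trait_params$residual_sd), 1)
  samples <- samples[, c("sample", "lake", "lake_system", "species",
                         "ecomorph", "sex", "standard_length_mm",
                         "gill_raker_count")]

  # 8. introgression tracts (non-overlapping per sample, half-open, binned)
  tracts <- list()
  for (ev in cfg$introgression_events) {
    rec <- samples$sample[samples$species == ev$recipient_species]
    if (length(rec) == 0) {
      stop("introgression recipient species not simulated: ",
           ev$recipient_species)
    }
    donor_l <- if (is.character(ev$donor_lake)) {
      match(ev$donor_lake, lakes)
    } else ev$donor_lake
    if (is.na(donor_l)) stop("unknown donor lake: ", ev$donor_lake)
    f_donor <- lake_base[, donor_l]
    tl <- ev$tract_length_bp
    n_bins <- floor(cfg$chrom_length_bp / tl)
    k_bins <- round(ev$tract_fraction * n_bins)
    for (id in rec) {
      ridx <- match(id, samples$sample)
      for (ch in seq_len(cfg$n_chromosomes)) {
        if (k_bins == 0) next
        bins <- sort(sample.int(n_bins, k_bins))
        for (b in bins) {
          a0 <- (b - 1) * tl
          b0 <- b * tl
          in_tract <- chrom_of == ch & loci$pos > a0 & loci$pos <= b0
          dosages[ridx, in_tract] <-
            stats::rbinom(sum(in_tract), 2, f_donor[in_tract])
          tracts[[length(tracts) + 1]] <- data.frame(
            sample = id, chrom = chrom_names[ch], start = a0, end = b0,
            donor_lake = lakes[donor_l], stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  tracts <- if (length(tracts)) do.call(rbind, tracts) else
    data.frame(sample = character(), chrom = character(),
               start = integer(), end = integer(),
               donor_lake = character(), stringsAsFactors = FALSE)

  truth_loci <- data.frame(
    chrom = loci$chrom, pos = loci$pos, class = class, p0 = p0,
    parallel_sign = par_sign, lake_specific_lake =
      ifelse(is.na(ls_lake), NA_character_, lakes[ls_lake]),
    trait_effect = ifelse(class == "polygenic", poly_beta,
                          ifelse(class == "large_effect", le_eff, NA_real_)),
    stringsAsFactors = FALSE
  )
  truth <- structure(list(
    loci = truth_loci,
    tracts = tracts,
    traits = data.frame(sample = samples$sample,
                        polygenic_score = round(poly_score, 6),
                        gill_raker_count = samples$gill_raker_count,
                        standard_length_mm = samples$standard_length_mm,
                        stringsAsFactors = FALSE),
    tree = sim_population_tree(cfg),
    contrast_ecomorphs = contrast
  ), class = "sim_truth")

  list(genotypes = geno_matrix(dosages, loci, samples$sample),
       samples = samples, truth = truth)
}

#' Population tree of a simulated radiation
#'
#' Builds the rooted Newick topology over the simulated population labels:
#' species within a lake form a clade, lake clades join in a ladder, and the
#' outgroup attaches at the root. Used to drive f-branch enumeration on
#' simulated data.
#'
#' @param config a [sim_config()].
#' @return Newick string (terminated by `;`).
#' @export
sim_population_tree <- function(config) {
  lakes <- sprintf("Lake%d", seq_len(config$n_lakes))
  ladder <- function(tips) Reduce(function(a, b) paste0("(", a, ",", b, ")"),
                                  tips)
  clades <- vapply(seq_len(config$n_lakes), function(l) {
    sp <- paste(config$ecomorphs_per_lake[[l]], lakes[l], sep = "_")
    ladder(sp)
  }, character(1))
  ingroup <- ladder(clades)
  if (config$n_outgroup > 0) {
    paste0("(", ingroup, ",Outgroup);")
  } else {
    paste0(ingroup, ";")
  }
}

#' Write simulation ground truth as TSV files
#'
#' Writes `loci.tsv`, `tracts.tsv`, `traits.tsv`, `tree.nwk` and
#' `contrast.txt` into `dir`. Files round-trip losslessly through
#' [read_truth()].
#'
#' @param truth a `sim_truth`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(truth$loci, "loci.tsv")
  wt(truth$tracts, "tracts.tsv")
  wt(truth$traits, "traits.tsv")
  writeLines(truth$tree, file.path(dir, "tree.nwk"))
  writeLines(truth$contrast_ecomorphs, file.path(dir, "contrast.txt"))
  invisible(dir)
}

#' Read simulation ground truth written by [write_truth()]
#' @param dir directory holding the truth TSVs.
#' @return A `sim_truth`.
#' @export
read_truth <- function(dir) {
  rt <- function(f, classes) utils::read.table(
    file.path(dir, f), header = TRUE, sep = "\t", stringsAsFactors = FALSE,
    colClasses = classes)
  structure(list(
    loci = rt("loci.tsv", c("character", "integer", "character", "numeric",
                            "integer", "character", "numeric")),
    tracts = rt("tracts.tsv", c("character", "character", "integer",
                                "integer", "character")),
    traits = rt("traits.tsv", c("character", "numeric", "numeric",
                                "numeric")),
    tree = readLines(file.path(dir, "tree.nwk"))[1],
    contrast_ecomorphs = readLines(file.path(dir, "contrast.txt"))
  ), class = "sim_truth")
}
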