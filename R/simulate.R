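#' @title Seeded synthetic data: Cq plates, dilution series, populations
#' @name synthetic_data
#' @description
#' Generators that emulate the statistical structure of real diagnostic
#' runs so every stage of the workflow is testable offline: (i) per-assay
#' Cq datasets with genotype-specific FAM/VIC behaviour (target Cq around
#' 23.4, strain- and assay-specific off-target lags, deterministic
#' no-fluorescence channels for SNP A/R and SNP C/C, heterozygote deltaCq
#' confined to 0-2 cycles); (ii) dilution series following a configurable
#' log-linear standard curve with a hard detection floor; and (iii)
#' two-strain population genotype matrices written as VCF + reference
#' FASTA + label file, with known diagnostic loci, background loci,
#' optional F1 hybrids, an unplaced-scaffold decoy and low-quality decoys.
#' All generators are fully deterministic under a fixed seed.
NULL

#' Default per-assay simulation profiles
#'
#' Off-target lag means/SDs and no-fluorescence probabilities reproduce
#' the observed per-assay behaviour: SNP A never fires VIC in R-strain
#' homozygotes and lags 7.05 +/- 0.89 cycles in C-strain ones; SNP B lags
#' 16.26 +/- 1.26 (R) and 17.12 +/- 1.38 (C); SNP C lags 10.32 +/- 0.97
#' (R) and never fires FAM in C-strain homozygotes; SNP D lags
#' 3.67 +/- 0.29 (R) and 5.77 +/- 0.45 (C). The lag parameters describe
#' reactions in which both fluorophores were detected.
#'
#' @return Data.frame with one row per assay: `assay_id`,
#'   `target_cq_mean`, `target_cq_sd`, `delta_mean_r`, `delta_sd_r`,
#'   `delta_mean_c`, `delta_sd_c`, `offtarget_nf_prob_r`,
#'   `offtarget_nf_prob_c`, `het_delta_max`.
#' @export
assay_sim_profiles <- function() {
  data.frame(
    assay_id = c("SNP A", "SNP B", "SNP C", "SNP D"),
    target_cq_mean = 23.4,
    target_cq_sd = 0.5,
    delta_mean_r = c(NA, 16.26, 10.32, 3.67),
    delta_sd_r = c(NA, 1.26, 0.97, 0.29),
    delta_mean_c = c(7.05, 17.12, NA, 5.77),
    delta_sd_c = c(0.89, 1.38, NA, 0.45),
    offtarget_nf_prob_r = c(1, 0, 0, 0),
    offtarget_nf_prob_c = c(0, 0, 1, 0),
    het_delta_max = 2,
    stringsAsFactors = FALSE)
}

# One homozygous reaction: the target fluorophore fires near the assay's
# mean Cq; the off-target either never fires (assay-specific NF channel)
# or lags by the assay's configured deltaCq. The lag distribution is the
# both-detected distribution, so the target draw is truncated to keep the
# lagged signal inside the cycling program.
sim_homozygote <- function(prof, strain, max_cycles) {
  if (strain == "R") {
    d_mean <- prof$delta_mean_r; d_sd <- prof$delta_sd_r
    nf_p <- prof$offtarget_nf_prob_r
  } else {
    d_mean <- prof$delta_mean_c; d_sd <- prof$delta_sd_c
    nf_p <- prof$offtarget_nf_prob_c
  }
  nf <- is.na(d_mean) || stats::runif(1) < nf_p
  if (nf) {
    target <- stats::rnorm(1, prof$target_cq_mean, prof$target_cq_sd)
    off <- NA_real_
  } else {
    d <- max(0, stats::rnorm(1, d_mean, d_sd))
    target <- rnorm_upper(1, prof$target_cq_mean, prof$target_cq_sd,
                          upper = max_cycles - d)
    off <- target + d
  }
  if (strain == "R") c(fam = target, vic = off) else c(fam = off, vic = target)
}

# One heterozygous reaction: both probes fire near the target mean, with
# |deltaCq| rejected into the heterozygote band.
sim_heterozygote <- function(prof, max_cycles) {
  repeat {
    f <- stats::rnorm(1, prof$target_cq_mean, prof$target_cq_sd)
    v <- stats::rnorm(1, prof$target_cq_mean, prof$target_cq_sd)
    if (abs(f - v) < prof$het_delta_max && max(f, v) <= max_cycles) break
  }
  c(fam = f, vic = v)
}

#' Simulate a TaqMan Cq dataset with known genotype truth
#'
#' @param truth Data.frame with columns `sample_id`, `assay_id` and
#'   `genotype` ("RR", "CC" or "H").
#' @param profiles Per-assay profiles (see [assay_sim_profiles()]).
#' @param n_replicates Technical replicates per reaction (default 2).
#' @param replicate_sd SD of technical replicate noise around the
#'   reaction mean, in cycles (default 0.15).
#' @param max_cycles Cycling program length; replicate values are bounded
#'   by it and an undetected channel is NF in every replicate.
#' @param dna_ng Template mass recorded per reaction (default 20 ng).
#' @param seed Mandatory integer seed.
#' @return A list: `records` (Cq record data.frame, NF as `NA`) and
#'   `truth` (the input truth table).
#' @export
simulate_cq_dataset <- function(truth, profiles = assay_sim_profiles(),
                                n_replicates = 2, replicate_sd = 0.15,
                                max_cycles = 40, dna_ng = 20, seed) {
  if (missing(seed)) {
    faw_abort("simulate_cq_dataset requires an explicit seed",
              "fawstrain_usage_error")
  }
  need <- c("sample_id", "assay_id", "genotype")
  if (!all(need %in% names(truth))) {
    faw_abort("truth must have columns sample_id, assay_id, genotype",
              "fawstrain_format_error")
  }
  bad <- setdiff(unique(truth$assay_id), profiles$assay_id)
  if (length(bad) > 0L) {
    faw_abort("no simulation profile for assay(s): %s",
              "fawstrain_value_error", paste(bad, collapse = ", "))
  }
  bad_g <- setdiff(unique(truth$genotype), c("RR", "CC", "H"))
  if (length(bad_g) > 0L) {
    faw_abort("unknown genotype(s) in truth: %s", "fawstrain_value_error",
              paste(bad_g, collapse = ", "))
  }
  set.seed(seed)
  rows <- vector("list", nrow(truth) * n_replicates)
  k <- 0L
  for (i in seq_len(nrow(truth))) {
    prof <- profiles[profiles$assay_id == truth$assay_id[i], ]
    reaction <- switch(truth$genotype[i],
      RR = sim_homozygote(prof, "R", max_cycles),
      CC = sim_homozygote(prof, "C", max_cycles),
      H = sim_heterozygote(prof, max_cycles))
    for (rep_i in seq_len(n_replicates)) {
      jitter <- stats::rnorm(2, 0, replicate_sd)
      fam <- if (is.na(reaction[["fam"]])) NA_real_ else
        min(reaction[["fam"]] + jitter[1L], max_cycles)
      vic <- if (is.na(reaction[["vic"]])) NA_real_ else
        min(reaction[["vic"]] + jitter[2L], max_cycles)
      k <- k + 1L
      rows[[k]] <- data.frame(sample_id = truth$sample_id[i],
                              assay_id = truth$assay_id[i],
                              replicate = rep_i, fam_cq = fam, vic_cq = vic,
                              dna_ng = dna_ng, stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  list(records = records, truth = truth)
}

#' Simulate a serial-dilution Cq series
#'
#' Cq follows `intercept + slope * log10(ng)` plus Gaussian noise for
#' amounts at or above the detection floor `lod`; below it no
#' fluorescence is recorded.
#'
#' @param assay_id,fluorophore Identifiers copied into the output.
#' @param concentrations Template amounts (ng); default the seven-step
#'   ten-fold series 100 ... 0.0001.
#' @param slope Standard-curve slope (cycles/decade); default -3.3219
#'   (100% efficiency).
#' @param intercept Cq at 1 ng; default 28.
#' @param noise_sd Cq noise SD (default 0.3).
#' @param lod Detection floor in ng (default 0.001).
#' @param n_bio Biological replicates per concentration (default 3).
#' @param max_cycles Values above this are recorded as NF (default 40).
#' @param seed Mandatory integer seed.
#' @return Data.frame: `assay_id`, `fluorophore`, `sample`, `dna_ng`,
#'   `cq` (`NA` = NF).
#' @export
simulate_dilution_series <- function(assay_id = "SNP A",
                                     fluorophore = "FAM",
                                     concentrations = c(100, 10, 1, 0.1,
                                                        0.01, 0.001, 1e-04),
                                     slope = -3.3219, intercept = 28,
                                     noise_sd = 0.3, lod = 0.001,
                                     n_bio = 3, max_cycles = 40, seed) {
  if (missing(seed)) {
    faw_abort("simulate_dilution_series requires an explicit seed",
              "fawstrain_usage_error")
  }
  set.seed(seed)
  grid <- expand.grid(sample = sprintf("bio%d", seq_len(n_bio)),
                      dna_ng = concentrations, stringsAsFactors = FALSE)
  grid <- grid[order(-grid$dna_ng, grid$sample), , drop = FALSE]
  cq <- intercept + slope * log10(grid$dna_ng) +
    stats::rnorm(nrow(grid), 0, noise_sd)
  cq[grid$dna_ng < lod] <- NA_real_
  cq[!is.na(cq) & cq > max_cycles] <- NA_real_
  out <- data.frame(assay_id = assay_id, fluorophore = fluorophore,
                    sample = grid$sample, dna_ng = grid$dna_ng, cq = cq,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Configuration for the two-strain population simulator
#'
#' @param n_per_strain Individuals per strain (default 50).
#' @param n_hybrids F1 hybrids appended to the cohort (default 0; hybrids
#'   are excluded from the two-group label file).
#' @param n_diagnostic_loci Loci with a strain allele-frequency
#'   differential (default 5).
#' @param n_background_loci Loci with a shared allele frequency
#'   (default 95).
#' @param diag_freq_differential Difference between the two strains'
#'   alternate-allele frequencies at diagnostic loci; 1 (default) means a
#'   fixed difference.
#' @param background_freq Shared alternate-allele frequency of background
#'   loci; `NULL` (default) draws each locus from Uniform(0.1, 0.9).
#' @param chrom_lengths Named integer vector of reference chromosome
#'   lengths; must include one name matching "unplaced" (the filter
#'   decoy) and one "Z".
#' @param lowqual_frac Fraction of background loci written with a decoy
#'   QUAL of 10 (default 0.05).
#' @param dp_mean,dp_min Poisson mean and clamp floor of per-genotype
#'   depth (defaults 20 and 3).
#' @param backcross Simulate hybrids as backcrosses (heterozygous with
#'   probability 1/2 per locus) instead of F1s (default FALSE).
#' @param seed Mandatory integer seed.
#' @return A list of class `faw_popconfig`.
#' @export
population_config <- function(n_per_strain = 50, n_hybrids = 0,
                              n_diagnostic_loci = 5,
                              n_background_loci = 95,
                              diag_freq_differential = 1,
                              background_freq = NULL,
                              chrom_lengths = c(Z = 20000L, `16` = 20000L,
                                                unplaced_scaffold_1 = 5000L),
                              lowqual_frac = 0.05, dp_mean = 20, dp_min = 3,
                              backcross = FALSE, seed) {
  if (missing(seed)) {
    faw_abort("population_config requires an explicit seed",
              "fawstrain_usage_error")
  }
  if (!any(grepl("unplaced", names(chrom_lengths), ignore.case = TRUE))) {
    faw_abort("chrom_lengths must include an 'unplaced' decoy chromosome",
              "fawstrain_value_error")
  }
  stopifnot(n_per_strain >= 2, n_diagnostic_loci >= 0,
            n_background_loci >= 1,
            diag_freq_differential >= 0, diag_freq_differential <= 1)
  structure(list(n_per_strain = n_per_strain, n_hybrids = n_hybrids,
                 n_diagnostic_loci = n_diagnostic_loci,
                 n_background_loci = n_background_loci,
                 diag_freq_differential = diag_freq_differential,
                 background_freq = background_freq,
                 chrom_lengths = chrom_lengths,
                 lowqual_frac = lowqual_frac, dp_mean = dp_mean,
                 dp_min = dp_min, backcross = backcross, seed = seed),
            class = "faw_popconfig")
}

#' Simulate a two-strain population: reference, VCF, labels, truth
#'
#' Builds a random reference, places diagnostic loci (strain-differential
#' allele frequencies, on placed chromosomes) and background loci (shared
#' frequencies; one of them on the unplaced decoy scaffold), draws
#' genotypes under Hardy-Weinberg within strain (F1 hybrids inherit one
#' allele from each strain's frequency distribution), attaches Poisson
#' depths and writes VCF v4.2 text. Deterministic: the same config (same
#' seed) yields byte-identical output files.
#'
#' @param config A [population_config()].
#' @param dir Optional output directory; when given, writes
#'   `reference.fa`, `variants.vcf`, `labels.csv`, `truth_loci.csv` and
#'   `truth_samples.csv`.
#' @return A list: `reference` (DNAStringSet), `vcf_lines` (character),
#'   `labels` (data.frame), `truth_loci`, `truth_samples`, and `paths`
#'   when `dir` was given.
#' @export
simulate_population <- function(config, dir = NULL) {
  stopifnot(inherits(config, "faw_popconfig"))
  set.seed(config$seed)
  cl <- config$chrom_lengths
  unplaced <- names(cl)[grepl("unplaced", names(cl), ignore.case = TRUE)][1L]
  placed <- setdiff(names(cl), unplaced)

  # reference sequences
  ref_seqs <- Biostrings::DNAStringSet(vapply(names(cl), function(ch) {
    paste(sample(c("A", "C", "G", "T"), cl[[ch]], replace = TRUE),
          collapse = "")
  }, character(1)))
  names(ref_seqs) <- names(cl)

  n_loci <- config$n_diagnostic_loci + config$n_background_loci
  # positions: diagnostic + most background on placed chromosomes, one
  # background locus on the unplaced decoy
  chrom <- character(n_loci)
  type <- c(rep("diagnostic", config$n_diagnostic_loci),
            rep("background", config$n_background_loci))
  chrom[type == "diagnostic"] <-
    placed[1L + (seq_len(config$n_diagnostic_loci) - 1L) %% length(placed)]
  n_bg <- config$n_background_loci
  chrom[type == "background"] <-
    placed[1L + (seq_len(n_bg) - 1L) %% length(placed)]
  chrom[which(type == "background")[n_bg]] <- unplaced
  pos <- integer(n_loci)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    lo <- min(300L, cl[[ch]] %/% 10L)
    pos[i] <- sort(sample(seq(lo, cl[[ch]] - lo), length(i)))
  }

  # strain allele frequencies (alternate allele)
  d <- config$diag_freq_differential
  p_c <- p_r <- numeric(n_loci)
  p_c[type == "diagnostic"] <- (1 + d) / 2
  p_r[type == "diagnostic"] <- (1 - d) / 2
  bg <- which(type == "background")
  shared <- if (is.null(config$background_freq)) {
    stats::runif(length(bg), 0.1, 0.9)
  } else rep(config$background_freq, length(bg))
  p_c[bg] <- p_r[bg] <- shared

  # alleles from the reference
  ref_allele <- vapply(seq_len(n_loci), function(i) {
    as.character(Biostrings::subseq(ref_seqs[[chrom[i]]], pos[i], pos[i]))
  }, character(1))
  alt_allele <- vapply(ref_allele, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))

  # QUAL: high, with decoy low-QUAL background loci
  qual <- rep(5000, n_loci)
  n_lowq <- floor(config$lowqual_frac * length(bg))
  if (n_lowq > 0L) qual[sample(bg, n_lowq)] <- 10

  samples <- c(sprintf("C%03d", seq_len(config$n_per_strain)),
               sprintf("R%03d", seq_len(config$n_per_strain)),
               if (config$n_hybrids > 0)
                 sprintf("H%03d", seq_len(config$n_hybrids)))
  group <- c(rep("C", config$n_per_strain), rep("R", config$n_per_strain),
             rep("H", config$n_hybrids))

  draw_gt <- function(p1, p2) {
    # one allele from each parental frequency distribution
    a1 <- stats::rbinom(1L, 1L, p1)
    a2 <- stats::rbinom(1L, 1L, p2)
    paste(sort(c(a1, a2)), collapse = "/")
  }
  gt <- matrix(NA_character_, n_loci, length(samples),
               dimnames = list(NULL, samples))
  for (i in seq_len(n_loci)) {
    for (j in seq_along(samples)) {
      gt[i, j] <- switch(group[j],
        C = draw_gt(p_c[i], p_c[i]),
        R = draw_gt(p_r[i], p_r[i]),
        H = if (config$backcross) {
          # backcross to C: one C allele, the other from an F1 parent
          draw_gt(p_c[i], if (stats::runif(1) < 0.5) p_c[i] else p_r[i])
        } else draw_gt(p_c[i], p_r[i]))
    }
  }
  dp <- matrix(pmax(stats::rpois(n_loci * length(samples), config$dp_mean),
                    config$dp_min),
               n_loci, length(samples))

  vcf_lines <- c(
    "##fileformat=VCFv4.2",
    "##source=fawstrain_population_simulator",
    sprintf("##contig=<ID=%s,length=%d>", names(cl), unname(cl)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  ord <- order(match(chrom, names(cl)), pos)
  for (i in ord) {
    fields <- paste(gt[i, ], dp[i, ], sep = ":")
    vcf_lines <- c(vcf_lines, paste(c(
      chrom[i], pos[i], ".", ref_allele[i], alt_allele[i],
      format(qual[i], scientific = FALSE), "PASS", ".", "GT:DP", fields),
      collapse = "\t"))
  }

  labels <- data.frame(sample_id = samples[group != "H"],
                       group = group[group != "H"],
                       stringsAsFactors = FALSE)
  truth_loci <- data.frame(chrom = chrom, pos = pos, ref = ref_allele,
                           alt = alt_allele, type = type, p_c = p_c,
                           p_r = p_r, qual = qual,
                           stringsAsFactors = FALSE)[ord, ]
  rownames(truth_loci) <- NULL
  truth_samples <- data.frame(sample_id = samples, group = group,
                              stringsAsFactors = FALSE)

  out <- list(reference = ref_seqs, vcf_lines = vcf_lines, labels = labels,
              truth_loci = truth_loci, truth_samples = truth_samples)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(reference = file.path(dir, "reference.fa"),
                  vcf = file.path(dir, "variants.vcf"),
                  labels = file.path(dir, "labels.csv"),
                  truth_loci = file.path(dir, "truth_loci.csv"),
                  truth_samples = file.path(dir, "truth_samples.csv"))
    Biostrings::writeXStringSet(ref_seqs, paths$reference)
    writeLines(vcf_lines, paths$vcf)
    utils::write.csv(labels, paths$labels, row.names = FALSE, quote = FALSE)
    utils::write.csv(truth_loci, paths$truth_loci, row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(truth_samples, paths$truth_samples, row.names = FALSE,
                     quote = FALSE)
    out$paths <- paths
  }
  out
}
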