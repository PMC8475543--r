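test_that("variant filters remove indels, low QUAL, incomplete and unplaced sites", {
  sites <- data.frame(
    chrom = c("Z", "Z", "Z", "unplaced_scaffold_12", "Z", "Z"),
    pos = c(100L, 200L, 300L, 400L, 500L, 600L),
    ref = c("A", "A", "AT", "A", "A", "A"),
    alt = c("G", "G", "A", "G", "G", "G"),
    qual = c(31, 10, 5000, 5000, 5000, 5000),
    stringsAsFactors = FALSE)
  gt <- matrix("0/1", 6, 4, dimnames = list(NULL, paste0("s", 1:4)))
  gt[5, 2] <- NA                       # incomplete call
  dp <- matrix(20L, 6, 4)
  dp[6, 3] <- 2L                       # below 3x coverage
  vs <- fawstrain:::new_variant_set(sites, gt, dp)
  out <- filter_variants(vs)
  rep <- attr(out, "filter_report")
  expect_equal(nrow(out$sites), 1L)
  expect_equal(out$sites$pos, 100L)
  expect_equal(rep$removed_indel_or_multiallelic, 1L)
  expect_equal(rep$removed_low_qual, 1L)
  expect_equal(rep$removed_incomplete_or_low_depth, 2L)
  expect_equal(rep$removed_unplaced, 1L)
  expect_equal(rep$n_retained, 1L)

  # without DP the depth filter must be disabled explicitly
  vs_nodp <- fawstrain:::new_variant_set(sites, gt, NULL)
  expect_error(filter_variants(vs_nodp), class = "fawstrain_format_error")
  expect_equal(nrow(filter_variants(vs_nodp, min_depth = 0)$sites), 2L)
})

test_that("filters commute: any application order retains the same set", {
  set.seed(17)
  n <- 40
  sites <- data.frame(
    chrom = sample(c("Z", "16", "unplaced_scaffold_1"), n, replace = TRUE),
    pos = seq_len(n) * 50L,
    ref = sample(c("A", "C", "AT"), n, replace = TRUE, prob = c(.4, .4, .2)),
    alt = "G", qual = sample(c(10, 5000), n, replace = TRUE),
    stringsAsFactors = FALSE)
  gt <- matrix(sample(c("0/0", "0/1", "1/1", NA), n * 6, replace = TRUE,
                      prob = c(.3, .3, .3, .1)), n, 6,
               dimnames = list(NULL, paste0("s", 1:6)))
  dp <- matrix(sample(c(2L, 20L), n * 6, replace = TRUE, prob = c(.1, .9)),
               n, 6)
  vs <- fawstrain:::new_variant_set(sites, gt, dp)
  full <- filter_variants(vs)

  single <- list(
    function(v) filter_variants(v, min_qual = 0, min_depth = 0,
                                require_complete = FALSE,
                                drop_unplaced = TRUE),
    function(v) filter_variants(v, min_qual = 30, min_depth = 0,
                                require_complete = FALSE,
                                drop_unplaced = FALSE),
    function(v) filter_variants(v, min_qual = 0, min_depth = 3,
                                require_complete = TRUE,
                                drop_unplaced = FALSE))
  for (perm in list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))) {
    v <- vs
    for (i in perm) v <- single[[i]](v)
    expect_equal(v$sites, full$sites)
  }
})

test_that("W&C Fst matches an independent per-allele oracle exhaustively", {
  # all 3^4 = 81 genotype configurations of 2 C + 2 R individuals
  configs <- as.matrix(expand.grid(0:2, 0:2, 0:2, 0:2))
  colnames(configs) <- c("c1", "c2", "r1", "r2")
  vs <- variants_from_dosage(configs)
  labels <- c(c1 = "C", c2 = "C", r1 = "R", r2 = "R")
  fst <- site_fst(vs, labels)
  for (i in seq_len(nrow(configs))) {
    expected <- oracle_wc_theta(list(configs[i, 1:2], configs[i, 3:4]))
    if (is.na(expected)) {
      expect_true(is.na(fst$fst[i]))
    } else {
      expect_equal(fst$fst[i], expected, tolerance = 1e-12)
    }
  }
})

test_that("Fst is 1 at fixed differences and ~0.77 at the 0.9/0.1 HWE config", {
  d_fixed <- cbind(matrix(0L, 1, 10), matrix(2L, 1, 10))
  colnames(d_fixed) <- c(paste0("c", 1:10), paste0("r", 1:10))
  labels <- setNames(rep(c("C", "R"), each = 10), colnames(d_fixed))
  expect_equal(site_fst(variants_from_dosage(d_fixed), labels)$fst, 1)

  # HWE-exact composition: p_alt 0.9 vs 0.1, h = 0.2 in both groups
  d_hwe <- cbind(matrix(rep(c(rep(2L, 8), rep(1L, 2)), 1), 1, 10),
                 matrix(rep(c(rep(0L, 8), rep(1L, 2)), 1), 1, 10))
  colnames(d_hwe) <- colnames(d_fixed)
  res <- site_fst(variants_from_dosage(d_hwe), labels)
  # frozen from the independent per-allele oracle
  expect_equal(res$fst, 0.7696476965, tolerance = 1e-9)
  expect_equal(res$p_c, 0.9)
  expect_equal(res$p_r, 0.1)

  # no differentiation: identical genotype counts give theta <= 0
  d_same <- cbind(matrix(c(2L, 2L, 1L, 1L, 0L), 1, 5),
                  matrix(c(2L, 2L, 1L, 1L, 0L), 1, 5))
  colnames(d_same) <- c(paste0("c", 1:5), paste0("r", 1:5))
  lab5 <- setNames(rep(c("C", "R"), each = 5), colnames(d_same))
  expect_lte(site_fst(variants_from_dosage(d_same), lab5)$fst, 0)
  # the clamped variant truncates into [0, 1]
  expect_gte(site_fst(variants_from_dosage(d_same), lab5,
                      clamp = TRUE)$fst, 0)
})

test_that("hudson cross-check broadly agrees with W&C on strong differentiation", {
  set.seed(23)
  n <- 30
  d <- rbind(cbind(matrix(rbinom(20 * n, 2, 0.95), n, 20),
                   matrix(rbinom(20 * n, 2, 0.05), n, 20)))
  colnames(d) <- c(paste0("c", 1:20), paste0("r", 1:20))
  labels <- setNames(rep(c("C", "R"), each = 20), colnames(d))
  vs <- variants_from_dosage(d)
  wc <- site_fst(vs, labels, estimator = "wc")$fst
  hu <- site_fst(vs, labels, estimator = "hudson")$fst
  expect_true(all(abs(wc - hu) < 0.1, na.rm = TRUE))
  expect_gt(mean(wc, na.rm = TRUE), 0.7)
})

test_that("diagnostic scan returns true loci, ordered, with monotone thresholds", {
  cfg <- population_config(seed = 207)
  sim <- simulate_population(cfg)
  tmp <- withr::local_tempdir()
  vcf_path <- file.path(tmp, "v.vcf")
  writeLines(sim$vcf_lines, vcf_path)
  vs <- filter_variants(read_variants(vcf_path))
  labels <- setNames(sim$labels$group, sim$labels$sample_id)

  cand <- scan_diagnostic(vs, labels, fst_threshold = 0.7)
  truth <- sim$truth_loci[sim$truth_loci$type == "diagnostic", ]
  expect_equal(nrow(cand), 5L)
  expect_setequal(paste(cand$chrom, cand$pos), paste(truth$chrom, truth$pos))
  expect_equal(cand$fst, rep(1, 5))
  # fixed difference: C allele in candidates matches the simulated C allele
  is_alt_c <- truth$p_c[match(paste(cand$chrom, cand$pos),
                              paste(truth$chrom, truth$pos))] > 0.5
  expect_equal(cand$c_allele,
               ifelse(is_alt_c,
                      truth$alt[match(paste(cand$chrom, cand$pos),
                                      paste(truth$chrom, truth$pos))],
                      truth$ref[match(paste(cand$chrom, cand$pos),
                                      paste(truth$chrom, truth$pos))]))
  # equal Fst ties are ordered by coordinate
  expect_equal(order(cand$chrom, cand$pos), seq_len(nrow(cand)))

  # monotone threshold: candidates(t2) subset of candidates(t1), t2 > t1
  c_lo <- scan_diagnostic(vs, labels, fst_threshold = 0.2)
  c_hi <- scan_diagnostic(vs, labels, fst_threshold = 0.9)
  expect_true(all(paste(c_hi$chrom, c_hi$pos) %in%
                    paste(c_lo$chrom, c_lo$pos)))
  expect_equal(nrow(scan_diagnostic(vs, labels, fst_threshold = 1.01)), 0L)
})

test_that("scan sensitivity and specificity reach 0.95 at differential 0.9", {
  cfg <- population_config(n_per_strain = 50, n_diagnostic_loci = 50,
                           n_background_loci = 950,
                           diag_freq_differential = 0.9, seed = 1001)
  sim <- simulate_population(cfg)
  tmp <- withr::local_tempdir()
  vcf_path <- file.path(tmp, "v.vcf")
  writeLines(sim$vcf_lines, vcf_path)
  vs <- filter_variants(read_variants(vcf_path))
  labels <- setNames(sim$labels$group, sim$labels$sample_id)
  cand <- scan_diagnostic(vs, labels, fst_threshold = 0.7)
  truth <- sim$truth_loci
  key <- function(df) paste(df$chrom, df$pos)
  diag_keys <- key(truth[truth$type == "diagnostic", ])
  kept_keys <- key(vs$sites)
  called <- key(cand)
  sensitivity <- mean(diag_keys %in% called)
  specificity <- mean(!setdiff(kept_keys, diag_keys) %in% called)
  expect_gte(sensitivity, 0.95)
  expect_gte(specificity, 0.95)
})

test_that("context windows are 501 positions with neighbours masked", {
  set.seed(3)
  ref <- Biostrings::DNAStringSet(c(chr1 = random_dna(1000)))
  ctx <- extract_context(ref, "chr1", 300, "A", "G",
                         other_positions = c(310L, 700L), flank = 250)
  expect_equal(ctx$window_start, 50L)
  expect_equal(ctx$window_end, 550L)
  # the bracket spells 5 characters but occupies one position
  expect_equal(nchar(ctx$sequence) - 4L, 501L)
  expect_false(ctx$truncated)
  chars <- strsplit(gsub("\\[A/G\\]", "X", ctx$sequence), "")[[1]]
  expect_equal(chars[300 - 50 + 1], "X")
  expect_equal(chars[310 - 50 + 1], "N")           # neighbour masked
  expect_equal(sum(chars == "N"), 1L)              # 700 is outside
  # unmasked positions equal the reference
  plain <- chars
  plain[300 - 50 + 1] <- substr(as.character(ref[[1]]), 300, 300)
  plain[310 - 50 + 1] <- substr(as.character(ref[[1]]), 310, 310)
  expect_equal(paste(plain, collapse = ""),
               substr(as.character(ref[[1]]), 50, 550))

  expect_warning(ctx2 <- extract_context(ref, "chr1", 100, "A", "G"),
                 "truncated")
  expect_equal(ctx2$window_start, 1L)
  expect_equal(ctx2$window_end, 350L)
  expect_true(ctx2$truncated)
  expect_error(extract_context(ref, "chrX", 100, "A", "G"),
               class = "fawstrain_value_error")
})

test_that("context FASTA writer emits one masked record per candidate", {
  set.seed(9)
  ref <- Biostrings::DNAStringSet(c(Z = random_dna(2000)))
  cand <- data.frame(chrom = "Z", pos = c(600L, 1200L), fst = 1,
                     c_allele = "A", r_allele = "G",
                     stringsAsFactors = FALSE)
  sites <- data.frame(chrom = "Z", pos = c(600L, 610L, 1200L))
  path <- withr::local_tempfile(fileext = ".fa")
  write_context_fasta(cand, ref, sites, path)
  lines <- readLines(path)
  expect_length(lines, 4L)
  expect_match(lines[1], "^>Z_600 \\[A/G\\]")
  expect_match(lines[2], "\\[A/G\\]")
  expect_match(lines[2], "N")
})
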