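# Shared fixtures and independent oracles, built in code at test time.

# Wide-format Cq records data.frame (NA = no fluorescence).
cq_records <- function(sample_id, assay_id, fam, vic, replicate = NULL) {
  n <- max(length(fam), length(vic))
  data.frame(sample_id = rep_len(sample_id, n),
             assay_id = rep_len(assay_id, n),
             replicate = replicate %||% seq_len(n),
             fam_cq = rep_len(fam, n), vic_cq = rep_len(vic, n),
             dna_ng = 20, stringsAsFactors = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Independent Weir & Cockerham (1984) oracle: variance components computed
# per allele and summed, from raw per-individual alt-allele dosages
# (0/1/2). Structured differently from the package's two-allele shortcut.
oracle_wc_theta <- function(geno_list) {
  r <- length(geno_list)
  n <- vapply(geno_list, length, numeric(1))
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  num <- 0
  den <- 0
  for (u in c("ref", "alt")) {
    p <- vapply(geno_list, function(g)
      (sum(g == 2L) * 2 + sum(g == 1L)) / (2 * length(g)), numeric(1))
    if (u == "ref") p <- 1 - p
    h <- vapply(geno_list, function(g) mean(g == 1L), numeric(1))
    pbar <- sum(n * p) / (r * nbar)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  if (!is.finite(den) || den == 0) return(NA_real_)
  num / den
}

# Build an faw_variants object directly from a dosage matrix
# (sites x samples, values 0/1/2 or NA).
variants_from_dosage <- function(dosage, chrom = "Z",
                                 pos = seq_len(nrow(dosage)) * 10L,
                                 qual = 5000, dp = 20L) {
  gt <- matrix(c("0/0", "0/1", "1/1")[dosage + 1L], nrow(dosage),
               ncol(dosage), dimnames = dimnames(dosage))
  dpm <- matrix(dp, nrow(dosage), ncol(dosage))
  dpm[is.na(gt)] <- NA_integer_
  fawstrain:::new_variant_set(
    data.frame(chrom = rep_len(chrom, nrow(dosage)), pos = pos,
               ref = "A", alt = "G", qual = rep_len(qual, nrow(dosage)),
               stringsAsFactors = FALSE),
    gt, dpm)
}

# A small reference + VCF on disk for parser round-trips.
write_tiny_vcf <- function(path, sites, gt, dp = NULL,
                           samples = colnames(gt)) {
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  fmt <- "GT"
  if (!is.null(dp)) {
    lines <- c(lines,
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">")
    fmt <- "GT:DP"
  }
  lines <- c(lines, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                            "FILTER", "INFO", "FORMAT", samples),
                          collapse = "\t"))
  for (i in seq_len(nrow(sites))) {
    cells <- if (is.null(dp)) gt[i, ] else paste(gt[i, ], dp[i, ], sep = ":")
    lines <- c(lines, paste(c(sites$chrom[i], sites$pos[i], ".",
                              sites$ref[i], sites$alt[i], sites$qual[i],
                              "PASS", ".", fmt, cells), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

# Random ACGT string.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
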