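#' @title Diagnostic SNP discovery from a two-strain genotype matrix
#' @name snp_discovery
#' @description
#' Starting from a multi-sample VCF of individuals pre-assigned to the C-
#' or R-strain (by their COI haplotype), the discovery workflow (i) keeps
#' only high-confidence biallelic SNPs -- no indels, site quality >= 30,
#' genotype present in every individual at >= 3x depth, not on an unplaced
#' scaffold -- (ii) computes a per-site Weir & Cockerham (1984) fixation
#' index between the two strains, (iii) ranks candidates with Fst above a
#' threshold (default 0.7), and (iv) extracts a 501 bp assay-design context
#' window around each candidate with the focal alleles in bracket notation
#' and every other known variant position masked as N.
NULL

#' Load a VCF into a variant set
#'
#' Thin wrapper over `vcfR::read.vcfR` that reshapes the records into the
#' package's `faw_variants` container: a site table plus per-sample GT and
#' DP matrices.
#'
#' @param path Path to a VCF (v4.x) file with per-sample GT (and normally
#'   DP) fields.
#' @return An object of class `faw_variants`: list with `sites`
#'   (data.frame `chrom`, `pos`, `ref`, `alt`, `qual`), `gt` (character
#'   matrix, sites x samples, e.g. "0/1" or `NA`), `dp` (integer matrix or
#'   `NULL` when the VCF carries no DP).
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) {
    faw_abort("VCF not found: %s", "fawstrain_io_error", path)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  gt <- vcfR::extract.gt(v, element = "GT")
  gt[gt %in% c(".", "./.", ".|.")] <- NA_character_
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dp <- NULL
  fmt_keys <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  if ("DP" %in% fmt_keys) {
    dp <- suppressWarnings(
      vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    storage.mode(dp) <- "integer"
  }
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
                      stringsAsFactors = FALSE)
  new_variant_set(sites, gt, dp)
}

new_variant_set <- function(sites, gt, dp = NULL) {
  structure(list(sites = sites, gt = gt, dp = dp), class = "faw_variants")
}

#' @export
print.faw_variants <- function(x, ...) {
  cat(sprintf("<faw_variants> %d site(s) x %d sample(s)\n",
              nrow(x$sites), ncol(x$gt)))
  invisible(x)
}

is_biallelic_snp <- function(sites) {
  nchar(sites$ref) == 1L & nchar(sites$alt) == 1L &
    sites$ref %in% c("A", "C", "G", "T") &
    sites$alt %in% c("A", "C", "G", "T") &
    !grepl(",", sites$alt, fixed = TRUE)
}

#' Filter variants for diagnostic-SNP discovery
#'
#' Retains biallelic SNPs (indels and multi-allelic records removed) with
#' site quality at least `min_qual`, a called genotype in every sample at
#' depth at least `min_depth`, and a chromosome name not matching the
#' unplaced-scaffold pattern. The four filters commute: the retained set
#' is their intersection, whatever the order. The attached report counts
#' removals per filter, evaluated in the order listed above.
#'
#' @param variants An `faw_variants` object (see [read_variants()]).
#' @param min_qual Minimum site QUAL (PHRED); default 30.
#' @param min_depth Minimum per-genotype depth in every sample; default 3.
#'   Set to 0 to skip the depth requirement (mandatory when the VCF has no
#'   DP field).
#' @param require_complete Require a called genotype in all samples
#'   (default TRUE).
#' @param drop_unplaced Remove sites whose chromosome matches
#'   `unplaced_pattern` (default TRUE).
#' @param unplaced_pattern Regular expression identifying unplaced
#'   scaffolds; default "unplaced" (case-insensitive).
#' @return The filtered `faw_variants`, with attribute `filter_report`
#'   (named list of counts).
#' @export
filter_variants <- function(variants, min_qual = 30, min_depth = 3,
                            require_complete = TRUE, drop_unplaced = TRUE,
                            unplaced_pattern = "unplaced") {
  stopifnot(inherits(variants, "faw_variants"))
  if (min_depth > 0 && is.null(variants$dp)) {
    faw_abort(paste("VCF has no DP field; supply min_depth = 0 to filter",
                    "without a depth requirement"),
              "fawstrain_format_error")
  }
  sites <- variants$sites
  n <- nrow(sites)
  pass_snp <- is_biallelic_snp(sites)
  pass_qual <- !is.na(sites$qual) & sites$qual >= min_qual
  complete <- rep(TRUE, n)
  if (require_complete) complete <- !apply(is.na(variants$gt), 1L, any)
  if (min_depth > 0) {
    depth_ok <- !apply(is.na(variants$dp) | variants$dp < min_depth, 1L, any)
    complete <- complete & depth_ok
  }
  placed <- rep(TRUE, n)
  if (drop_unplaced) {
    placed <- !grepl(unplaced_pattern, sites$chrom, ignore.case = TRUE)
  }
  keep <- pass_snp & pass_qual & complete & placed
  report <- list(
    n_input = n,
    removed_indel_or_multiallelic = sum(!pass_snp),
    removed_low_qual = sum(pass_snp & !pass_qual),
    removed_incomplete_or_low_depth = sum(pass_snp & pass_qual & !complete),
    removed_unplaced = sum(pass_snp & pass_qual & complete & !placed),
    n_retained = sum(keep))
  out <- new_variant_set(sites[keep, , drop = FALSE],
                         variants$gt[keep, , drop = FALSE],
                         if (is.null(variants$dp)) NULL else
                           variants$dp[keep, , drop = FALSE])
  attr(out, "filter_report") <- report
  out
}

# Per-population allele/heterozygote summaries from one site's genotypes.
# Missing genotypes are dropped per-site from the counts.
pop_summary <- function(gt_row, samples_in_pop) {
  g <- gt_row[samples_in_pop]
  g <- g[!is.na(g)]
  n <- length(g)
  if (n == 0L) return(list(n = 0L, p = NA_real_, h = NA_real_))
  alt_count <- vapply(strsplit(g, "/", fixed = TRUE), function(al)
    sum(al == "1"), numeric(1))
  list(n = n, p = sum(alt_count) / (2 * n),
       h = mean(alt_count == 1L))
}

# Weir & Cockerham (1984) single-locus theta for two populations from
# sample sizes, alt-allele frequencies and observed heterozygosities.
wc_theta <- function(n, p, h, clamp = FALSE) {
  r <- length(n)
  if (any(n < 2)) return(NA_real_)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  den <- a + b + cc
  if (!is.finite(den) || den == 0) return(NA_real_)
  th <- a / den
  if (clamp) th <- min(max(th, 0), 1)
  th
}

#' Per-site fixation index between two strains
#'
#' Computes the Weir & Cockerham (1984) single-locus theta between the two
#' labelled groups at every site, from group allele frequencies, sample
#' sizes and observed heterozygosity. The unclamped estimator may be
#' negative at undifferentiated sites; `clamp = TRUE` truncates to [0, 1].
#' A Hudson-style estimator (`estimator = "hudson"`) is available as a
#' cross-check. Sites where either group has fewer than two called
#' individuals get `NA` and are excluded from scans.
#'
#' @param variants An `faw_variants` object.
#' @param labels Named character vector (or two-column data.frame
#'   `sample_id`, `group`) assigning samples to "C" or "R"; samples with
#'   other labels are ignored.
#' @param estimator "wc" (default) or "hudson".
#' @param clamp Truncate estimates to [0, 1]; default FALSE.
#' @return A data.frame per site: `chrom`, `pos`, `fst`, `p_c`, `p_r`
#'   (alt-allele frequencies), `n_c`, `n_r`.
#' @export
site_fst <- function(variants, labels, estimator = c("wc", "hudson"),
                     clamp = FALSE) {
  stopifnot(inherits(variants, "faw_variants"))
  estimator <- match.arg(estimator)
  labels <- as_label_vector(labels)
  samples <- colnames(variants$gt)
  c_samples <- intersect(samples, names(labels)[labels == "C"])
  r_samples <- intersect(samples, names(labels)[labels == "R"])
  if (length(c_samples) < 2L || length(r_samples) < 2L) {
    faw_abort("need at least two labelled samples per strain",
              "fawstrain_value_error")
  }
  res <- lapply(seq_len(nrow(variants$sites)), function(i) {
    row <- variants$gt[i, ]
    sc <- pop_summary(row, c_samples)
    sr <- pop_summary(row, r_samples)
    fst <- NA_real_
    if (sc$n >= 2L && sr$n >= 2L) {
      fst <- if (estimator == "wc") {
        wc_theta(c(sc$n, sr$n), c(sc$p, sr$p), c(sc$h, sr$h), clamp = clamp)
      } else {
        hudson_fst(c(sc$n, sr$n), c(sc$p, sr$p), clamp = clamp)
      }
    }
    c(fst = fst, p_c = sc$p, p_r = sr$p, n_c = sc$n, n_r = sr$n)
  })
  out <- cbind(variants$sites[, c("chrom", "pos")],
               as.data.frame(do.call(rbind, res)))
  rownames(out) <- NULL
  out
}

# Hudson estimator with the standard small-sample correction of the
# within-population heterozygosity; offered as an independent cross-check.
hudson_fst <- function(n, p, clamp = FALSE) {
  num <- (p[1] - p[2])^2 -
    p[1] * (1 - p[1]) / (2 * n[1] - 1) - p[2] * (1 - p[2]) / (2 * n[2] - 1)
  den <- p[1] * (1 - p[2]) + p[2] * (1 - p[1])
  if (!is.finite(den) || den == 0) return(NA_real_)
  f <- num / den
  if (clamp) f <- min(max(f, 0), 1)
  f
}

as_label_vector <- function(labels) {
  if (is.data.frame(labels)) {
    need <- c("sample_id", "group")
    if (!all(need %in% names(labels))) {
      faw_abort("label table must have columns sample_id and group",
                "fawstrain_format_error")
    }
    labels <- stats::setNames(toupper(labels$group), labels$sample_id)
  }
  if (is.null(names(labels))) {
    faw_abort("labels must be named by sample id", "fawstrain_value_error")
  }
  labels
}

#' Read a two-column sample-label file
#'
#' @param path CSV/TSV with columns `sample_id` (or `sample`) and `group`.
#' @return Named character vector of group labels.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) {
    faw_abort("label file not found: %s", "fawstrain_io_error", path)
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  names(df)[names(df) == "sample"] <- "sample_id"
  as_label_vector(df)
}

#' Scan for diagnostic candidate SNPs
#'
#' Ranks sites whose between-strain Fst exceeds the threshold, Fst
#' descending with coordinate tie-breaks, and assigns each candidate's
#' strain-predominant alleles: the C-strain allele is the allele at higher
#' frequency in the C group (and conversely for R).
#'
#' @param variants Filtered `faw_variants`.
#' @param labels Sample-to-strain labels (see [site_fst()]).
#' @param fst_threshold Candidates must have Fst strictly above this
#'   (default 0.7).
#' @param estimator Passed to [site_fst()].
#' @return A data.frame: `chrom`, `pos`, `fst`, `c_allele`, `r_allele`,
#'   `p_c`, `p_r`, `n_c`, `n_r` (possibly 0 rows).
#' @export
scan_diagnostic <- function(variants, labels, fst_threshold = 0.7,
                            estimator = "wc") {
  fst <- site_fst(variants, labels, estimator = estimator)
  keep <- !is.na(fst$fst) & fst$fst > fst_threshold
  out <- cbind(fst[keep, , drop = FALSE],
               variants$sites[keep, c("ref", "alt"), drop = FALSE])
  # allele predominating in the C group is the C-strain allele
  c_has_alt <- out$p_c >= out$p_r
  out$c_allele <- ifelse(c_has_alt, out$alt, out$ref)
  out$r_allele <- ifelse(c_has_alt, out$ref, out$alt)
  ord <- order(-out$fst, out$chrom, out$pos)
  out <- out[ord, c("chrom", "pos", "fst", "c_allele", "r_allele",
                    "p_c", "p_r", "n_c", "n_r"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract an assay-design context sequence around a focal SNP
#'
#' Returns the reference window `flank` bp either side of the focal
#' position (501 positions with the default flank of 250, the bracket
#' counting as one position). The focal position is rendered as
#' `[C_allele/R_allele]`; every other known variant position inside the
#' window is masked as `N` so probe design avoids it. Windows running off
#' a chromosome end are truncated with a warning.
#'
#' @param reference A `Biostrings::DNAStringSet` or path to a FASTA file.
#' @param chrom,pos Focal SNP coordinates (1-based).
#' @param c_allele,r_allele Focal alleles; the C-strain allele is written
#'   first in the bracket.
#' @param other_positions Integer positions (on `chrom`) of all other
#'   known variants; those inside the window are masked.
#' @param flank Flank size in bp (default 250).
#' @return A list of class `faw_context`: `sequence`, `window_start`,
#'   `window_end`, `truncated`, `chrom`, `pos`.
#' @export
extract_context <- function(reference, chrom, pos, c_allele, r_allele,
                            other_positions = integer(0), flank = 250) {
  ref <- load_reference(reference)
  ref_names <- sub("\\s.*$", "", names(ref))
  idx <- match(chrom, ref_names)
  if (is.na(idx)) {
    faw_abort("chromosome '%s' not found in the reference",
              "fawstrain_value_error", chrom)
  }
  chrom_len <- Biostrings::width(ref)[idx]
  if (pos < 1L || pos > chrom_len) {
    faw_abort("position %d outside chromosome '%s' (length %d)",
              "fawstrain_value_error", pos, chrom, chrom_len)
  }
  start <- max(1L, pos - as.integer(flank))
  end <- min(chrom_len, pos + as.integer(flank))
  truncated <- (start > pos - flank) || (end < pos + flank)
  if (truncated) {
    faw_warn("context window for %s:%d truncated to %d-%d", chrom, pos,
             start, end)
  }
  window <- strsplit(as.character(
    Biostrings::subseq(ref[[idx]], start, end)), "")[[1L]]
  rel <- function(p) p - start + 1L
  mask <- other_positions[other_positions >= start &
                          other_positions <= end &
                          other_positions != pos]
  window[rel(mask)] <- "N"
  window[rel(pos)] <- sprintf("[%s/%s]", c_allele, r_allele)
  structure(list(sequence = paste(window, collapse = ""),
                 window_start = start, window_end = end,
                 truncated = truncated, chrom = chrom, pos = pos),
            class = "faw_context")
}

load_reference <- function(reference) {
  if (inherits(reference, "DNAStringSet")) return(reference)
  if (is.character(reference) && length(reference) == 1L) {
    if (!file.exists(reference)) {
      faw_abort("reference FASTA not found: %s", "fawstrain_io_error",
                reference)
    }
    return(Biostrings::readDNAStringSet(reference))
  }
  faw_abort("reference must be a DNAStringSet or FASTA path",
            "fawstrain_value_error")
}

#' @export
print.faw_context <- function(x, ...) {
  cat(sprintf("<faw_context> %s:%d window %d-%d%s\n", x$chrom, x$pos,
              x$window_start, x$window_end,
              if (x$truncated) " (truncated)" else ""))
  invisible(x)
}

#' Write context sequences for a candidate table as FASTA
#'
#' @param candidates Candidate data.frame from [scan_diagnostic()].
#' @param reference Reference FASTA path or `DNAStringSet`.
#' @param all_sites Data.frame of all known variant sites (`chrom`,
#'   `pos`), used for N-masking neighbours.
#' @param path Output FASTA path.
#' @param flank Flank size (default 250).
#' @return `path`, invisibly.
#' @export
write_context_fasta <- function(candidates, reference, all_sites, path,
                                flank = 250) {
  ref <- load_reference(reference)
  lines <- character(0)
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    others <- all_sites$pos[all_sites$chrom == cand$chrom]
    ctx <- extract_context(ref, cand$chrom, cand$pos, cand$c_allele,
                           cand$r_allele, other_positions = others,
                           flank = flank)
    lines <- c(lines,
               sprintf(">%s_%d [%s/%s] fst=%.4f window=%d-%d", cand$chrom,
                       cand$pos, cand$c_allele, cand$r_allele, cand$fst,
                       ctx$window_start, ctx$window_end),
               ctx$sequence)
  }
  writeLines(lines, path)
  invisible(path)
}
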