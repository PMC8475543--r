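#' @title Multi-marker consensus strain assignment
#' @name consensus_typing
#' @description
#' Per-marker strain calls (four TaqMan SNP assays plus the COI and Tpi
#' RFLP markers) are combined into a per-sample consensus. A sample is
#' assigned C, R or H when at least `min_agree` of its markers (default 5
#' of the 6-marker panel) agree; failing that, a sample with at least two
#' hybrid (H) marker calls is assigned H; otherwise no consensus (NONE) is
#' reached. Because COI is maternally inherited it can never vote H, and
#' because female Lepidoptera carry a single Z chromosome, an H call at a
#' Z-linked marker in a known female is biologically impossible and is
#' demoted to INCONCLUSIVE with an `IMPOSSIBLE_HET` flag.
NULL

STRAIN_LEVELS <- c("C", "R", "H", "INCONCLUSIVE")

# Map genotype-call vocabulary (CC/RR) onto strain vocabulary (C/R).
normalize_strain_call <- function(call) {
  x <- toupper(trimws(as.character(call)))
  x[x == "CC"] <- "C"
  x[x == "RR"] <- "R"
  bad <- setdiff(unique(x), STRAIN_LEVELS)
  if (length(bad) > 0L) {
    faw_abort("unrecognised strain call(s): %s", "fawstrain_value_error",
              paste(bad, collapse = ", "))
  }
  x
}

# Apply marker-level validity rules to one sample's calls before voting:
# COI cannot vote H; a female cannot be heterozygous at a Z-linked marker.
validate_marker_calls <- function(calls, assay_ids, sex = "unknown",
                                  assays = builtin_assays()) {
  flags <- rep("", length(calls))
  for (i in seq_along(calls)) {
    a <- assays[[assay_ids[i]]]
    if (is.null(a)) next
    if (a$marker_class == "rflp_coi" && calls[i] == "H") {
      calls[i] <- "INCONCLUSIVE"
      flags[i] <- "COI_H_INVALID"
    } else if (identical(sex, "female") && a$linkage == "Z" &&
               calls[i] == "H") {
      calls[i] <- "INCONCLUSIVE"
      flags[i] <- "IMPOSSIBLE_HET"
    }
  }
  list(calls = calls, flags = flags)
}

#' Consensus strain for one sample
#'
#' @param calls Named character vector of marker calls (names = assay ids;
#'   values among C/R/H/INCONCLUSIVE, with CC/RR accepted as synonyms).
#' @param min_agree Minimum number of agreeing non-inconclusive markers for
#'   a consensus (absolute count; default 5 for the 6-marker panel).
#' @param sex "male", "female" or "unknown"; used to invalidate impossible
#'   heterozygote calls at Z-linked markers in females.
#' @param assays Assay definitions used for linkage/class lookups.
#' @return A list of class `faw_consensus`: `consensus` ("C","R","H" or
#'   "NONE"), `n_agree`, `n_markers` (markers with a non-inconclusive
#'   call), `calls` (after validity demotions) and `flags`.
#' @examples
#' consensus_strain(c(`SNP A` = "C", `SNP B` = "C", `SNP C` = "C",
#'                    `SNP D` = "C", COI = "C", Tpi = "R"))
#' @export
consensus_strain <- function(calls, min_agree = 5, sex = "unknown",
                             assays = builtin_assays()) {
  if (length(calls) == 0L) {
    faw_abort("empty marker call set", "fawstrain_usage_error")
  }
  sex <- match.arg(sex, c("unknown", "male", "female"))
  x <- normalize_strain_call(calls)
  ids <- names(calls) %||% rep(NA_character_, length(calls))
  v <- validate_marker_calls(x, ids, sex = sex, assays = assays)
  x <- v$calls
  informative <- x[x != "INCONCLUSIVE"]
  if (length(informative) == 0L) {
    faw_abort("no non-inconclusive marker call for this sample",
              "fawstrain_usage_error")
  }
  counts <- table(factor(informative, levels = c("C", "R", "H")))
  top <- names(counts)[which.max(counts)]
  consensus <- "NONE"
  n_agree <- as.integer(max(counts))
  if (max(counts) >= min_agree) {
    consensus <- top
  } else if (counts[["H"]] >= 2L) {
    # discordant markers, but two independent hybrid signals
    consensus <- "H"
    n_agree <- as.integer(counts[["H"]])
  }
  structure(list(consensus = consensus, n_agree = n_agree,
                 n_markers = length(informative),
                 calls = stats::setNames(x, ids), flags = v$flags),
            class = "faw_consensus")
}

#' @export
print.faw_consensus <- function(x, ...) {
  cat(sprintf("<faw_consensus> %s (%d/%d markers agree)\n", x$consensus,
              x$n_agree, x$n_markers))
  invisible(x)
}

#' Consensus strain assignment for a cohort
#'
#' @param calls Long data.frame with columns `sample_id`, `assay_id`,
#'   `call` (typically [call_plate()] output merged with RFLP calls).
#' @param metadata Optional data.frame with columns `sample_id` and `sex`.
#' @param min_agree Absolute agreement threshold; `NULL` scales the
#'   6-marker default as `ceiling(5/6 * m)` for an m-marker panel.
#' @param assays Assay definitions.
#' @return A data.frame with one row per sample: `consensus`, `n_agree`,
#'   `n_markers`.
#' @export
consensus_table <- function(calls, metadata = NULL, min_agree = NULL,
                            assays = builtin_assays()) {
  need <- c("sample_id", "assay_id", "call")
  if (!all(need %in% names(calls))) {
    faw_abort("calls must have columns sample_id, assay_id, call",
              "fawstrain_format_error")
  }
  sex_of <- function(s) {
    if (is.null(metadata)) return("unknown")
    m <- metadata$sex[match(s, metadata$sample_id)]
    if (is.na(m) || !m %in% c("male", "female")) "unknown" else m
  }
  samples <- sort(unique(calls$sample_id))
  rows <- lapply(samples, function(s) {
    sub <- calls[calls$sample_id == s, , drop = FALSE]
    ma <- min_agree %||% ceiling(5 / 6 * nrow(sub))
    cs <- consensus_strain(stats::setNames(sub$call, sub$assay_id),
                           min_agree = ma, sex = sex_of(s), assays = assays)
    data.frame(sample_id = s, consensus = cs$consensus,
               n_agree = cs$n_agree, n_markers = cs$n_markers,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-assay agreement with the consensus
#'
#' Computes, for every assay, how many samples' marker calls match the
#' sample's consensus strain. Samples without a consensus (NONE) are
#' excluded from every assay's denominator. The cohort-level summary (the
#' attribute `cohort`) reports the percentage of samples that reached a
#' consensus.
#'
#' @param calls Long call data.frame (`sample_id`, `assay_id`, `call`).
#' @param consensuses Output of [consensus_table()] for the same samples.
#' @return A data.frame per assay (`n_match`, `n_mismatch`,
#'   `n_inconclusive`, `proportion`), with attribute `cohort` = list of
#'   `n_samples`, `n_consensus`, `pct_consensus`.
#' @export
marker_accuracy <- function(calls, consensuses) {
  n_samples <- nrow(consensuses)
  with_cons <- consensuses[consensuses$consensus != "NONE", , drop = FALSE]
  if (nrow(with_cons) == 0L) {
    faw_abort("no sample reached a consensus; accuracy undefined",
              "fawstrain_value_error")
  }
  calls <- calls[calls$sample_id %in% with_cons$sample_id, , drop = FALSE]
  calls$call <- normalize_strain_call(calls$call)
  calls$truth <- with_cons$consensus[match(calls$sample_id,
                                           with_cons$sample_id)]
  rows <- lapply(split(calls, calls$assay_id), function(sub) {
    inc <- sub$call == "INCONCLUSIVE"
    match_n <- sum(!inc & sub$call == sub$truth)
    data.frame(assay_id = sub$assay_id[1L],
               n_match = match_n,
               n_mismatch = sum(!inc & sub$call != sub$truth),
               n_inconclusive = sum(inc),
               proportion = match_n / nrow(sub),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$assay_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cohort") <- list(
    n_samples = n_samples,
    n_consensus = nrow(with_cons),
    pct_consensus = 100 * nrow(with_cons) / n_samples)
  out
}

#' Chi-square test of homogeneity across assays
#'
#' Pearson chi-square test on an r x c contingency table (typically
#' match/mismatch counts per assay) with expectations from the row/column
#' margins and df = (r-1)(c-1); no continuity correction.
#'
#' @param counts Numeric matrix or data.frame of non-negative counts.
#' @return A list with `statistic`, `df` and `p_value`.
#' @export
chi_square_homogeneity <- function(counts) {
  m <- as.matrix(counts)
  if (any(m < 0) || anyNA(m)) {
    faw_abort("counts must be non-negative and complete",
              "fawstrain_value_error")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    faw_abort("zero row or column margin: expected counts are undefined",
              "fawstrain_value_error")
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' Recommended three-marker panel by sex
#'
#' With only three assays a strain can be confidently assigned. Males (ZZ)
#' can be typed with the three Z-linked SNP assays; for females or samples
#' of unknown sex the autosomal SNP D replaces SNP B so hybrids remain
#' detectable on the single-Z background.
#'
#' @param sex "male", "female" or "unknown".
#' @return Character vector of assay ids, in recommended order.
#' @export
recommend_markers <- function(sex = "unknown") {
  sex <- match.arg(sex, c("unknown", "male", "female"))
  if (sex == "male") c("SNP A", "SNP B", "SNP C") else
    c("SNP A", "SNP C", "SNP D")
}
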