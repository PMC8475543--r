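#' @title TaqMan genotype calling from Cq tables
#' @name taqman_caller
#' @description
#' Allele-specific TaqMan genotyping reads two fluorophores per reaction:
#' FAM reports the R-strain allele and VIC the C-strain allele. Reactions
#' are run in technical duplicate; a fluorophore counts as detected only if
#' it fired in every replicate. The signed cycle difference between the two
#' replicate-averaged Cq values (deltaCq) separates homozygotes (the target
#' probe leads by several cycles, or the off-target probe never fires) from
#' heterozygotes (both probes fire within 0-2 cycles of each other).
#' On disk, "no fluorescence" (NF) is encoded as Cq 0; in memory it is an
#' explicit not-detected state (`NA`) so no arithmetic ever touches the
#' sentinel.
NULL

CALL_LEVELS <- c("CC", "RR", "H", "INCONCLUSIVE")

#' Read a Cq table
#'
#' Reads a delimited text export of FAM/VIC quantification cycles. Two
#' layouts are auto-detected from the header: wide (columns `sample`,
#' `assay`, `replicate`, `fam_cq`, `vic_cq`, optional `dna_ng`) and long
#' (columns `sample`, `assay`, `replicate`, `fluorophore`, `cq`). A Cq of 0
#' or an empty field means no fluorescence was detected (NF) and is stored
#' as `NA`.
#'
#' @param path Path to a CSV/TSV file (separator sniffed from the header).
#' @param max_cycles Upper bound for a valid Cq (cycles in the qPCR
#'   program); larger values are a value error. Default 40.
#' @param known_assays Optional character vector of recognised assay ids;
#'   rows with other ids are kept but flagged with a warning.
#' @return A data.frame of Cq records with columns `sample_id`, `assay_id`,
#'   `replicate`, `fam_cq`, `vic_cq`, `dna_ng` (`NA` = NF).
#' @export
read_cq_table <- function(path, max_cycles = 40, known_assays = NULL) {
  if (!file.exists(path)) {
    faw_abort("Cq table not found: %s", "fawstrain_io_error", path)
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA", "NF", "N/A"))
  names(df) <- tolower(names(df))
  names(df)[names(df) == "sample"] <- "sample_id"
  names(df)[names(df) == "assay"] <- "assay_id"
  long <- all(c("fluorophore", "cq") %in% names(df))
  need <- if (long) c("sample_id", "assay_id", "replicate", "fluorophore", "cq")
          else c("sample_id", "assay_id", "replicate", "fam_cq", "vic_cq")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    faw_abort("Cq table %s is missing required column(s): %s",
              "fawstrain_format_error", path,
              paste(missing_cols, collapse = ", "))
  }
  if (long) {
    fl <- toupper(df$fluorophore)
    if (!all(fl %in% c("FAM", "VIC"))) {
      faw_abort("long-format fluorophore column must be FAM or VIC",
                "fawstrain_format_error")
    }
    key <- interaction(df$sample_id, df$assay_id, df$replicate, drop = TRUE)
    wide <- data.frame(
      sample_id = tapply(df$sample_id, key, `[`, 1L),
      assay_id = tapply(df$assay_id, key, `[`, 1L),
      replicate = as.integer(tapply(df$replicate, key, `[`, 1L)),
      fam_cq = as.numeric(tapply(ifelse(fl == "FAM", df$cq, NA), key,
                                 function(x) x[!is.na(x)][1L])),
      vic_cq = as.numeric(tapply(ifelse(fl == "VIC", df$cq, NA), key,
                                 function(x) x[!is.na(x)][1L])),
      stringsAsFactors = FALSE)
    if ("dna_ng" %in% names(df)) {
      wide$dna_ng <- as.numeric(tapply(df$dna_ng, key, `[`, 1L))
    }
    df <- wide
    rownames(df) <- NULL
  }
  if (!"dna_ng" %in% names(df)) df$dna_ng <- rep(NA_real_, nrow(df))
  for (col in c("fam_cq", "vic_cq")) {
    x <- as.numeric(df[[col]])
    if (any(x < 0, na.rm = TRUE)) {
      faw_abort("negative Cq in column %s", "fawstrain_value_error", col)
    }
    if (any(x > max_cycles, na.rm = TRUE)) {
      faw_abort("Cq above max_cycles (%s) in column %s: %s",
                "fawstrain_value_error", max_cycles, col,
                max(x, na.rm = TRUE))
    }
    x[!is.na(x) & x == 0] <- NA_real_   # NF-as-zero disk convention
    df[[col]] <- x
  }
  df$replicate <- as.integer(df$replicate)
  if (any(df$replicate < 1L, na.rm = TRUE)) {
    faw_abort("replicate indices must be >= 1", "fawstrain_value_error")
  }
  if (!is.null(known_assays)) {
    unknown <- setdiff(unique(df$assay_id), known_assays)
    if (length(unknown) > 0L) {
      faw_warn("Cq table contains unknown assay id(s): %s",
               paste(unknown, collapse = ", "))
    }
  }
  df[c("sample_id", "assay_id", "replicate", "fam_cq", "vic_cq", "dna_ng")]
}

#' Write a Cq table using the NF-as-zero disk convention
#'
#' @param records Cq records as returned by [read_cq_table()] or
#'   [simulate_cq_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cq_table <- function(records, path) {
  out <- records
  out$fam_cq <- ifelse(is.na(out$fam_cq), 0, out$fam_cq)
  out$vic_cq <- ifelse(is.na(out$vic_cq), 0, out$vic_cq)
  names(out)[names(out) == "sample_id"] <- "sample"
  names(out)[names(out) == "assay_id"] <- "assay"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate technical replicates
#'
#' Averages Cq per fluorophore over technical replicates of the same
#' sample x assay reaction. A fluorophore is considered detected only when
#' it was detected in all replicates; if any replicate is NF the
#' fluorophore is treated as not detected and its mean is `NA`.
#'
#' @param records Cq record data.frame (see [read_cq_table()]).
#' @return A data.frame with one row per (sample, assay): `fam_cq_mean`,
#'   `vic_cq_mean`, `fam_detected`, `vic_detected`, `n_replicates`,
#'   `dna_ng`.
#' @export
aggregate_replicates <- function(records) {
  if (nrow(records) == 0L) {
    faw_warn("no Cq records to aggregate")
    return(data.frame(sample_id = character(0), assay_id = character(0),
                      fam_cq_mean = numeric(0), vic_cq_mean = numeric(0),
                      fam_detected = logical(0), vic_detected = logical(0),
                      n_replicates = integer(0), dna_ng = numeric(0)))
  }
  key <- paste(records$sample_id, records$assay_id, sep = "\r")
  idx <- split(seq_len(nrow(records)), key)
  rows <- lapply(idx, function(i) {
    fam <- records$fam_cq[i]
    vic <- records$vic_cq[i]
    fam_det <- length(fam) > 0L && !anyNA(fam)
    vic_det <- length(vic) > 0L && !anyNA(vic)
    data.frame(sample_id = records$sample_id[i[1L]],
               assay_id = records$assay_id[i[1L]],
               fam_cq_mean = if (fam_det) mean(fam) else NA_real_,
               vic_cq_mean = if (vic_det) mean(vic) else NA_real_,
               fam_detected = fam_det, vic_detected = vic_det,
               n_replicates = length(i),
               dna_ng = records$dna_ng[i[1L]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id, out$assay_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Signed deltaCq for an aggregated reaction
#'
#' deltaCq is the absolute cycle difference between the replicate-averaged
#' FAM and VIC Cq values; the leading fluorophore is the one detected
#' earlier (smaller Cq). When either fluorophore is not detected, deltaCq
#' is undefined and the reaction carries the `SINGLE_FLUOROPHORE` flag (or
#' `NO_SIGNAL` when neither fired).
#'
#' @param agg One or more rows from [aggregate_replicates()].
#' @return `agg` with added columns `delta_cq` (>= 0 or `NA`),
#'   `leading_fluorophore` ("FAM", "VIC", "tie" or "none") and `flags`.
#' @export
delta_cq <- function(agg) {
  both <- agg$fam_detected & agg$vic_detected
  d <- ifelse(both, abs(agg$fam_cq_mean - agg$vic_cq_mean), NA_real_)
  lead <- rep("none", nrow(agg))
  lead[both & agg$fam_cq_mean < agg$vic_cq_mean] <- "FAM"
  lead[both & agg$vic_cq_mean < agg$fam_cq_mean] <- "VIC"
  lead[both & agg$vic_cq_mean == agg$fam_cq_mean] <- "tie"
  lead[!both & agg$fam_detected] <- "FAM"
  lead[!both & agg$vic_detected] <- "VIC"
  flags <- character(nrow(agg))
  flags[xor(agg$fam_detected, agg$vic_detected)] <- "SINGLE_FLUOROPHORE"
  flags[!agg$fam_detected & !agg$vic_detected] <- "NO_SIGNAL"
  agg$delta_cq <- d
  agg$leading_fluorophore <- lead
  agg$flags <- flags
  agg
}

#' Call the genotype of one aggregated reaction
#'
#' Calling rules for a TaqMan SNP assay, applied to replicate-averaged Cq:
#' FAM-only detected -> `RR`; VIC-only -> `CC`; neither -> `INCONCLUSIVE`
#' (`NO_SIGNAL`); both detected: |deltaCq| <= `het_max_delta` -> `H`,
#' |deltaCq| >= `homo_min_delta` -> homozygote for the leading
#' fluorophore's strain, dead-band values in between -> `INCONCLUSIVE`.
#' A leading Cq above `max_valid_cq` adds a `LOW_TEMPLATE` flag.
#'
#' @param agg A single row from [aggregate_replicates()].
#' @param assay The `faw_assay` definition (must be a taqman_snp marker).
#' @return A one-row data.frame: `sample_id`, `assay_id`, `call`,
#'   `delta_cq`, `leading_fluorophore`, `flags`.
#' @export
call_genotype <- function(agg, assay) {
  if (!inherits(assay, "faw_assay") || assay$marker_class != "taqman_snp") {
    faw_abort("call_genotype requires a taqman_snp assay definition",
              "fawstrain_usage_error")
  }
  if (nrow(agg) != 1L) {
    faw_abort("call_genotype expects a single aggregated reaction",
              "fawstrain_usage_error")
  }
  th <- assay$thresholds
  x <- delta_cq(agg)
  flags <- character(0)
  if (nzchar(x$flags)) flags <- strsplit(x$flags, ";", fixed = TRUE)[[1L]]
  call <- "INCONCLUSIVE"
  if (x$fam_detected && !x$vic_detected) {
    call <- "RR"
  } else if (x$vic_detected && !x$fam_detected) {
    call <- "CC"
  } else if (x$fam_detected && x$vic_detected) {
    if (x$delta_cq <= th$het_max_delta) {
      call <- "H"
    } else if (x$delta_cq >= th$homo_min_delta) {
      call <- if (x$leading_fluorophore == "FAM") "RR" else "CC"
    }
  }
  lead_cq <- suppressWarnings(
    min(c(x$fam_cq_mean[x$fam_detected], x$vic_cq_mean[x$vic_detected])))
  if (is.finite(lead_cq) && lead_cq > th$max_valid_cq) {
    flags <- c(flags, "LOW_TEMPLATE")
  }
  data.frame(sample_id = x$sample_id, assay_id = x$assay_id,
             call = call, delta_cq = x$delta_cq,
             leading_fluorophore = x$leading_fluorophore,
             flags = collapse_flags(flags),
             fam_cq = x$fam_cq_mean, vic_cq = x$vic_cq_mean,
             n_replicates = x$n_replicates,
             stringsAsFactors = FALSE)
}

#' Call a full plate of Cq records
#'
#' Aggregates technical replicates and emits one genotype call per
#' (sample, assay), in deterministic (sample, assay) order.
#'
#' @param records Cq record data.frame (see [read_cq_table()]).
#' @param assays An `faw_assay_set`; records for assay ids not present are
#'   dropped with a warning.
#' @return A data.frame of genotype calls (see [call_genotype()]).
#' @export
call_plate <- function(records, assays = builtin_assays()) {
  known <- names(assays)[vapply(assays, function(a)
    a$marker_class == "taqman_snp", logical(1))]
  unknown <- setdiff(unique(records$assay_id), known)
  if (length(unknown) > 0L) {
    faw_warn("dropping records for non-TaqMan or unknown assay(s): %s",
             paste(unknown, collapse = ", "))
    records <- records[records$assay_id %in% known, , drop = FALSE]
  }
  agg <- aggregate_replicates(records)
  if (nrow(agg) == 0L) {
    return(data.frame(sample_id = character(0), assay_id = character(0),
                      call = character(0), delta_cq = numeric(0),
                      leading_fluorophore = character(0),
                      flags = character(0), fam_cq = numeric(0),
                      vic_cq = numeric(0), n_replicates = integer(0)))
  }
  calls <- do.call(rbind, lapply(seq_len(nrow(agg)), function(i) {
    call_genotype(agg[i, , drop = FALSE], assays[[agg$assay_id[i]]])
  }))
  calls <- calls[order(calls$sample_id, calls$assay_id), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}
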