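#' @title Diagnostic assay registry
#' @name assay_registry
#' @description
#' The package ships the six diagnostic markers used for fall armyworm
#' host-strain determination: four allele-specific TaqMan SNP assays
#' (SNP A-D) and the two classical PCR-RFLP markers (mitochondrial COI and
#' Z-linked Tpi). Each marker is described by an `faw_assay` object holding
#' the primer/probe sequences, the strain-specific alleles, its chromosomal
#' location and linkage, and the Cq calling thresholds. By design the FAM
#' probe always reports the R-strain allele and the VIC probe the C-strain
#' allele.
NULL

#' Calling thresholds for a TaqMan assay
#'
#' Thresholds governing how replicate-averaged Cq values are turned into
#' genotype calls.
#'
#' @param het_max_delta Maximum |deltaCq| (cycles) for a heterozygous call.
#'   Default 2: observed heterozygote deltaCq spans 0-2 cycles.
#' @param homo_min_delta Minimum deltaCq for a homozygous call when both
#'   fluorophores fire. Default 3: below the smallest homozygous deltaCq
#'   seen for any assay (SNP D, R-strain, 3.67 - 2 SD). Values in the dead
#'   band `(het_max_delta, homo_min_delta)` are INCONCLUSIVE.
#' @param max_valid_cq Cq of the leading fluorophore above which the call is
#'   flagged `LOW_TEMPLATE` (not rejected). Default 30.
#' @param max_cycles Total cycles of the qPCR program. Default 40.
#' @return A list of class `faw_thresholds`.
#' @export
calling_thresholds <- function(het_max_delta = 2, homo_min_delta = 3,
                               max_valid_cq = 30, max_cycles = 40) {
  for (v in list(het_max_delta, homo_min_delta, max_valid_cq, max_cycles)) {
    if (!is_scalar_number(v)) {
      faw_abort("thresholds must be finite scalar numbers",
                "fawstrain_value_error")
    }
  }
  if (!(0 <= het_max_delta && het_max_delta < homo_min_delta &&
        homo_min_delta <= max_cycles)) {
    faw_abort(
      "need 0 <= het_max_delta < homo_min_delta <= max_cycles (got %s, %s, %s)",
      "fawstrain_value_error", het_max_delta, homo_min_delta, max_cycles)
  }
  if (max_valid_cq > max_cycles) {
    faw_abort("max_valid_cq (%s) exceeds max_cycles (%s)",
              "fawstrain_value_error", max_valid_cq, max_cycles)
  }
  structure(list(het_max_delta = het_max_delta,
                 homo_min_delta = homo_min_delta,
                 max_valid_cq = max_valid_cq,
                 max_cycles = max_cycles),
            class = "faw_thresholds")
}

#' Construct a diagnostic assay definition
#'
#' @param assay_id Short marker name, e.g. "SNP A".
#' @param marker_class One of "taqman_snp", "rflp_coi", "rflp_tpi".
#' @param chromosome Chromosome label (e.g. "1/Z", "16", "mtDNA").
#' @param position 1-based coordinate of the SNP on the reference chromosome
#'   map; `NA` for the RFLP markers.
#' @param c_allele,r_allele Single nucleotides associated with the C- and
#'   R-strain (taqman_snp only).
#' @param product_length Expected amplicon length (bp).
#' @param primers Named list with `forward` and `reverse` sequences (IUPAC
#'   codes permitted).
#' @param probes Named list with `fam` and `vic` probe sequences
#'   (taqman_snp only).
#' @param linkage One of "Z", "autosomal", "mitochondrial".
#' @param thresholds A [calling_thresholds()] object.
#' @return An object of class `faw_assay`.
#' @export
new_assay <- function(assay_id, marker_class, chromosome, position = NA,
                      c_allele = NA_character_, r_allele = NA_character_,
                      product_length, primers, probes = NULL,
                      linkage, thresholds = calling_thresholds()) {
  marker_class <- match.arg(marker_class,
                            c("taqman_snp", "rflp_coi", "rflp_tpi"))
  linkage <- match.arg(linkage, c("Z", "autosomal", "mitochondrial"))
  if (!is_scalar_number(product_length) || product_length <= 0) {
    faw_abort("product_length must be a positive number",
              "fawstrain_value_error")
  }
  if (!all(c("forward", "reverse") %in% names(primers))) {
    faw_abort("primers must be a named list with 'forward' and 'reverse'",
              "fawstrain_value_error")
  }
  if (marker_class == "taqman_snp") {
    if (is.na(c_allele) || is.na(r_allele) ||
        !nzchar(c_allele) || !nzchar(r_allele)) {
      faw_abort("taqman_snp assays need c_allele and r_allele",
                "fawstrain_value_error")
    }
    if (identical(c_allele, r_allele)) {
      faw_abort("c_allele and r_allele must differ (%s)",
                "fawstrain_value_error", assay_id)
    }
    if (is.null(probes) || !all(c("fam", "vic") %in% names(probes))) {
      faw_abort("taqman_snp assays need 'fam' and 'vic' probes",
                "fawstrain_value_error")
    }
    if (identical(probes$fam, probes$vic)) {
      faw_abort("FAM and VIC probes must differ (%s)",
                "fawstrain_value_error", assay_id)
    }
  }
  # COI is the only maternally inherited marker in the panel
  if ((linkage == "mitochondrial") != (marker_class == "rflp_coi")) {
    faw_abort("linkage 'mitochondrial' is valid only for rflp_coi markers",
              "fawstrain_value_error")
  }
  if (!inherits(thresholds, "faw_thresholds")) {
    thresholds <- do.call(calling_thresholds, thresholds)
  }
  structure(list(
    assay_id = assay_id,
    marker_class = marker_class,
    chromosome = as.character(chromosome),
    position = if (is.na(position)) NA_integer_ else as.integer(position),
    c_allele = as.character(c_allele),
    r_allele = as.character(r_allele),
    fam_strain = "R",
    vic_strain = "C",
    product_length = as.integer(product_length),
    primers = list(forward = toupper(primers$forward),
                   reverse = toupper(primers$reverse)),
    probes = if (is.null(probes)) NULL else
      list(fam = toupper(probes$fam), vic = toupper(probes$vic)),
    linkage = linkage,
    thresholds = thresholds
  ), class = "faw_assay")
}

#' Built-in diagnostic assay panel
#'
#' Returns the six shipped marker definitions: TaqMan assays SNP A-D plus
#' the COI and Tpi PCR-RFLP markers, with primer/probe sequences, alleles,
#' chromosomal positions and expected product lengths. SNP A-C and Tpi are
#' Z-linked, SNP D is autosomal (chromosome 16) and COI is mitochondrial.
#'
#' @return A named list of `faw_assay` objects (class `faw_assay_set`).
#' @examples
#' panel <- builtin_assays()
#' panel[["SNP A"]]$position
#' @export
builtin_assays <- function() {
  a <- list(
    new_assay("SNP A", "taqman_snp", "1/Z", 14104488,
              c_allele = "A", r_allele = "G", product_length = 62,
              primers = list(forward = "GCAAGTGCAATTTTCCCATCTGATG",
                             reverse = "CAAGCCGTTCGCGGTTAG"),
              probes = list(fam = "AGACCAAAAGGACTCAT",
                            vic = "CTAGACCAAAAAGACTCAT"),
              linkage = "Z"),
    new_assay("SNP B", "taqman_snp", "1/Z", 4933322,
              c_allele = "G", r_allele = "C", product_length = 113,
              primers = list(forward = "GGGAACTCATATACTAAAATCGGAAAAACCT",
                             reverse = "ACACTCGCATTATTTGTGTGCAATT"),
              probes = list(fam = "CCGCAGTAGCGTATGT",
                            vic = "TCCGCAGTACCGTATGT"),
              linkage = "Z"),
    new_assay("SNP C", "taqman_snp", "1/Z", 4683787,
              c_allele = "C", r_allele = "T", product_length = 57,
              primers = list(forward = "TGACAGCATTGATGTGCTGGAT",
                             reverse = "CGCCGGAGCGTTACAGA"),
              probes = list(fam = "CGCTACCAAAGCCAG",
                            vic = "CGCTACCAGAGCCAG"),
              linkage = "Z"),
    new_assay("SNP D", "taqman_snp", "16", 14134047,
              c_allele = "C", r_allele = "G", product_length = 70,
              primers = list(forward = "TGAGTGCCAACAGCTATCTTCTG",
                             reverse = "GCAGTCCATTACAGCTGGTGAA"),
              probes = list(fam = "AGCTCATGTCCTACTCC",
                            vic = "AGCTCATGTCGTACTCC"),
              linkage = "autosomal"),
    new_assay("COI", "rflp_coi", "mtDNA", NA, product_length = 568,
              primers = list(
                forward = parse_degenerate_primer("GAGCTGAATTAGG (G/A)ACTCCAGG"),
                reverse = parse_degenerate_primer("ATCACCTCC(A/T)CCTGCAGGATC")),
              linkage = "mitochondrial"),
    new_assay("Tpi", "rflp_tpi", "1/Z", NA, product_length = 600,
              primers = list(
                forward = "GGTTGCCCATGCTCTTGAGTCCGGACTGAAGG",
                reverse = "AGTCACTGACCCACCATACTG"),
              linkage = "Z")
  )
  names(a) <- vapply(a, `[[`, character(1), "assay_id")
  structure(a, class = "faw_assay_set")
}

#' Collapse a degenerate primer written with (X/Y) groups to IUPAC codes
#'
#' Legacy primer notation spells a two-fold degenerate position as a
#' parenthesised pair, e.g. `"GAGCTGAATTAGG (G/A)ACTCCAGG"`. This collapses
#' each `(X/Y)` group to the single IUPAC nucleotide code covering both
#' bases (here `R`) and strips whitespace.
#'
#' @param text Primer string containing only A/C/G/T/U, whitespace and
#'   well-formed `(X/Y)` groups.
#' @return The primer as a plain IUPAC string.
#' @examples
#' parse_degenerate_primer("ATCACCTCC(A/T)CCTGCAGGATC")
#' @export
parse_degenerate_primer <- function(text) {
  if (!is.character(text) || length(text) != 1L) {
    faw_abort("primer text must be a single string", "fawstrain_value_error")
  }
  s <- gsub("[[:space:]]+", "", toupper(text))
  s <- gsub("U", "T", s, fixed = TRUE)
  # reverse IUPAC lookup: sorted base set -> code
  code_of <- c(A = "A", C = "C", G = "G", T = "T",
               "AC" = "M", "AG" = "R", "AT" = "W",
               "CG" = "S", "CT" = "Y", "GT" = "K")
  out <- character(0)
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "(") {
      grp <- regmatches(substring(s, i),
                        regexpr("^\\([ACGT]/[ACGT]\\)", substring(s, i)))
      if (length(grp) == 0L) {
        faw_abort("malformed degenerate group at '%s'",
                  "fawstrain_parse_error", substring(s, i, min(i + 5L, n)))
      }
      bases <- sort(unique(c(substr(grp, 2, 2), substr(grp, 4, 4))))
      key <- paste(bases, collapse = "")
      out <- c(out, code_of[[key]])
      i <- i + 5L
    } else if (ch %in% c("A", "C", "G", "T")) {
      out <- c(out, ch)
      i <- i + 1L
    } else {
      faw_abort("invalid character '%s' in primer", "fawstrain_parse_error", ch)
    }
  }
  paste(out, collapse = "")
}

#' Write assay definitions to a YAML configuration file
#'
#' The configuration mirrors the fields of [new_assay()], one document entry
#' per assay; [read_assay_config()] restores identical definitions.
#'
#' @param assays An `faw_assay_set` or list of `faw_assay` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_assay_config <- function(assays, path) {
  entries <- lapply(unclass(assays), function(a) {
    list(assay_id = a$assay_id,
         marker_class = a$marker_class,
         chromosome = a$chromosome,
         position = if (is.na(a$position)) NULL else a$position,
         c_allele = if (is.na(a$c_allele)) NULL else a$c_allele,
         r_allele = if (is.na(a$r_allele)) NULL else a$r_allele,
         product_length = a$product_length,
         primers = a$primers,
         probes = a$probes,
         linkage = a$linkage,
         thresholds = unclass(a$thresholds))
  })
  yaml::write_yaml(list(assays = unname(entries)), path)
  invisible(path)
}

#' Read assay definitions from a YAML configuration file
#'
#' @param path Path to a file written by [write_assay_config()] (or edited
#'   by hand, e.g. to override per-assay thresholds).
#' @return An `faw_assay_set`.
#' @export
read_assay_config <- function(path) {
  if (!file.exists(path)) {
    faw_abort("assay config not found: %s", "fawstrain_io_error", path)
  }
  doc <- yaml::read_yaml(path)
  if (is.null(doc$assays)) {
    faw_abort("config has no 'assays' section", "fawstrain_format_error")
  }
  a <- lapply(doc$assays, function(e) {
    new_assay(e$assay_id, e$marker_class, e$chromosome,
              position = e$position %||% NA,
              c_allele = e$c_allele %||% NA_character_,
              r_allele = e$r_allele %||% NA_character_,
              product_length = e$product_length,
              primers = e$primers, probes = e$probes,
              linkage = e$linkage,
              thresholds = do.call(calling_thresholds, e$thresholds))
  })
  names(a) <- vapply(a, `[[`, character(1), "assay_id")
  structure(a, class = "faw_assay_set")
}

#' @export
print.faw_assay <- function(x, ...) {
  cat(sprintf("<faw_assay> %s (%s, %s)\n", x$assay_id, x$marker_class,
              x$linkage))
  if (x$marker_class == "taqman_snp") {
    cat(sprintf("  chrom %s pos %s  C/R alleles %s/%s  product %d bp\n",
                x$chromosome, format(x$position, big.mark = ","),
                x$c_allele, x$r_allele, x$product_length))
  } else {
    cat(sprintf("  chrom %s  product %d bp\n", x$chromosome,
                x$product_length))
  }
  invisible(x)
}

#' @export
print.faw_assay_set <- function(x, ...) {
  cat(sprintf("<faw_assay_set> %d markers: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}
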