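#' @title In-silico PCR and restriction digestion (COI / Tpi RFLP)
#' @name insilico_rflp
#' @description
#' The two classical fall armyworm strain markers are PCR-RFLP assays: a
#' 568 bp COI amplicon (degenerate primer pair JM-76/JM-77) digested with
#' MspI and SacI, and a ~600 bp Tpi amplicon digested with MspI. The
#' C-strain COI amplicon is cut by MspI and not by SacI; the R-strain shows
#' the reciprocal pattern. This module predicts amplicons from template
#' sequences (IUPAC-aware primer matching), digests them and applies the
#' strain classification rules. Both built-in recognition sites (MspI CCGG,
#' SacI GAGCTC) are palindromic, so plus-strand scanning finds every
#' double-stranded site.
NULL

#' Built-in restriction enzymes
#'
#' @return A named list of enzymes, each a list with `name`,
#'   `recognition_site` and `cut_offset` (1-based position within the site
#'   after which the top strand is cleaved; MspI C^CGG -> 1, SacI
#'   GAGCT^C -> 5).
#' @export
restriction_enzymes <- function() {
  list(
    MspI = list(name = "MspI", recognition_site = "CCGG", cut_offset = 1L),
    SacI = list(name = "SacI", recognition_site = "GAGCTC", cut_offset = 5L)
  )
}

as_enzyme <- function(enzyme) {
  if (is.character(enzyme) && length(enzyme) == 1L) {
    e <- restriction_enzymes()[[enzyme]]
    if (is.null(e)) {
      faw_abort("unknown enzyme '%s'", "fawstrain_value_error", enzyme)
    }
    return(e)
  }
  need <- c("name", "recognition_site", "cut_offset")
  if (!is.list(enzyme) || !all(need %in% names(enzyme))) {
    faw_abort("enzyme must be a name or a list with %s",
              "fawstrain_value_error", paste(need, collapse = ", "))
  }
  site_len <- nchar(enzyme$recognition_site)
  if (enzyme$cut_offset < 0 || enzyme$cut_offset > site_len) {
    faw_abort("cut_offset must lie within the recognition site",
              "fawstrain_value_error")
  }
  enzyme
}

#' Digest a linear sequence with a restriction enzyme
#'
#' Every plus-strand occurrence of the recognition site produces one cut
#' (overlapping sites each cut; duplicate cut positions are collapsed).
#' With no site the whole molecule is returned as a single fragment.
#'
#' @param seq A single DNA sequence (character or `Biostrings::DNAString`),
#'   A/C/G/T only.
#' @param enzyme Enzyme name ("MspI", "SacI") or an enzyme list (see
#'   [restriction_enzymes()]); IUPAC codes are allowed in the site.
#' @return A list of class `faw_digest`: `enzyme`, `cut_positions`
#'   (1-based, cleavage occurs after these positions) and
#'   `fragment_lengths` (left to right; sums to the input length).
#' @examples
#' digest("AACCGGTT", "MspI")$fragment_lengths  # 3, 5
#' @export
digest <- function(seq, enzyme) {
  enzyme <- as_enzyme(enzyme)
  s <- toupper(as.character(seq))
  if (length(s) != 1L || !nzchar(s)) {
    faw_abort("digest expects a single non-empty sequence",
              "fawstrain_value_error")
  }
  if (grepl("[^ACGT]", s)) {
    faw_abort("digest input must contain only A/C/G/T",
              "fawstrain_value_error")
  }
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(enzyme$recognition_site),
    Biostrings::DNAString(s), fixed = FALSE)
  cuts <- sort(unique(Biostrings::start(hits) + enzyme$cut_offset - 1L))
  # cuts at the very ends produce empty fragments; drop them
  cuts <- cuts[cuts >= 1L & cuts < nchar(s)]
  frags <- diff(c(0L, cuts, nchar(s)))
  structure(list(enzyme = enzyme$name, cut_positions = cuts,
                 fragment_lengths = frags),
            class = "faw_digest")
}

#' @export
print.faw_digest <- function(x, ...) {
  cat(sprintf("<faw_digest> %s: %d cut(s); fragments %s bp\n", x$enzyme,
              length(x$cut_positions),
              paste(x$fragment_lengths, collapse = ", ")))
  invisible(x)
}

# Count IUPAC-aware mismatches of a primer against an equally long
# template region; returns Inf on length mismatch.
iupac_mismatches <- function(primer, region) {
  if (nchar(primer) != nchar(region)) return(Inf)
  map <- Biostrings::IUPAC_CODE_MAP
  p <- strsplit(toupper(primer), "")[[1L]]
  r <- strsplit(toupper(region), "")[[1L]]
  sum(vapply(seq_along(p), function(i) {
    ps <- strsplit(map[[p[i]]] %||% "", "")[[1L]]
    rs <- strsplit(map[[r[i]]] %||% "", "")[[1L]]
    length(intersect(ps, rs)) == 0L
  }, logical(1)))
}

#' Predict a PCR product from a template and a primer pair
#'
#' Finds the forward primer on the plus strand and the reverse primer as a
#' reverse complement downstream, allowing IUPAC degeneracy in the primers
#' and up to `max_mismatch` mismatches per primer. When `max_mismatch > 0`
#' a mismatch at a primer's 3'-terminal base still disqualifies the match
#' (extension from a mismatched 3' end is inefficient). The shortest valid
#' product is returned; several non-nested products raise an ambiguity
#' error listing all of them.
#'
#' @param template A single DNA sequence (character or `DNAString`).
#' @param fwd,rev Primer sequences (>= 15 nt, IUPAC allowed).
#' @param max_mismatch Maximum mismatches tolerated per primer (default 0).
#' @param template_id Identifier copied into the result.
#' @return A list of class `faw_amplicon`: `template_id`, `start`, `end`
#'   (1-based inclusive), `sequence`, `fwd_mismatches`, `rev_mismatches`,
#'   `length`.
#' @export
find_amplicon <- function(template, fwd, rev, max_mismatch = 0,
                          template_id = "template") {
  s <- toupper(as.character(template))
  fwd <- toupper(as.character(fwd))
  rev <- toupper(as.character(rev))
  if (nchar(fwd) < 15L || nchar(rev) < 15L) {
    faw_abort("primers must be at least 15 nt", "fawstrain_value_error")
  }
  if (nchar(s) < nchar(fwd) + nchar(rev)) {
    faw_abort("template shorter than the combined primer length",
              "fawstrain_value_error")
  }
  subj <- Biostrings::DNAString(s)
  f_hits <- Biostrings::matchPattern(Biostrings::DNAString(fwd), subj,
                                     max.mismatch = max_mismatch,
                                     fixed = FALSE)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(rev)))
  r_hits <- Biostrings::matchPattern(Biostrings::DNAString(rc), subj,
                                     max.mismatch = max_mismatch,
                                     fixed = FALSE)
  ok3 <- function(primer, region, terminal_idx) {
    # 3'-terminal base of the primer must pair even when mismatches are
    # allowed elsewhere
    p <- substr(primer, terminal_idx, terminal_idx)
    r <- substr(region, terminal_idx, terminal_idx)
    iupac_mismatches(p, r) == 0L
  }
  f_starts <- Biostrings::start(f_hits)
  r_starts <- Biostrings::start(r_hits)
  keep_f <- vapply(seq_along(f_starts), function(i) {
    region <- substr(s, f_starts[i], f_starts[i] + nchar(fwd) - 1L)
    max_mismatch == 0 || ok3(fwd, region, nchar(fwd))
  }, logical(1))
  keep_r <- vapply(seq_along(r_starts), function(i) {
    region <- substr(s, r_starts[i], r_starts[i] + nchar(rc) - 1L)
    # the reverse primer's 3' end maps to the FIRST base of the rev-comp
    # site on the plus strand
    max_mismatch == 0 || ok3(rc, region, 1L)
  }, logical(1))
  f_starts <- f_starts[keep_f]
  r_starts <- r_starts[keep_r]
  products <- list()
  for (fs in f_starts) {
    fe <- fs + nchar(fwd) - 1L
    for (rs in r_starts) {
      re <- rs + nchar(rc) - 1L
      if (rs > fe) {
        products[[length(products) + 1L]] <- c(start = fs, end = re)
      }
    }
  }
  if (length(products) == 0L) {
    faw_abort("no amplicon: primer pair does not define a product on this template",
              "fawstrain_notfound_error")
  }
  iv <- do.call(rbind, products)
  # drop products that strictly contain another product (nested: keep inner)
  contains <- function(i, j) {
    iv[i, "start"] <= iv[j, "start"] && iv[i, "end"] >= iv[j, "end"] &&
      (iv[i, "start"] < iv[j, "start"] || iv[i, "end"] > iv[j, "end"])
  }
  n <- nrow(iv)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && contains(i, j)) keep[i] <- FALSE
    }
  }
  iv <- iv[keep, , drop = FALSE]
  iv <- unique(iv)
  if (nrow(iv) > 1L) {
    faw_abort("ambiguous amplification: %d non-nested products (%s)",
              "fawstrain_ambiguity_error", nrow(iv),
              paste(sprintf("%d-%d", iv[, "start"], iv[, "end"]),
                    collapse = ", "))
  }
  fs <- iv[1L, "start"]; re <- iv[1L, "end"]
  amp_seq <- substr(s, fs, re)
  structure(list(
    template_id = template_id, start = unname(fs), end = unname(re),
    sequence = amp_seq,
    fwd_mismatches = iupac_mismatches(fwd, substr(s, fs, fs + nchar(fwd) - 1L)),
    rev_mismatches = iupac_mismatches(rc, substr(s, re - nchar(rc) + 1L, re)),
    length = nchar(amp_seq)
  ), class = "faw_amplicon")
}

#' @export
print.faw_amplicon <- function(x, ...) {
  cat(sprintf("<faw_amplicon> %s:%d-%d (%d bp)\n", x$template_id, x$start,
              x$end, x$length))
  invisible(x)
}

#' Classify a COI amplicon as C- or R-strain
#'
#' The C-strain mitochondrial amplicon is cut by MspI and not by SacI; the
#' R-strain shows the reciprocal pattern. Any other cut combination (both
#' or neither enzyme cutting) is UNRESOLVED. Being maternally inherited,
#' COI can never identify a hybrid.
#'
#' @param amplicon Amplicon sequence (character, `DNAString` or
#'   `faw_amplicon`).
#' @return A list: `call` ("C", "R" or "UNRESOLVED") plus both
#'   `faw_digest` results (`mspi`, `saci`).
#' @export
classify_coi <- function(amplicon) {
  s <- if (inherits(amplicon, "faw_amplicon")) amplicon$sequence
       else as.character(amplicon)
  mspi <- digest(s, "MspI")
  saci <- digest(s, "SacI")
  m <- length(mspi$cut_positions)
  k <- length(saci$cut_positions)
  call <- if (m >= 1L && k == 0L) "C"
          else if (k >= 1L && m == 0L) "R"
          else "UNRESOLVED"
  list(call = call, mspi = mspi, saci = saci)
}

#' Classify a Tpi amplicon (or diploid haplotype pair) by MspI digestion
#'
#' The Tpi RFLP scores whether MspI cuts the amplicon. Which strain carries
#' the cut site is configurable through `pattern_map` (fragment sizes and
#' polarity vary with the reference used; the shipped default maps
#' cut -> C). A diploid individual supplied as two haplotype sequences with
#' discordant cut states is a hybrid.
#'
#' @param haplotypes Character vector of 1 (haploid/hemizygous) or 2
#'   (diploid) amplicon sequences.
#' @param pattern_map Named character vector mapping the digest states
#'   `cut`, `uncut` and `mixed` to strain labels.
#' @return A list: `call` ("C", "R", "H" or "UNRESOLVED"), `states` (per
#'   haplotype) and the per-haplotype `faw_digest` results.
#' @export
classify_tpi <- function(haplotypes,
                         pattern_map = c(cut = "C", uncut = "R",
                                         mixed = "H")) {
  if (!all(c("cut", "uncut", "mixed") %in% names(pattern_map))) {
    faw_abort("pattern_map must define 'cut', 'uncut' and 'mixed'",
              "fawstrain_config_error")
  }
  haplotypes <- vapply(haplotypes, function(h) {
    if (inherits(h, "faw_amplicon")) h$sequence else as.character(h)
  }, character(1))
  if (!length(haplotypes) %in% c(1L, 2L)) {
    faw_abort("classify_tpi expects 1 or 2 haplotype sequences",
              "fawstrain_usage_error")
  }
  digests <- lapply(haplotypes, digest, enzyme = "MspI")
  states <- vapply(digests, function(d)
    if (length(d$cut_positions) >= 1L) "cut" else "uncut", character(1))
  key <- if (length(unique(states)) > 1L) "mixed" else states[[1L]]
  list(call = unname(pattern_map[[key]]), states = unname(states),
       digests = digests)
}
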