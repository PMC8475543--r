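#' @title Assay sensitivity: standard curves and limit of detection
#' @name standard_curve
#' @description
#' Sensitivity of a TaqMan assay is characterised with a ten-fold serial
#' dilution series: replicate-averaged Cq is regressed on log10 template
#' mass (ng), giving the slope (cycles per decade; -3.32 at 100%
#' amplification efficiency), intercept (Cq at 1 ng), R-squared, the
#' derived efficiency `10^(-1/slope) - 1`, and the limit of detection --
#' the smallest amount at which every replicate still produced signal.
#' Undetected (NF) points are excluded from the fit.
NULL

#' Fit a standard curve to dilution-series Cq data
#'
#' Ordinary least squares of Cq on log10(DNA ng). Rows with `NA` Cq (no
#' fluorescence) are excluded; at least three detected points at distinct
#' concentrations are required.
#'
#' @param points Data.frame with columns `dna_ng` (> 0) and `cq`
#'   (replicate-averaged Cq; `NA` = not detected). Extra columns (e.g.
#'   `sample`) are ignored by the fit but used by [lod()].
#' @return A list of class `faw_curve`: `slope`, `intercept`, `r_squared`,
#'   `efficiency`, `n_points`, `lod_ng`.
#' @examples
#' pts <- data.frame(dna_ng = c(100, 10, 1, 0.1),
#'                   cq = 23 - 3.3219 * log10(c(100, 10, 1, 0.1)))
#' fit_curve(pts)$slope
#' @export
fit_curve <- function(points) {
  if (!all(c("dna_ng", "cq") %in% names(points))) {
    faw_abort("points must have columns dna_ng and cq",
              "fawstrain_format_error")
  }
  if (any(points$dna_ng <= 0, na.rm = TRUE)) {
    faw_abort("dna_ng must be positive", "fawstrain_value_error")
  }
  det <- points[!is.na(points$cq), , drop = FALSE]
  if (nrow(det) < 3L || length(unique(det$dna_ng)) < 3L) {
    faw_abort("need >= 3 detected points at distinct concentrations (have %d)",
              "fawstrain_insufficient_data_error",
              length(unique(det$dna_ng)))
  }
  x <- log10(det$dna_ng)
  if (stats::var(x) == 0) {
    faw_abort("all concentrations equal: singular fit",
              "fawstrain_value_error")
  }
  fit <- stats::lm(cq ~ x, data = data.frame(cq = det$cq, x = x))
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  # noiseless series trip lm's "essentially perfect fit" warning; a perfect
  # fit is a legitimate input here (R^2 = 1)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  eff <- if (slope < 0) 10^(-1 / slope) - 1 else NA_real_
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 efficiency = eff, n_points = nrow(det),
                 lod_ng = tryCatch(lod(points), error = function(e) NA_real_,
                                   warning = function(w) suppressWarnings(lod(points)))),
            class = "faw_curve")
}

#' @export
print.faw_curve <- function(x, ...) {
  cat(sprintf(
    "<faw_curve> slope %.4f  intercept %.2f  R^2 %.4f  eff %.1f%%  LOD %g ng\n",
    x$slope, x$intercept, x$r_squared, 100 * x$efficiency, x$lod_ng))
  invisible(x)
}

#' Limit of detection of a dilution series
#'
#' The LOD is the smallest tested concentration whose replicates were all
#' detected, subject to every larger tested concentration also being fully
#' detected. A non-monotone detection pattern (an NF level above a
#' detected one) raises a warning, and the LOD becomes the smallest fully
#' detected level above the highest undetected one.
#'
#' @param points Data.frame with `dna_ng` and `cq` (`NA` = NF); rows at
#'   the same `dna_ng` are treated as replicates.
#' @return Concentration in ng.
#' @export
lod <- function(points) {
  conc <- sort(unique(points$dna_ng), decreasing = TRUE)
  full <- vapply(conc, function(cg)
    !anyNA(points$cq[points$dna_ng == cg]), logical(1))
  if (!any(full)) {
    faw_abort("no concentration was detected in all replicates",
              "fawstrain_value_error")
  }
  if (all(full)) return(min(conc))
  highest_nf <- max(conc[!full])
  detected_above <- conc[full & conc > highest_nf]
  # non-monotone: some NF level sits above a detected level
  if (any(full & conc < highest_nf)) {
    faw_warn("non-monotone detection: NF at %g ng above detected levels",
             highest_nf)
  }
  if (length(detected_above) == 0L) {
    faw_abort("no fully detected concentration above the highest NF level",
              "fawstrain_value_error")
  }
  min(detected_above)
}

#' Fit standard curves per assay and fluorophore
#'
#' @param points Data.frame with columns `assay_id`, `fluorophore`,
#'   `dna_ng`, `cq`.
#' @return Data.frame with one row per assay x fluorophore: slope,
#'   intercept, r_squared, efficiency, n_points, lod_ng.
#' @export
fit_curves <- function(points) {
  need <- c("assay_id", "fluorophore", "dna_ng", "cq")
  if (!all(need %in% names(points))) {
    faw_abort("points must have columns %s", "fawstrain_format_error",
              paste(need, collapse = ", "))
  }
  key <- paste(points$assay_id, points$fluorophore, sep = "\r")
  rows <- lapply(split(points, key), function(sub) {
    fit <- fit_curve(sub)
    data.frame(assay_id = sub$assay_id[1L],
               fluorophore = sub$fluorophore[1L],
               slope = fit$slope, intercept = fit$intercept,
               r_squared = fit$r_squared, efficiency = fit$efficiency,
               n_points = fit$n_points, lod_ng = fit$lod_ng,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$assay_id, out$fluorophore), , drop = FALSE]
  rownames(out) <- NULL
  out
}
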