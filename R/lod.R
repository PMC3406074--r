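#' Estimate the limit of detection from a spike-in dilution series
#'
#' The limit of detection is the smallest spike amount at which the
#' detection criterion (at least `min_peptides` distinct tryptic peptides)
#' is met and stays met at every larger amount -- the first sustained
#' crossing, which guards against non-monotone noise in the series.
#'
#' @param amounts_fmol spike amounts, strictly ascending.
#' @param peptides_detected distinct-peptide counts, same length.
#' @param min_peptides detection criterion (default 2).
#' @return list with `lod_fmol` (NA when never reached) and `reached`.
#' @export
estimate_lod <- function(amounts_fmol, peptides_detected,
                         min_peptides = 2L) {
  stopifnot(length(amounts_fmol) == length(peptides_detected),
            length(amounts_fmol) >= 1L)
  if (is.unsorted(amounts_fmol, strictly = TRUE))
    stop("spike amounts must be strictly ascending")
  ok <- peptides_detected >= min_peptides
  sustained <- rev(cumprod(rev(ok))) > 0
  if (!any(sustained)) return(list(lod_fmol = NA_real_, reached = FALSE))
  list(lod_fmol = amounts_fmol[which(sustained)[1]], reached = TRUE)
}

#' Convert an absolute limit of detection to a concentration bound
#'
#' @param lod_fmol limit of detection in fmol.
#' @param analyzed_mg protein mass analysed, in mg.
#' @return concentration in pmol per mg protein.
#' @export
lod_to_concentration <- function(lod_fmol, analyzed_mg) {
  if (!is.numeric(lod_fmol) || !is.numeric(analyzed_mg) ||
      any(lod_fmol <= 0) || any(analyzed_mg <= 0))
    stop("input error: lod and analysed mass must be positive")
  lod_fmol * 1e-3 / analyzed_mg
}

#' Round to significant figures, halves away from zero
#'
#' Plain `signif()` rounds halves to even; published bounded ratios here
#' follow the round-half-away-from-zero convention (0.0025 -> 0.003).
#'
#' @param x numeric.
#' @param digits significant figures.
#' @return rounded numeric.
#' @export
signif_away <- function(x, digits = 1L) {
  out <- x
  nz <- is.finite(x) & x != 0
  s <- sign(x[nz]); a <- abs(x[nz])
  e <- floor(log10(a)) - digits + 1L
  m <- a / 10^e
  # nudge for binary representation error before taking the half-step
  out[nz] <- s * floor(m + 0.5 + sqrt(.Machine$double.eps)) * 10^e
  out
}

#' Render the bounded skin/liver ratio from LOD-based levels
#'
#' The skin level is itself an upper bound (the protein was not detected,
#' so its level is below the concentration equivalent of the LOD); the
#' ratio to the measured liver level is therefore also an upper bound,
#' rendered `"<x"` at one significant figure. With no defined comparator
#' (analyte undetected in liver too) the comparison is not applicable.
#'
#' @param skin_bound upper bound on the skin level, pmol/mg.
#' @param liver_level measured liver level, pmol/mg (NA when undetected).
#' @return text such as `"<0.003"`, or `"n/a"`.
#' @export
relative_bound <- function(skin_bound, liver_level) {
  if (!is.numeric(skin_bound) || skin_bound <= 0)
    stop("input error: skin bound must be positive")
  if (is.na(liver_level)) return("n/a")
  if (liver_level <= 0) stop("input error: liver level must be positive")
  r <- signif_away(skin_bound / liver_level, 1L)
  paste0("<", format(r, scientific = FALSE, trim = TRUE))
}

#' Parse a rendered bound back to its numeric value
#'
#' @param text rendered bound, e.g. `"<0.003"` or `">6.7"`.
#' @return numeric value (NA for `"n/a"`).
#' @export
parse_bound <- function(text) {
  if (text == "n/a") return(NA_real_)
  as.numeric(sub("^[<>]", "", text))
}

#' Minimum fold separation between comparator and bounded levels
#'
#' Given upper bounds on the level in one tissue and measured comparator
#' levels in the other, the smallest comparator/bound ratio is a
#' guaranteed ("at least") fold separation across the panel.
#'
#' @param skin_bounds upper bounds, pmol/mg.
#' @param liver_levels comparator levels, pmol/mg (NA rows are skipped).
#' @return list with `min_fold` (the raw minimum ratio) and `rendered`
#'   (two significant figures with `>=` semantics).
#' @export
min_fold_separation <- function(skin_bounds, liver_levels) {
  stopifnot(length(skin_bounds) == length(liver_levels))
  ok <- !is.na(liver_levels)
  if (!any(ok)) stop("no report with a defined comparator")
  if (any(skin_bounds[ok] <= 0) || any(liver_levels[ok] <= 0))
    stop("input error: levels must be positive")
  folds <- liver_levels[ok] / skin_bounds[ok]
  mf <- min(folds)
  list(min_fold = mf,
       rendered = paste0(">=", format(signif_away(mf, 2L),
                                      scientific = FALSE, trim = TRUE)))
}

#' Activity equivalent of a proteomic detection limit
#'
#' Converts a concentration detection limit into the enzyme activity it
#' corresponds to, given the specific activity of the pure protein; used
#' to compare proteomic and activity-assay sensitivity.
#'
#' @param lod_pmol_per_mg detection limit, pmol enzyme per mg protein.
#' @param specific_activity nmol/min per pmol enzyme.
#' @return activity in nmol/min per mg protein.
#' @export
activity_equivalent <- function(lod_pmol_per_mg, specific_activity) {
  if (!is.numeric(lod_pmol_per_mg) || !is.numeric(specific_activity) ||
      any(lod_pmol_per_mg <= 0) || any(specific_activity <= 0))
    stop("input error: inputs must be positive")
  lod_pmol_per_mg * specific_activity
}

#' Sensitivity ratio of two detection methods
#'
#' @param immunoblot_lod detection limit of the reference method, pmol/mg.
#' @param ms_lod detection limit of the MS method, pmol/mg.
#' @return fold sensitivity advantage of the MS method.
#' @export
sensitivity_ratio <- function(immunoblot_lod, ms_lod) {
  if (!is.numeric(immunoblot_lod) || !is.numeric(ms_lod) ||
      any(immunoblot_lod <= 0) || any(ms_lod <= 0))
    stop("input error: detection limits must be positive")
  immunoblot_lod / ms_lod
}

#' Build a limit-of-detection report row for one analyte
#'
#' Chains [estimate_lod()], [lod_to_concentration()] and
#' [relative_bound()] for a spike series, mirroring the shape of a
#' published LOD panel: absolute LOD, concentration bound in the analysed
#' sample, and the bounded ratio to a comparator tissue level.
#'
#' @param series data.frame from [generate_spike_series()] (or with the
#'   same columns).
#' @param analyzed_mg protein mass analysed, mg. The panel arithmetic is
#'   sensitive to this choice, so it is always explicit.
#' @param comparator_pmol_per_mg measured comparator level (NA if
#'   undetected).
#' @param min_peptides detection criterion (default 2).
#' @return one-row data.frame: `analyte`, `lod_fmol`, `skin_bound`
#'   (pmol/mg, NA when the LOD was not reached), `comparator`,
#'   `relative_bound`.
#' @export
lod_report <- function(series, analyzed_mg, comparator_pmol_per_mg = NA,
                       min_peptides = 2L) {
  est <- estimate_lod(series$amount_fmol, series$peptides_detected,
                      min_peptides)
  if (!est$reached)
    return(data.frame(analyte = series$analyte[1], lod_fmol = NA_real_,
                      skin_bound = NA_real_,
                      comparator = comparator_pmol_per_mg,
                      relative_bound = "not-reached",
                      stringsAsFactors = FALSE))
  conc <- lod_to_concentration(est$lod_fmol, analyzed_mg)
  data.frame(analyte = series$analyte[1], lod_fmol = est$lod_fmol,
             skin_bound = conc, comparator = comparator_pmol_per_mg,
             relative_bound = relative_bound(conc, comparator_pmol_per_mg),
             stringsAsFactors = FALSE)
}
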