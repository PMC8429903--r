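#' Construct a probe calibration
#'
#' @param probeId one of "SG1", "SE1", "SHC".
#' @param targetEnzyme enzyme the probe reports; defaults to the panel
#'   mapping (SG1 = beta-galactosidase, SE1 = carboxylesterase,
#'   SHC = hNQO1).
#' @param classMeans,classSds named numeric vectors over tissue classes
#'   (normal, ulcer, adenoma, cancer).
#' @return a \linkS4class{ProbeCalibration}.
#' @export
ProbeCalibration <- function(probeId, classMeans, classSds,
                             targetEnzyme = NULL) {
  if (is.null(targetEnzyme))
    targetEnzyme <- if (probeId %in% names(.PROBES))
      unname(.PROBES[[probeId]]) else "unknown"
  new("ProbeCalibration", probeId = probeId, targetEnzyme = targetEnzyme,
      classMeans = classMeans, classSds = classSds)
}

#' Default imaging calibrations for the SG1 / SE1 / SHC panel
#'
#' Mean whole-depth Ch2/Ch1 ratios and between-sample SDs per tissue class
#' for the three enzyme-activity probes, as measured on gastric tissue by
#' two-photon microscopy.  SG1 (beta-galactosidase) rises in cancer, SE1
#' (carboxylesterase) falls, SHC (hNQO1) does not separate cancer from the
#' other conditions.
#'
#' @return named list of \linkS4class{ProbeCalibration} objects.
#' @export
#' @examples
#' imagingCalibrations()[["SG1"]]
imagingCalibrations <- function() {
  list(
    SG1 = ProbeCalibration("SG1",
      classMeans = c(normal = 0.656, ulcer = 0.992, adenoma = 0.927,
                     cancer = 1.127),
      classSds   = c(normal = 0.142, ulcer = 0.119, adenoma = 0.049,
                     cancer = 0.109)),
    SE1 = ProbeCalibration("SE1",
      classMeans = c(normal = 0.876, ulcer = 0.884, adenoma = 0.879,
                     cancer = 0.579),
      classSds   = c(normal = 0.049, ulcer = 0.048, adenoma = 0.059,
                     cancer = 0.089)),
    SHC = ProbeCalibration("SHC",
      classMeans = c(normal = 1.393, ulcer = 1.317, adenoma = 1.343,
                     cancer = 1.354),
      classSds   = c(normal = 0.141, ulcer = 0.120, adenoma = 0.073,
                     cancer = 0.174)))
}

#' Default lysate-assay endpoint calibrations
#'
#' Group means and SDs of the t = 120 min Ch2/Ch1 endpoint ratio for probe
#' reactions with lysis-buffer-treated tissue (1 uM probe, 200 ug protein).
#'
#' Note the SE1 direction: carboxylesterase activity is LOWER in cancer, so
#' the cancer endpoint (1.313) lies below the normal endpoint (1.859),
#' matching the imaging directionality.
#'
#' @return named list of \linkS4class{ProbeCalibration} objects holding
#'   endpoint statistics.
#' @export
lysateCalibrations <- function() {
  list(
    SG1 = ProbeCalibration("SG1",
      classMeans = c(normal = 1.324, ulcer = 1.579, adenoma = 1.639,
                     cancer = 1.794),
      classSds   = c(normal = 0.035, ulcer = 0.055, adenoma = 0.047,
                     cancer = 0.048)),
    SE1 = ProbeCalibration("SE1",
      classMeans = c(normal = 1.859, ulcer = 1.775, adenoma = 1.677,
                     cancer = 1.313),
      classSds   = c(normal = 0.053, ulcer = 0.063, adenoma = 0.051,
                     cancer = 0.051)),
    SHC = ProbeCalibration("SHC",
      classMeans = c(normal = 0.657, ulcer = 0.664, adenoma = 0.671,
                     cancer = 0.687),
      classSds   = c(normal = 0.038, ulcer = 0.029, adenoma = 0.028,
                     cancer = 0.048)))
}

#' Diagnostic direction of a probe
#'
#' "above" when the cancer mean exceeds the normal mean (SG1), "below"
#' otherwise (SE1; SHC is weakly "below" but not diagnostic).
#'
#' @param calibration a \linkS4class{ProbeCalibration}.
#' @return "above" or "below".
#' @export
probeDirection <- function(calibration) {
  stopifnot(is(calibration, "ProbeCalibration"))
  m <- classMeans(calibration)
  if (!all(c("normal", "cancer") %in% names(m)))
    stop("calibration must carry normal and cancer classes")
  if (m[["cancer"]] > m[["normal"]]) "above" else "below"
}

#' Default per-probe display range for pseudocolor rendering
#'
#' The range spans [mu_normal - 2 sd_normal, mu_cancer + 2 sd_cancer]
#' (endpoints sorted, so inverted probes such as SE1 work too).
#'
#' @param calibration a \linkS4class{ProbeCalibration}.
#' @return numeric length-2 ratio range.
#' @export
defaultDisplayRange <- function(calibration) {
  m <- classMeans(calibration); s <- classSds(calibration)
  lo <- m[["normal"]] - 2 * s[["normal"]]
  hi <- m[["cancer"]] + 2 * s[["cancer"]]
  rng <- sort(c(lo, hi))
  if (rng[1] <= 0) rng[1] <- min(m) / 4
  unname(rng)
}

#' Table 1 cohort sizes
#'
#' Per-class subject counts of the study cohort (total 76).
#' @return named integer vector.
#' @export
cohortCounts <- function() {
  c(normal = 21L, ulcer = 18L, adenoma = 17L, cancer = 20L)
}
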