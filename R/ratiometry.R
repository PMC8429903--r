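#' Foreground mask for a two-channel stack
#'
#' Segments signal-bearing (gland) voxels on the summed-channel intensity.
#' Two methods: Otsu's threshold on the pooled intensity histogram
#' (default), or a percentile cut keeping voxels above the p-th percentile
#' of summed intensity.  Voxels with Ch1 = 0 are always excluded (the
#' ratio is undefined there), as are voxels saturated at the 16-bit
#' maximum in either channel (the ratio is biased at saturation), and
#' voxels with Ch2 = 0 (the ratio would be zero, outside the positive
#' support the downstream statistics assume).  The mask is deterministic
#' given the stack and parameters.
#'
#' @param stack a \linkS4class{TwoChannelStack}.
#' @param method \code{"otsu"} or \code{"percentile"}.
#' @param p percentile (0--100) for the percentile method.
#' @return 3-D logical array.
#' @export
foregroundMask <- function(stack, method = c("otsu", "percentile"),
                           p = 50) {
  stopifnot(is(stack, "TwoChannelStack"))
  method <- match.arg(method)
  ch1 <- channel1(stack); ch2 <- channel2(stack)
  total <- ch1 + ch2
  eligible <- ch1 > 0 & ch2 > 0 & ch1 < .BIT_MAX & ch2 < .BIT_MAX
  if (!any(eligible))
    stop("empty foreground mask: no voxels with Ch1 > 0 below saturation ",
         "(max Ch1 = ", max(ch1), ", max Ch2 = ", max(ch2), ")")
  if (method == "otsu") {
    mx <- max(total)
    norm <- total / mx
    img <- EBImage::Image(as.vector(norm), dim = c(length(norm), 1L))
    th <- EBImage::otsu(img, range = c(0, 1), levels = 256L)
    mask <- eligible & total > th * mx
  } else {
    if (p < 0 || p > 100) stop("percentile p must lie in [0, 100]")
    th <- quantile(total[eligible], probs = p / 100, names = FALSE)
    mask <- eligible & total >= th
  }
  if (!any(mask))
    stop("empty foreground mask after thresholding (method = ", method,
         "); check staining/exposure")
  mask
}

#' Per-voxel Ch2/Ch1 ratio volume
#'
#' Ratios are computed voxel-wise inside the mask and are NA elsewhere.
#' The map is scale-invariant: multiplying both channels by any c > 0
#' leaves it unchanged.  Ratio values are never clipped for statistics;
#' \code{displayRange} only affects rendering.
#'
#' @param stack a \linkS4class{TwoChannelStack}.
#' @param mask 3-D logical foreground array (from
#'   \code{\link{foregroundMask}}).
#' @param displayRange ratio bounds for rendering; default is the
#'   calibration-driven range for the stack's probe when known, otherwise
#'   the observed ratio range.
#' @param calibrations named calibration list used for the default display
#'   range.
#' @return a \linkS4class{RatioVolume}.
#' @export
ratioMap <- function(stack, mask = foregroundMask(stack),
                     displayRange = NULL,
                     calibrations = imagingCalibrations()) {
  stopifnot(is(stack, "TwoChannelStack"))
  if (!identical(dim(mask), dim(channel1(stack))))
    stop("mask shape must match the stack")
  if (!any(mask)) stop("mask is empty")
  ch1 <- channel1(stack)
  stopifnot(all(ch1[mask] > 0))  # mask contract
  ratios <- array(NA_real_, dim(ch1))
  ratios[mask] <- channel2(stack)[mask] / ch1[mask]
  if (is.null(displayRange)) {
    calib <- calibrations[[probeId(stack)]]
    displayRange <- if (!is.null(calib)) defaultDisplayRange(calib)
      else range(ratios[mask])
    if (displayRange[1] >= displayRange[2])
      displayRange <- displayRange + c(-0.5, 0.5)
  }
  new("RatioVolume", ratios = ratios, mask = mask,
      zPositions = zPositions(stack), displayRange = displayRange,
      probeId = probeId(stack), sampleId = sampleId(stack),
      tissueClass = tissueClass(stack))
}

#' Whole-depth sample mean ratio
#'
#' The sample summary statistic: the arithmetic mean of per-voxel Ch2/Ch1
#' ratios over all masked voxels of all sections inside the depth window,
#' every masked voxel weighted equally ("entire sample depth").  This is
#' the mean of ratios, not the ratio of channel means — the two differ
#' under spatial heterogeneity.
#'
#' @param ratioVolume a \linkS4class{RatioVolume}.
#' @param depthWindow depth interval in micrometres; sections outside are
#'   excluded.
#' @return one-row data.frame: sample_id, probe_id, tissue_class,
#'   mean_ratio, n_foreground_voxels, n_sections.
#' @export
sampleMeanRatio <- function(ratioVolume, depthWindow = c(80, 200)) {
  stopifnot(is(ratioVolume, "RatioVolume"))
  z <- zPositions(ratioVolume)
  keep <- which(z >= depthWindow[1] & z <= depthWindow[2])
  if (!length(keep))
    stop("no sections inside depth window [", depthWindow[1], ", ",
         depthWindow[2], "] um (stack covers ", min(z), "-", max(z), " um)")
  m <- foregroundOf(ratioVolume)[, , keep, drop = FALSE]
  v <- ratios(ratioVolume)[, , keep, drop = FALSE][m]
  if (!length(v))
    stop("no masked voxels inside the depth window")
  data.frame(sample_id = sampleId(ratioVolume),
             probe_id = probeId(ratioVolume),
             tissue_class = tissueClass(ratioVolume),
             mean_ratio = mean(v),
             n_foreground_voxels = length(v),
             n_sections = length(keep), stringsAsFactors = FALSE)
}

#' Ratio colormap
#'
#' Blue-to-red ramp (blue/cyan low ratio, green mid, yellow/red high),
#' matching the visual convention that low-activity tissue renders
#' green-to-blue and high-activity tissue yellow-to-red.
#'
#' @return function mapping values in [0, 1] to an n x 3 RGB matrix in
#'   [0, 1].
#' @export
ratioColormap <- function() {
  ramp <- grDevices::colorRamp(
    c("#0000CD", "#00B2EE", "#00CD00", "#FFFF00", "#FF4500"),
    space = "rgb")
  function(v) ramp(pmin(pmax(v, 0), 1)) / 255
}

#' Pseudocolor ratiometric section images
#'
#' Hue encodes the ratio clipped to the display range; brightness encodes
#' the summed channel intensity normalized to the stack maximum;
#' background (unmasked) voxels render black.  Deterministic.
#'
#' @param ratioVolume a \linkS4class{RatioVolume}.
#' @param stack the matching \linkS4class{TwoChannelStack} supplying the
#'   intensity.
#' @param colormap function as returned by \code{\link{ratioColormap}}.
#' @param displayRange overrides the volume's display range.
#' @return list of nx x ny x 3 RGB arrays, one per section, with the
#'   z position attached as attribute \code{"z_um"}.
#' @export
pseudocolor <- function(ratioVolume, stack, colormap = ratioColormap(),
                        displayRange = NULL) {
  stopifnot(is(ratioVolume, "RatioVolume"), is(stack, "TwoChannelStack"))
  rng <- displayRange
  if (is.null(rng)) rng <- ratioVolume@displayRange
  if (length(rng) != 2L || rng[1] >= rng[2])
    stop("display range must be an increasing pair")
  total <- channel1(stack) + channel2(stack)
  bright <- total / max(total)
  r <- ratios(ratioVolume); m <- foregroundOf(ratioVolume)
  nz <- dim(r)[3]
  out <- vector("list", nz)
  for (z in seq_len(nz)) {
    rz <- r[, , z]; mz <- m[, , z]; bz <- bright[, , z]
    rgb <- array(0, c(dim(rz), 3L))
    if (any(mz)) {
      v <- (rz[mz] - rng[1]) / (rng[2] - rng[1])
      cols <- colormap(v) * bz[mz]
      for (k in 1:3) {
        plane <- rgb[, , k]; plane[mz] <- cols[, k]; rgb[, , k] <- plane
      }
    }
    attr(rgb, "z_um") <- zPositions(ratioVolume)[z]
    out[[z]] <- rgb
  }
  out
}

#' Write pseudocolor sections as PNG files
#'
#' Files are named \code{{sample}_{z}um.png} in \code{dir}.
#'
#' @param sections list from \code{\link{pseudocolor}}.
#' @param dir output directory (created if needed).
#' @param sampleId sample identifier used in filenames.
#' @return character vector of written paths.
#' @export
writePseudocolorPNG <- function(sections, dir, sampleId) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vapply(sections, function(sec) {
    path <- file.path(dir, sprintf("%s_%gum.png", sampleId,
                                   attr(sec, "z_um")))
    png::writePNG(aperm(sec, c(2, 1, 3)), path)
    path
  }, character(1))
}
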