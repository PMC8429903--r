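#' ProbeCalibration: per-probe, per-tissue-class ratio statistics
#'
#' Holds, for one ratiometric two-photon probe, the mean Ch2/Ch1 ratio and
#' the between-sample standard deviation for each tissue class
#' (normal, ulcer, adenoma, cancer).  These numbers drive the synthetic
#' cohort generator and set default display ranges for rendering.
#'
#' @slot probeId single probe identifier, one of \code{"SG1"} (reports
#'   beta-galactosidase), \code{"SE1"} (carboxylesterase) or \code{"SHC"}
#'   (hNQO1).
#' @slot targetEnzyme the enzyme the probe reports.
#' @slot classMeans named numeric, mean Ch2/Ch1 ratio per tissue class.
#' @slot classSds named numeric, between-sample SD per tissue class.
#' @export
setClass("ProbeCalibration",
  representation(probeId = "character", targetEnzyme = "character",
                 classMeans = "numeric", classSds = "numeric"))

setValidity("ProbeCalibration", function(object) {
  msg <- character()
  if (length(object@probeId) != 1L)
    msg <- c(msg, "probeId must be a single string")
  cls <- names(object@classMeans)
  if (is.null(cls) || !all(cls %in% .TISSUE_CLASSES))
    msg <- c(msg, "classMeans must be named with tissue classes")
  if (!identical(sort(names(object@classSds)), sort(cls)))
    msg <- c(msg, "classSds must carry the same classes as classMeans")
  if (any(object@classMeans <= 0) || any(object@classSds <= 0))
    msg <- c(msg, "all means and SDs must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' AcquisitionParams: imaging/simulation acquisition settings
#'
#' @slot imageSize pixels per side of each optical section.
#' @slot pixelSize lateral pixel size in micrometres.
#' @slot zPositions depths of the optical sections in micrometres below the
#'   tissue surface (surface = 0, increasing downward), strictly increasing,
#'   within 0--500.
#' @slot depthWindow two numbers, the depth interval (micrometres) used for
#'   whole-sample summaries and depth profiles.
#' @slot attenuationLength exponential signal-loss length scale with depth,
#'   micrometres.
#' @slot photonBudget expected photon counts at the brightest voxel at the
#'   tissue surface (z = 0).
#' @slot readNoiseSd additive detector read noise SD, counts.
#' @slot probeConcentration probe staining concentration, micromolar.
#' @export
setClass("AcquisitionParams",
  representation(imageSize = "integer", pixelSize = "numeric",
                 zPositions = "numeric", depthWindow = "numeric",
                 attenuationLength = "numeric", photonBudget = "numeric",
                 readNoiseSd = "numeric", probeConcentration = "numeric"))

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  z <- object@zPositions
  if (length(z) < 1L || any(diff(z) <= 0))
    msg <- c(msg, "zPositions must be strictly increasing")
  if (any(z < 0 | z > 500))
    msg <- c(msg, "zPositions must lie within 0-500 micrometres")
  if (object@photonBudget <= 0)
    msg <- c(msg, "photonBudget must be > 0")
  if (object@attenuationLength <= 0)
    msg <- c(msg, "attenuationLength must be > 0")
  if (object@readNoiseSd < 0)
    msg <- c(msg, "readNoiseSd must be >= 0")
  if (length(object@depthWindow) != 2L ||
      object@depthWindow[1] >= object@depthWindow[2])
    msg <- c(msg, "depthWindow must be an increasing pair")
  if (length(msg)) msg else TRUE
})

#' GlandGeometry: gastric gland lattice parameters for tissue phantoms
#'
#' Glands are modelled as tubules (bright annular walls around a dark lumen)
#' on a periodic 2-D lattice extruded in z.  \code{disorder} in [0, 1]
#' randomly displaces tubule centres and perturbs radii; 0 gives a perfectly
#' periodic lattice, cancer-like phantoms use values >= 0.5.
#'
#' @slot tubuleRadius outer tubule radius, micrometres.
#' @slot spacing lattice spacing, micrometres.
#' @slot wallThickness gland wall (bright annulus) thickness, micrometres.
#' @slot disorder fraction in [0, 1] controlling lattice irregularity.
#' @slot jitterSd per-section centre jitter SD, micrometres.
#' @slot backgroundBrightness relative brightness outside gland walls.
#' @export
setClass("GlandGeometry",
  representation(tubuleRadius = "numeric", spacing = "numeric",
                 wallThickness = "numeric", disorder = "numeric",
                 jitterSd = "numeric", backgroundBrightness = "numeric"))

setValidity("GlandGeometry", function(object) {
  msg <- character()
  if (object@disorder < 0 || object@disorder > 1)
    msg <- c(msg, "disorder must lie in [0, 1]")
  if (object@tubuleRadius <= 0 || object@spacing <= 0 ||
      object@wallThickness <= 0)
    msg <- c(msg, "tubuleRadius, spacing and wallThickness must be positive")
  if (object@wallThickness > object@tubuleRadius)
    msg <- c(msg, "wallThickness cannot exceed tubuleRadius")
  if (length(msg)) msg else TRUE
})

#' Phantom: synthetic tissue ground truth
#'
#' @slot trueRatio 3-D array of per-voxel true Ch2/Ch1 ratios (> 0).
#' @slot brightness 3-D array of relative emission brightness (a.u.).
#' @slot glandMask 3-D logical array, TRUE on gland-wall voxels (the
#'   ground-truth foreground).
#' @slot geometry the \linkS4class{GlandGeometry} used.
#' @slot tissueClass tissue class label.
#' @slot probeId probe identifier.
#' @slot sampleRatioMean the realized per-sample mean ratio drawn from the
#'   calibration for this phantom.
#' @export
setClass("Phantom",
  representation(trueRatio = "array", brightness = "array",
                 glandMask = "array", geometry = "GlandGeometry",
                 tissueClass = "character", probeId = "character",
                 sampleRatioMean = "numeric"))

setValidity("Phantom", function(object) {
  msg <- character()
  if (any(object@trueRatio <= 0))
    msg <- c(msg, "trueRatio values must be strictly positive")
  if (!identical(dim(object@trueRatio), dim(object@brightness)) ||
      !identical(dim(object@trueRatio), dim(object@glandMask)))
    msg <- c(msg, "trueRatio, brightness and glandMask shapes must agree")
  if (object@sampleRatioMean <= 0)
    msg <- c(msg, "sampleRatioMean must be positive")
  if (length(msg)) msg else TRUE
})

#' TwoChannelStack: registered two-channel intensity z-stack
#'
#' @slot ch1 3-D array of Ch1 (400--450 nm) photon counts.
#' @slot ch2 3-D array of Ch2 (600--650 nm) photon counts.
#' @slot zPositions section depths, micrometres below the surface.
#' @slot pixelSize lateral pixel size, micrometres.
#' @slot bands 2 x 2 numeric matrix of emission bands in nm
#'   (rows Ch1, Ch2; columns lower, upper).
#' @slot probeId,sampleId,tissueClass provenance (tissueClass may be NA for
#'   blinded analysis).
#' @export
setClass("TwoChannelStack",
  representation(ch1 = "array", ch2 = "array", zPositions = "numeric",
                 pixelSize = "numeric", bands = "matrix",
                 probeId = "character", sampleId = "character",
                 tissueClass = "character"))

setValidity("TwoChannelStack", function(object) {
  msg <- character()
  if (!identical(dim(object@ch1), dim(object@ch2)))
    msg <- c(msg, "ch1 and ch2 must have identical shapes")
  if (length(dim(object@ch1)) != 3L)
    msg <- c(msg, "channels must be 3-D arrays")
  else if (dim(object@ch1)[3] != length(object@zPositions))
    msg <- c(msg, "number of sections must equal length(zPositions)")
  if (any(diff(object@zPositions) <= 0))
    msg <- c(msg, "zPositions must be strictly increasing")
  if (min(object@ch1, object@ch2) < 0)
    msg <- c(msg, "intensities must be non-negative")
  b <- object@bands
  if (!all(dim(b) == c(2L, 2L)))
    msg <- c(msg, "bands must be a 2 x 2 matrix")
  else if (b[2, 1] <= b[1, 2])
    msg <- c(msg, "Ch2 band must lie entirely above the Ch1 band")
  if (length(msg)) msg else TRUE
})

#' RatioVolume: foreground-masked per-voxel Ch2/Ch1 ratio volume
#'
#' @slot ratios 3-D array of Ch2/Ch1 values, NA outside the mask.
#' @slot mask 3-D logical foreground array.
#' @slot zPositions section depths, micrometres.
#' @slot displayRange ratio bounds used for pseudocolor rendering.
#' @slot probeId,sampleId,tissueClass provenance.
#' @export
setClass("RatioVolume",
  representation(ratios = "array", mask = "array", zPositions = "numeric",
                 displayRange = "numeric", probeId = "character",
                 sampleId = "character", tissueClass = "character"))

setValidity("RatioVolume", function(object) {
  msg <- character()
  if (!identical(dim(object@ratios), dim(object@mask)))
    msg <- c(msg, "ratios and mask shapes must agree")
  v <- object@ratios[object@mask]
  if (any(!is.finite(v)) || any(v <= 0))
    msg <- c(msg, "masked ratios must be finite and > 0")
  if (dim(object@ratios)[3] != length(object@zPositions))
    msg <- c(msg, "sections must match zPositions")
  if (length(object@displayRange) != 2L ||
      object@displayRange[1] >= object@displayRange[2])
    msg <- c(msg, "displayRange must be an increasing pair")
  if (length(msg)) msg else TRUE
})

#' DepthProfile: per-section ratio statistics versus depth
#'
#' Mean, min and max of masked per-voxel ratios for every retained optical
#' section (error bars in plots carry min/max; SD is stored additionally).
#'
#' @slot z section depths, micrometres (strictly increasing).
#' @slot meanRatio,minRatio,maxRatio,sdRatio per-section statistics (NA where
#'   a section has an empty mask).
#' @slot nVoxels masked voxel count per section.
#' @slot probeId,sampleId provenance.
#' @export
setClass("DepthProfile",
  representation(z = "numeric", meanRatio = "numeric", minRatio = "numeric",
                 maxRatio = "numeric", sdRatio = "numeric",
                 nVoxels = "integer", probeId = "character",
                 sampleId = "character"))

setValidity("DepthProfile", function(object) {
  msg <- character()
  n <- length(object@z)
  if (any(diff(object@z) <= 0))
    msg <- c(msg, "z must be strictly increasing")
  if (length(object@meanRatio) != n || length(object@minRatio) != n ||
      length(object@maxRatio) != n || length(object@nVoxels) != n)
    msg <- c(msg, "per-section vectors must have one entry per depth")
  ok <- object@nVoxels > 0L
  if (any(object@minRatio[ok] > object@meanRatio[ok]) ||
      any(object@meanRatio[ok] > object@maxRatio[ok]))
    msg <- c(msg, "min <= mean <= max must hold per section")
  if (length(msg)) msg else TRUE
})

#' LysateTimeSeries: plate-reader Ch2/Ch1 ratio time course
#'
#' Ratio trajectory of a probe reacting with homogenized (lysis
#' buffer-treated) tissue, sampled every 10 minutes from 0 to 120 minutes
#' in the default assay design (1 uM probe, 200 ug protein).
#'
#' @slot timeMin measurement times, minutes, strictly increasing.
#' @slot ratio Ch2/Ch1 at each time point (> 0).
#' @slot sampleId,probeId,tissueClass provenance (tissueClass may be NA).
#' @slot probeConcentration probe concentration, micromolar.
#' @slot proteinAmount lysate protein input, micrograms.
#' @export
setClass("LysateTimeSeries",
  representation(timeMin = "numeric", ratio = "numeric",
                 sampleId = "character", probeId = "character",
                 tissueClass = "character", probeConcentration = "numeric",
                 proteinAmount = "numeric"))

setValidity("LysateTimeSeries", function(object) {
  msg <- character()
  if (length(object@timeMin) != length(object@ratio))
    msg <- c(msg, "timeMin and ratio must have equal length")
  if (any(diff(object@timeMin) <= 0))
    msg <- c(msg, "timeMin must be strictly increasing")
  if (any(object@ratio <= 0))
    msg <- c(msg, "ratios must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' LysateAssayParams: generator settings for one lysate time course
#'
#' The trajectory follows a first-order approach to plateau,
#' R(t) = Rinf - (Rinf - R0) exp(-k t), with additive Gaussian read noise.
#'
#' @slot probeConcentration micromolar (default 1).
#' @slot proteinAmount micrograms (default 200).
#' @slot timePoints minutes, 0 to 120 in steps of 10.
#' @slot k first-order conversion rate, per minute (>= 0).
#' @slot R0 initial ratio.
#' @slot Rinf plateau ratio.
#' @slot noiseSd per-time-point additive noise SD.
#' @export
setClass("LysateAssayParams",
  representation(probeConcentration = "numeric", proteinAmount = "numeric",
                 timePoints = "numeric", k = "numeric", R0 = "numeric",
                 Rinf = "numeric", noiseSd = "numeric"))

setValidity("LysateAssayParams", function(object) {
  msg <- character()
  tp <- object@timePoints
  if (any(diff(tp) != 10) || tp[length(tp)] != 120)
    msg <- c(msg, "timePoints must step by 10 min and end at 120 min")
  if (object@k < 0)
    msg <- c(msg, "k must be non-negative")
  if (object@R0 <= 0 || object@Rinf <= 0)
    msg <- c(msg, "R0 and Rinf must be positive")
  if (object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be non-negative")
  if (length(msg)) msg else TRUE
})

#' CohortDesign: layout of a simulated imaging cohort
#'
#' @slot counts named integer vector of per-class sample counts.
#' @slot probes probe panel to simulate.
#' @slot calibrations named list of \linkS4class{ProbeCalibration}.
#' @slot acquisition \linkS4class{AcquisitionParams} shared by all samples.
#' @slot masterSeed integer master seed; per-sample seeds are derived
#'   deterministically from it.
#' @slot textureSd within-sample spatial texture SD (ratio units).
#' @export
setClass("CohortDesign",
  representation(counts = "integer", probes = "character",
                 calibrations = "list", acquisition = "AcquisitionParams",
                 masterSeed = "integer", textureSd = "numeric"))

setValidity("CohortDesign", function(object) {
  msg <- character()
  if (is.null(names(object@counts)) ||
      !all(names(object@counts) %in% .TISSUE_CLASSES))
    msg <- c(msg, "counts must be named with tissue classes")
  if (any(object@counts < 1L))
    msg <- c(msg, "all class counts must be >= 1")
  if (!all(object@probes %in% names(object@calibrations)))
    msg <- c(msg, "every probe needs a calibration")
  if (length(msg)) msg else TRUE
})

#' ClassifierRule: single-threshold diagnostic rule on sample mean ratios
#'
#' @slot probeId probe the rule applies to.
#' @slot threshold ratio cut-off.
#' @slot direction \code{"above"} (ratio above threshold calls the positive
#'   class, as for SG1) or \code{"below"} (as for SE1).
#' @slot positiveClass the tissue class called when the rule fires.
#' @export
setClass("ClassifierRule",
  representation(probeId = "character", threshold = "numeric",
                 direction = "character", positiveClass = "character"))

setValidity("ClassifierRule", function(object) {
  if (!object@direction %in% c("above", "below"))
    return("direction must be 'above' or 'below'")
  TRUE
})
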