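#' Acquisition parameters
#'
#' Defaults mirror the study conditions: 64 x 64 px sections (2 um pixels),
#' 30 sections evenly covering the 80-200 um depth window, 10 uM probe
#' staining, a 500-count photon budget at the surface and exponential
#' depth attenuation.
#'
#' @param imageSize pixels per section side.
#' @param pixelSize lateral pixel size, um.
#' @param zPositions section depths, um; default 30 sections spanning
#'   \code{depthWindow}.
#' @param depthWindow analysis depth window, um.
#' @param attenuationLength exponential attenuation length, um.
#' @param photonBudget expected counts at the brightest surface voxel.
#' @param readNoiseSd detector read noise SD, counts.
#' @param probeConcentration staining concentration, uM.
#' @return an \linkS4class{AcquisitionParams}.
#' @export
AcquisitionParams <- function(imageSize = 64L, pixelSize = 2,
                              zPositions = NULL, depthWindow = c(80, 200),
                              attenuationLength = 150, photonBudget = 500,
                              readNoiseSd = 1, probeConcentration = 10) {
  if (is.null(zPositions))
    zPositions <- seq(depthWindow[1], depthWindow[2], length.out = 30)
  new("AcquisitionParams", imageSize = as.integer(imageSize),
      pixelSize = pixelSize, zPositions = as.numeric(zPositions),
      depthWindow = as.numeric(depthWindow),
      attenuationLength = attenuationLength, photonBudget = photonBudget,
      readNoiseSd = readNoiseSd, probeConcentration = probeConcentration)
}

#' Gland lattice geometry
#'
#' @param tubuleRadius outer tubule radius, um.
#' @param spacing lattice spacing, um.
#' @param wallThickness bright annular wall thickness, um.
#' @param disorder lattice irregularity fraction in [0, 1].
#' @param jitterSd per-section centre jitter SD, um.
#' @param backgroundBrightness relative brightness outside walls.
#' @return a \linkS4class{GlandGeometry}.
#' @export
GlandGeometry <- function(tubuleRadius = 11, spacing = 30,
                          wallThickness = 5, disorder = 0,
                          jitterSd = 0.5, backgroundBrightness = 0.02) {
  new("GlandGeometry", tubuleRadius = tubuleRadius, spacing = spacing,
      wallThickness = wallThickness, disorder = disorder,
      jitterSd = jitterSd, backgroundBrightness = backgroundBrightness)
}

#' Class-typical gland geometry
#'
#' Normal mucosa keeps a near-periodic gland lattice; ulcer and adenoma are
#' progressively irregular; cancer glands are irregular and disordered
#' (disorder >= 0.5).
#'
#' @param tissueClass one of normal, ulcer, adenoma, cancer.
#' @param ... further arguments passed to \code{\link{GlandGeometry}}.
#' @export
defaultGlandGeometry <- function(tissueClass, ...) {
  disorder <- switch(tissueClass,
    normal = 0.05, ulcer = 0.2, adenoma = 0.3, cancer = 0.6,
    stop("unknown tissue class: ", tissueClass))
  GlandGeometry(disorder = disorder, ...)
}

## Tubule centres for one phantom: hexagonal-offset lattice with
## disorder-scaled displacement and radius perturbation (drawn from the
## active RNG stream).
.tubuleCentres <- function(fieldSize, geom) {
  s <- geom@spacing
  xs <- seq(-s / 2, fieldSize + s / 2, by = s)
  ys <- seq(-s / 2, fieldSize + s / 2, by = s)
  cx <- rep(xs, times = length(ys))
  cy <- rep(ys, each = length(xs))
  odd <- rep(seq_along(ys) %% 2 == 0, each = length(xs))
  cx[odd] <- cx[odd] + s / 2
  n <- length(cx)
  disp <- geom@disorder * s / 3
  cx <- cx + rnorm(n, 0, disp)
  cy <- cy + rnorm(n, 0, disp)
  radius <- geom@tubuleRadius *
    (1 + geom@disorder * stats::runif(n, -0.4, 0.4))
  list(x = cx, y = cy, radius = pmax(radius, geom@wallThickness))
}

## Brightness and gland-wall mask for one section given jittered centres.
.sectionBrightness <- function(nx, ny, pixelSize, centres, jx, jy, geom) {
  px <- (seq_len(nx) - 0.5) * pixelSize
  py <- (seq_len(ny) - 0.5) * pixelSize
  wall <- matrix(FALSE, nx, ny)
  for (t in seq_along(centres$x)) {
    dx <- px - (centres$x[t] + jx[t])
    dy <- py - (centres$y[t] + jy[t])
    d2 <- outer(dx^2, dy^2, "+")
    r <- centres$radius[t]
    wall <- wall | (d2 <= r^2 & d2 >= (r - geom@wallThickness)^2)
  }
  wall
}

#' Build a synthetic tissue phantom
#'
#' Draws the per-sample mean ratio from the calibration's
#' Normal(mu_class, sd_class) (truncated at zero), lays down a
#' gland-structured brightness field (bright tubule walls on a near-zero
#' background) and modulates the ratio with a smooth spatial texture field
#' of standard deviation \code{textureSd}.
#'
#' @param tissueClass tissue class to emulate.
#' @param calibration a \linkS4class{ProbeCalibration}.
#' @param geometry a \linkS4class{GlandGeometry}; default is the
#'   class-typical geometry from \code{\link{defaultGlandGeometry}}.
#' @param acquisition an \linkS4class{AcquisitionParams}.
#' @param seed integer seed; the phantom is a pure function of its
#'   arguments.
#' @param textureSd within-sample spatial SD of the true ratio field
#'   (ratio units).
#' @return a \linkS4class{Phantom}.
#' @export
#' @examples
#' ph <- buildPhantom("cancer", imagingCalibrations()[["SG1"]], seed = 1)
#' sampleRatioMean(ph)
buildPhantom <- function(tissueClass, calibration, geometry = NULL,
                         acquisition = AcquisitionParams(), seed,
                         textureSd = 0.05) {
  if (!tissueClass %in% names(classMeans(calibration)))
    stop("tissue class '", tissueClass, "' not present in calibration for ",
         probeId(calibration))
  if (is.null(geometry)) geometry <- defaultGlandGeometry(tissueClass)
  mu <- classMeans(calibration)[[tissueClass]]
  sigma <- classSds(calibration)[[tissueClass]]
  nx <- acquisition@imageSize
  nz <- length(acquisition@zPositions)
  .withSeed(seed, {
    m <- .rtruncnorm(1L, mu, sigma)
    dims <- c(nx, nx, nz)
    tex <- if (textureSd > 0) .smoothField(dims) else array(0, dims)
    ratio <- pmax(m + textureSd * tex, 0.01)
    centres <- .tubuleCentres(nx * acquisition@pixelSize, geometry)
    ntub <- length(centres$x)
    bright <- array(geometry@backgroundBrightness, dims)
    wallMask <- array(FALSE, dims)
    for (z in seq_len(nz)) {
      jx <- rnorm(ntub, 0, geometry@jitterSd)
      jy <- rnorm(ntub, 0, geometry@jitterSd)
      w <- .sectionBrightness(nx, nx, acquisition@pixelSize, centres,
                              jx, jy, geometry)
      wallMask[, , z] <- w
      bright[, , z][w] <- 1
    }
    new("Phantom", trueRatio = ratio, brightness = bright,
        glandMask = wallMask, geometry = geometry,
        tissueClass = tissueClass, probeId = probeId(calibration),
        sampleRatioMean = m)
  })
}

#' Render a phantom into an acquired two-channel stack
#'
#' Forward imaging model: for a voxel with true ratio r and relative
#' brightness b at depth z, the expected band intensities are
#' \deqn{E[Ch2] = B r / (1 + r), \quad E[Ch1] = B / (1 + r),}
#' with \eqn{B = b \cdot \mathrm{photonBudget} \cdot e^{-z/\ell}} and
#' \eqn{\ell} the attenuation length, so Ch1 + Ch2 conserve B and the
#' emission ratio is exactly r.  With \code{noise = TRUE} observed counts
#' are Poisson(E) plus Gaussian read noise, rounded and clipped to the
#' 16-bit range.
#'
#' @param phantom a \linkS4class{Phantom}.
#' @param acquisition an \linkS4class{AcquisitionParams} whose grid matches
#'   the phantom.
#' @param seed integer seed for the photon/read noise.
#' @param noise logical; \code{FALSE} returns the noise-free expected
#'   intensities (not rounded).
#' @return a \linkS4class{TwoChannelStack}.
#' @export
renderStack <- function(phantom, acquisition = AcquisitionParams(),
                        seed = 1L, noise = TRUE) {
  if (acquisition@photonBudget <= 0) stop("photonBudget must be positive")
  dims <- dim(trueRatio(phantom))
  if (dims[3] != length(acquisition@zPositions))
    stop("phantom and acquisition z grids are incompatible")
  if (dims[1] != acquisition@imageSize)
    stop("phantom and acquisition image sizes are incompatible")
  r <- trueRatio(phantom)
  att <- exp(-acquisition@zPositions / acquisition@attenuationLength)
  B <- brightnessField(phantom) * acquisition@photonBudget *
    rep(att, each = dims[1] * dims[2])
  e2 <- B * r / (1 + r)
  e1 <- B / (1 + r)
  if (noise) {
    n <- length(e1)
    .withSeed(seed, {
      c1 <- rpois(n, e1) + rnorm(n, 0, acquisition@readNoiseSd)
      c2 <- rpois(n, e2) + rnorm(n, 0, acquisition@readNoiseSd)
      e1 <- array(pmin(pmax(round(c1), 0), .BIT_MAX), dims)
      e2 <- array(pmin(pmax(round(c2), 0), .BIT_MAX), dims)
    })
  }
  new("TwoChannelStack", ch1 = e1, ch2 = e2,
      zPositions = acquisition@zPositions,
      pixelSize = acquisition@pixelSize, bands = defaultBands(),
      probeId = probeId(phantom), sampleId = NA_character_,
      tissueClass = tissueClass(phantom))
}

#' Default emission bands (nm)
#' @return 2 x 2 matrix, rows Ch1 (400-450 nm) and Ch2 (600-650 nm).
#' @export
defaultBands <- function() {
  matrix(c(400, 450, 600, 650), nrow = 2, byrow = TRUE,
         dimnames = list(c("Ch1", "Ch2"), c("lower_nm", "upper_nm")))
}

#' Simulate one acquired sample
#'
#' Convenience wrapper: builds the class-typical phantom and renders it,
#' using sub-seeds derived deterministically from \code{seed}.
#'
#' @inheritParams buildPhantom
#' @param sampleId identifier stored in the stack.
#' @param noise passed to \code{\link{renderStack}}.
#' @return list with elements \code{stack} (\linkS4class{TwoChannelStack})
#'   and \code{phantom} (\linkS4class{Phantom}).
#' @export
simulateSample <- function(tissueClass, calibration,
                           acquisition = AcquisitionParams(), seed,
                           textureSd = 0.05, geometry = NULL,
                           sampleId = NA_character_, noise = TRUE) {
  ph <- buildPhantom(tissueClass, calibration, geometry, acquisition,
                     seed = .deriveSeed(seed, "phantom"),
                     textureSd = textureSd)
  st <- renderStack(ph, acquisition, seed = .deriveSeed(seed, "render"),
                    noise = noise)
  st@sampleId <- sampleId
  list(stack = st, phantom = ph)
}

#' Cohort design
#'
#' @param counts named per-class sample counts; default Table-1 sizes
#'   (normal 21, ulcer 18, adenoma 17, cancer 20).
#' @param probes probe panel.
#' @param calibrations named list of calibrations.
#' @param acquisition shared acquisition parameters.
#' @param masterSeed master seed; per-sample seeds derive from it.
#' @param textureSd within-sample texture SD.
#' @return a \linkS4class{CohortDesign}.
#' @export
CohortDesign <- function(counts = cohortCounts(),
                         probes = c("SG1", "SE1", "SHC"),
                         calibrations = imagingCalibrations(),
                         acquisition = AcquisitionParams(),
                         masterSeed = 1L, textureSd = 0.05) {
  cn <- names(counts)
  counts <- as.integer(counts)
  names(counts) <- cn
  new("CohortDesign", counts = counts,
      probes = probes, calibrations = calibrations,
      acquisition = acquisition, masterSeed = as.integer(masterSeed),
      textureSd = textureSd)
}

#' Simulate a full imaging cohort
#'
#' One stack per sample per probe.  The manifest records sample id, class,
#' probe, derived seed and the true per-sample mean ratio; the run is fully
#' reproducible from the master seed.  When \code{dir} is given, stacks are
#' written as multi-page TIFFs with JSON sidecars and dropped from memory;
#' otherwise they are returned in a list.
#'
#' @param design a \linkS4class{CohortDesign}.
#' @param dir optional output directory.
#' @return list with \code{manifest} (data.frame) and \code{stacks}
#'   (named list, empty when \code{dir} is used).
#' @export
simulateCohort <- function(design, dir = NULL) {
  stopifnot(is(design, "CohortDesign"))
  validObject(design)
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  rows <- list(); stacks <- list()
  for (probe in design@probes) {
    calib <- design@calibrations[[probe]]
    for (cls in names(design@counts)) {
      for (i in seq_len(design@counts[[cls]])) {
        sid <- sprintf("%s_%s_%02d", probe, cls, i)
        seed <- .deriveSeed(design@masterSeed, probe, cls, i)
        sim <- simulateSample(cls, calib, design@acquisition, seed = seed,
                              textureSd = design@textureSd, sampleId = sid)
        path <- NA_character_
        if (!is.null(dir)) {
          path <- file.path(dir, paste0(sid, ".tif"))
          writeStack(sim$stack, path, seed = seed)
        } else {
          stacks[[sid]] <- sim$stack
        }
        rows[[sid]] <- data.frame(
          sample_id = sid, tissue_class = cls, probe_id = probe,
          seed = seed, true_mean_ratio = sampleRatioMean(sim$phantom),
          tiff_path = path, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(dir))
    writeManifest(manifest, file.path(dir, "manifest.csv"))
  list(manifest = manifest, stacks = stacks)
}

#' Draw cohort sample means at summary level
#'
#' Bypasses the imaging forward model and draws per-sample mean ratios
#' directly from the calibration's truncated normal distributions.  Used
#' for power analyses over many replicate cohorts where the full image
#' pipeline would add nothing but runtime.
#'
#' @param probe probe id present in \code{calibrations}.
#' @param counts named per-class sample counts.
#' @param calibrations named list of calibrations.
#' @param seed integer seed.
#' @return data.frame with columns sample_id, tissue_class, probe_id,
#'   mean_ratio.
#' @export
simulateCohortSummaries <- function(probe, counts = cohortCounts(),
                                    calibrations = imagingCalibrations(),
                                    seed = 1L) {
  calib <- calibrations[[probe]]
  if (is.null(calib)) stop("no calibration for probe ", probe)
  .withSeed(seed, {
    rows <- lapply(names(counts), function(cls) {
      n <- counts[[cls]]
      data.frame(
        sample_id = sprintf("%s_%s_%02d", probe, cls, seq_len(n)),
        tissue_class = cls, probe_id = probe,
        mean_ratio = .rtruncnorm(n, classMeans(calib)[[cls]],
                                 classSds(calib)[[cls]]),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Lysate assay parameters
#'
#' @param k first-order conversion rate, per minute.
#' @param R0 initial Ch2/Ch1 ratio.
#' @param Rinf plateau ratio.
#' @param noiseSd per-time-point additive noise SD.
#' @param timePoints minutes; default 0 to 120 by 10.
#' @param probeConcentration uM (default 1, the lysate assay condition).
#' @param proteinAmount ug protein (default 200).
#' @return a \linkS4class{LysateAssayParams}.
#' @export
LysateAssayParams <- function(k, R0, Rinf, noiseSd = 0.02,
                              timePoints = seq(0, 120, by = 10),
                              probeConcentration = 1, proteinAmount = 200) {
  new("LysateAssayParams", probeConcentration = probeConcentration,
      proteinAmount = proteinAmount, timePoints = as.numeric(timePoints),
      k = k, R0 = R0, Rinf = Rinf, noiseSd = noiseSd)
}

#' Simulate one lysate time course
#'
#' First-order approach to plateau,
#' R(t) = Rinf - (Rinf - R0) exp(-k t), plus independent Gaussian noise at
#' each time point (values floored just above zero).
#'
#' @param params a \linkS4class{LysateAssayParams}.
#' @param seed integer seed.
#' @param sampleId,probeId,tissueClass provenance stored in the series.
#' @return a \linkS4class{LysateTimeSeries}.
#' @export
simulateLysateSeries <- function(params, seed = 1L,
                                 sampleId = NA_character_,
                                 probeId = NA_character_,
                                 tissueClass = NA_character_) {
  stopifnot(is(params, "LysateAssayParams"))
  validObject(params)
  tp <- params@timePoints
  mu <- params@Rinf - (params@Rinf - params@R0) * exp(-params@k * tp)
  r <- if (params@noiseSd > 0)
    .withSeed(seed, mu + rnorm(length(tp), 0, params@noiseSd)) else mu
  new("LysateTimeSeries", timeMin = tp, ratio = pmax(r, 1e-6),
      sampleId = sampleId, probeId = probeId, tissueClass = tissueClass,
      probeConcentration = params@probeConcentration,
      proteinAmount = params@proteinAmount)
}

#' Simulate a lysate cohort for one probe and tissue class
#'
#' Per sample, a target endpoint ratio is drawn from the lysate endpoint
#' calibration Normal(mu_class, sd_class) (truncated at zero) and the
#' plateau Rinf is solved so the noise-free t = 120 min value equals that
#' draw; the trajectory then follows the first-order model with additive
#' measurement noise.
#'
#' @param probe probe id.
#' @param tissueClass tissue class.
#' @param n number of samples.
#' @param masterSeed master seed; per-sample seeds derive from it.
#' @param calibrations endpoint calibrations
#'   (default \code{\link{lysateCalibrations}}).
#' @param k conversion rate, per minute.
#' @param R0 initial ratio shared by all samples.
#' @param noiseSd per-time-point noise SD.
#' @return list with \code{series} (list of \linkS4class{LysateTimeSeries})
#'   and \code{truth} (data.frame of drawn endpoints).
#' @export
simulateLysateCohort <- function(probe, tissueClass, n, masterSeed = 1L,
                                 calibrations = lysateCalibrations(),
                                 k = 0.03, R0 = 0.5, noiseSd = 0.02) {
  calib <- calibrations[[probe]]
  if (is.null(calib)) stop("no lysate calibration for probe ", probe)
  if (!tissueClass %in% names(classMeans(calib)))
    stop("unknown tissue class: ", tissueClass)
  if (k < 0) stop("k must be non-negative")
  mu <- classMeans(calib)[[tissueClass]]
  sigma <- classSds(calib)[[tissueClass]]
  decay <- exp(-k * 120)
  series <- vector("list", n); truth <- numeric(n)
  for (i in seq_len(n)) {
    seed <- .deriveSeed(masterSeed, "lysate", probe, tissueClass, i)
    endpoint <- .withSeed(seed, .rtruncnorm(1L, mu, sigma))
    Rinf <- (endpoint - R0 * decay) / (1 - decay)
    sid <- sprintf("%s_%s_lys%02d", probe, tissueClass, i)
    params <- LysateAssayParams(k = k, R0 = R0, Rinf = Rinf,
                                noiseSd = noiseSd)
    series[[i]] <- simulateLysateSeries(params,
                                        seed = .deriveSeed(seed, "noise"),
                                        sampleId = sid, probeId = probe,
                                        tissueClass = tissueClass)
    truth[i] <- endpoint
  }
  names(series) <- vapply(series, sampleId, character(1))
  list(series = series,
       truth = data.frame(sample_id = names(series),
                          tissue_class = tissueClass, probe_id = probe,
                          true_endpoint = truth, stringsAsFactors = FALSE))
}
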