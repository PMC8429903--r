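#' Per-section depth profile of a ratio volume
#'
#' Mean, minimum, maximum and SD of the masked per-voxel ratios of every
#' section whose depth lies inside the window.  Sections with an empty
#' mask are retained with \code{n_voxels = 0} and NA statistics (plots
#' drop them).  Error bars in the standard plot carry min/max; the SD is
#' stored additionally.  Sections are binned by exact z position — no
#' interpolation across depth.
#'
#' @param ratioVolume a \linkS4class{RatioVolume}.
#' @param depthWindow depth interval, micrometres.
#' @return a \linkS4class{DepthProfile}.
#' @export
depthProfile <- function(ratioVolume, depthWindow = c(80, 200)) {
  stopifnot(is(ratioVolume, "RatioVolume"))
  z <- zPositions(ratioVolume)
  if (depthWindow[1] > max(z) || depthWindow[2] < min(z))
    stop("depth window [", depthWindow[1], ", ", depthWindow[2],
         "] um lies outside the stack z-range ", min(z), "-", max(z), " um")
  keep <- which(z >= depthWindow[1] & z <= depthWindow[2])
  if (!length(keep)) stop("no sections inside the depth window")
  r <- ratios(ratioVolume); m <- foregroundOf(ratioVolume)
  stats <- vapply(keep, function(i) {
    v <- r[, , i][m[, , i]]
    if (!length(v)) return(c(NA_real_, NA_real_, NA_real_, NA_real_, 0))
    c(mean(v), min(v), max(v), if (length(v) > 1) sd(v) else 0, length(v))
  }, numeric(5))
  ok <- stats[5, ] > 0
  if (!any(ok))
    stop("every section inside the depth window has an empty mask")
  new("DepthProfile", z = z[keep], meanRatio = stats[1, ],
      minRatio = stats[2, ], maxRatio = stats[3, ], sdRatio = stats[4, ],
      nVoxels = as.integer(stats[5, ]), probeId = probeId(ratioVolume),
      sampleId = sampleId(ratioVolume))
}

#' Consistency between a depth profile and the whole-sample mean
#'
#' The voxel-count-weighted mean of per-section mean ratios must equal the
#' whole-sample mean ratio (an algebraic identity when both were computed
#' over the same depth window); disagreement beyond the tolerance is an
#' internal-consistency error.
#'
#' @param profile a \linkS4class{DepthProfile}.
#' @param sampleSummary one-row data.frame from
#'   \code{\link{sampleMeanRatio}} for the same sample.
#' @param tol relative tolerance.
#' @return invisibly, a list with the weighted mean, the sample mean and
#'   their relative error.
#' @export
profileConsistency <- function(profile, sampleSummary, tol = 1e-9) {
  stopifnot(is(profile, "DepthProfile"))
  if (!identical(sampleSummary$sample_id, sampleId(profile)) &&
      !(is.na(sampleSummary$sample_id) && is.na(sampleId(profile))))
    stop("profile and summary refer to different samples")
  ok <- profile@nVoxels > 0L
  w <- profile@nVoxels[ok]
  weighted <- sum(w * profile@meanRatio[ok]) / sum(w)
  target <- sampleSummary$mean_ratio
  relErr <- abs(weighted - target) / abs(target)
  if (!is.finite(relErr) || relErr > tol)
    stop(sprintf(
      "internal-consistency error: weighted section mean %.12f vs sample mean %.12f (rel. err %.3g > %.3g)",
      weighted, target, relErr, tol))
  invisible(list(weighted_mean = weighted, sample_mean = target,
                 rel_error = relErr))
}

#' Depth-profile line plot
#'
#' Mean ratio versus depth with min/max error bars, Fig-8 style.
#'
#' @param profile a \linkS4class{DepthProfile}.
#' @return a ggplot object.
#' @export
plotDepthProfile <- function(profile) {
  df <- as.data.frame(profile)
  df <- df[df$n_voxels > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z_um, y = .data$mean_ratio)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$min_ratio,
                                        ymax = .data$max_ratio),
                           width = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::labs(x = "Depth (µm)", y = "Ch2/Ch1 ratio",
                  title = sprintf("%s — %s", df$probe_id[1],
                                  df$sample_id[1])) +
    ggplot2::theme_classic()
}
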