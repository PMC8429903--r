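#' Endpoint ratio of a lysate time course
#'
#' The per-sample readout of the lysate assay: the Ch2/Ch1 ratio at
#' t = 120 min (the endpoint, not a window mean — each sample contributes
#' a single relative ratio).
#'
#' @param series a \linkS4class{LysateTimeSeries}.
#' @return the ratio at 120 min.
#' @export
endpointRatio <- function(series) {
  stopifnot(is(series, "LysateTimeSeries"))
  i <- which(timePoints(series) == 120)
  if (!length(i))
    stop("series '", sampleId(series),
         "' is missing the final 120 min time point")
  ratios(series)[i]
}

#' Fit first-order conversion kinetics to a lysate time course
#'
#' Nonlinear least squares on R(t) = Rinf - (Rinf - R0) exp(-k t) with
#' k bounded at zero.  Initialization: R0 from the first point, Rinf from
#' the last, k from a log-linearized two-point estimate at mid-course.
#' Non-convergence is reported (\code{converged = FALSE} plus message),
#' never thrown.
#'
#' @param series a \linkS4class{LysateTimeSeries} with at least 4 points.
#' @return list with R0, Rinf, k, rss, converged, message.
#' @export
#' @examples
#' p <- LysateAssayParams(k = 0.05, R0 = 0.5, Rinf = 1.8, noiseSd = 0)
#' fitFirstOrder(simulateLysateSeries(p))
fitFirstOrder <- function(series) {
  stopifnot(is(series, "LysateTimeSeries"))
  t <- timePoints(series); y <- ratios(series)
  if (length(t) < 4L) stop("need at least 4 time points to fit")
  if (sd(y) < 1e-12)
    return(list(R0 = y[1], Rinf = y[1], k = 0, rss = 0,
                converged = TRUE, message = "flat series"))
  r0 <- y[1]; rinf <- y[length(y)]
  tm <- t[ceiling(length(t) / 2)]
  ym <- y[ceiling(length(t) / 2)]
  frac <- (rinf - ym) / (rinf - r0 + 1e-12)
  k0 <- if (is.finite(frac) && frac > 1e-6 && frac < 1 && tm > 0)
    -log(frac) / tm else 0.02
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ Rinf - (Rinf - R0) * exp(-k * t),
                      start = list(R0 = r0, Rinf = rinf, k = k0),
                      lower = c(R0 = 0, Rinf = 0, k = 0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(list(R0 = NA_real_, Rinf = NA_real_, k = NA_real_,
                rss = NA_real_, converged = FALSE,
                message = conditionMessage(fit)))
  cf <- coef(fit)
  list(R0 = unname(cf["R0"]), Rinf = unname(cf["Rinf"]),
       k = unname(cf["k"]), rss = sum(resid(fit)^2), converged = TRUE,
       message = "converged")
}

#' Kinetics fit table for a list of lysate series
#'
#' @param seriesList list of \linkS4class{LysateTimeSeries}.
#' @return data.frame: sample_id, probe_id, tissue_class, R0, Rinf, k,
#'   rss, converged.
#' @export
fitLysateCohort <- function(seriesList) {
  rows <- lapply(seriesList, function(s) {
    f <- fitFirstOrder(s)
    data.frame(sample_id = sampleId(s), probe_id = probeId(s),
               tissue_class = tissueClass(s), R0 = f$R0, Rinf = f$Rinf,
               k = f$k, rss = f$rss, converged = f$converged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Endpoint table for a list of lysate series
#'
#' @param seriesList list of \linkS4class{LysateTimeSeries}.
#' @return data.frame: sample_id, probe_id, tissue_class, endpoint_ratio.
#' @export
lysateEndpoints <- function(seriesList) {
  rows <- lapply(seriesList, function(s)
    data.frame(sample_id = sampleId(s), probe_id = probeId(s),
               tissue_class = tissueClass(s),
               endpoint_ratio = endpointRatio(s),
               stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Compare lysate endpoint ratios between two tissue classes
#'
#' Delegates to \code{\link{compareGroups}} on the endpoint ratios.
#'
#' @param endpoints data.frame from \code{\link{lysateEndpoints}}.
#' @param classA,classB tissue classes; the fold change is
#'   mean(classB) / mean(classA).
#' @param ... passed on to \code{\link{compareGroups}}.
#' @return one-row comparison data.frame.
#' @export
compareLysateGroups <- function(endpoints, classA, classB, ...) {
  compareGroups(endpoints, probe = NULL, classA, classB,
                valueColumn = "endpoint_ratio", ...)
}
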