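#' Default run configuration
#'
#' A flat, fully serializable (YAML) list driving the end-to-end pipeline.
#' Every run writes its resolved configuration next to its outputs, so any
#' artifact is reproducible from that file alone.
#'
#' @param outdir output directory.
#' @param probes probe panel.
#' @param counts named per-class sample counts.
#' @param seed master seed.
#' @param imageSize,pixelSize,nSections,depthWindow,attenuationLength,photonBudget,readNoiseSd
#'   acquisition settings (see \code{\link{AcquisitionParams}}).
#' @param textureSd within-sample texture SD.
#' @param maskMethod \code{"otsu"} or \code{"percentile"}.
#' @param maskPercentile percentile for the percentile method.
#' @param alpha significance level.
#' @param testGate \code{"shapiro"}, \code{"t"} or \code{"wilcoxon"}.
#' @param adjust \code{"none"} or \code{"bonferroni"}.
#' @param lysateK,lysateR0,lysateNoiseSd lysate generator settings.
#' @param writeRenders logical; write pseudocolor PNGs during analysis.
#' @return named list (class \code{"tpmRunConfig"}).
#' @export
runConfig <- function(outdir = "tpm_run", probes = c("SG1", "SE1", "SHC"),
                      counts = cohortCounts(), seed = 1L,
                      imageSize = 64L, pixelSize = 2, nSections = 30L,
                      depthWindow = c(80, 200), attenuationLength = 150,
                      photonBudget = 500, readNoiseSd = 1,
                      textureSd = 0.05, maskMethod = "otsu",
                      maskPercentile = 50, alpha = 0.05,
                      testGate = "shapiro", adjust = "none",
                      lysateK = 0.03, lysateR0 = 0.5,
                      lysateNoiseSd = 0.02, writeRenders = FALSE) {
  cfg <- list(outdir = outdir, probes = probes,
              counts = as.list(counts), seed = as.integer(seed),
              imageSize = as.integer(imageSize), pixelSize = pixelSize,
              nSections = as.integer(nSections),
              depthWindow = as.numeric(depthWindow),
              attenuationLength = attenuationLength,
              photonBudget = photonBudget, readNoiseSd = readNoiseSd,
              textureSd = textureSd, maskMethod = maskMethod,
              maskPercentile = maskPercentile, alpha = alpha,
              testGate = testGate, adjust = adjust, lysateK = lysateK,
              lysateR0 = lysateR0, lysateNoiseSd = lysateNoiseSd,
              writeRenders = writeRenders)
  class(cfg) <- c("tpmRunConfig", "list")
  cfg
}

#' Read / write a run configuration (YAML)
#' @param path YAML file path.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  cfg <- runConfig()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(raw)] <- raw
  cfg$counts <- lapply(cfg$counts, as.integer)
  class(cfg) <- c("tpmRunConfig", "list")
  cfg
}

#' @rdname readRunConfig
#' @param config a run configuration list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.cfgAcquisition <- function(config) {
  AcquisitionParams(
    imageSize = config$imageSize, pixelSize = config$pixelSize,
    zPositions = seq(config$depthWindow[1], config$depthWindow[2],
                     length.out = config$nSections),
    depthWindow = config$depthWindow,
    attenuationLength = config$attenuationLength,
    photonBudget = config$photonBudget,
    readNoiseSd = config$readNoiseSd)
}

.stageLog <- function(stage, t0) {
  message(sprintf("[%s] %s finished in %.1f s",
                  format(Sys.time(), "%H:%M:%S"), stage,
                  as.numeric(Sys.time()) - t0))
}

#' Simulate a cohort to disk
#'
#' Writes one TIFF + sidecar per sample per probe, the cohort manifest and
#' the resolved configuration under \code{config$outdir}.
#'
#' @param config a run configuration from \code{\link{runConfig}}.
#' @return the manifest data.frame, invisibly.
#' @export
runSimulate <- function(config) {
  t0 <- as.numeric(Sys.time())
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  writeRunConfig(config, file.path(config$outdir, "config_resolved.yaml"))
  design <- CohortDesign(counts = unlist(config$counts),
                         probes = config$probes,
                         acquisition = .cfgAcquisition(config),
                         masterSeed = config$seed,
                         textureSd = config$textureSd)
  res <- simulateCohort(design, dir = file.path(config$outdir, "stacks"))
  writeManifest(res$manifest, file.path(config$outdir, "manifest.csv"))
  .stageLog("simulate", t0)
  invisible(res$manifest)
}

#' Analyze a simulated (or provided) cohort
#'
#' For every manifest entry: read the stack, compute the foreground mask,
#' the ratio volume, the whole-depth sample mean and the depth profile
#' (asserting the profile/sample-mean aggregation identity on every
#' sample).  Writes \code{summaries.csv} and \code{profiles.csv}; with
#' \code{writeRenders} also pseudocolor PNGs.
#'
#' @param config a run configuration.
#' @return list with \code{summaries} and \code{profiles} data.frames.
#' @export
runAnalyze <- function(config) {
  t0 <- as.numeric(Sys.time())
  manifest <- readManifest(file.path(config$outdir, "manifest.csv"))
  sums <- list(); profs <- list()
  for (i in seq_len(nrow(manifest))) {
    st <- readStack(manifest$tiff_path[i])
    mask <- foregroundMask(st, method = config$maskMethod,
                           p = config$maskPercentile)
    rv <- ratioMap(st, mask)
    sm <- sampleMeanRatio(rv, depthWindow = config$depthWindow)
    prof <- depthProfile(rv, depthWindow = config$depthWindow)
    profileConsistency(prof, sm)
    sums[[i]] <- sm
    profs[[i]] <- as.data.frame(prof)
    if (isTRUE(config$writeRenders))
      writePseudocolorPNG(pseudocolor(rv, st),
                          file.path(config$outdir, "renders"),
                          sampleId(st))
  }
  summaries <- do.call(rbind, c(sums, list(make.row.names = FALSE)))
  profiles <- do.call(rbind, c(profs, list(make.row.names = FALSE)))
  writeSummary(summaries, file.path(config$outdir, "summaries.csv"))
  writeSummary(profiles, file.path(config$outdir, "profiles.csv"))
  .stageLog("analyze", t0)
  list(summaries = summaries, profiles = profiles)
}

#' Group comparisons and box plots
#'
#' All pairwise class comparisons per probe (6 rows per probe) on the
#' analyzed summaries, written to \code{comparisons.csv}, plus one box
#' plot per probe.
#'
#' @param config a run configuration.
#' @return the comparison data.frame.
#' @export
runCompare <- function(config) {
  t0 <- as.numeric(Sys.time())
  summaries <- read.csv(file.path(config$outdir, "summaries.csv"),
                        stringsAsFactors = FALSE)
  comp <- compareAllGroups(summaries, alpha = config$alpha,
                           gate = config$testGate, adjust = config$adjust)
  writeSummary(comp, file.path(config$outdir, "comparisons.csv"))
  for (probe in unique(summaries$probe_id)) {
    gp <- plotGroupBoxes(summaries[summaries$probe_id == probe, ])
    ggplot2::ggsave(file.path(config$outdir,
                              sprintf("boxplot_%s.png", probe)),
                    gp, width = 4, height = 4, dpi = 150)
  }
  .stageLog("compare", t0)
  comp
}

#' Lysate arm: simulate, fit kinetics, compare endpoints
#'
#' Simulates calibrated lysate cohorts for every probe and class at the
#' configured counts, writes the endpoint and kinetics-fit tables and the
#' cancer-vs-normal comparisons.
#'
#' @param config a run configuration.
#' @return list with \code{endpoints}, \code{fits} and \code{comparisons}.
#' @export
runLysate <- function(config) {
  t0 <- as.numeric(Sys.time())
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  allSeries <- list()
  for (probe in config$probes)
    for (cls in names(config$counts)) {
      sim <- simulateLysateCohort(probe, cls, config$counts[[cls]],
                                  masterSeed = config$seed,
                                  k = config$lysateK,
                                  R0 = config$lysateR0,
                                  noiseSd = config$lysateNoiseSd)
      allSeries <- c(allSeries, sim$series)
    }
  endpoints <- lysateEndpoints(allSeries)
  fits <- fitLysateCohort(allSeries)
  comps <- do.call(rbind, lapply(config$probes, function(probe) {
    ep <- endpoints[endpoints$probe_id == probe, ]
    compareLysateGroups(ep, "normal", "cancer", alpha = config$alpha,
                        gate = config$testGate)
  }))
  writeSummary(endpoints, file.path(config$outdir,
                                    "lysate_endpoints.csv"))
  writeSummary(fits, file.path(config$outdir, "lysate_fits.csv"))
  writeSummary(comps, file.path(config$outdir, "lysate_comparisons.csv"))
  .stageLog("lysate", t0)
  list(endpoints = endpoints, fits = fits, comparisons = comps)
}

#' Write a markdown run report
#'
#' Mutual-verification layout: imaging group statistics, lysate endpoint
#' statistics and the simulation truth side by side.
#'
#' @param config a run configuration.
#' @return path of the written report, invisibly.
#' @export
runReport <- function(config) {
  t0 <- as.numeric(Sys.time())
  path <- file.path(config$outdir, "report.md")
  lines <- c("# Ratiometric two-photon pipeline report", "")
  compPath <- file.path(config$outdir, "comparisons.csv")
  if (file.exists(compPath)) {
    comp <- read.csv(compPath, stringsAsFactors = FALSE)
    lines <- c(lines, "## Imaging group comparisons", "",
               .mdTable(comp[, c("probe_id", "group_a", "group_b",
                                 "mean_a", "mean_b", "test_used",
                                 "p_value", "fold_change")]), "")
  }
  lysPath <- file.path(config$outdir, "lysate_comparisons.csv")
  if (file.exists(lysPath)) {
    lys <- read.csv(lysPath, stringsAsFactors = FALSE)
    lines <- c(lines, "## Lysate endpoint comparisons", "",
               .mdTable(lys[, c("probe_id", "group_a", "group_b",
                                "mean_a", "mean_b", "test_used",
                                "p_value", "fold_change")]), "")
  }
  manPath <- file.path(config$outdir, "manifest.csv")
  if (file.exists(manPath)) {
    man <- readManifest(manPath)
    agg <- stats::aggregate(true_mean_ratio ~ probe_id + tissue_class,
                            man, mean)
    lines <- c(lines, "## Simulation truth (mean of drawn sample means)",
               "", .mdTable(agg), "")
  }
  writeLines(lines, path)
  .stageLog("report", t0)
  invisible(path)
}

.mdTable <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 4))
  header <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  body <- apply(df, 1, function(r)
    paste("|", paste(r, collapse = " | "), "|"))
  c(header, sep, body)
}
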