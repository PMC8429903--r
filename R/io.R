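#' Write a two-channel stack as multi-page TIFF plus JSON sidecar
#'
#' Page order is z-major, channel-minor (z1/Ch1, z1/Ch2, z2/Ch1, ...),
#' 16-bit unsigned, no compression.  The sidecar records probe, sample id,
#' tissue class, pixel size, z positions, emission bands and the seed.
#' Counts must be integral and within 0..65535; anything else is an error
#' rather than a silent rounding.
#'
#' @param stack a \linkS4class{TwoChannelStack}.
#' @param tiffPath output TIFF path.
#' @param sidecarPath output JSON path; default replaces the extension with
#'   \code{.json}.
#' @param seed seed recorded in the sidecar (NA when unknown).
#' @return invisibly, \code{tiffPath}.
#' @export
writeStack <- function(stack, tiffPath, sidecarPath = NULL, seed = NA) {
  stopifnot(is(stack, "TwoChannelStack"))
  validObject(stack)
  if (is.null(sidecarPath)) sidecarPath <- .sidecarPath(tiffPath)
  ch1 <- channel1(stack); ch2 <- channel2(stack)
  vals <- c(ch1, ch2)
  if (max(vals) > .BIT_MAX || any(abs(vals - round(vals)) > 1e-6))
    stop("stack intensities must be integral counts within 0..", .BIT_MAX)
  nz <- dim(ch1)[3]
  pages <- vector("list", 2L * nz)
  for (z in seq_len(nz)) {
    pages[[2L * z - 1L]] <- round(ch1[, , z]) / .BIT_MAX
    pages[[2L * z]] <- round(ch2[, , z]) / .BIT_MAX
  }
  tiff::writeTIFF(pages, tiffPath, bits.per.sample = 16L,
                  compression = "none", reduce = FALSE)
  meta <- list(probe = probeId(stack), sample_id = sampleId(stack),
               tissue_class = tissueClass(stack),
               pixel_size_um = pixelSize(stack),
               z_positions_um = zPositions(stack),
               channel_bands_nm = list(
                 Ch1 = as.numeric(stack@bands[1, ]),
                 Ch2 = as.numeric(stack@bands[2, ])),
               seed = seed)
  jsonlite::write_json(meta, sidecarPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(tiffPath)
}

.sidecarPath <- function(tiffPath) sub("\\.tiff?$", ".json", tiffPath)

#' Read a two-channel stack written by \code{\link{writeStack}}
#'
#' Round-trips bit-exactly.  Missing sidecar fields, a page count that does
#' not equal twice the number of z positions, or non-monotone z positions
#' all fail loudly — a silent channel swap would invert the diagnostic
#' direction of every probe.
#'
#' @param tiffPath path to the multi-page TIFF.
#' @param sidecarPath path to the JSON sidecar; default derived from
#'   \code{tiffPath}.
#' @return a \linkS4class{TwoChannelStack}.
#' @export
readStack <- function(tiffPath, sidecarPath = NULL) {
  if (is.null(sidecarPath)) sidecarPath <- .sidecarPath(tiffPath)
  if (!file.exists(tiffPath)) stop("TIFF not found: ", tiffPath)
  if (!file.exists(sidecarPath)) stop("sidecar not found: ", sidecarPath)
  meta <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
  required <- c("probe", "pixel_size_um", "z_positions_um",
                "channel_bands_nm")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("sidecar ", sidecarPath, " is missing required field(s): ",
         paste(missing, collapse = ", "))
  z <- as.numeric(meta$z_positions_um)
  if (any(diff(z) <= 0))
    stop("sidecar z positions must be strictly increasing")
  pages <- tiff::readTIFF(tiffPath, all = TRUE, as.is = TRUE)
  if (length(pages) != 2L * length(z))
    stop("page count ", length(pages), " does not match 2 x ",
         length(z), " z positions in ", sidecarPath)
  nx <- nrow(pages[[1]]); ny <- ncol(pages[[1]])
  ch1 <- array(0, c(nx, ny, length(z)))
  ch2 <- array(0, c(nx, ny, length(z)))
  for (i in seq_along(z)) {
    ch1[, , i] <- pages[[2L * i - 1L]]
    ch2[, , i] <- pages[[2L * i]]
  }
  bands <- defaultBands()
  bands[1, ] <- as.numeric(meta$channel_bands_nm$Ch1)
  bands[2, ] <- as.numeric(meta$channel_bands_nm$Ch2)
  new("TwoChannelStack", ch1 = ch1, ch2 = ch2, zPositions = z,
      pixelSize = as.numeric(meta$pixel_size_um), bands = bands,
      probeId = as.character(meta$probe),
      sampleId = if (is.null(meta$sample_id)) NA_character_ else
        as.character(meta$sample_id),
      tissueClass = if (is.null(meta$tissue_class) ||
                        is.na(meta$tissue_class)) NA_character_ else
        as.character(meta$tissue_class))
}

.MANIFEST_COLS <- c("sample_id", "tissue_class", "probe_id", "seed",
                    "true_mean_ratio", "tiff_path")

#' Read a cohort manifest CSV
#'
#' Required columns: sample_id, tissue_class, probe_id, seed,
#' true_mean_ratio, tiff_path.  Unknown columns are preserved.  An empty
#' (header-only) manifest is a valid empty cohort; duplicated sample ids
#' are an error.
#'
#' @param csvPath path to the manifest.
#' @return data.frame.
#' @export
readManifest <- function(csvPath) {
  if (!file.exists(csvPath)) stop("manifest not found: ", csvPath)
  df <- read.csv(csvPath, stringsAsFactors = FALSE)
  missing <- setdiff(.MANIFEST_COLS, names(df))
  if (length(missing))
    stop("manifest ", csvPath, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("manifest contains duplicated sample_id values")
  df
}

#' Write a cohort manifest CSV
#' @param manifest data.frame with the manifest schema.
#' @param csvPath output path.
#' @export
writeManifest <- function(manifest, csvPath) {
  missing <- setdiff(.MANIFEST_COLS, names(manifest))
  if (length(missing))
    stop("manifest is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(manifest$sample_id))
    stop("manifest contains duplicated sample_id values")
  writeSummary(manifest, csvPath)
}

#' Write a result table as CSV
#'
#' Plain UTF-8 CSV with a header row and "." as the decimal mark;
#' deterministic byte-for-byte for identical input.
#'
#' @param table data.frame.
#' @param csvPath output path.
#' @return invisibly, \code{csvPath}.
#' @export
writeSummary <- function(table, csvPath) {
  stopifnot(is.data.frame(table))
  write.csv(table, csvPath, row.names = FALSE, quote = TRUE, na = "NA",
            fileEncoding = "UTF-8")
  invisible(csvPath)
}

#' Write a lysate time series CSV (columns time_min, ratio)
#' @param series a \linkS4class{LysateTimeSeries}.
#' @param csvPath output path.
#' @export
writeLysateSeries <- function(series, csvPath) {
  stopifnot(is(series, "LysateTimeSeries"))
  writeSummary(as.data.frame(series), csvPath)
}

#' Read a lysate time series CSV
#' @param csvPath path to a CSV with columns time_min and ratio.
#' @param sampleId,probeId,tissueClass provenance to attach.
#' @param probeConcentration,proteinAmount assay metadata.
#' @return a \linkS4class{LysateTimeSeries}.
#' @export
readLysateSeries <- function(csvPath, sampleId = NA_character_,
                             probeId = NA_character_,
                             tissueClass = NA_character_,
                             probeConcentration = 1, proteinAmount = 200) {
  df <- read.csv(csvPath, stringsAsFactors = FALSE)
  missing <- setdiff(c("time_min", "ratio"), names(df))
  if (length(missing))
    stop("lysate CSV ", csvPath, " is missing column(s): ",
         paste(missing, collapse = ", "))
  new("LysateTimeSeries", timeMin = as.numeric(df$time_min),
      ratio = as.numeric(df$ratio), sampleId = sampleId, probeId = probeId,
      tissueClass = tissueClass, probeConcentration = probeConcentration,
      proteinAmount = proteinAmount)
}
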