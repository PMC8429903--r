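# Small in-code fixtures shared across the suite.

# Compact acquisition grid for fast tests: 16 x 16 px, 6 sections spanning
# the 80-200 um analysis window.
smallAcq <- function(nSections = 6L, imageSize = 16L)
  AcquisitionParams(imageSize = imageSize,
                    zPositions = seq(80, 200, length.out = nSections))

# Stack built directly from channel arrays (bypasses the simulator).
stackFromChannels <- function(ch1, ch2, z = NULL, probe = "SG1",
                              sampleId = "fix", tissueClass = NA_character_) {
  if (is.matrix(ch1)) { ch1 <- array(ch1, c(dim(ch1), 1)); ch2 <- array(ch2, c(dim(ch2), 1)) }
  if (is.null(z)) z <- seq(80, 200, length.out = dim(ch1)[3])
  new("TwoChannelStack", ch1 = ch1, ch2 = ch2, zPositions = z,
      pixelSize = 2, bands = defaultBands(), probeId = probe,
      sampleId = sampleId, tissueClass = tissueClass)
}

# Stack with a uniform true ratio r and uniform brightness B, noise-free.
uniformStack <- function(r, B = 1000, dims = c(4, 4, 3)) {
  ch1 <- array(B / (1 + r), dims)
  ch2 <- array(B * r / (1 + r), dims)
  stackFromChannels(ch1, ch2)
}

# Independent brute-force oracle: per-voxel loop computing ratio map and
# masked mean, no vectorization shared with the implementation.
bruteForceRatio <- function(ch1, ch2, mask) {
  d <- dim(ch1)
  out <- array(NA_real_, d)
  vals <- c()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    if (mask[i, j, k]) {
      out[i, j, k] <- ch2[i, j, k] / ch1[i, j, k]
      vals <- c(vals, out[i, j, k])
    }
  list(map = out, mean = mean(vals))
}

# Independent exact rank-sum oracle: enumerate all group assignments and
# compute the two-sided p for the observed rank sum.
bruteForceRankSumP <- function(x, y) {
  n <- length(x) + length(y)
  rk <- rank(c(x, y))
  wObs <- sum(rk[seq_along(x)])
  combs <- combn(n, length(x))
  ws <- apply(combs, 2, function(idx) sum(rk[idx]))
  min(1, 2 * min(mean(ws <= wObs + 1e-9), mean(ws >= wObs - 1e-9)))
}
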