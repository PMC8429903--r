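#' @keywords internal
"_PACKAGE"

#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats rnorm rpois quantile sd shapiro.test t.test wilcox.test
#'   median coef resid p.adjust
#' @importFrom utils read.csv write.csv combn
#' @importFrom ggplot2 .data
NULL

.TISSUE_CLASSES <- c("normal", "ulcer", "adenoma", "cancer")
.PROBES <- c(SG1 = "beta-galactosidase", SE1 = "carboxylesterase",
             SHC = "hNQO1")
.BIT_MAX <- 65535

## Evaluate `code` under a fixed RNG seed without disturbing the caller's
## RNG stream.
.withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed %% 2147483647L))
  code
}

## Deterministic sub-seed from a master seed and a string key (probe, class,
## replicate index, stage).  Kept strictly below 2^31 - 1.
.deriveSeed <- function(master, ...) {
  key <- paste(c(...), collapse = "/")
  b <- utf8ToInt(key)
  h <- sum(b * seq_along(b)) %% 104729
  as.integer((as.numeric(master) %% 20000 * 104729 + h * 2654435 +
                as.numeric(master)) %% 2147483647)
}

## Normal draws truncated to (lower, Inf) by rejection.
.rtruncnorm <- function(n, mean, sd, lower = 0) {
  if (sd < 0) stop("standard deviation must be non-negative")
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw > lower
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

## Row-normalized Gaussian smoothing matrix for a 1-D grid of size n.
.smoothMat <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  d <- outer(seq_len(n), seq_len(n), "-")
  k <- exp(-0.5 * (d / sigma)^2)
  k / rowSums(k)
}

## Smooth standard-normal random field: white noise smoothed in x, y and z,
## restandardized to mean 0 / sd 1 over the volume.
.smoothField <- function(dims, sigmaXY = 4, sigmaZ = 1.5) {
  a <- array(rnorm(prod(dims)), dim = dims)
  kx <- .smoothMat(dims[1], sigmaXY)
  ky <- .smoothMat(dims[2], sigmaXY)
  for (z in seq_len(dims[3]))
    a[, , z] <- kx %*% a[, , z] %*% t(ky)
  if (dims[3] > 1) {
    kz <- .smoothMat(dims[3], sigmaZ)
    m <- matrix(a, ncol = dims[3])
    a <- array(m %*% t(kz), dim = dims)
  }
  (a - mean(a)) / sd(a)
}

.assertScalarNumber <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(name, " must be a single finite number")
  if (positive && x <= 0)
    stop(name, " must be strictly positive")
  invisible(x)
}
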