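## Exact two-sided rank-sum p-value by full enumeration of group
## assignments, with average ranks for ties.  Used when ties prevent
## stats::wilcox.test from being exact and the groups are small enough to
## enumerate; stats::wilcox.test handles everything else.
.exactRankSumP <- function(x, y, maxComb = 5e5) {
  nx <- length(x); n <- nx + length(y)
  if (choose(n, nx) > maxComb) return(NA_real_)
  rk <- rank(c(x, y))
  wObs <- sum(rk[seq_len(nx)])
  idx <- combn(n, nx)
  ws <- colSums(matrix(rk[idx], nrow = nx))
  eps <- 1e-9
  pLo <- mean(ws <= wObs + eps)
  pHi <- mean(ws >= wObs - eps)
  min(1, 2 * min(pLo, pHi))
}

.rankSumTest <- function(a, b) {
  n <- length(a) + length(b)
  ties <- anyDuplicated(c(a, b)) > 0
  if (ties && n <= 20) {
    p <- .exactRankSumP(a, b)
    if (!is.na(p)) {
      w <- sum(rank(c(a, b))[seq_along(a)]) -
        length(a) * (length(a) + 1) / 2
      return(list(statistic = w, p.value = p, exact = TRUE))
    }
  }
  wt <- suppressWarnings(wilcox.test(a, b, exact = !ties,
                                     correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       exact = !ties && n < 50)
}

.isNormalish <- function(v, alpha) {
  if (length(v) < 3L || sd(v) == 0) return(FALSE)
  shapiro.test(v)$p.value >= alpha
}

#' Two-group comparison of sample mean ratios
#'
#' Test choice follows the "t-test or rank-sum, as appropriate"
#' convention, resolved with a Shapiro–Wilk gate: if both groups look
#' normal at \code{gateAlpha} a Welch (unequal-variance) two-sample t-test
#' is used, otherwise a Wilcoxon rank-sum test — exact for small samples,
#' including tie-aware enumeration for total n of at most 20.  All p-values
#' are two-sided.
#'
#' @param summaries data.frame with columns \code{tissue_class},
#'   \code{probe_id} and the value column.
#' @param probe probe id to subset on (ignored when \code{summaries} has a
#'   single probe and \code{probe} is NULL).
#' @param classA,classB tissue classes to compare; the fold change is
#'   mean(classB) / mean(classA).
#' @param alpha significance level.
#' @param gate \code{"shapiro"} (default), \code{"t"} to force Welch, or
#'   \code{"wilcoxon"} to force the rank-sum test.
#' @param gateAlpha Shapiro–Wilk level for the normality gate.
#' @param valueColumn column holding the per-sample values.
#' @return one-row data.frame: probe_id, group_a, group_b, n_a, n_b,
#'   mean_a, sd_a, mean_b, sd_b, test_used, statistic, p_value,
#'   fold_change, significant, alpha.
#' @export
#' @examples
#' s <- simulateCohortSummaries("SG1", seed = 7)
#' compareGroups(s, "SG1", "normal", "cancer")
compareGroups <- function(summaries, probe = NULL, classA, classB,
                          alpha = 0.05, gate = c("shapiro", "t",
                                                 "wilcoxon"),
                          gateAlpha = 0.05, valueColumn = "mean_ratio") {
  gate <- match.arg(gate)
  if (!valueColumn %in% names(summaries))
    stop("summaries lack a '", valueColumn, "' column")
  if (!is.null(probe))
    summaries <- summaries[summaries$probe_id == probe, , drop = FALSE]
  a <- summaries[[valueColumn]][summaries$tissue_class == classA]
  b <- summaries[[valueColumn]][summaries$tissue_class == classB]
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 samples per group (", classA, ": ", length(a),
         ", ", classB, ": ", length(b), ")")
  useT <- switch(gate,
    t = TRUE, wilcoxon = FALSE,
    shapiro = .isNormalish(a, gateAlpha) && .isNormalish(b, gateAlpha))
  if (useT) {
    tt <- t.test(a, b, var.equal = FALSE)
    testUsed <- "t-test"; statistic <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    rs <- .rankSumTest(a, b)
    testUsed <- "wilcoxon"; statistic <- rs$statistic
    p <- rs$p.value
  }
  data.frame(probe_id = if (is.null(probe)) summaries$probe_id[1] else
               probe,
             group_a = classA, group_b = classB,
             n_a = length(a), n_b = length(b),
             mean_a = mean(a), sd_a = sd(a),
             mean_b = mean(b), sd_b = sd(b),
             test_used = testUsed, statistic = statistic, p_value = p,
             fold_change = foldChange(mean(a), mean(b)),
             significant = p < alpha, alpha = alpha,
             stringsAsFactors = FALSE)
}

#' All pairwise class comparisons for each probe
#'
#' Six class pairs per probe (4 classes choose 2).  Unadjusted p-values by
#' default, matching the single-comparison convention; Bonferroni
#' adjustment across the grid is available but off by default.
#'
#' @inheritParams compareGroups
#' @param adjust \code{"none"} (default) or \code{"bonferroni"}.
#' @return data.frame, one row per probe and class pair.
#' @export
compareAllGroups <- function(summaries, alpha = 0.05,
                             gate = "shapiro", gateAlpha = 0.05,
                             valueColumn = "mean_ratio",
                             adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  probes <- unique(summaries$probe_id)
  classes <- intersect(.TISSUE_CLASSES, unique(summaries$tissue_class))
  pairs <- combn(classes, 2L)
  rows <- list()
  for (probe in probes) {
    for (j in seq_len(ncol(pairs))) {
      rows[[length(rows) + 1L]] <- compareGroups(
        summaries, probe, pairs[1, j], pairs[2, j], alpha = alpha,
        gate = gate, gateAlpha = gateAlpha, valueColumn = valueColumn)
    }
  }
  out <- do.call(rbind, rows)
  if (adjust == "bonferroni") {
    out$p_value <- p.adjust(out$p_value, method = "bonferroni")
    out$significant <- out$p_value < out$alpha
  }
  out
}

#' Fold change between group means
#'
#' @param meanA,meanB strictly positive group means; the result is
#'   \code{meanB / meanA}.
#' @param digits optional rounding of the reported value.
#' @return dimensionless fold change.
#' @export
#' @examples
#' foldChange(0.656, 1.127, digits = 2)  # 1.72
foldChange <- function(meanA, meanB, digits = NULL) {
  .assertScalarNumber(meanA, "meanA", positive = TRUE)
  .assertScalarNumber(meanB, "meanB", positive = TRUE)
  fc <- meanB / meanA
  if (!is.null(digits)) fc <- round(fc, digits)
  fc
}

#' Fit a single-threshold diagnostic rule
#'
#' Scans candidate thresholds (midpoints between consecutive sorted sample
#' means) and picks the one maximizing Youden's J
#' (sensitivity + specificity - 1).  The calling direction comes from the
#' probe calibration: above-threshold calls cancer for SG1, below-threshold
#' for SE1.  Ties at the threshold are called non-cancer (conservative),
#' so "above" means strictly greater.  Among equal-J candidates the one
#' with the widest margin between the groups (largest gap) is preferred,
#' then the smallest.
#'
#' @param summaries labeled per-sample summaries.
#' @param probe probe id.
#' @param positiveClass class treated as positive (default cancer).
#' @param calibrations calibrations supplying the direction.
#' @param valueColumn column holding the per-sample values.
#' @return a \linkS4class{ClassifierRule}.
#' @export
fitThreshold <- function(summaries, probe, positiveClass = "cancer",
                         calibrations = imagingCalibrations(),
                         valueColumn = "mean_ratio") {
  df <- summaries[summaries$probe_id == probe, , drop = FALSE]
  pos <- df[[valueColumn]][df$tissue_class == positiveClass]
  neg <- df[[valueColumn]][df$tissue_class != positiveClass]
  if (!length(pos) || !length(neg))
    stop("both the positive class and at least one other class are needed")
  direction <- probeDirection(calibrations[[probe]])
  v <- sort(unique(c(pos, neg)))
  cand <- if (length(v) > 1) (v[-1] + v[-length(v)]) / 2 else v
  j <- vapply(cand, function(th) {
    called <- if (direction == "above") c(pos, neg) > th else
      c(pos, neg) < th
    isPos <- c(rep(TRUE, length(pos)), rep(FALSE, length(neg)))
    sens <- sum(called & isPos) / length(pos)
    spec <- sum(!called & !isPos) / length(neg)
    sens + spec - 1
  }, numeric(1))
  best <- which(j >= max(j) - 1e-12)
  if (length(best) > 1L) {
    gap <- vapply(best, function(i) {
      below <- v[v < cand[i]]; above <- v[v > cand[i]]
      if (length(below) && length(above)) min(above) - max(below) else 0
    }, numeric(1))
    best <- best[which.max(gap)]
  }
  new("ClassifierRule", probeId = probe, threshold = cand[best[1]],
      direction = direction, positiveClass = positiveClass)
}

#' Evaluate a threshold rule on labeled summaries
#'
#' @param rule a \linkS4class{ClassifierRule}.
#' @param summaries labeled per-sample summaries (tissue_class must not be
#'   NA).
#' @param valueColumn column holding the per-sample values.
#' @return list with the confusion counts (tp, fp, tn, fn), sensitivity,
#'   specificity and accuracy (NA where the denominator is empty).
#' @export
evaluateClassifier <- function(rule, summaries,
                               valueColumn = "mean_ratio") {
  stopifnot(is(rule, "ClassifierRule"))
  if (!nrow(summaries))
    return(list(tp = 0L, fp = 0L, tn = 0L, fn = 0L,
                sensitivity = NA_real_, specificity = NA_real_,
                accuracy = NA_real_))
  if (any(is.na(summaries$tissue_class)))
    stop("unlabeled sample(s): tissue_class is NA")
  v <- summaries[[valueColumn]]
  called <- if (rule@direction == "above") v > rule@threshold else
    v < rule@threshold
  isPos <- summaries$tissue_class == rule@positiveClass
  tp <- sum(called & isPos); fp <- sum(called & !isPos)
  fn <- sum(!called & isPos); tn <- sum(!called & !isPos)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       accuracy = (tp + tn) / nrow(summaries))
}

#' Box plot of sample mean ratios per tissue class
#'
#' @param summaries per-sample summaries for one probe.
#' @param valueColumn column holding the per-sample values.
#' @return a ggplot object.
#' @export
plotGroupBoxes <- function(summaries, valueColumn = "mean_ratio") {
  df <- summaries
  df$tissue_class <- factor(df$tissue_class, levels = .TISSUE_CLASSES)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tissue_class,
                                   y = .data[[valueColumn]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, size = 1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "Ch2/Ch1 ratio",
                  title = unique(df$probe_id)[1]) +
    ggplot2::theme_classic()
}
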