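mkSummaries <- function(a, b, classA = "normal", classB = "cancer",
                        probe = "SG1") {
  data.frame(sample_id = sprintf("s%02d", seq_len(length(a) + length(b))),
             tissue_class = rep(c(classA, classB),
                                c(length(a), length(b))),
             probe_id = probe, mean_ratio = c(a, b),
             stringsAsFactors = FALSE)
}

test_that("rank-sum p-values match the enumerated exact null", {
  # the textbook separated case: all 252 assignments enumerated
  s <- mkSummaries(1:5, 6:10)
  cmp <- compareGroups(s, "SG1", "normal", "cancer", gate = "wilcoxon")
  expect_equal(cmp$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(round(cmp$p_value, 6), 0.007937)

  # random small instances, no ties: implementation vs brute force
  set.seed(101)
  for (rep in 1:5) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    v <- sample(1:100, na + nb)
    s <- mkSummaries(v[1:na], v[(na + 1):(na + nb)])
    cmp <- compareGroups(s, "SG1", "normal", "cancer", gate = "wilcoxon")
    expect_equal(cmp$p_value,
                 bruteForceRankSumP(v[1:na], v[(na + 1):(na + nb)]),
                 tolerance = 1e-10)
  }

  # with ties the tie-aware exact path still matches enumeration
  set.seed(202)
  for (rep in 1:5) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    v <- sample(1:5, na + nb, replace = TRUE)
    s <- mkSummaries(v[1:na], v[(na + 1):(na + nb)])
    cmp <- compareGroups(s, "SG1", "normal", "cancer", gate = "wilcoxon")
    expect_equal(cmp$p_value,
                 bruteForceRankSumP(v[1:na], v[(na + 1):(na + nb)]),
                 tolerance = 1e-10)
  }
})

test_that("identical groups give p = 1 and fold change 1", {
  s <- mkSummaries(c(1, 2, 3, 4), c(1, 2, 3, 4))
  cmp <- compareGroups(s, "SG1", "normal", "cancer", gate = "wilcoxon")
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$fold_change, 1)
  expect_false(cmp$significant)
})

test_that("Welch t-test matches the textbook closed form", {
  a <- c(0.60, 0.65, 0.70, 0.62, 0.68)
  b <- c(1.05, 1.15, 1.10, 1.20, 1.08)
  s <- mkSummaries(a, b)
  cmp <- compareGroups(s, "SG1", "normal", "cancer", gate = "t")
  se <- sqrt(var(a) / 5 + var(b) / 5)
  tStat <- (mean(a) - mean(b)) / se
  df <- se^4 / ((var(a) / 5)^2 / 4 + (var(b) / 5)^2 / 4)
  expect_equal(cmp$statistic, tStat, tolerance = 1e-12)
  expect_equal(cmp$p_value, 2 * pt(abs(tStat), df, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_identical(cmp$test_used, "t-test")
})

test_that("the Shapiro gate picks the rank-sum test for skewed data", {
  set.seed(11)
  a <- exp(rnorm(15, 0, 1.5))  # heavily skewed
  b <- exp(rnorm(15, 2, 1.5))
  s <- mkSummaries(a, b)
  cmp <- compareGroups(s, "SG1", "normal", "cancer")
  expect_identical(cmp$test_used, "wilcoxon")
  # near-normal draws go to Welch
  set.seed(12)
  s2 <- mkSummaries(rnorm(15, 1, 0.05), rnorm(15, 2, 0.05))
  expect_identical(compareGroups(s2, "SG1", "normal",
                                 "cancer")$test_used, "t-test")
})

test_that("group-size preconditions are enforced", {
  s <- mkSummaries(0.5, c(1, 1.1))
  expect_error(compareGroups(s, "SG1", "normal", "cancer"),
               "at least 2 samples")
})

test_that("fold change arithmetic and reciprocity", {
  expect_equal(foldChange(0.656, 1.127, digits = 2), 1.72)
  expect_equal(foldChange(2, 2), 1)
  expect_equal(foldChange(2, 1), 0.5)
  expect_error(foldChange(0, 1), "positive")
  expect_error(foldChange(1, -2), "positive")
  set.seed(3)
  for (i in 1:5) {
    a <- runif(1, 0.1, 3); b <- runif(1, 0.1, 3)
    expect_equal(foldChange(a, b) * foldChange(b, a), 1,
                 tolerance = 1e-12)
  }
})

test_that("threshold fitting maximizes Youden's J over midpoints", {
  # boundary-pair midpoint for separated groups
  s <- mkSummaries(c(0.5, 0.6), c(1.0, 1.1))
  rule <- fitThreshold(s, "SG1")
  expect_equal(rule@threshold, 0.8)
  expect_identical(rule@direction, "above")
  ev <- evaluateClassifier(rule, s)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)

  # SE1 calls cancer below the threshold
  sSE1 <- mkSummaries(c(0.85, 0.9), c(0.55, 0.6), probe = "SE1")
  ruleSE1 <- fitThreshold(sSE1, "SE1")
  expect_identical(ruleSE1@direction, "below")
  evSE1 <- evaluateClassifier(ruleSE1, sSE1)
  expect_equal(evSE1$sensitivity, 1)
  expect_equal(evSE1$specificity, 1)
})

test_that("classifier evaluation: confusion counts and boundaries", {
  # hand-built 4-sample case with one misclassification
  s <- mkSummaries(c(0.5, 0.9), c(0.7, 1.2))
  rule <- new("ClassifierRule", probeId = "SG1", threshold = 0.8,
              direction = "above", positiveClass = "cancer")
  ev <- evaluateClassifier(rule, s)
  expect_equal(ev$tp, 1L); expect_equal(ev$fn, 1L)
  expect_equal(ev$tn, 1L); expect_equal(ev$fp, 1L)
  expect_equal(ev$accuracy, 0.5)

  s2 <- mkSummaries(c(0.5, 0.6, 0.7), 1.2)
  ev2 <- evaluateClassifier(rule, s2)
  expect_equal(ev2$accuracy, 1)

  # ties at the threshold are called non-cancer
  sT <- mkSummaries(0.8, c(0.8, 1.0))
  evT <- evaluateClassifier(rule, sT)
  expect_equal(evT$tp, 1L); expect_equal(evT$fn, 1L)

  # empty input: zero-count matrix
  ev0 <- evaluateClassifier(rule, mkSummaries(0.5, 1.2)[0, ])
  expect_equal(ev0$tp + ev0$fp + ev0$tn + ev0$fn, 0L)

  # all-cancer input: specificity undefined, reported NA
  sC <- mkSummaries(numeric(0), c(1.0, 1.2))
  evC <- evaluateClassifier(rule, sC)
  expect_equal(evC$sensitivity, 1)
  expect_true(is.na(evC$specificity))

  # unlabeled samples are a validation error
  sN <- mkSummaries(0.5, c(1, 1.2)); sN$tissue_class[1] <- NA
  expect_error(evaluateClassifier(rule, sN), "unlabeled")
})

test_that("simulated SE1 cohorts train an accurate threshold rule", {
  accs <- vapply(1:50, function(i) {
    s <- simulateCohortSummaries("SE1",
                                 counts = c(normal = 21L, cancer = 20L),
                                 seed = 5000 + i)
    rule <- fitThreshold(s, "SE1")
    evaluateClassifier(rule, s)$accuracy
  }, numeric(1))
  expect_gte(mean(accs), 0.9)
})

test_that("all pairwise comparisons produce six rows per probe", {
  s <- rbind(simulateCohortSummaries("SG1", seed = 1),
             simulateCohortSummaries("SHC", seed = 2))
  comp <- compareAllGroups(s)
  expect_equal(nrow(comp), 12L)
  expect_equal(sum(comp$probe_id == "SG1"), 6L)
  # Bonferroni never lowers a p-value
  compB <- compareAllGroups(s, adjust = "bonferroni")
  expect_true(all(compB$p_value >= comp$p_value - 1e-12))
})
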