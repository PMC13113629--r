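test_that("Spearman rho equals Pearson on average ranks, including ties", {
  set.seed(17)
  for (i in 1:20) {
    x <- sample(round(runif(8, 0, 5), 1), 8, replace = TRUE)
    y <- round(rnorm(8), 1)
    sc <- spearmanCor(x, y)
    if (is.na(sc$rho)) next
    # manual average ranks + Pearson product-moment formula
    rx <- rank(x); ry <- rank(y)
    manual <- sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    expect_equal(sc$rho, manual, tolerance = 1e-12)
  }
  expect_equal(spearmanCor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearmanCor(1:10, -(1:10))$rho, -1)
  expect_true(is.na(spearmanCor(rep(1, 5), 1:5)$rho))
})

test_that("Mann-Whitney exact p agrees with full enumeration", {
  expect_equal(mannWhitney(1:3, 4:6)$U, 0)
  expect_equal(mannWhitney(1:3, 4:6)$p, 0.1)
  set.seed(23)
  for (i in 1:15) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    v <- sample(seq(0.1, 50, by = 0.1), n1 + n2)  # untied
    x <- v[1:n1]; y <- v[-(1:n1)]
    expect_equal(mannWhitney(x, y)$p, enumerateMannWhitneyP(x, y),
                 tolerance = 1e-12)
  }
})

test_that("U statistics of the two orientations sum to n1*n2", {
  set.seed(29)
  for (i in 1:20) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1))
    expect_equal(mannWhitney(x, y)$U + mannWhitney(y, x)$U,
                 length(x) * length(y))
  }
  # identical groups: p = 1 under the approximation by symmetry
  z <- rnorm(25)
  expect_gt(mannWhitney(c(z, 0.01), c(z, 0.01))$p, 0.95)
})

test_that("Hodges-Lehmann estimate equals the brute-force pairwise median", {
  expect_equal(hodgesLehmann(c(1, 2, 3), 0), 2)
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(sample(2:15, 1)); y <- rnorm(sample(2:15, 1))
    brute <- median(apply(expand.grid(x = x, y = y), 1,
                          function(r) r["x"] - r["y"]))
    expect_equal(hodgesLehmann(x, y), brute, tolerance = 1e-12)
  }
  # location model: shifting one group by delta shifts the estimate
  x <- rnorm(12); delta <- 3.7
  expect_equal(hodgesLehmann(x + delta, x), delta, tolerance = 1e-9)
})

test_that("Moses CI endpoints are order statistics of the pairwise differences", {
  ci <- hlConfidenceInterval(c(1, 2, 3), 0, level = 0.998)
  expect_equal(ci$low, 1)   # degenerate tiny-sample interval: (min, max)
  expect_equal(ci$high, 3)
  set.seed(37)
  for (i in 1:20) {
    x <- rnorm(sample(4:18, 1)); y <- rnorm(sample(4:18, 1))
    d <- sort(as.vector(outer(x, y, "-")))
    ci <- hlConfidenceInterval(x, y, level = 0.95)
    expect_true(ci$low %in% d && ci$high %in% d)
    expect_lte(ci$low, hodgesLehmann(x, y))
    expect_gte(ci$high, hodgesLehmann(x, y))
    # spec'd order-statistic construction, recomputed independently
    if (ci$k >= 0) {
      N <- length(d)
      ks <- 0:N
      kOracle <- max(ks[pwilcox(ks, length(x), length(y)) <= 0.025])
      expect_equal(ci$k, kOracle)
      expect_equal(c(ci$low, ci$high), c(d[kOracle + 1], d[N - kOracle]))
    }
  }
})

test_that("HL estimate and CI are equivariant under adding a constant", {
  set.seed(41)
  x <- rnorm(20); y <- rnorm(15); shift <- 11.5
  ci <- hlConfidenceInterval(x, y, level = 0.998)
  ciS <- hlConfidenceInterval(x + shift, y + shift, level = 0.998)
  expect_equal(ci$low, ciS$low, tolerance = 1e-9)
  expect_equal(ci$high, ciS$high, tolerance = 1e-9)
  expect_equal(hodgesLehmann(x + shift, y + shift), hodgesLehmann(x, y),
               tolerance = 1e-9)
  # the exact interval agrees with wilcox.test's achieved interval
  wt <- wilcox.test(x, y, conf.int = TRUE, conf.level = 0.95,
                    exact = TRUE)
  ci95 <- hlConfidenceInterval(x, y, level = 0.95)
  expect_equal(as.numeric(wt$conf.int), c(ci95$low, ci95$high),
               tolerance = 1e-9)
  expect_error(hlConfidenceInterval(x, y, level = 1.2), "level")
})

test_that("Bonferroni adjustment caps at 1, is monotone, and the inventory factors multiply out", {
  expect_equal(bonferroni(0.001, 23), 0.023)
  expect_equal(bonferroni(0.1, 23), 1)
  expect_true(all(bonferroni(runif(50), 23) <= 1))
  p <- 0.004
  expect_lte(bonferroni(p, 9), bonferroni(p, 23))
  f <- correctionFactors(9, 14)
  expect_equal(f$factorMatrix, 126)
  expect_equal(f$factorBiomarker, 23)
  expect_error(bonferroni(0.1, 0), ">= 1")
})

test_that("perfectly separated groups give AUC 1 at the separating midpoint", {
  r <- rocAnalysis(c(1, 2, 3, 10, 11, 12),
                   c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  expect_equal(r$cutoff, 6.5)
  expect_equal(r$ppv, 100); expect_equal(r$npv, 100)
  expect_error(rocAnalysis(1:4, rep(TRUE, 4)), "both classes")
})

test_that("AUC equals the normalized Mann-Whitney U statistic", {
  set.seed(43)
  for (i in 1:200) {
    n1 <- sample(3:15, 1); n2 <- sample(3:15, 1)
    scores <- round(rnorm(n1 + n2), 1)   # ties likely
    labels <- c(rep(TRUE, n1), rep(FALSE, n2))
    r <- rocAnalysis(scores, labels)
    u <- mannWhitney(scores[labels], scores[!labels])$U
    expect_equal(r$auc, u / (n1 * n2), tolerance = 1e-12)
  }
})

test_that("AUC and DeLong CI agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(47)
  for (i in 1:10) {
    scores <- rnorm(60)
    labels <- c(rep(TRUE, 25), rep(FALSE, 35))
    scores[labels] <- scores[labels] + 1
    r <- rocAnalysis(scores, labels)
    pr <- pROC::roc(labels, scores, direction = "<", quiet = TRUE)
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
    ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
    expect_equal(c(r$aucCiLow, r$aucCiHigh), ci[c(1, 3)],
                 tolerance = 1e-8)
  }
})

test_that("operating-point metrics satisfy the Bayes consistency with prevalence", {
  set.seed(53)
  for (i in 1:20) {
    scores <- rnorm(40)
    labels <- runif(40) < 0.4
    if (!any(labels) || all(labels)) next
    r <- rocAnalysis(scores, labels)
    prev <- mean(labels)
    se <- r$sensitivity / 100; sp <- r$specificity / 100
    if (!is.na(r$ppv)) {
      expect_equal(r$ppv / 100,
                   se * prev / (se * prev + (1 - sp) * (1 - prev)),
                   tolerance = 1e-9)
    }
    if (!is.na(r$npv)) {
      expect_equal(r$npv / 100,
                   sp * (1 - prev) / (sp * (1 - prev) + (1 - se) * prev),
                   tolerance = 1e-9)
    }
  }
})

test_that("orientation is honoured, not auto-flipped", {
  scores <- c(1, 2, 3, 10, 11, 12)
  labels <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  r <- rocAnalysis(scores, labels, orientation = -1)
  expect_equal(r$auc, 0)   # reported honestly below 0.5
})

test_that("null scores give AUC near one half on average", {
  set.seed(59)
  aucs <- replicate(300, {
    rocAnalysis(rnorm(30), c(rep(TRUE, 12), rep(FALSE, 18)))$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})
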