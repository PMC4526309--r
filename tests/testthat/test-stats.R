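test_that("rank-sum test matches brute-force ranks and handles ties", {
  r <- wilcoxon_ranksum(c(1, 2, 3), c(10, 11, 12))
  # W statistic of x: sum of x ranks minus n(n+1)/2 = (1+2+3) - 6 = 0
  expect_equal(r$statistic, 0)
  # same values in both samples
  expect_equal(wilcoxon_ranksum(rep(2, 5), rep(2, 7))$p_value, 1)
  ra <- wilcoxon_ranksum(c(5, 6, 7, 8), c(5, 6, 7, 8))
  expect_gt(ra$p_value, 0.9)
  # brute-force midrank oracle on a tied sample
  x <- c(1, 2, 2, 5); y <- c(2, 3, 3)
  rk <- rank(c(x, y))
  expect_equal(wilcoxon_ranksum(x, y)$statistic,
               sum(rk[1:4]) - 4 * 5 / 2)
  expect_error(wilcoxon_ranksum(numeric(0), 1), "nonempty")
})

test_that("rank-sum test holds its nominal level under the null", {
  set.seed(61)
  rej <- mean(replicate(4000, wilcoxon_ranksum(rnorm(20), rnorm(20))$p_value < 0.05))
  expect_gt(rej, 0.04)
  expect_lt(rej, 0.06)
})

test_that("normality test reproduces an independent reference implementation", {
  # frozen reference values computed with an independent implementation
  # of the same omnibus statistic (transformed skewness + kurtosis)
  x <- c(2.1, 3.5, 1.2, 4.8, 2.9, 3.3, 0.7, 5.6, 2.2, 3.1,
         4.0, 1.9, 2.8, 3.7, 6.5, 0.3, 2.5, 3.9, 1.4, 4.4)
  dp <- dagostino_pearson(x)
  expect_equal(dp$statistic, 0.41760009325332, tolerance = 1e-10)
  expect_equal(dp$p_value, 0.81155749307931, tolerance = 1e-10)
  expect_equal(dp$z_skew, 0.62619044299818, tolerance = 1e-10)
  expect_equal(dp$z_kurt, 0.15964216971420, tolerance = 1e-10)
  dp2 <- dagostino_pearson((1:12)^3 / 100)
  expect_equal(dp2$statistic, 3.29616223758980, tolerance = 1e-10)
  expect_equal(dp2$p_value, 0.19241878338108, tolerance = 1e-10)

  expect_error(dagostino_pearson(rnorm(5)), "at least 8")
})

test_that("normality test is calibrated and detects skewness", {
  set.seed(71)
  rej <- mean(replicate(4000, dagostino_pearson(rnorm(300))$p_value < 0.05))
  expect_gt(rej, 0.035)
  expect_lt(rej, 0.065)
  expect_lt(dagostino_pearson(rexp(500))$p_value, 1e-3)
})

test_that("mid-P Fisher reproduces published contingency p-values", {
  # NR vs PR+CR association tables with their printed p-values
  expect_equal(round(fisher_midp(rbind(c(8, 5), c(11, 45)))$p_value, 3), 0.005)
  expect_equal(round(fisher_midp(rbind(c(12, 27), c(7, 23)))$p_value, 2), 0.51)
  expect_equal(round(fisher_midp(rbind(c(15, 37), c(4, 13)))$p_value, 2), 0.70)
  expect_equal(round(fisher_midp(rbind(c(14, 28), c(5, 22)))$p_value, 2), 0.19)
  expect_equal(round(fisher_midp(rbind(c(11, 41), c(8, 9)))$p_value, 2), 0.05)
  expect_equal(round(fisher_midp(rbind(c(4, 22), c(15, 28)))$p_value, 2), 0.09)
})

test_that("mid-P Fisher invariances and relation to the classical test", {
  expect_equal(fisher_midp(rbind(c(5, 5), c(5, 5)))$p_value, 1)
  zm <- fisher_midp(rbind(c(0, 0), c(3, 4)))
  expect_equal(zm$p_value, 1)
  expect_equal(zm$flag, "zero margin")
  expect_error(fisher_midp(c(1, -2, 3, 4)), "non-negative")

  # classical doubling-rule Fisher p as an enumeration oracle
  classic <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    s <- max(0, k - n):min(k, m)
    pr <- dhyper(s, m, n, k)
    min(1, 2 * min(sum(pr[s <= a]), sum(pr[s >= a])))
  }
  set.seed(12)
  for (i in 1:50) {
    t <- matrix(rpois(4, 8), 2, 2)
    if (sum(t) == 0) next
    pm <- fisher_midp(t)$p_value
    # simultaneous row+column swap leaves the table's association intact
    expect_equal(fisher_midp(t[2:1, 2:1])$p_value, pm, tolerance = 1e-12)
    expect_lte(pm, classic(t[1, 1], t[1, 2], t[2, 1], t[2, 2]) + 1e-12)
  }
})

test_that("ROC analysis: separability, orientation and Youden cut-off", {
  r <- roc_analysis(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T))
  expect_equal(r$auc, 1)
  expect_equal(r$se, 100)
  expect_equal(r$sp, 100)

  # low scores indicating the positive class are auto-reoriented
  r2 <- roc_analysis(c(10, 11, 12, 1, 2, 3), c(F, F, F, T, T, T))
  expect_equal(r2$direction, "<=")
  expect_equal(r2$auc, 1)

  # fixed orientation: reversing labels maps AUC to 1 - AUC
  set.seed(2)
  sc <- rnorm(40); lb <- rep(c(TRUE, FALSE), 20)
  a1 <- roc_analysis(sc, lb, direction = ">=")$auc
  a2 <- roc_analysis(sc, !lb, direction = ">=")$auc
  expect_equal(a1 + a2, 1, tolerance = 1e-12)

  # invariance under strictly monotone transforms
  a3 <- roc_analysis(exp(sc), lb, direction = ">=")$auc
  expect_equal(a1, a3, tolerance = 1e-12)

  expect_error(roc_analysis(1:5, rep(TRUE, 5)), "both classes")

  # Youden ties break toward sensitivity: positives score {2, 4},
  # negatives {1, 3}; cutoffs >=4 and >=2 both give J = 0.5 and the
  # latter has Se 100%
  rt <- roc_analysis(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE), direction = ">=")
  expect_equal(rt$se, 100)
  expect_equal(rt$cutoff, 2)
})

test_that("trapezoid AUC equals the rank statistic and external reference", {
  skip_if_not_installed("pROC")
  set.seed(13)
  for (i in 1:40) {
    n1 <- sample(5:15, 1); n0 <- sample(5:15, 1)
    sc <- round(c(rnorm(n1, 1), rnorm(n0)), sample(0:2, 1))  # forces ties
    lb <- rep(c(TRUE, FALSE), c(n1, n0))
    r <- roc_analysis(sc, lb, direction = ">=")
    u <- (sum(rank(sc)[lb]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    expect_equal(r$auc, u, tolerance = 1e-12)
    pr <- pROC::roc(lb, sc, direction = "<", quiet = TRUE)
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  }
})

test_that("AUC is at chance under label permutation", {
  set.seed(14)
  sc <- rnorm(40)
  aucs <- replicate(2000, roc_analysis(sc, sample(rep(c(TRUE, FALSE), 20)),
                                       direction = ">=")$auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.01)
})

test_that("paired AUC comparison agrees with an external DeLong implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  lb <- rep(c(TRUE, FALSE), each = 30)
  a <- rnorm(60) + lb
  b <- 0.5 * a + rnorm(60)
  mine <- compare_auc(a, b, lb)
  pr <- pROC::roc.test(pROC::roc(lb, a, direction = "<", quiet = TRUE),
                       pROC::roc(lb, b, direction = "<", quiet = TRUE),
                       method = "delong")
  expect_equal(mine$statistic, unname(pr$statistic), tolerance = 1e-10)
  expect_equal(mine$p_value, pr$p.value, tolerance = 1e-10)

  expect_equal(compare_auc(a, a, lb)$p_value, 1)
  expect_equal(compare_auc(a, exp(a), lb)$difference, 0)
})

test_that("paired AUC comparison holds its level under the null", {
  set.seed(15)
  rej <- mean(replicate(1500, {
    lab <- rep(c(TRUE, FALSE), each = 40)
    base <- rnorm(80)
    compare_auc(base + rnorm(80), base + rnorm(80), lab)$p_value < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})
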