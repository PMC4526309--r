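new_test_result <- function(statistic, p_value, method, flag = NULL) {
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 flag = flag),
            class = "nac_test")
}

#' @export
print.nac_test <- function(x, ...) {
  cat(sprintf("<nac_test> %s: statistic = %.6g, p = %.4g%s\n",
              x$method, x$statistic, x$p_value,
              if (!is.null(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum comparison of two independent samples using
#' midranks for ties, the normal approximation with tie-corrected
#' variance, and continuity correction — the form appropriate for
#' feature comparisons between tissue groups where exact enumeration is
#' unnecessary. Degenerate input (every value identical across both
#' samples) returns p = 1 with a flag.
#'
#' @param x,y numeric samples.
#' @return A `nac_test` with the rank-sum statistic W (of `x`) and the
#'   two-sided p-value.
#' @export
wilcoxon_ranksum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  if (length(unique(c(x, y))) == 1L)
    return(new_test_result(statistic = 0, p_value = 1,
                           method = "Wilcoxon rank-sum", flag = "all values tied"))
  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  new_test_result(statistic = unname(wt$statistic), p_value = wt$p.value,
                  method = "Wilcoxon rank-sum")
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed-skewness Z (D'Agostino) and
#' transformed-kurtosis Z (Anscombe-Glynn) into the omnibus statistic
#' K-squared = Z_skew^2 + Z_kurt^2, referred to a chi-square distribution
#' with 2 degrees of freedom. The transformations are the standard
#' finite-sample normalizations; they require n >= 8.
#'
#' @param x numeric sample of at least 8 observations.
#' @return A `nac_test` with statistic K-squared and its p-value;
#'   `$z_skew` and `$z_kurt` carry the component statistics.
#' @export
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson needs at least 8 observations")
  if (sd(x) == 0) stop("constant sample: normality test undefined")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  # skewness component (D'Agostino 1970)
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis component (Anscombe-Glynn 1983)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z_kurt <- ((1 - 2 / (9 * a)) -
               ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z_skew^2 + z_kurt^2
  out <- new_test_result(statistic = k2,
                         p_value = pchisq(k2, df = 2, lower.tail = FALSE),
                         method = "D'Agostino-Pearson omnibus")
  out$z_skew <- z_skew
  out$z_kurt <- z_kurt
  out
}

as_2x2 <- function(t) {
  if (is.matrix(t)) {
    if (!identical(dim(t), c(2L, 2L))) stop("table must be 2x2")
    t <- c(t[1, 1], t[1, 2], t[2, 1], t[2, 2])
  }
  t <- as.numeric(t)
  if (length(t) != 4L || any(t < 0) || any(t != round(t)))
    stop("a 2x2 table needs 4 non-negative integer counts")
  if (sum(t) == 0) stop("empty table")
  t
}

#' Mid-P Fisher exact test for a 2x2 table
#'
#' Exact conditional test of association in a 2x2 contingency table,
#' using the mid-P correction: conditional on the margins, the first
#' cell follows a hypergeometric distribution, and each one-sided mid-P
#' value is the probability of a strictly more extreme table plus half
#' the probability of the observed one. The two-sided p-value doubles
#' the smaller one-sided mid-P (capped at 1). Mid-P reduces the
#' conservatism of the classical Fisher test while retaining exact
#' enumeration. A table with a zero margin carries no information about
#' association and returns p = 1 with a flag.
#'
#' @param tab a 2x2 matrix of counts `rbind(c(a, b), c(c, d))` (rows:
#'   feature present/absent; columns: the two outcome groups), or the
#'   vector `c(a, b, c, d)` in row-major order.
#' @return A `nac_test` with the observed first cell as statistic and
#'   the two-sided mid-P value; `$one_sided` carries both one-sided
#'   mid-P values.
#' @examples
#' fisher_midp(rbind(c(8, 5), c(11, 45)))$p_value  # ~0.005
#' @export
fisher_midp <- function(tab) {
  t <- as_2x2(tab)
  a <- t[1]; b <- t[2]; c_ <- t[3]; d <- t[4]
  m <- a + b; n <- c_ + d; k <- a + c_
  if (m == 0 || n == 0 || k == 0 || b + d == 0)
    return(new_test_result(statistic = a, p_value = 1,
                           method = "mid-P Fisher exact", flag = "zero margin"))
  lo <- max(0, k - n); hi <- min(k, m)
  support <- lo:hi
  pr <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  p_lower <- sum(pr[support < a]) + 0.5 * p_obs
  p_upper <- sum(pr[support > a]) + 0.5 * p_obs
  out <- new_test_result(statistic = a,
                         p_value = min(1, 2 * min(p_lower, p_upper)),
                         method = "mid-P Fisher exact")
  out$one_sided <- c(lower = p_lower, upper = p_upper)
  out
}

#' Empirical ROC analysis with Youden cut-off
#'
#' Receiver operating characteristic of a continuous marker against a
#' binary outcome (positive class first level of `labels` when a factor,
#' or `TRUE`). The empirical curve is evaluated at every distinct
#' threshold; the area under it is computed by the trapezoid rule, which
#' equals the Mann-Whitney two-sample statistic U divided by n1*n2. The
#' reported cut-off maximizes the Youden index J = Se + Sp - 1, with
#' ties resolved toward higher sensitivity (detection of the positive
#' class is the priority). The marker orientation is chosen
#' automatically so that AUC >= 0.5 and recorded in `direction`
#' (`">="`: high values indicate the positive class). The test against
#' AUC = 0.5 uses the Mann-Whitney normal approximation.
#'
#' @param scores numeric marker values.
#' @param labels logical vector (`TRUE` = positive) or factor whose
#'   first level is the positive class.
#' @param direction `"auto"` (default), `">="` or `"<="`.
#' @return An object of class `roc_result`: `auc`, `p_vs_half`,
#'   `cutoff`, `se`, `sp` (percent), `direction`, `curve` (data.frame
#'   with columns `cutoff`, `fpr`, `tpr`), `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(scores, labels, direction = c("auto", ">=", "<=")) {
  direction <- match.arg(direction)
  if (is.factor(labels)) labels <- labels == levels(labels)[1]
  if (is.character(labels)) stop("`labels` must be logical or factor")
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("`scores` and `labels` lengths differ")
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  auc_ge <- {
    r <- rank(scores)            # midranks handle ties
    (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  if (direction == "auto") direction <- if (auc_ge >= 0.5) ">=" else "<="
  s <- if (direction == ">=") scores else -scores
  auc <- if (direction == ">=") auc_ge else 1 - auc_ge
  th <- sort(unique(s), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(s[labels] >= t) / n_pos, numeric(1))
  fpr <- vapply(th, function(t) sum(s[!labels] >= t) / n_neg, numeric(1))
  curve <- data.frame(cutoff = c(NA, if (direction == ">=") th else -th, NA),
                      fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  # trapezoid area over the empirical curve
  auc_trap <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
  j <- curve$tpr - curve$fpr
  cand <- which(!is.na(curve$cutoff))
  best <- cand[j[cand] == max(j[cand])]
  best <- best[which.max(curve$tpr[best])]     # ties: higher Se
  wt <- suppressWarnings(wilcox.test(scores[labels], scores[!labels],
                                     exact = FALSE, correct = FALSE))
  structure(list(auc = auc_trap, auc_rank = auc,
                 p_vs_half = wt$p.value,
                 cutoff = curve$cutoff[best],
                 se = 100 * curve$tpr[best], sp = 100 * (1 - curve$fpr[best]),
                 direction = direction, curve = curve,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC = %.3f (p vs 0.5 = %.3g), cutoff %s %.4g: Se %.0f%%, Sp %.0f%% (%d pos / %d neg)\n",
    x$auc, x$p_vs_half, x$direction, x$cutoff, x$se, x$sp, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$curve$fpr, x$curve$tpr, type = "l",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

# Placement values of DeLong's method: for each positive subject the
# mean indicator psi over negatives (and vice versa), psi = 1, 1/2, 0
# for greater / tied / smaller.
delong_placements <- function(scores, labels) {
  xp <- scores[labels]; xn <- scores[!labels]
  psi <- function(a, b) (sign(a - b) + 1) / 2
  v10 <- vapply(xp, function(a) mean(psi(a, xn)), numeric(1))
  v01 <- vapply(xn, function(b) mean(psi(xp, b)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Paired AUC comparison (DeLong)
#'
#' Tests whether two markers measured on the same subjects have equal
#' AUC, using the asymptotic normality of the paired difference of
#' empirical AUCs with the covariance estimated from the two markers'
#' placement-value vectors. Markers are compared in the orientation
#' given (no automatic flipping — a data-driven re-orientation would
#' distort the null distribution of the paired difference); orient a
#' marker beforehand, e.g. by negating it when [roc_analysis()] reports
#' direction `"<="`.
#'
#' @param scores_a,scores_b numeric marker values on the same subjects.
#' @param labels logical (`TRUE` = positive) or factor with the positive
#'   class first.
#' @return A `nac_test` with the z statistic and two-sided p-value;
#'   `$auc` carries both AUCs.
#' @export
compare_auc <- function(scores_a, scores_b, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[1]
  labels <- as.logical(labels)
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels))
    stop("paired design: both score vectors must match `labels` in length")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  d <- pa$auc - pb$auc
  s10 <- var(pa$v10 - pb$v10)
  s01 <- var(pa$v01 - pb$v01)
  v <- s10 / n_pos + s01 / n_neg
  if (v <= 0 || !is.finite(v)) {
    out <- new_test_result(statistic = 0, p_value = 1,
                           method = "DeLong paired AUC comparison",
                           flag = if (d == 0) "identical placements" else "zero variance")
  } else {
    z <- d / sqrt(v)
    out <- new_test_result(statistic = z, p_value = 2 * pnorm(-abs(z)),
                           method = "DeLong paired AUC comparison")
  }
  out$auc <- c(a = pa$auc, b = pb$auc)
  out$difference <- d
  out
}
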