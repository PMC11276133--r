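#' Mean absolute and mean squared error
#'
#' `mae(truth, pred)` is `mean(|truth - pred|)` and `mse(truth, pred)` is
#' `mean((truth - pred)^2)`. MAE is the primary count-error metric here
#' because it is in ePVS units and robust to outliers; MSE is reported
#' alongside.
#'
#' @param truth,pred Equal-length nonempty numeric vectors.
#' @return A single number.
#' @examples
#' mae(c(0, 48), c(48, 0)) # 48
#' mse(c(0, 48), c(48, 0)) # 2304
#' @export
mae <- function(truth, pred) {
  check_paired(truth, pred)
  mean(abs(truth - pred))
}

#' @rdname mae
#' @export
mse <- function(truth, pred) {
  check_paired(truth, pred)
  mean((truth - pred)^2)
}

check_paired <- function(truth, pred) {
  if (length(truth) == 0 || length(truth) != length(pred)) {
    stopf("`truth` (length %d) and `pred` (length %d) must be nonempty and of equal length",
          length(truth), length(pred))
  }
  if (anyNA(truth) || anyNA(pred)) stopf("inputs contain missing values")
  invisible(NULL)
}

#' Exact-agreement grade accuracy
#'
#' Percentage of positions where the predicted grade equals the true grade.
#'
#' @param truth_grades,pred_grades Equal-length integer vectors of grades.
#' @return Accuracy in percent (0--100).
#' @examples
#' grade_accuracy(c(1, 2, 3), c(1, 2, 4)) # 66.67
#' @export
grade_accuracy <- function(truth_grades, pred_grades) {
  check_paired(truth_grades, pred_grades)
  100 * mean(truth_grades == pred_grades)
}

#' Intraclass correlation between two ratings
#'
#' Single-measure two-way random-effects ICC between paired ratings of the
#' same subjects, used to assess agreement between predicted and expert ePVS
#' grades. The default `type = "agreement"` is ICC(2,1) (absolute agreement);
#' `type = "consistency"` gives ICC(3,1), which ignores systematic offsets.
#' The 95% confidence interval for ICC(2,1) uses the F-based approximation of
#' McGraw & Wong with Satterthwaite degrees of freedom.
#'
#' @param truth,pred Paired numeric ratings, length >= 5.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A one-row tibble: `icc`, `ci_low`, `ci_high`, `n`, `k`, `type`.
#' @examples
#' icc(c(1, 2, 3, 4, 2, 0), c(1, 2, 3, 4, 2, 0))$icc # exactly 1
#' @export
icc <- function(truth, pred, type = c("agreement", "consistency"),
                conf_level = 0.95) {
  type <- match.arg(type)
  check_paired(truth, pred)
  n <- length(truth)
  if (n < 5) stopf("ICC requires at least 5 paired ratings (got %d)", n)
  x <- cbind(truth, pred)
  k <- 2L
  if (all(x == x[1, 1])) stopf("ICC undefined: ratings have zero total variance")

  grand <- mean(x)
  rowm <- rowMeans(x)
  colm <- colMeans(x)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sse <- sum((x - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mserr <- sse / ((n - 1) * (k - 1))

  alpha <- 1 - conf_level
  if (type == "consistency") {
    est <- (msr - mserr) / (msr + (k - 1) * mserr)
    f <- msr / mserr
    df1 <- n - 1
    df2 <- (n - 1) * (k - 1)
    fl <- f / qf(1 - alpha / 2, df1, df2)
    fu <- f * qf(1 - alpha / 2, df2, df1)
    lo <- (fl - 1) / (fl + (k - 1))
    hi <- (fu - 1) / (fu + (k - 1))
  } else {
    est <- (msr - mserr) / (msr + (k - 1) * mserr + k / n * (msc - mserr))
    if (est >= 1) { # degenerate perfect agreement: zero within-subject variance
      v <- Inf
    } else {
      a <- k * est / (n * (1 - est))
      b <- 1 + k * est * (n - 1) / (n * (1 - est))
      v <- (a * msc + b * mserr)^2 /
        ((a * msc)^2 / (k - 1) + (b * mserr)^2 / ((n - 1) * (k - 1)))
    }
    f1 <- qf(1 - alpha / 2, n - 1, v)
    f2 <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f1 * mserr) /
      (f1 * (k * msc + (k * n - k - n) * mserr) + n * msr)
    hi <- n * (f2 * msr - mserr) /
      (k * msc + (k * n - k - n) * mserr + n * f2 * msr)
  }
  est <- min(1, max(-1, est))
  tibble(
    icc = est,
    ci_low = min(max(-1, lo), est),
    ci_high = max(min(1, hi), est),
    n = n, k = k, type = type
  )
}
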