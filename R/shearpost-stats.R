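# Trend statistics (Pearson correlation, zero-slope regression tests) and
# the exact-permutation Mann-Whitney rank test used for the Murray's-law
# validation analog.

#' Exact-permutation Mann-Whitney (rank-sum) test
#'
#' Two-sided Mann-Whitney U test of whether two samples come from the same
#' population. For group sizes up to \code{exactMax} the p value is
#' computed by full enumeration of all group assignments (handling ties by
#' midranks); larger samples use the normal approximation with tie
#' correction.
#'
#' @param x,y numeric samples (>= 3 each recommended).
#' @param exactMax largest per-group size for exact enumeration.
#' @return list with \code{statistic} (U for x), \code{p.value},
#'   \code{method}.
#' @export
mannWhitneyExact <- function(x, y, exactMax = 10L) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  Uobs <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  mid <- nx * ny / 2
  if (max(nx, ny) <= exactMax) {
    combos <- combn(nx + ny, nx)
    rsum <- colSums(matrix(rk[combos], nrow = nx))
    U <- rsum - nx * (nx + 1) / 2
    p <- mean(abs(U - mid) >= abs(Uobs - mid) - 1e-9)
    list(statistic = Uobs, p.value = p, method = "exact permutation")
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    list(statistic = Uobs, p.value = wt$p.value,
         method = "normal approximation with tie correction")
  }
}

#' Compare simulated and measured samples (rank test)
#'
#' The validation-analog check: two-sided exact-permutation Mann-Whitney
#' test between simulated and measured velocity samples.
#'
#' @param simulated,measured numeric samples, >= 3 each.
#' @return the \code{\link{mannWhitneyExact}} result.
#' @export
twoSampleCheck <- function(simulated, measured) {
  if (length(simulated) < 3 || length(measured) < 3)
    stop("need >= 3 samples per group")
  mannWhitneyExact(simulated, measured)
}

#' Correlation and zero-slope regression statistics for a trend table
#'
#' For each (quantity, covariate) contrast, computes Pearson's correlation
#' coefficient and the p value for the hypothesis that the regression
#' slope is zero, pooling rows across vessels.
#'
#' @param table data.frame with the quantity and covariate columns (e.g. a
#'   stage-sweep trend table).
#' @param quantities column names of the measured quantities.
#' @param covariates column names of the covariates.
#' @return data.frame: quantity, covariate, n, rho, slope, slope_p,
#'   slope_lo, slope_hi (95\% CI); rho is NA with a note when the
#'   covariate is constant.
#' @export
trendStatistics <- function(table,
                            quantities = c("tau_mPa", "gamma_per_s",
                                           "Vc_mm_s"),
                            covariates = c("age_days", "area_mm2")) {
  out <- list()
  for (qn in quantities) for (cv in covariates) {
    if (qn == cv) next
    yv <- table[[qn]]; xv <- table[[cv]]
    n <- sum(is.finite(yv) & is.finite(xv))
    if (n < 3) stop("need >= 3 rows per contrast")
    if (sd(xv) < .Machine$double.eps) {
      out[[length(out) + 1L]] <- data.frame(
        quantity = qn, covariate = cv, n = n, rho = NA_real_,
        slope = NA_real_, slope_p = NA_real_, slope_lo = NA_real_,
        slope_hi = NA_real_, note = "constant covariate: undefined",
        stringsAsFactors = FALSE)
      next
    }
    rho <- cor(xv, yv)
    fit <- lm(yv ~ xv)
    sm <- summary(fit)$coefficients
    slope <- sm["xv", "Estimate"]
    pval <- sm["xv", "Pr(>|t|)"]
    ci <- stats::confint(fit)["xv", ]
    out[[length(out) + 1L]] <- data.frame(
      quantity = qn, covariate = cv, n = n, rho = rho, slope = slope,
      slope_p = pval, slope_lo = ci[1], slope_hi = ci[2], note = "",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
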