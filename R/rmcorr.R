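#' Repeated-measures correlation
#'
#' Common within-subject correlation via the subject-adjusted analysis of
#' covariance: regress y on subject indicators plus x (one common slope);
#' `r = sign(slope) * sqrt(SS_x / (SS_x + SS_err))` where `SS_x` is the sum
#' of squares attributable to x after subjects and `SS_err` the residual.
#' Degrees of freedom are `N - k - 1` for N paired observations and k
#' subjects; the p-value is two-sided from the t distribution.
#'
#' Subjects with fewer than two complete paired observations are dropped
#' with a warning; fewer than two remaining subjects is an error.
#'
#' @param table data.frame holding the variables.
#' @param x,y column names of the two endpoints.
#' @param subject column name of the subject identifier.
#' @return an `rmcorr_result`: `r`, `df`, `p`, `n_obs`, `n_subjects`.
#' @export
rmcorr <- function(table, x, y, subject = "participant") {
  need <- c(x, y, subject)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("table lacks columns: ", paste(miss, collapse = ", "))
  df <- table[stats::complete.cases(table[, need]), need]
  names(df) <- c("x", "y", "subject")
  df$subject <- factor(df$subject)
  counts <- table(df$subject)
  drop <- names(counts)[counts < 2]
  if (length(drop)) {
    warning("dropping ", length(drop), " subject(s) with < 2 paired observations")
    df <- df[!(df$subject %in% drop), ]
    df$subject <- droplevels(df$subject)
  }
  k <- nlevels(df$subject)
  if (k < 2) stop("need at least 2 subjects with >= 2 paired observations")
  n <- nrow(df)

  fit <- stats::lm(y ~ subject + x, data = df)
  # the ANOVA F-statistics are unused (we only need the sums of squares), so
  # the perfect-fit warning about them is irrelevant here
  an <- withCallingHandlers(
    stats::anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ss_x <- an["x", "Sum Sq"]
  ss_err <- an["Residuals", "Sum Sq"]
  slope <- stats::coef(fit)[["x"]]
  denom <- ss_x + ss_err
  # degenerate case: y explained exactly by subject indicators leaves only
  # numerical dust in both sums of squares
  ss_tot <- sum((df$y - mean(df$y))^2)
  r <- if (!is.finite(slope) || ss_x <= 0 || denom <= 1e-12 * max(ss_tot, 1)) 0
       else sign(slope) * sqrt(ss_x / denom)
  dfree <- n - k - 1
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt(dfree / (1 - r^2))
    2 * stats::pt(-abs(tval), dfree)
  }
  structure(list(r = r, df = dfree, p = p, n_obs = n, n_subjects = k),
            class = "rmcorr_result")
}

#' @export
print.rmcorr_result <- function(x, ...) {
  cat(sprintf("rmcorr: r = %.4f, df = %d, p = %.3g (%d obs, %d subjects)\n",
              x$r, x$df, x$p, x$n_obs, x$n_subjects))
  invisible(x)
}
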