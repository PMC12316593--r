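#' Agreement statistics between estimated and gold-standard pressures
#'
#' Reports the mean absolute error with the standard deviation of the
#' absolute errors (the "MAE +- SD" convention), the Bland-Altman mean
#' difference with 1.96-SD limits of agreement on the signed differences
#' (estimate minus truth), and the Pearson correlation (flagged `NA` when
#' the truth is constant).
#'
#' @param estimates Numeric mmHg estimates.
#' @param truth Numeric mmHg gold standard, same length (>= 2).
#' @return An `agreement_report` list: `n`, `mae`, `sd_ae`, `mean_error`,
#'   `loa_low`, `loa_high`, `pearson_r`.
#' @export
agreement_report <- function(estimates, truth) {
  if (length(estimates) != length(truth))
    .bp_stop("bp_invalid", "length mismatch")
  if (length(truth) < 2L) .bp_stop("bp_invalid", "need at least 2 pairs")
  e <- estimates - truth
  r <- if (sd(truth) == 0 || sd(estimates) == 0) NA_real_
       else cor(estimates, truth)
  structure(list(n = length(e), mae = mean(abs(e)), sd_ae = sd(abs(e)),
                 mean_error = mean(e),
                 loa_low = mean(e) - 1.96 * sd(e),
                 loa_high = mean(e) + 1.96 * sd(e),
                 pearson_r = r),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("n=%d  MAE %.2f +- %.2f mmHg  bias %.2f  LoA [%.2f, %.2f]  r=%s\n",
              x$n, x$mae, x$sd_ae, x$mean_error, x$loa_low, x$loa_high,
              ifelse(is.na(x$pearson_r), "NA", sprintf("%.3f", x$pearson_r))))
  invisible(x)
}

#' Device-standard grading of pressure errors
#'
#' Cumulative percentages of absolute errors within 5/10/15 mmHg; the BHS
#' grade ladder (A: >= 60/85/95%, B: >= 50/75/90%, C: >= 40/65/85%, else D);
#' and the AAMI criterion (|mean signed error| <= 5 mmHg and SD of the
#' signed error <= 8 mmHg).
#'
#' @param errors Signed errors in mmHg (estimate - truth), length >= 1.
#' @return A `grade_report` list: `pct_within_5/10/15`, `bhs_grade`,
#'   `aami_pass`.
#' @export
standards_grade <- function(errors) {
  if (!length(errors)) .bp_stop("bp_invalid", "need at least one error")
  a <- abs(errors)
  p5 <- 100 * mean(a <= 5)
  p10 <- 100 * mean(a <= 10)
  p15 <- 100 * mean(a <= 15)
  grade <- if (p5 >= 60 && p10 >= 85 && p15 >= 95) "A"
           else if (p5 >= 50 && p10 >= 75 && p15 >= 90) "B"
           else if (p5 >= 40 && p10 >= 65 && p15 >= 85) "C"
           else "D"
  aami <- length(errors) >= 2L && abs(mean(errors)) <= 5 && sd(errors) <= 8
  structure(list(pct_within_5 = p5, pct_within_10 = p10, pct_within_15 = p15,
                 bhs_grade = grade, aami_pass = aami),
            class = "grade_report")
}

#' Stratified agreement reports
#'
#' One [agreement_report()] per stratum (pressure bin, age group, gender,
#' race, CV fold, ...). Pressure bins default to 10-mmHg edges over
#' \[80, 220\] for systolic and \[40, 120\] for diastolic. Strata with fewer
#' than 2 rows are reported with counts only.
#'
#' @param estimates,truth Numeric mmHg vectors.
#' @param strata Vector of stratum labels per row, or `"bp_bin"` to bin by
#'   the truth values.
#' @param target `"systolic"` or `"diastolic"` (sets default bin edges).
#' @return Data frame: `stratum`, `n`, `mae`, `sd_ae`, `mean_error`,
#'   `loa_low`, `loa_high`.
#' @export
stratified_report <- function(estimates, truth, strata = "bp_bin",
                              target = c("systolic", "diastolic")) {
  target <- match.arg(target)
  if (identical(strata, "bp_bin")) {
    edges <- if (target == "systolic") seq(80, 220, by = 10)
             else seq(40, 120, by = 10)
    strata <- cut(truth, edges, include.lowest = TRUE)
  }
  strata <- as.character(strata)
  labs <- unique(strata)
  rows <- lapply(labs, function(s) {
    idx <- which(strata == s)
    if (length(idx) < 2L)
      return(data.frame(stratum = s, n = length(idx), mae = NA_real_,
                        sd_ae = NA_real_, mean_error = NA_real_,
                        loa_low = NA_real_, loa_high = NA_real_))
    r <- agreement_report(estimates[idx], truth[idx])
    data.frame(stratum = s, n = r$n, mae = r$mae, sd_ae = r$sd_ae,
               mean_error = r$mean_error, loa_low = r$loa_low,
               loa_high = r$loa_high)
  })
  do.call(rbind, rows)
}

#' Dynamic-tracking lag via 20-sample windowed cross-correlation
#'
#' Splits the series into consecutive 20-sample windows, cross-correlates
#' estimate against truth over lags -10..+10 in each, and reports the modal
#' argmax lag (ties broken toward 0). A low-confidence flag is raised when
#' the correlations are weak or the mode is unstable.
#'
#' @param estimated,true Equal-length numeric series (>= 40 samples).
#' @param window Window length in samples.
#' @param max_lag Largest lag magnitude examined.
#' @return A `tracking_lag` list: `lag`, `mode_freq`, `median_peak_cor`,
#'   `low_confidence`, `per_window` (argmax lag per window).
#' @export
tracking_lag <- function(estimated, true, window = 20L, max_lag = 10L) {
  n <- length(true)
  if (length(estimated) != n) .bp_stop("bp_invalid", "length mismatch")
  if (n < 2L * window) .bp_stop("bp_invalid", "series too short")
  lags <- -max_lag:max_lag
  starts <- seq(1L, n - window + 1L, by = window)
  best_lag <- rep(NA_integer_, length(starts))
  best_cor <- rep(NA_real_, length(starts))
  for (w in seq_along(starts)) {
    s <- starts[w]
    tr <- true[s:(s + window - 1L)]
    if (sd(tr) == 0) next
    cc <- vapply(lags, function(l) {
      idx <- (s + l):(s + l + window - 1L)
      ok <- idx >= 1L & idx <= n
      if (sum(ok) < window / 2) return(NA_real_)
      es <- estimated[idx[ok]]
      if (sd(es) == 0 || sd(tr[ok]) == 0) return(NA_real_)
      cor(es, tr[ok])
    }, numeric(1L))
    if (all(is.na(cc))) next
    # ties toward lag 0
    mx <- max(cc, na.rm = TRUE)
    cand <- lags[which(!is.na(cc) & cc >= mx - 1e-12)]
    best_lag[w] <- cand[which.min(abs(cand))]
    best_cor[w] <- mx
  }
  ok <- !is.na(best_lag)
  if (!any(ok))
    return(structure(list(lag = NA_integer_, mode_freq = 0,
                          median_peak_cor = NA_real_, low_confidence = TRUE,
                          per_window = best_lag), class = "tracking_lag"))
  tab <- table(best_lag[ok])
  top <- as.integer(names(tab)[tab == max(tab)])
  lag <- top[which.min(abs(top))]
  mode_freq <- max(tab) / sum(ok)
  med_cor <- median(best_cor[ok])
  structure(list(lag = lag, mode_freq = mode_freq,
                 median_peak_cor = med_cor,
                 low_confidence = (med_cor < 0.5 || mode_freq < 0.4),
                 per_window = best_lag),
            class = "tracking_lag")
}
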