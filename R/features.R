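#' Hjorth mobility and complexity of a signal window
#'
#' With `d` the first differences of `x`, `S0 = sqrt(sum(x^2)/N)`,
#' `S1 = sqrt(sum(d^2)/(N-1))` and `S2 = sqrt(sum((d[j+1]-d[j])^2)/(N-2))`:
#' mobility is `S1/S0` (first-order variation) and complexity is `S2`
#' (second-order variation).
#'
#' @param x Numeric vector, length at least 3.
#' @return `c(mobility=, complexity=)`; mobility is `NA` (flagged missing)
#'   for an all-zero signal.
#' @export
hjorth_params <- function(x) {
  n <- length(x)
  if (n < 3L) .bp_stop("bp_invalid", "need at least 3 samples")
  d <- diff(x)
  s0 <- sqrt(sum(x^2) / n)
  s1 <- sqrt(sum(d^2) / (n - 1L))
  s2 <- sqrt(sum(diff(d)^2) / (n - 2L))
  mob <- if (s0 == 0) NA_real_ else s1 / s0
  c(mobility = mob, complexity = s2)
}

#' Amplitude-histogram entropy
#'
#' The window's amplitude range is split into `M` equal bins; with `p_i` the
#' occupancy fraction of bin `i`, the entropy is `sum(p_i * log(1/p_i))`
#' (natural log, `0 log(1/0) := 0`, summed over all occupied bins). A
#' constant signal has zero range and entropy 0 by convention. The measure is
#' invariant to amplitude scaling because bins are range-relative.
#'
#' @param x Numeric vector.
#' @param M Bin count (default 32).
#' @return Non-negative entropy in nats.
#' @export
amplitude_entropy <- function(x, M = 32L) {
  if (length(x) < M) .bp_stop("bp_invalid", "need at least M samples")
  rng <- range(x)
  if (diff(rng) == 0) return(0)
  bin <- pmin(M, floor((x - rng[1L]) / diff(rng) * M) + 1L)
  p <- tabulate(bin, M) / length(x)
  p <- p[p > 0]
  sum(p * log(1 / p))
}

#' Higuchi fractal dimension
#'
#' Standard Higuchi estimate with `k_max = 8`: average curve lengths `L(k)`
#' over decimated sub-series, slope of `log L(k)` vs `log(1/k)`. Values lie
#' in `[1, 2]` for sampled one-dimensional signals; a straight line gives
#' about 1, white noise approaches 2. Constant signals return 1 by
#' convention; inputs shorter than 32 samples are flagged missing.
#'
#' @param x Numeric vector.
#' @param k_max Maximum decimation step.
#' @return Estimated dimension, or `NA` for too-short input.
#' @export
fractal_dimension <- function(x, k_max = 8L) {
  n <- length(x)
  if (n < 32L) return(NA_real_)
  if (diff(range(x)) == 0) return(1)
  lk <- numeric(k_max)
  for (k in seq_len(k_max)) {
    lm <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      nm <- length(idx)
      if (nm < 2L) { lm[m] <- NA; next }
      lm[m] <- sum(abs(diff(x[idx]))) * (n - 1) / ((nm - 1) * k) / k
    }
    lk[k] <- mean(lm, na.rm = TRUE)
  }
  ok <- lk > 0 & is.finite(lk)
  if (sum(ok) < 2L) return(NA_real_)
  xk <- log(1 / seq_len(k_max)[ok])
  yk <- log(lk[ok])
  sum((xk - mean(xk)) * (yk - mean(yk))) / sum((xk - mean(xk))^2)
}

#' Normalized autocorrelation at the window's center lag
#'
#' The biased autocorrelation estimate `r(k) = sum(x_i x_{i+k}) / sum(x_i^2)`
#' evaluated at lag `k = floor(N/2)` (the "center" of the autocorrelation
#' function; lag 0 is identically 1 and carries no information).
#'
#' @param x Numeric vector, length at least 2.
#' @param lag Lag to evaluate; defaults to `floor(length(x)/2)`.
#' @return Autocorrelation value, or `NA` for a zero-energy signal.
#' @export
autocorr_feature <- function(x, lag = NULL) {
  n <- length(x)
  if (n < 2L) .bp_stop("bp_invalid", "need at least 2 samples")
  if (is.null(lag)) lag <- floor(n / 2)
  e <- sum(x^2)
  if (e == 0) return(NA_real_)
  if (lag == 0L) return(1)
  sum(x[seq_len(n - lag)] * x[seq_len(n - lag) + lag]) / e
}

#' Kaiser-Teager energy vector
#'
#' `KTE_i = s_i^2 - s_{i+1} * s_{i-1}` for interior samples. Scales as the
#' square of the signal amplitude.
#'
#' @param s Numeric vector, length at least 3.
#' @return Numeric vector of length `length(s) - 2`.
#' @export
kaiser_teager_energy <- function(s) {
  n <- length(s)
  if (n < 3L) .bp_stop("bp_invalid", "need at least 3 samples")
  s[2:(n - 1L)]^2 - s[3:n] * s[1:(n - 2L)]
}

#' Spectral entropy of the power distribution
#'
#' Entropy (natural log) of the normalized one-sided FFT power spectrum of
#' the mean-removed signal, excluding the DC bin. Clean quasi-periodic pulses
#' concentrate power in few bins (low entropy); noise spreads it (high).
#'
#' @param x Numeric vector.
#' @return Entropy in nats; `NA` for constant input.
#' @export
spectral_entropy <- function(x) {
  x <- x - mean(x)
  if (all(x == 0)) return(NA_real_)
  P <- Mod(fft(x))^2
  half <- P[2:(floor(length(x) / 2) + 1L)]
  p <- half / sum(half)
  p <- p[p > 0]
  sum(p * log(1 / p))
}

#' Fifth-order autoregressive coefficients (Yule-Walker)
#'
#' Fits `s_t = a1 s_{t-1} + ... + a5 s_{t-5} + e_t` on the mean-removed
#' signal by solving the Yule-Walker equations with biased autocovariances
#' (closed form, deterministic).
#'
#' @param x Numeric vector, length greater than 10.
#' @param order Model order (default 5).
#' @return Coefficient vector `a1..a5`, or `NA`s for (near-)constant input.
#' @export
ar_coefficients <- function(x, order = 5L) {
  n <- length(x)
  if (n <= 2L * order) return(rep(NA_real_, order))
  x <- x - mean(x)
  if (sum(x^2) < 1e-24) return(rep(NA_real_, order))
  acv <- vapply(0:order, function(k)
    sum(x[seq_len(n - k)] * x[seq_len(n - k) + k]) / n, numeric(1L))
  R <- stats::toeplitz(acv[seq_len(order)])
  out <- tryCatch(solve(R, acv[2:(order + 1L)]),
                  error = function(e) rep(NA_real_, order))
  as.numeric(out)
}

#' Per-lead corrected QT interval and T-wave amplitude for a sequence
#'
#' Per beat, QT runs from QRS onset to T end; Bazett's correction
#' (`QTc = QT / sqrt(RR)`, RR in seconds, RR taken to the previous beat, or
#' the following beat for the first one) is applied per beat and the
#' sequence value is the median across beats. T amplitude is the median
#' T-peak amplitude relative to the baseline-corrected signal's zero line.
#'
#' @param fid An `ecg_fiducials` frame for one lead (whole record).
#' @param beat_rows Indices of the rows of `fid` belonging to the sequence.
#' @param fs Sampling rate, Hz.
#' @return `c(qtc=, t_amp=)` in seconds and mV; `NA` when no beat in the
#'   sequence has a resolvable T end.
#' @export
ecg_beat_features <- function(fid, beat_rows, fs = BP_FS) {
  rows <- fid[beat_rows, , drop = FALSE]
  ok <- !is.na(rows$t_end) & !is.na(rows$qrs_onset)
  if (!any(ok)) return(c(qtc = NA_real_, t_amp = NA_real_))
  qtc <- vapply(which(ok), function(i) {
    gi <- beat_rows[i]
    rr <- if (gi > 1L) fid$r_peak[gi] - fid$r_peak[gi - 1L]
          else if (gi < nrow(fid)) fid$r_peak[gi + 1L] - fid$r_peak[gi]
          else NA_integer_
    if (is.na(rr) || rr <= 0) return(NA_real_)
    qt <- (rows$t_end[i] - rows$qrs_onset[i]) / fs
    qt / sqrt(rr / fs)
  }, numeric(1L))
  c(qtc = median(qtc, na.rm = TRUE),
    t_amp = median(rows$t_amp[ok], na.rm = TRUE))
}

#' SpO2 morphology features for a sequence window
#'
#' Four summary statistics (mean, variance, inter-quartile range, skewness)
#' of the Kaiser-Teager energy vector, the spectral entropy of the power
#' distribution, and the five Yule-Walker AR(5) coefficients.
#'
#' @param spo2 SpO2 samples over the sequence extent.
#' @return Named vector `kte_mean, kte_var, kte_iqr, kte_skew,
#'   spectral_entropy, ar1..ar5`.
#' @export
spo2_features <- function(spo2) {
  if (length(spo2) < 10L) .bp_stop("bp_invalid", "need at least 10 samples")
  kte <- kaiser_teager_energy(spo2)
  m2 <- mean((kte - mean(kte))^2)
  skew <- if (m2 > 0) mean((kte - mean(kte))^3) / m2^1.5 else 0
  ar <- ar_coefficients(spo2, 5L)
  c(kte_mean = mean(kte), kte_var = var(kte),
    kte_iqr = unname(quantile(kte, 0.75) - quantile(kte, 0.25)),
    kte_skew = skew,
    spectral_entropy = spectral_entropy(spo2),
    ar1 = ar[1L], ar2 = ar[2L], ar3 = ar[3L], ar4 = ar[4L], ar5 = ar[5L])
}

#' Timing features for a sequence
#'
#' Heart rate = 60 / median RR (median across leads and beats; a single-beat
#' window uses the instantaneous RR to the previous beat); PAT = mean over
#' beats of (SpO2 peak time - R peak time); T2SpO2 = median over beats of the
#' signed delay (SpO2 peak time - T-end time).
#'
#' @param ecg_fids List of 4 `ecg_fiducials`.
#' @param ref_rows Rows of the reference-lead fiducials for the sequence's
#'   beats.
#' @param ref_lead Reference lead index.
#' @param spo2_peaks 0-based SpO2 peak indices matched per beat (`NA`
#'   allowed).
#' @param fs Sampling rate, Hz.
#' @return `c(heart_rate=, pat=, t2spo2=)` in bpm and seconds.
#' @export
timing_features <- function(ecg_fids, ref_rows, ref_lead, spo2_peaks,
                            fs = BP_FS) {
  ref <- ecg_fids[[ref_lead]]
  rr_all <- unlist(lapply(seq_along(ecg_fids), function(l) {
    f <- ecg_fids[[l]]
    rsub <- if (l == ref_lead) ref_rows else {
      # rows of this lead whose R peak matches a sequence beat
      unlist(lapply(ref$r_peak[ref_rows], function(r) {
        j <- which.min(abs(f$r_peak - r))
        if (length(j) && abs(f$r_peak[j] - r) <= round(0.1 * fs)) j else NULL
      }))
    }
    if (length(rsub) == 0L) return(numeric(0))
    prev <- rsub - 1L
    ok <- prev >= 1L
    (f$r_peak[rsub[ok]] - f$r_peak[prev[ok]]) / fs
  }))
  hr <- if (length(rr_all)) 60 / median(rr_all) else NA_real_
  r_t <- ref$r_peak[ref_rows]
  t_e <- ref$t_end[ref_rows]
  ok <- !is.na(spo2_peaks)
  pat <- if (any(ok)) mean((spo2_peaks[ok] - r_t[ok]) / fs) else NA_real_
  ok2 <- ok & !is.na(t_e)
  t2 <- if (any(ok2)) median((spo2_peaks[ok2] - t_e[ok2]) / fs) else NA_real_
  c(heart_rate = hr, pat = pat, t2spo2 = t2)
}

#' Encode demographics into the 7 model entries
#'
#' Gender: 1 = female, 2 = male, `NA` = missing/other. Race: an indicator
#' vector in the fixed order (White, Hispanic, Asian, Black); unknown race is
#' all zeros.
#'
#' @param subject A [subject_info()].
#' @return Named numeric vector of 7 entries (`age`, `bmi`, `gender_code`,
#'   `race_white`, `race_hispanic`, `race_asian`, `race_black`).
#' @export
encode_demographics <- function(subject) {
  g <- switch(ifelse(is.na(subject$gender), "missing", subject$gender),
              female = 1, male = 2, missing = NA_real_)
  race <- c(race_white = 0, race_hispanic = 0, race_asian = 0, race_black = 0)
  if (!is.na(subject$race))
    race[paste0("race_", tolower(subject$race))] <- 1
  c(age = subject$age, bmi = subject$bmi, gender_code = g, race)
}

#' The fixed 48-entry feature schema
#' @return Character vector of the 48 feature names in canonical order.
#' @export
feature_schema <- function() {
  ecg <- as.vector(vapply(1:4, function(l)
    paste0(c("mobility", "complexity", "fractal", "entropy", "autocorr",
             "qtc", "t_amp"), "_l", l), character(7L)))
  c(ecg,
    "kte_mean", "kte_var", "kte_iqr", "kte_skew", "spectral_entropy",
    paste0("ar", 1:5),
    "heart_rate", "pat", "t2spo2",
    "age", "bmi", "gender_code",
    "race_white", "race_hispanic", "race_asian", "race_black")
}

#' Assemble the 48-entry feature vector for one beat sequence
#'
#' Window-level features (Hjorth, fractal dimension, entropy,
#' autocorrelation, SpO2 morphology) are computed over the sequence extent of
#' each channel; beat-level features (QTc, T amplitude, the timing features)
#' are reduced by the rule stated in their computations (medians, mean for
#' PAT). Missing components stay `NA` and propagate to the model layer,
#' where training-set medians impute them. Features are deliberately not
#' normalized.
#'
#' @param record A [waveform_record()].
#' @param delin [delineate_record()] output.
#' @param beats `beat_table`.
#' @param seq_row One row of a `beat_sequences` frame.
#' @param fs Sampling rate, Hz.
#' @return Named numeric vector following [feature_schema()].
#' @export
assemble_feature_vector <- function(record, delin, beats, seq_row,
                                    fs = BP_FS) {
  ks <- seq_row$first_beat:seq_row$last_beat
  ref <- which.max(vapply(delin$ecg, nrow, integer(1L)))
  # map beat rows (beat k uses reference fiducial row k+1; see assemble_beats)
  ref_rows <- ks + 1L
  ecg_lo <- min(beats$ecg_start[ks]) + 1L
  ecg_hi <- max(beats$ecg_end[ks])
  out <- setNames(rep(NA_real_, 48L), feature_schema())
  for (l in 1:4) {
    x <- delin$ecg_bc[ecg_lo:ecg_hi, l]
    hj <- hjorth_params(x)
    out[paste0("mobility_l", l)] <- hj[["mobility"]]
    out[paste0("complexity_l", l)] <- hj[["complexity"]]
    out[paste0("fractal_l", l)] <- fractal_dimension(x)
    out[paste0("entropy_l", l)] <- amplitude_entropy(x)
    out[paste0("autocorr_l", l)] <- autocorr_feature(x)
    f <- delin$ecg[[l]]
    rows <- if (l == ref) ref_rows else {
      unlist(lapply(delin$ecg[[ref]]$r_peak[ref_rows], function(r) {
        j <- which.min(abs(f$r_peak - r))
        if (length(j) && abs(f$r_peak[j] - r) <= round(0.1 * fs)) j else NA_integer_
      }))
    }
    rows <- rows[!is.na(rows)]
    if (length(rows)) {
      eb <- ecg_beat_features(f, rows, fs)
      out[paste0("qtc_l", l)] <- eb[["qtc"]]
      out[paste0("t_amp_l", l)] <- eb[["t_amp"]]
    }
  }
  sp_lo <- min(beats$spo2_start[ks]) + 1L
  sp_hi <- max(beats$spo2_end[ks])
  out[names(spo2_features(record$spo2[sp_lo:sp_hi]))] <-
    spo2_features(record$spo2[sp_lo:sp_hi])
  # per-beat SpO2 peak: the detected pulse peak inside each beat's extent
  spo2_peaks <- vapply(ks, function(k) {
    j <- which(delin$spo2$valley == beats$spo2_start[k])
    if (length(j) == 1L) delin$spo2$peak[j] else NA_integer_
  }, integer(1L))
  out[c("heart_rate", "pat", "t2spo2")] <-
    timing_features(delin$ecg, ref_rows, ref, spo2_peaks, fs)
  out[names(encode_demographics(record$subject))] <-
    encode_demographics(record$subject)
  out
}

#' Feature table for all accepted sequences of a record
#'
#' @param record A [waveform_record()].
#' @param delin [delineate_record()] output.
#' @param beats `beat_table`.
#' @param sequences Output of [gold_standard_bp()] (only `accepted` rows are
#'   featurized).
#' @return Data frame: `subject_id`, `seq_id`, `win_index`, `run`,
#'   `gold_sys`, `gold_dia`, then the 48 feature columns.
#' @export
sequence_features <- function(record, delin, beats, sequences) {
  acc <- sequences[sequences$accepted, , drop = FALSE]
  if (!nrow(acc))
    return(cbind(data.frame(subject_id = character(0), seq_id = integer(0),
                            win_index = integer(0), run = integer(0),
                            gold_sys = numeric(0), gold_dia = numeric(0)),
                 as.data.frame(matrix(numeric(0), 0L, 48L,
                                      dimnames = list(NULL, feature_schema())))))
  fmat <- t(vapply(seq_len(nrow(acc)), function(i)
    assemble_feature_vector(record, delin, beats, acc[i, ], record$fs),
    numeric(48L)))
  cbind(data.frame(subject_id = record$subject_id, seq_id = acc$seq_id,
                   win_index = acc$win_index, run = acc$run,
                   gold_sys = acc$gold_sys, gold_dia = acc$gold_dia),
        as.data.frame(fmat))
}

#' Feature selection
#'
#' Default rule: drop the race indicators (4), gender (1), the per-lead
#' fractal dimensions (4) and the AR coefficients (5), leaving 34 of the 48
#' features — the set found uninformative by out-of-bag importance on the
#' development data. Data-driven mode ranks all features by a fitted forest's
#' OOB permutation importance instead and keeps the top `n_keep`.
#'
#' @param features Feature matrix or data frame with the 48 schema columns
#'   (used for validation; may have zero rows in default mode).
#' @param importance Optional named importance vector (e.g. from
#'   [train_forest()]); when supplied, data-driven ranking is used.
#' @param n_keep Number of features kept in data-driven mode.
#' @return A `selection_report` list: `selected`, `excluded`, `importance`.
#' @export
select_features <- function(features = NULL, importance = NULL,
                            n_keep = 34L) {
  schema <- feature_schema()
  if (!is.null(features)) {
    if (nrow(features) == 0)
      .bp_stop("bp_invalid", "empty feature matrix")
    if (!all(schema %in% colnames(features)))
      .bp_stop("bp_invalid", "feature table does not follow the 48-entry schema")
  }
  if (is.null(importance)) {
    excluded <- c(paste0("fractal_l", 1:4), paste0("ar", 1:5), "gender_code",
                  "race_white", "race_hispanic", "race_asian", "race_black")
    selected <- setdiff(schema, excluded)
    imp <- NULL
  } else {
    o <- order(importance, decreasing = TRUE)
    selected <- names(importance)[o][seq_len(min(n_keep, length(importance)))]
    excluded <- setdiff(schema, selected)
    imp <- importance[o]
  }
  structure(list(selected = selected, excluded = excluded, importance = imp),
            class = "selection_report")
}
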