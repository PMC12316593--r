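#' Remove ECG baseline wander with a two-stage median filter
#'
#' The baseline estimate is a cascade of two running medians: a short kernel
#' (200 ms) that removes the QRS complexes and a long kernel (600 ms) that
#' removes P/T waves, leaving the slow wander, which is then subtracted. The
#' cascade preserves QRS morphology (R amplitude change < 5% on clean beats).
#'
#' @param ecg_lead Numeric vector of one ECG lead.
#' @param fs Sampling rate, Hz.
#' @return Baseline-corrected signal, same length.
#' @export
remove_baseline_wander <- function(ecg_lead, fs = BP_FS) {
  k1 <- .odd(round(0.2 * fs))
  k2 <- .odd(round(0.6 * fs))
  if (length(ecg_lead) <= k2) return(ecg_lead - median(ecg_lead))
  baseline <- runmed(runmed(ecg_lead, k1, endrule = "median"), k2,
                     endrule = "median")
  ecg_lead - as.numeric(baseline)
}

.odd <- function(k) if (k %% 2L == 0L) k + 1L else k

# Windowed-sinc (Hamming) low-pass FIR; `order` taps minus one.
.fir_lowpass <- function(order, fc, fs) {
  n_tap <- order + 1L
  k <- seq_len(n_tap) - 1L - (n_tap - 1L) / 2
  h <- ifelse(k == 0, 2 * fc / fs, sin(2 * pi * fc / fs * k) / (pi * k))
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n_tap) - 1L) / (n_tap - 1L))
  h <- h * w
  h / sum(h)
}

#' Suppress pacemaker spikes for the delineation pass
#'
#' For paced subjects, applies a 51-order low-pass FIR with a 15 Hz cutoff
#' that flattens the narrow pacing artifacts which would otherwise be
#' mistaken for R peaks. The filtered signal is used only for delineation;
#' features are computed on the unfiltered, baseline-corrected signal. For
#' non-paced subjects this is the identity.
#'
#' @param ecg_lead Numeric vector.
#' @param paced Logical pacing flag (from subject metadata, not detection).
#' @param fs Sampling rate, Hz.
#' @return Filtered (or identical) signal, same length, aligned with the
#'   input (linear-phase delay compensated to the nearest sample).
#' @export
suppress_pacing_spikes <- function(ecg_lead, paced, fs = BP_FS) {
  if (!isTRUE(paced)) return(ecg_lead)
  h <- .fir_lowpass(51L, 15, fs)
  .conv_centered(ecg_lead, h)
}

# full convolution, centered on the input (group delay compensated)
.conv_centered <- function(x, h) {
  n <- length(x)
  pad <- length(h)
  xp <- c(rep(x[1L], pad), x, rep(x[n], pad))
  y <- .fft_conv_full(xp, h)
  delay <- floor((length(h) - 1L) / 2) + pad
  y[delay + 1L + seq_len(n) - 1L]
}

# ---------------------------------------------------------------------------
# Dyadic a-trous wavelet details (quadratic-spline derivative bank). At each
# scale the detail behaves like a smoothed derivative of the signal: sharp
# slopes (QRS) dominate low scales, slow waves (T) dominate scale 4. Group
# delays of the dilated filters are compensated so details align with x.
.swt_details <- function(x, n_scales = 4L) {
  h0 <- c(1, 3, 3, 1) / 8
  g0 <- c(2, -2)
  n <- length(x)
  out <- matrix(0, n, n_scales)
  s <- x
  delay_s <- 0
  for (k in seq_len(n_scales)) {
    dil <- 2L^(k - 1L)
    g <- numeric((length(g0) - 1L) * dil + 1L)
    g[seq(1L, length(g), by = dil)] <- g0
    hF <- numeric((length(h0) - 1L) * dil + 1L)
    hF[seq(1L, length(hF), by = dil)] <- h0
    w <- .fft_conv_full(c(s, numeric(length(g))), g)
    dly <- round(delay_s + (length(g) - 1L) / 2)
    idx <- pmin(pmax(seq_len(n) + dly, 1L), length(w))
    out[, k] <- w[idx]
    s <- .fft_conv_full(c(s, numeric(length(hF))), hF)[seq_len(n + dly)]
    delay_s <- delay_s + (length(hF) - 1L) / 2
    s <- s[seq_len(min(length(s), n + ceiling(delay_s)))]
  }
  out
}

.local_extrema <- function(w) {
  n <- length(w)
  if (n < 3L) return(integer(0))
  d <- diff(w)
  which(d[-(n - 1L)] * d[-1L] < 0 | (d[-(n - 1L)] != 0 & d[-1L] == 0)) + 1L
}

#' Wavelet-based ECG delineation
#'
#' Multiscale dyadic-wavelet delineation: R peaks come from opposite-sign
#' modulus-maxima pairs of the scale-2 detail (zero crossing between the
#' pair, refined to the local extremum of the signal), with a 200 ms
#' refractory; QRS onset/offset from the decay of the scale-2 modulus around
#' the QRS; T peak and T end from the scale-4 detail in the post-QRS search
#' window, T end being the point where the post-peak modulus falls below 45%
#' of its maximum (the 2-sigma point for a Gaussian T wave).
#'
#' @param ecg_lead Baseline-corrected ECG lead.
#' @param fs Sampling rate, Hz.
#' @return An `ecg_fiducials` data frame with 0-based sample indices:
#'   columns `beat`, `r_peak`, `qrs_onset`, `qrs_offset`, `t_peak`, `t_end`,
#'   `t_amp` (T columns `NA` when the T wave is not resolvable). Empty (with
#'   a warning) when no beats are found.
#' @export
delineate_ecg <- function(ecg_lead, fs = BP_FS) {
  n <- length(ecg_lead)
  empty <- data.frame(beat = integer(0), r_peak = integer(0),
                      qrs_onset = integer(0), qrs_offset = integer(0),
                      t_peak = integer(0), t_end = integer(0),
                      t_amp = numeric(0))
  class(empty) <- c("ecg_fiducials", "data.frame")
  if (n < fs) {
    .bp_warn("bp_no_beats", "signal too short to delineate")
    return(empty)
  }
  W <- .swt_details(ecg_lead, 4L)
  w2 <- W[, 2L]
  w4 <- W[, 4L]

  # robust QRS threshold: median of per-2s block maxima of |w2|
  blk <- ceiling(seq_along(w2) / (2 * fs))
  seg_max <- tapply(abs(w2), blk, max)
  thr <- max(0.4 * median(seg_max), 0.1 * max(abs(w2)))
  if (!is.finite(thr) || max(abs(w2)) < 1e-9 || thr <= 0) {
    .bp_warn("bp_no_beats", "no QRS-scale activity found")
    return(empty)
  }

  ext <- .local_extrema(w2)
  ext <- ext[abs(w2[ext]) > thr]
  # pair opposite-sign maxima within 80 ms -> zero crossing = R
  r_cand <- integer(0)
  i <- 1L
  max_gap <- round(0.08 * fs)
  while (i < length(ext)) {
    a <- ext[i]; b <- ext[i + 1L]
    if (b - a <= max_gap && sign(w2[a]) != sign(w2[b])) {
      seg <- w2[a:b]
      zc <- which(seg[-length(seg)] * seg[-1L] <= 0)[1L]
      r <- if (is.na(zc)) a + which.min(abs(seg)) - 1L else a + zc - 1L
      r_cand <- c(r_cand, r)
      i <- i + 2L
    } else i <- i + 1L
  }
  if (!length(r_cand)) {
    .bp_warn("bp_no_beats", "no modulus-maxima pairs found")
    return(empty)
  }
  # refine to the signal extremum and apply the refractory period
  half <- round(0.04 * fs)
  r_ref <- vapply(r_cand, function(r) {
    lo <- max(1L, r - half); hi <- min(n, r + half)
    as.integer(lo + which.max(abs(ecg_lead[lo:hi])) - 1L)
  }, integer(1L))
  r_ref <- sort(unique(r_ref))
  refr <- round(0.2 * fs)
  keep <- logical(length(r_ref))
  last <- -Inf
  for (j in seq_along(r_ref)) {
    if (r_ref[j] - last >= refr) { keep[j] <- TRUE; last <- r_ref[j] }
    else if (abs(ecg_lead[r_ref[j]]) > abs(ecg_lead[last])) {
      keep[which(r_ref == last)] <- FALSE
      keep[j] <- TRUE; last <- r_ref[j]
    }
  }
  r_peaks <- r_ref[keep]
  nb <- length(r_peaks)
  if (nb < 2L) .bp_warn("bp_no_beats", "fewer than 2 beats found")

  qrs_on <- qrs_off <- t_peak <- t_end <- rep(NA_integer_, nb)
  t_amp <- rep(NA_real_, nb)
  rr_med <- if (nb > 1L) median(diff(r_peaks)) else round(0.8 * fs)
  srch <- round(0.08 * fs)
  for (j in seq_len(nb)) {
    r <- r_peaks[j]
    # pre-R modulus maximum -> scan back for onset
    lo <- max(1L, r - srch)
    pre <- lo - 1L + which.max(abs(w2[lo:r]))
    pk <- abs(w2[pre])
    k <- pre
    while (k > max(1L, pre - srch) && abs(w2[k]) > 0.05 * pk) k <- k - 1L
    qrs_on[j] <- k
    hi <- min(n, r + srch)
    post <- r - 1L + which.max(abs(w2[r:hi]))
    pk <- abs(w2[post])
    k <- post
    while (k < min(n, post + srch) && abs(w2[k]) > 0.05 * pk) k <- k + 1L
    qrs_off[j] <- k

    # T search window
    rr <- if (j < nb) r_peaks[j + 1L] - r else rr_med
    t_lo <- min(n, qrs_off[j] + round(0.06 * fs))
    t_hi <- min(n, r + round(min(0.6 * rr, 0.55 * fs)))
    if (t_hi - t_lo < round(0.1 * fs)) next
    seg <- w4[t_lo:t_hi]
    e <- .local_extrema(seg)
    e <- e[abs(seg[e]) > 0.15 * max(abs(seg))]
    if (length(e) < 2L) next
    # dominant opposite-sign pair
    o <- order(abs(seg[e]), decreasing = TRUE)
    a <- NULL
    for (ii in o) for (jj in o) {
      if (e[ii] < e[jj] && sign(seg[e[ii]]) != sign(seg[e[jj]])) {
        a <- c(e[ii], e[jj]); break
      }
    }
    if (is.null(a)) next
    zseg <- seg[a[1L]:a[2L]]
    zc <- which(zseg[-length(zseg)] * zseg[-1L] <= 0)[1L]
    if (is.na(zc)) next
    tp <- t_lo + a[1L] - 1L + zc - 1L
    # refine to signal extremum
    h2 <- round(0.03 * fs)
    plo <- max(1L, tp - h2); phi <- min(n, tp + h2)
    tp <- plo + which.max(abs(ecg_lead[plo:phi])) - 1L
    t_peak[j] <- tp
    # T end: post-peak modulus decay below 45% of the second maximum ...
    m2 <- t_lo + a[2L] - 1L
    pk <- abs(w4[m2])
    k <- m2
    lim <- min(n, m2 + round(0.25 * fs))
    while (k < lim && abs(w4[k]) > 0.45 * pk) k <- k + 1L
    # ... refined on the signal: a Gaussian T wave decays to e^-2 of its
    # peak at the 2-sigma point, which the scale-4 smoothing overestimates
    amp <- abs(ecg_lead[tp])
    ref <- which(abs(ecg_lead[tp:min(n, k + 10L)]) <= exp(-2) * amp)[1L]
    t_end[j] <- if (!is.na(ref)) tp + ref - 1L else k
    t_amp[j] <- ecg_lead[tp]
  }
  ok <- !is.na(t_peak) | TRUE  # keep all beats; T columns may be NA
  fid <- data.frame(beat = seq_len(nb), r_peak = r_peaks - 1L,
                    qrs_onset = qrs_on - 1L, qrs_offset = qrs_off - 1L,
                    t_peak = t_peak - 1L, t_end = t_end - 1L,
                    t_amp = t_amp)[ok, ]
  # enforce fiducial ordering; violations invalidate the T columns
  bad <- with(fid, !is.na(t_end) &
                !(qrs_onset < r_peak & r_peak < qrs_offset &
                  qrs_offset <= t_peak & t_peak <= t_end))
  fid$t_peak[bad] <- NA_integer_
  fid$t_end[bad] <- NA_integer_
  fid$t_amp[bad] <- NA_real_
  class(fid) <- c("ecg_fiducials", "data.frame")
  fid
}

#' Slope-sum pulse valley and peak detection for SpO2/ABP
#'
#' Applies the slope-sum function (windowed sum of positive first
#' differences, 128 ms window) twice, detects pulse onsets from adaptive
#' threshold crossings of the enhanced slope signal (threshold initialized
#' from the first 10 s, 200 ms refractory, exponentially updated per beat),
#' then places each valley at the signal minimum immediately preceding the
#' onset and records the extreme amplitudes between consecutive valleys.
#'
#' @param pulse Numeric vector (SpO2 or ABP).
#' @param fs Sampling rate, Hz.
#' @return A `pulse_fiducials` data frame with 0-based columns `beat`,
#'   `valley`, `peak`, `min_amp`, `max_amp`; one row per beat between
#'   consecutive valleys. Fewer than 2 valleys yields an empty frame with an
#'   `insufficient-pulses` warning.
#' @export
detect_pulse_valleys <- function(pulse, fs = BP_FS) {
  n <- length(pulse)
  empty <- data.frame(beat = integer(0), valley = integer(0),
                      peak = integer(0), min_amp = numeric(0),
                      max_amp = numeric(0))
  class(empty) <- c("pulse_fiducials", "data.frame")
  w <- round(0.128 * fs)
  ssf_once <- function(x) {
    d <- pmax(diff(x), 0)
    c(0, as.numeric(stats::filter(d, rep(1, w), sides = 1)))
  }
  s1 <- ssf_once(pulse)
  s1[is.na(s1)] <- 0
  s2 <- ssf_once(s1)
  s2[is.na(s2)] <- 0
  init <- s2[seq_len(min(n, 10L * fs))]
  base <- quantile(init, 0.98, names = FALSE)
  if (!is.finite(base) || base <= 1e-12) {
    .bp_warn("bp_insufficient_pulses", "no pulsatile activity found")
    return(empty)
  }
  thr <- 0.25 * base
  refr <- round(0.2 * fs)
  onsets <- integer(0)
  ema <- base
  i <- 2L
  while (i <= n) {
    if (s2[i] > thr && s2[i - 1L] <= thr) {
      hi <- min(n, i + refr)
      loc_pk <- max(s2[i:hi])
      onsets <- c(onsets, i)
      ema <- 0.875 * ema + 0.125 * loc_pk
      thr <- 0.25 * ema
      i <- i + refr
    } else i <- i + 1L
  }
  if (length(onsets) < 2L) {
    .bp_warn("bp_insufficient_pulses", "fewer than 2 pulse onsets detected")
    return(empty)
  }
  back <- round(0.15 * fs); fwd <- round(0.05 * fs)
  valleys <- vapply(onsets, function(o) {
    lo <- max(1L, o - back); hi <- min(n, o + fwd)
    seg <- pulse[lo:hi]
    # rightmost minimum: robust when the pulse sits on a flat stretch
    as.integer(lo + max(which(seg <= min(seg) + 1e-12)) - 1L)
  }, integer(1L))
  valleys <- sort(unique(valleys))
  if (length(valleys) < 2L) {
    .bp_warn("bp_insufficient_pulses", "fewer than 2 valleys detected")
    return(empty)
  }
  nb <- length(valleys) - 1L
  peak <- integer(nb); min_amp <- max_amp <- numeric(nb)
  for (k in seq_len(nb)) {
    seg <- valleys[k]:(valleys[k + 1L] - 1L)
    peak[k] <- seg[which.max(pulse[seg])]
    min_amp[k] <- min(pulse[seg])
    max_amp[k] <- max(pulse[seg])
  }
  fid <- data.frame(beat = seq_len(nb), valley = valleys[-length(valleys)] - 1L,
                    peak = peak - 1L, min_amp = min_amp, max_amp = max_amp)
  class(fid) <- c("pulse_fiducials", "data.frame")
  fid
}

#' Delineate all six channels of a record
#'
#' Convenience wrapper: baseline-corrects each ECG lead (plus the pacing
#' filter for paced subjects, used for the delineation pass only), runs
#' [delineate_ecg()] per lead and [detect_pulse_valleys()] on SpO2 and ABP.
#'
#' @param record A [waveform_record()] at 250 Hz.
#' @return A list with `ecg` (list of 4 `ecg_fiducials`), `spo2`, `abp`
#'   (`pulse_fiducials`) and `ecg_bc` (the baseline-corrected leads used for
#'   feature extraction).
#' @export
delineate_record <- function(record) {
  stopifnot(inherits(record, "waveform_record"))
  fs <- record$fs
  ecg_bc <- apply(record$ecg, 2L, remove_baseline_wander, fs = fs)
  ecg_del <- if (record$paced)
    apply(ecg_bc, 2L, suppress_pacing_spikes, paced = TRUE, fs = fs)
  else ecg_bc
  ecg_f <- lapply(seq_len(4L), function(j) delineate_ecg(ecg_del[, j], fs))
  list(ecg = ecg_f,
       spo2 = detect_pulse_valleys(record$spo2, fs),
       abp = detect_pulse_valleys(record$abp, fs),
       ecg_bc = ecg_bc)
}
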