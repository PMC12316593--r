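#' Simulation configuration
#'
#' Describes a synthetic ICU-style cohort: heart-rate dynamics, programmed
#' systolic/diastolic trajectories, the mapping from blood pressure to pulse
#' arrival time (PAT) and pulse amplitude, noise injection probabilities and
#' the pacing fraction. The generator exists because the source ICU waveform
#' data is private; it produces records whose timing and amplitude structure
#' carry a recoverable BP signal, with exact ground truth for every fiducial.
#'
#' The PAT model is `PAT_ms = a - b * (systolic - 120)` with `b > 0`, i.e. the
#' inverse PAT-BP relationship the estimation method relies on; each subject
#' gets an idiosyncratic intercept `a_s ~ N(a, pat_a_sd)`, which is what makes
#' subject-specific calibration genuinely informative. Beat-level gold
#' pressures are the smooth programmed trajectory plus independent
#' `N(0, bp_beat_noise_sd)` jitter that no feature can explain, so the
#' simulator has a known irreducible error floor.
#'
#' @param n_subjects Number of subjects.
#' @param duration_s Seconds of signal per subject.
#' @param fs Sampling rate (Hz); records are generated directly at 250 Hz.
#' @param hr_base_range Baseline heart-rate range (bpm); each subject draws
#'   uniformly from it.
#' @param hr_resp_amp_bpm Amplitude of the sinusoidal respiratory modulation
#'   of heart rate (bpm).
#' @param hr_resp_freq_hz Respiratory modulation frequency (Hz).
#' @param rr_jitter_sd Multiplicative white jitter SD on each RR interval.
#' @param sys_base Population systolic baseline (mmHg).
#' @param sys_age_slope Added mmHg per year of age above 60 (mild, keeps age
#'   an informative feature).
#' @param subject_offset_sd SD of the per-subject systolic offset (mmHg).
#' @param drift_amp Amplitude of slow sinusoidal systolic drift (mmHg).
#' @param drift_period_s Period of the drift (s).
#' @param bp_step A `list(time_s=, delta=)` step-change schedule applied to
#'   the systolic trajectory, or `NULL`.
#' @param bp_beat_noise_sd Beat-level gold-pressure jitter SD (mmHg).
#' @param pp_base Pulse pressure at systolic 120 (mmHg).
#' @param pp_slope Pulse-pressure increase per mmHg of systolic above 120.
#' @param pat_a Population PAT intercept at systolic 120 (ms).
#' @param pat_a_sd Between-subject SD of the PAT intercept (ms).
#' @param pat_b PAT decrease per mmHg of systolic (ms/mmHg).
#' @param abp_delay_ms Delay from the R peak to the ABP beat valley (ms).
#' @param spo2_baseline SpO2 valley level (%).
#' @param spo2_amp_base,spo2_amp_slope SpO2 pulse amplitude at pulse pressure
#'   40 mmHg and its slope per mmHg of pulse pressure (amplitude tied to
#'   pulse pressure).
#' @param noise_mix Named per-type probabilities in `[0,1]` that a given
#'   channel/4-s window is injected with each of the four noise classes
#'   (`loose_lead`, `baseline_wander`, `hf_jitter`, `flat_saturation`).
#' @param pace_fraction Fraction of subjects flagged as paced (pacing spikes
#'   added to their ECG).
#' @param seed RNG seed. All randomness flows from it through a per-subject
#'   counter-based split, so cohorts are reproducible subject by subject.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 20L, duration_s = 300,
                              fs = BP_FS,
                              hr_base_range = c(60, 90),
                              hr_resp_amp_bpm = 2.5, hr_resp_freq_hz = 0.25,
                              rr_jitter_sd = 0.01,
                              sys_base = 120, sys_age_slope = 0.15,
                              subject_offset_sd = 10,
                              drift_amp = 10, drift_period_s = 240,
                              bp_step = NULL, bp_beat_noise_sd = 2,
                              pp_base = 42, pp_slope = 0.25,
                              pat_a = 220, pat_a_sd = 4, pat_b = 0.8,
                              abp_delay_ms = 120,
                              spo2_baseline = 96,
                              spo2_amp_base = 1.5, spo2_amp_slope = 0.03,
                              noise_mix = c(loose_lead = 0, baseline_wander = 0,
                                            hf_jitter = 0, flat_saturation = 0),
                              pace_fraction = 0, seed = 1L) {
  stopifnot(n_subjects >= 0, duration_s > 0, fs > 0, pat_b >= 0,
            pace_fraction >= 0, pace_fraction <= 1)
  nm <- c("loose_lead", "baseline_wander", "hf_jitter", "flat_saturation")
  mix <- setNames(rep(0, 4L), nm)
  if (length(noise_mix)) mix[names(noise_mix)] <- noise_mix
  if (any(mix < 0 | mix > 1))
    .bp_stop("bp_invalid", "noise_mix probabilities must be in [0,1]")
  structure(as.list(environment()), class = "simulation_config")
}

# counter-based per-subject seed split (kept below 2^31)
.subject_seed <- function(seed, i) {
  (as.double(seed) * 1000003 + i * 7919) %% 2147483629
}

.with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Gaussian bump helper: adds amp * exp(-(t - mu)^2 / (2 sd^2)) to sig over a
# bounded support (+-4 sd), in place via index arithmetic.
.add_gauss <- function(sig, center_idx, sd_samp, amp) {
  half <- ceiling(4 * sd_samp)
  lo <- max(1L, center_idx - half); hi <- min(length(sig), center_idx + half)
  if (lo > hi) return(sig)
  k <- lo:hi
  sig[k] <- sig[k] + amp * exp(-((k - center_idx)^2) / (2 * sd_samp^2))
  sig
}

# per-lead ECG morphology: amplitudes in mV; the 4th lead is the precordial
# one, with a distinct (deeper S, taller R/T) morphology.
.lead_morphology <- function() {
  list(
    scale = c(0.8, 1.0, 0.6, 1.4),
    t_rel = c(0.30, 0.30, 0.30, 0.36),
    s_rel = c(-0.15, -0.15, -0.15, -0.25))
}

# timing constants (seconds relative to the R peak)
.ECG_T <- list(p_mu = -0.20, p_sd = 0.025, p_amp = 0.10,
               q_mu = -0.028, q_sd = 0.008, q_amp = -0.10,
               r_sd = 0.010,
               s_mu = 0.028, s_sd = 0.008,
               t_mu = 0.26, t_sd = 0.04)

#' Simulate one subject's six-channel record with exact ground truth
#'
#' Builds ECG beats from Gaussian P-QRS-T templates (per-lead amplitude
#' scaling, distinct precordial morphology), an asymmetric ABP pulse that
#' touches the programmed diastolic value at each valley sample and the
#' systolic value at each peak sample exactly, and an SpO2 pulse delayed by
#' the programmed PAT after the R peak with amplitude tied to pulse pressure.
#' All fiducials are snapped to the sample grid and recorded in the returned
#' ground truth. Ground-truth T-end is defined as the 2-sigma point of the
#' Gaussian T wave.
#'
#' @param config A [simulation_config()].
#' @param subject_index 1-based subject index within the cohort.
#' @return A list with elements `record` (a [waveform_record()]) and `truth`
#'   (class `bp_ground_truth`: `$beats` beat table with 0-based sample
#'   indices, `$noise` window-label table, `$params` realized subject
#'   parameters).
#' @export
simulate_subject_record <- function(config, subject_index = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(.subject_seed(config$seed, subject_index), {
    fs <- config$fs
    n <- round(config$duration_s * fs)
    if (config$duration_s < 2)
      .bp_stop("bp_invalid", "duration too short for a single beat")

    ## --- demographics -----------------------------------------------------
    age <- round(runif(1, 20, 90))
    bmi <- round(runif(1, 16, 45), 1)
    gender <- sample(c("female", "male", NA), 1, prob = c(0.35, 0.6, 0.05))
    race <- sample(c("White", "Hispanic", "Asian", "Black", NA), 1,
                   prob = c(0.65, 0.08, 0.05, 0.07, 0.15))
    paced <- runif(1) < config$pace_fraction

    ## --- subject-level parameters ----------------------------------------
    hr_base <- runif(1, config$hr_base_range[1], config$hr_base_range[2])
    sys_off <- rnorm(1, 0, config$subject_offset_sd)
    a_s <- rnorm(1, config$pat_a, config$pat_a_sd)
    drift_phase <- runif(1, 0, 2 * pi)

    ## --- beat times -------------------------------------------------------
    r_t <- numeric(0)
    t_cur <- 0.6
    margin <- 0.8
    while (TRUE) {
      hr_t <- hr_base + config$hr_resp_amp_bpm *
        sin(2 * pi * config$hr_resp_freq_hz * t_cur)
      rr <- (60 / hr_t) * (1 + rnorm(1, 0, config$rr_jitter_sd))
      rr <- max(rr, 0.3)
      if (t_cur + rr > config$duration_s - margin) break
      r_t <- c(r_t, t_cur)
      t_cur <- t_cur + rr
    }
    if (length(r_t) < 2L)
      .bp_stop("bp_invalid", "duration too short for one beat")
    r_idx <- round(r_t * fs)
    nb <- length(r_idx)

    ## --- programmed pressures --------------------------------------------
    sys_smooth <- config$sys_base + config$sys_age_slope * (age - 60) +
      sys_off + config$drift_amp *
        sin(2 * pi * r_t / config$drift_period_s + drift_phase)
    if (!is.null(config$bp_step))
      sys_smooth <- sys_smooth +
        config$bp_step$delta * (r_t >= config$bp_step$time_s)
    pp <- pmax(25, config$pp_base + config$pp_slope * (sys_smooth - 120))
    sys_k <- sys_smooth + rnorm(nb, 0, config$bp_beat_noise_sd)
    dia_k <- sys_smooth - pp + rnorm(nb, 0, config$bp_beat_noise_sd)
    dia_k <- pmin(dia_k, sys_k - 10)  # pulse-pressure floor
    pat_ms <- pmin(400, pmax(80, a_s - config$pat_b * (sys_smooth - 120)))

    ## --- ECG --------------------------------------------------------------
    mor <- .lead_morphology()
    tm <- .ECG_T
    ecg <- matrix(0, n, 4L)
    for (lead in 1:4) {
      sig <- numeric(n)
      sc <- mor$scale[lead]
      for (k in seq_len(nb)) {
        c0 <- r_idx[k] + 1L  # 1-based center of R
        sig <- .add_gauss(sig, c0 + round(tm$p_mu * fs), tm$p_sd * fs,
                          tm$p_amp * sc)
        sig <- .add_gauss(sig, c0 + round(tm$q_mu * fs), tm$q_sd * fs,
                          tm$q_amp * sc)
        sig <- .add_gauss(sig, c0, tm$r_sd * fs, 1.0 * sc)
        sig <- .add_gauss(sig, c0 + round(tm$s_mu * fs), tm$s_sd * fs,
                          mor$s_rel[lead] * sc)
        sig <- .add_gauss(sig, c0 + round(tm$t_mu * fs), tm$t_sd * fs,
                          mor$t_rel[lead] * sc)
      }
      if (paced) {
        spike_idx <- r_idx + 1L + round(tm$q_mu * fs) - 8L
        ok <- spike_idx >= 1L & spike_idx <= n
        sig[spike_idx[ok]] <- sig[spike_idx[ok]] + 4.0
      }
      ecg[, lead] <- sig
    }

    ## --- SpO2 -------------------------------------------------------------
    p_k <- r_idx + round(pat_ms * fs / 1000)
    rr_k <- c(diff(r_idx), round(fs * 60 / hr_base))
    # rise time bounded by PAT so the pulse foot always follows the R peak
    v_k <- p_k - round(pmin(0.15 * rr_k, 0.6 * (p_k - r_idx)))
    amp_k <- config$spo2_amp_base + config$spo2_amp_slope * (pp - 40)
    spo2 <- rep(config$spo2_baseline, n)
    for (k in seq_len(nb)) {
      a <- v_k[k] + 1L; b <- p_k[k] + 1L
      e <- if (k < nb) v_k[k + 1L] + 1L else min(n, b + rr_k[k])
      if (a < 1L || e > n || b <= a || e <= b) next
      up <- a:b
      spo2[up] <- config$spo2_baseline +
        amp_k[k] * 0.5 * (1 - cos(pi * (up - a) / (b - a)))
      dn <- (b + 1L):e
      spo2[dn] <- config$spo2_baseline +
        amp_k[k] * 0.5 * (1 + cos(pi * (dn - b) / (e - b)))
    }

    ## --- ABP --------------------------------------------------------------
    av_k <- r_idx + round(config$abp_delay_ms * fs / 1000)
    ap_k <- av_k + round(0.30 * rr_k)
    abp <- rep(mean(dia_k), n)
    abp[seq_len(min(n, av_k[1L]))] <- dia_k[1L]
    for (k in seq_len(nb)) {
      a <- av_k[k] + 1L; b <- ap_k[k] + 1L
      e <- if (k < nb) av_k[k + 1L] + 1L else min(n, b + rr_k[k])
      if (a < 1L || e > n || b <= a || e <= b) next
      up <- a:b
      abp[up] <- dia_k[k] + (sys_k[k] - dia_k[k]) *
        0.5 * (1 - cos(pi * (up - a) / (b - a)))
      dn <- (b + 1L):e
      # decay back toward this beat's diastolic; the next beat overwrites
      # from its own valley sample onward
      abp[dn] <- dia_k[k] + (sys_k[k] - dia_k[k]) *
        0.5 * (1 + cos(pi * (dn - b) / (e - b)))
      if (k == nb && e < n) abp[(e + 1L):n] <- abp[e]
    }

    ## --- keep only beats fully inside the record --------------------------
    t_peak_idx <- r_idx + round(tm$t_mu * fs)
    t_end_idx <- t_peak_idx + round(2 * tm$t_sd * fs)
    qrs_on_idx <- r_idx + round(tm$q_mu * fs) - round(2 * tm$q_sd * fs)
    qrs_off_idx <- r_idx + round(tm$s_mu * fs) + round(2 * tm$s_sd * fs)
    keep <- v_k >= 0 & t_end_idx < n & av_k >= 0 &
      c(av_k[-1L], n) < n & p_k < n
    beats <- data.frame(
      beat = seq_len(sum(keep)),
      r_idx = r_idx[keep], qrs_on = qrs_on_idx[keep],
      qrs_off = qrs_off_idx[keep], t_peak = t_peak_idx[keep],
      t_end = t_end_idx[keep],
      spo2_valley = v_k[keep], spo2_peak = p_k[keep],
      abp_valley = av_k[keep], abp_peak = ap_k[keep],
      sys = sys_k[keep], dia = dia_k[keep], pat_ms = pat_ms[keep])

    record <- waveform_record(
      subject_id = sprintf("S%03d", subject_index), fs = fs, ecg = ecg,
      spo2 = spo2, abp = abp,
      subject = subject_info(age, bmi, gender, race), paced = paced)

    ## --- noise injection --------------------------------------------------
    noise_labels <- .empty_noise_labels(record)
    mix <- config$noise_mix
    if (any(mix > 0)) {
      chans <- names(record_channels(record))
      starts <- .window_starts(n, fs)
      for (ci in seq_along(chans)) {
        for (ws in starts) {
          for (ty in names(mix)) {
            if (mix[[ty]] > 0 && runif(1) < mix[[ty]]) {
              inj <- inject_noise(record, ty, channel = ci,
                                  span = c(ws, min(n, ws + 4L * fs)),
                                  seed = sample.int(2^30, 1L))
              record <- inj$record
              noise_labels <- .merge_noise_labels(noise_labels, inj$labels)
            }
          }
        }
      }
    }

    truth <- structure(list(beats = beats, noise = noise_labels,
                            params = list(hr_base = hr_base, sys_off = sys_off,
                                          pat_a = a_s, paced = paced)),
                       class = "bp_ground_truth")
    list(record = record, truth = truth)
  })
}

.window_starts <- function(n, fs = BP_FS) {
  len <- 4L * fs; stride <- round(3.5 * fs)
  if (n < len) return(integer(0))
  seq(0L, n - len, by = stride)
}

.empty_noise_labels <- function(record) {
  n <- record_length(record)
  starts <- .window_starts(n, record$fs)
  chans <- names(record_channels(record))
  if (!length(starts))
    return(data.frame(channel = character(0), start = integer(0),
                      noisy = logical(0)))
  data.frame(channel = rep(chans, each = length(starts)),
             start = rep(starts, times = length(chans)),
             noisy = FALSE)
}

.merge_noise_labels <- function(base, extra) {
  key_b <- paste(base$channel, base$start)
  key_e <- paste(extra$channel[extra$noisy], extra$start[extra$noisy])
  base$noisy <- base$noisy | key_b %in% key_e
  base
}

#' Simulate a cohort of subjects
#'
#' Subjects draw distinct demographics (age 20-90, BMI 16-45) and distinct
#' subject-level systolic offsets and PAT intercepts, so subject-specific
#' modeling is meaningful. Reproducible under the config seed regardless of
#' generation order (counter-based per-subject seeds).
#'
#' @param config A [simulation_config()] with `n_subjects >= 1`.
#' @return A list of `n_subjects` elements, each `list(record, truth)`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_subjects < 1L)
    .bp_stop("bp_invalid", "n_subjects must be >= 1")
  lapply(seq_len(config$n_subjects),
         function(i) simulate_subject_record(config, i))
}

#' Inject one of the four artifact classes into a record
#'
#' Modifies only the selected channel over the selected span and returns the
#' affected 4-s quality-window labels. The four classes mirror the artifact
#' taxonomy seen in ICU telemetry: large transients from loose lead contact,
#' large-amplitude baseline wander below 0.8 Hz, broadband high-frequency
#' jitter, and flat segments / rail saturation.
#'
#' @param record A [waveform_record()].
#' @param noise_type One of `"loose_lead"`, `"baseline_wander"`,
#'   `"hf_jitter"`, `"flat_saturation"`.
#' @param channel Channel index 1-6 or name (`ecg_<lead>`, `"spo2"`, `"abp"`).
#' @param span Two-element 0-based half-open sample interval `[start, end)`.
#' @param seed RNG seed for the noise realization.
#' @param snr_db Target SNR for `hf_jitter` (dB).
#' @return `list(record, labels)` where `labels` marks every 4-s window of
#'   the affected channel overlapping the span as noisy.
#' @export
inject_noise <- function(record, noise_type, channel, span, seed = 1L,
                         snr_db = 0) {
  types <- c("loose_lead", "baseline_wander", "hf_jitter", "flat_saturation")
  if (!noise_type %in% types)
    .bp_stop("bp_invalid", "unknown noise_type '%s'", noise_type)
  chans <- names(record_channels(record))
  if (is.character(channel)) channel <- match(channel, chans)
  if (is.na(channel) || channel < 1L || channel > 6L)
    .bp_stop("bp_invalid", "channel must identify one of the 6 channels")
  n <- record_length(record)
  span <- as.integer(span)
  if (span[1] < 0L || span[2] > n || span[2] <= span[1])
    .bp_stop("bp_invalid", "span must lie within the record")
  idx <- (span[1] + 1L):span[2]
  fs <- record$fs

  x <- record_channels(record)[[channel]]
  seg <- x[idx]
  p2p <- diff(range(seg))
  if (p2p == 0) p2p <- max(abs(seg), 1)

  .with_seed(seed, {
    seg2 <- switch(noise_type,
      loose_lead = {
        n_ev <- max(1L, round(length(idx) / fs))
        pos <- sort(sample.int(length(idx), n_ev))
        out <- seg
        for (p in pos) {
          dur <- round(runif(1, 0.08, 0.3) * fs)
          amp <- sample(c(-1, 1), 1) * runif(1, 4, 10) * p2p
          k <- p:min(length(idx), p + dur)
          out[k] <- out[k] + amp * exp(-(k - p) / (0.06 * fs))
        }
        out
      },
      baseline_wander = {
        f <- runif(1, 0.15, 0.6)
        a <- runif(1, 2.5, 5) * p2p
        tt <- (idx - 1L) / fs
        seg + a * sin(2 * pi * f * tt + runif(1, 0, 2 * pi))
      },
      hf_jitter = {
        rms <- sqrt(mean((seg - mean(seg))^2))
        if (rms == 0) rms <- p2p / 4
        seg + rnorm(length(seg), 0, rms / 10^(snr_db / 20))
      },
      flat_saturation = {
        if (runif(1) < 0.5) rep(seg[1L], length(seg))
        else {
          rail <- switch(channel_kinds(record)[[channel]],
                         spo2 = 100, abp = 250, ecg = max(seg) + 0.5 * p2p)
          rep(rail, length(seg))
        }
      })
    x[idx] <- seg2
  })

  if (channel <= 4L) record$ecg[, channel] <- x
  else if (channel == 5L) record$spo2 <- x
  else record$abp <- x

  starts <- .window_starts(n, fs)
  affected <- starts < span[2] & (starts + 4L * fs) > span[1]
  labels <- data.frame(channel = chans[channel], start = starts,
                       noisy = affected)
  list(record = record, labels = labels)
}
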