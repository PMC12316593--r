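#' Segment a record into 4-s quality windows
#'
#' Windows are 4 s long (1000 samples at 250 Hz) with 0.5 s overlap, i.e.
#' consecutive starts 3.5 s apart; the trailing partial window is dropped.
#'
#' @param record A [waveform_record()] at 250 Hz.
#' @return Data frame with one row per (channel, window): `channel`, `kind`,
#'   `start` (0-based sample index). Empty, with a warning, for records
#'   shorter than 4 s.
#' @export
segment_quality_windows <- function(record) {
  stopifnot(inherits(record, "waveform_record"))
  n <- record_length(record)
  starts <- .window_starts(n, record$fs)
  kinds <- channel_kinds(record)
  if (!length(starts)) {
    .bp_warn("bp_short_record", "record shorter than 4 s; no quality windows")
    return(data.frame(channel = character(0), kind = character(0),
                      start = integer(0)))
  }
  data.frame(channel = rep(names(kinds), each = length(starts)),
             kind = rep(unname(kinds), each = length(starts)),
             start = rep(starts, times = length(kinds)))
}

#' Extract the samples of one quality window
#' @param record A [waveform_record()].
#' @param channel Channel name or index.
#' @param start 0-based start sample.
#' @return Numeric vector of `4 * fs` samples.
#' @export
window_samples <- function(record, channel, start) {
  x <- record_channels(record)[[channel]]
  len <- 4L * record$fs
  if (start < 0L || start + len > length(x))
    .bp_stop("bp_index", "window [%d, %d) outside record", start, start + len)
  x[(start + 1L):(start + len)]
}

#' Hard artifact screens for one window
#'
#' Rule-based screens applied before any classifier: `flat_flag` is raised by
#' any run of at least 0.5 s of identical samples (within one quantization
#' step) or samples pinned at a physiological rail; `range_flag` by any SpO2
#' sample outside 0-100% or ABP sample outside 0-250 mmHg. Either flag makes
#' the window noisy outright and the classifier is skipped.
#'
#' @param window Numeric vector of window samples.
#' @param channel_kind `"ecg"`, `"spo2"` or `"abp"`.
#' @param fs Sampling rate, Hz.
#' @return Named logical vector `c(flat_flag=, range_flag=)`.
#' @export
screen_hard_artifacts <- function(window, channel_kind = c("ecg", "spo2", "abp"),
                                  fs = BP_FS) {
  channel_kind <- match.arg(channel_kind)
  run_thr <- round(0.5 * fs)
  tol <- max(diff(range(window)) * 1e-9, 1e-12)
  flat_same <- abs(diff(window)) <= tol
  rail <- switch(channel_kind,
                 spo2 = window >= 100 | window <= 0,
                 abp = window >= 250 | window <= 0,
                 ecg = rep(FALSE, length(window)))
  pinned <- flat_same | (rail[-1L] & rail[-length(rail)])
  r <- rle(pinned)
  flat_flag <- any(r$lengths[r$values] + 1L >= run_thr)
  range_flag <- switch(channel_kind,
                       spo2 = any(window < 0 | window > 100),
                       abp = any(window < 0 | window > 250),
                       ecg = FALSE)
  c(flat_flag = flat_flag, range_flag = range_flag)
}

#' Periodicity measure of an RR-interval vector
#'
#' `PM = 100 - 100 * sd(I) / mean(I)`, where `sd` is the sample standard
#' deviation. 100 means perfectly regular intervals; larger variability
#' lowers the score (it can go negative for grossly irregular input). The
#' measure is invariant to rescaling all intervals by a positive constant.
#'
#' @param rr_intervals Numeric vector of at least 2 R-R durations.
#' @return Scalar score, at most 100.
#' @export
periodicity_measure <- function(rr_intervals) {
  if (length(rr_intervals) < 2L)
    .bp_stop("bp_insufficient_beats", "need at least 2 R-R intervals")
  m <- mean(rr_intervals)
  if (m == 0) .bp_stop("bp_invalid", "mean R-R interval is zero")
  100 - 100 * sd(rr_intervals) / m
}

# simple peak detector used only to feed SQI features; not the delineator
.sqi_peaks <- function(window, kind, fs = BP_FS) {
  n <- length(window)
  z <- window - runmed(window, .odd(round(0.4 * fs)), endrule = "median")
  if (kind != "ecg") z <- window - min(window)
  top <- max(z)
  if (top <= 0) return(integer(0))
  thr <- 0.5 * top
  cand <- which(z > thr)
  cand <- cand[c(TRUE, diff(cand) > 1L)]
  refr <- round(0.25 * fs)
  peaks <- integer(0)
  for (s in cand) {
    hi <- min(n, s + refr)
    p <- s + which.max(z[s:hi]) - 1L
    if (!length(peaks) || p - peaks[length(peaks)] >= refr)
      peaks <- c(peaks, p)
  }
  peaks
}

#' Hand-engineered quality features for one window
#'
#' Six scalar signal-quality indices: the periodicity measure of the R-R (or
#' pulse-to-pulse) intervals; the mean Pearson correlation of consecutive
#' 120 ms QRS snippets; the maximum normalized spectral energy above 12 Hz
#' (Hann-windowed periodogram, normalized by total window energy); sharpness
#' `(2/pi) * atan(S_bar)` where `S_bar` is the mean over beats of the largest
#' absolute first difference within 60 ms of the peak, normalized by the
#' beat's peak-to-peak amplitude; and two amplitude-consistency scores
#' `1 - sd/mean` over the per-beat peak-to-peak amplitudes (`dp_stability`)
#' and the peak heights (`peak_stability`). Beat-dependent features are `NA`
#' when fewer than 2 peaks are supplied.
#'
#' @param window Numeric vector of window samples.
#' @param r_peaks Sorted 0-based peak indices inside the window.
#' @param fs Sampling rate, Hz.
#' @return Named numeric vector with elements `pm`, `corr_measure`, `e12`,
#'   `sharpness`, `dp_stability`, `peak_stability`.
#' @export
sqi_features <- function(window, r_peaks, fs = BP_FS) {
  n <- length(window)
  r1 <- as.integer(r_peaks) + 1L  # to 1-based
  if (length(r1) && (min(r1) < 1L || max(r1) > n))
    .bp_stop("bp_index", "r_peaks outside window")
  nb <- length(r1)
  out <- c(pm = NA_real_, corr_measure = NA_real_, e12 = NA_real_,
           sharpness = NA_real_, dp_stability = NA_real_,
           peak_stability = NA_real_)

  ## spectral feature needs no beats
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
  xw <- (window - mean(window)) * hann
  P <- Mod(fft(xw))^2
  half <- P[seq_len(floor(n / 2) + 1L)]
  tot <- sum(half)
  if (tot > 0) {
    freq <- (seq_along(half) - 1L) * fs / n
    out["e12"] <- max(half[freq >= 12] / tot)
  }
  if (nb >= 3L)
    out["pm"] <- periodicity_measure(diff(r1))
  if (nb < 2L) return(out)

  ## consecutive-QRS correlation, 120 ms snippets centred on the peak
  hw <- round(0.06 * fs)
  snips <- lapply(r1, function(r) {
    if (r - hw < 1L || r + hw > n) return(NULL)
    window[(r - hw):(r + hw)]
  })
  snips <- Filter(Negate(is.null), snips)
  if (length(snips) >= 2L) {
    cors <- vapply(seq_len(length(snips) - 1L), function(i) {
      a <- snips[[i]]; b <- snips[[i + 1L]]
      if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
      cor(a, b)
    }, numeric(1L))
    out["corr_measure"] <- mean(cors, na.rm = TRUE)
  }

  ## per-beat regions bounded by midpoints between consecutive peaks
  mids <- floor((r1[-nb] + r1[-1L]) / 2)
  bounds <- c(1L, mids, n)
  steep <- dp <- numeric(nb)
  for (k in seq_len(nb)) {
    reg <- bounds[k]:bounds[k + 1L]
    p2p <- diff(range(window[reg]))
    dp[k] <- p2p
    lo <- max(1L, r1[k] - round(0.06 * fs))
    hi <- min(n, r1[k] + round(0.06 * fs))
    steep[k] <- if (p2p > 0) max(abs(diff(window[lo:hi]))) / p2p else 0
  }
  out["sharpness"] <- (2 / pi) * atan(mean(steep))
  if (mean(dp) > 0) out["dp_stability"] <- 1 - sd(dp) / mean(dp)
  hts <- window[r1]
  if (mean(hts) != 0) out["peak_stability"] <- 1 - sd(hts) / mean(hts)
  out
}

#' Quality features for every window of a record
#'
#' Runs the hard screens and [sqi_features()] (with the internal peak
#' detector) over all windows of all channels.
#'
#' @param record A [waveform_record()] at 250 Hz.
#' @return The [segment_quality_windows()] table augmented with `flat_flag`,
#'   `range_flag` and the six quality features.
#' @export
record_quality_features <- function(record) {
  wins <- segment_quality_windows(record)
  if (!nrow(wins)) return(wins)
  feat <- matrix(NA_real_, nrow(wins), 6L,
                 dimnames = list(NULL, c("pm", "corr_measure", "e12",
                                         "sharpness", "dp_stability",
                                         "peak_stability")))
  flat <- rng <- logical(nrow(wins))
  for (i in seq_len(nrow(wins))) {
    x <- window_samples(record, wins$channel[i], wins$start[i])
    sc <- screen_hard_artifacts(x, wins$kind[i], record$fs)
    flat[i] <- sc[["flat_flag"]]; rng[i] <- sc[["range_flag"]]
    pk <- .sqi_peaks(x, wins$kind[i], record$fs)
    feat[i, ] <- sqi_features(x, pk - 1L, record$fs)
  }
  cbind(wins, flat_flag = flat, range_flag = rng, as.data.frame(feat))
}

# default architecture of the hybrid noise classifier
.noise_arch_default <- function() {
  list(k1 = 16L, l1 = 500L, k2 = 32L, l2 = 250L, fc = 32L,
       epochs = 30L, batch = 64L, lr = 1e-3, threshold = 0.5)
}

.prep_conv_input <- function(X) {
  mu <- rowMeans(X)
  s <- sqrt(pmax(rowMeans(X^2) - mu^2, 0))
  s[s == 0] <- 1
  (X - mu) / s
}

.prep_hand <- function(H, center, scale) {
  Hs <- sweep(sweep(as.matrix(H), 2L, center, "-"), 2L, scale, "/")
  Hs[!is.finite(Hs)] <- 0
  Hs
}

#' Train the hybrid convolutional noise classifier
#'
#' The model fuses two feature paths over a z-scored 1000-sample window: a
#' convolutional stack (16 filters of length 500, ReLU, max-pool 2; 32
#' filters of length 250, ReLU, max-pool 2; valid convolutions, ceil-mode
#' pooling) and the six hand-engineered quality features, concatenated into a
#' 32-unit rectified dense layer and a sigmoid output. Trained with minibatch
#' Adam on cross-entropy; 80% of the corpus is used for training, the held
#' 20% for the test metrics stored in the model.
#'
#' @param X Numeric matrix, one 1000-sample window per row.
#' @param H Numeric matrix of the six quality features per row (`NA` allowed;
#'   standardized and zero-imputed internally).
#' @param y Labels: 1 = noisy, 0 = clean; both classes must be present.
#' @param arch Architecture/optimizer settings, see `.noise_arch_default`.
#' @param seed RNG seed (weights, shuffling, the 80/20 split).
#' @return A `hybrid_noise_model` with weights, feature standardization,
#'   decision threshold and held-out `test_metrics`.
#' @export
train_noise_classifier <- function(X, H, y, arch = list(), seed = 1L) {
  a <- utils::modifyList(.noise_arch_default(), arch)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L)
    .bp_stop("bp_single_class", "corpus must contain both classes")
  stopifnot(nrow(X) == length(y), nrow(H) == length(y))
  .with_seed(seed, {
    n <- length(y)
    test_idx <- sample.int(n, round(0.2 * n))
    tr <- setdiff(seq_len(n), test_idx)
    center <- apply(H[tr, , drop = FALSE], 2L, mean, na.rm = TRUE)
    scale <- apply(H[tr, , drop = FALSE], 2L, sd, na.rm = TRUE)
    scale[!is.finite(scale) | scale == 0] <- 1
    center[!is.finite(center)] <- 0
    Xs <- .prep_conv_input(as.matrix(X))
    Hs <- .prep_hand(H, center, scale)
    w0 <- .cpp_convnet_init(ncol(X), ncol(H), a$k1, a$l1, a$k2, a$l2, a$fc)
    w <- .cpp_convnet_train(w0, Xs[tr, , drop = FALSE],
                            Hs[tr, , drop = FALSE], y[tr],
                            a$epochs, a$batch, a$lr)
    model <- structure(list(weights = w, arch = a, hand_center = center,
                            hand_scale = scale, threshold = a$threshold,
                            seed = seed),
                       class = "hybrid_noise_model")
    p_test <- predict(model, X[test_idx, , drop = FALSE],
                      H[test_idx, , drop = FALSE])
    yhat <- as.numeric(p_test >= a$threshold)
    yt <- y[test_idx]
    model$test_metrics <- c(
      sensitivity = if (any(yt == 1)) mean(yhat[yt == 1] == 1) else NA_real_,
      specificity = if (any(yt == 0)) mean(yhat[yt == 0] == 0) else NA_real_)
    model
  })
}

#' Predict noise probability for windows
#' @param object A `hybrid_noise_model`.
#' @param X Window matrix (rows = windows).
#' @param H Quality-feature matrix.
#' @param ... Unused.
#' @return Probabilities in `[0, 1]` that each window is noisy.
#' @export
predict.hybrid_noise_model <- function(object, X, H, ...) {
  Xs <- .prep_conv_input(as.matrix(X))
  Hs <- .prep_hand(H, object$hand_center, object$hand_scale)
  as.numeric(.cpp_convnet_predict(object$weights, Xs, Hs))
}

#' Classify all windows of a record and fuse into a clean-sample mask
#'
#' Every window is first hard-screened; windows passing the screens are
#' classified by the hybrid model when one is supplied (no model means the
#' screens alone decide). Fusion follows the all-channel rule: a sample is
#' clean only when every overlapping window on every one of the six channels
#' is clean; samples not covered by any complete window are left unclean.
#' Fusion is monotone: marking any window noisy can only shrink the clean
#' set.
#'
#' @param record A [waveform_record()] at 250 Hz.
#' @param model Optional `hybrid_noise_model`.
#' @return `list(windows, clean_mask)`: the per-window table (flags,
#'   probability, clean decision) and a per-sample logical mask.
#' @export
classify_and_fuse <- function(record, model = NULL) {
  qf <- record_quality_features(record)
  n <- record_length(record)
  if (!nrow(qf))
    return(list(windows = qf, clean_mask = rep(FALSE, n)))
  hard_noisy <- qf$flat_flag | qf$range_flag
  prob <- rep(NA_real_, nrow(qf))
  clean <- !hard_noisy
  if (!is.null(model) && any(!hard_noisy)) {
    idx <- which(!hard_noisy)
    len <- 4L * record$fs
    X <- t(vapply(idx, function(i)
      window_samples(record, qf$channel[i], qf$start[i]), numeric(len)))
    Hm <- as.matrix(qf[idx, c("pm", "corr_measure", "e12", "sharpness",
                              "dp_stability", "peak_stability")])
    prob[idx] <- predict(model, X, Hm)
    clean[idx] <- prob[idx] < model$threshold
  }
  qf$prob <- prob
  qf$clean <- clean
  len <- 4L * record$fs
  covered <- rep(FALSE, n)
  mask <- rep(TRUE, n)
  for (i in seq_len(nrow(qf))) {
    span <- (qf$start[i] + 1L):(qf$start[i] + len)
    covered[span] <- TRUE
    if (!qf$clean[i]) mask[span] <- FALSE
  }
  mask[!covered] <- FALSE
  list(windows = qf, clean_mask = mask)
}

#' Build a labeled synthetic window corpus for noise-classifier training
#'
#' Simulates clean subjects, harvests 4-s windows from all six channels, and
#' injects one of the four artifact classes into half of them (balanced over
#' classes and channels). Returns the raw windows, the six quality features
#' per window and the binary labels, ready for [train_noise_classifier()].
#'
#' @param n_windows Total corpus size (half clean, half noisy).
#' @param seed RNG seed.
#' @param duration_s Signal length per simulated subject.
#' @return `list(X, H, y, type, kind)`: window matrix, feature matrix,
#'   labels (1 = noisy), injected noise type (`"clean"` for clean rows) and
#'   channel kind per row.
#' @export
simulate_noise_corpus <- function(n_windows = 2000L, seed = 1L,
                                  duration_s = 120) {
  fs <- BP_FS
  len <- 4L * fs
  types <- c("loose_lead", "baseline_wander", "hf_jitter", "flat_saturation")
  per_subject <- 6L * (floor((duration_s - 4) / 3.5) + 1L)
  n_subj <- ceiling(n_windows / per_subject) + 1L
  cfg <- simulation_config(n_subjects = n_subj, duration_s = duration_s,
                           seed = .subject_seed(seed, 77L))
  X <- matrix(NA_real_, n_windows, len)
  H <- matrix(NA_real_, n_windows, 6L)
  y <- numeric(n_windows)
  type <- character(n_windows)
  kind <- character(n_windows)
  row <- 0L
  .with_seed(seed, {
    for (si in seq_len(n_subj)) {
      if (row >= n_windows) break
      rec <- simulate_subject_record(cfg, si)$record
      wins <- segment_quality_windows(rec)
      wins <- wins[sample.int(nrow(wins)), ]
      for (i in seq_len(nrow(wins))) {
        if (row >= n_windows) break
        row <- row + 1L
        noisy <- row %% 2L == 0L
        ch <- wins$channel[i]; st <- wins$start[i]
        rec_i <- rec
        if (noisy) {
          ty <- types[1L + (row %/% 2L) %% 4L]
          rec_i <- inject_noise(rec, ty, ch, c(st, st + len),
                                seed = sample.int(2^30, 1L),
                                snr_db = runif(1, -3, 6))$record
          type[row] <- ty
        } else type[row] <- "clean"
        x <- window_samples(rec_i, ch, st)
        pk <- .sqi_peaks(x, wins$kind[i], fs)
        X[row, ] <- x
        H[row, ] <- sqi_features(x, pk - 1L, fs)
        y[row] <- as.numeric(noisy)
        kind[row] <- wins$kind[i]
      }
    }
  })
  keep <- seq_len(row)
  list(X = X[keep, , drop = FALSE], H = H[keep, , drop = FALSE],
       y = y[keep], type = type[keep], kind = kind[keep])
}
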