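test_that("Hjorth parameters match hand-computed examples and the oracle", {
  h <- hjorth_params(c(0, 1, 2, 3))
  expect_equal(h[["mobility"]], 1 / sqrt(3.5))
  expect_equal(h[["complexity"]], 0)
  h2 <- hjorth_params(c(1, -1, 1, -1))
  expect_equal(h2[["mobility"]], 2)
  hc <- hjorth_params(rep(4.2, 10))
  expect_equal(unname(hc), c(0, 0))
  expect_true(is.na(hjorth_params(rep(0, 10))[["mobility"]]))
  expect_error(hjorth_params(c(1, 2)), class = "bp_invalid")
  set.seed(31)
  for (i in 1:25) {
    x <- rnorm(sample(10:400, 1))
    expect_equal(hjorth_params(x), oracle_hjorth(x), tolerance = 1e-12)
    # mobility is scale-invariant
    expect_equal(hjorth_params(3.3 * x)[["mobility"]],
                 hjorth_params(x)[["mobility"]], tolerance = 1e-12)
  }
})

test_that("amplitude entropy matches closed forms and the oracle", {
  expect_equal(amplitude_entropy(rep(1, 64)), 0)
  # exactly uniform over 4 bins with M = 4
  x <- rep(c(0.1, 0.35, 0.6, 0.85), 16)
  expect_equal(amplitude_entropy(x, M = 4L), log(4))
  x2 <- rep(c(0, 1), 32)
  expect_equal(amplitude_entropy(x2, M = 2L), log(2))
  set.seed(32)
  for (i in 1:25) {
    x <- rnorm(sample(50:500, 1))
    expect_equal(amplitude_entropy(x), oracle_entropy(x), tolerance = 1e-12)
    expect_equal(amplitude_entropy(5 * x + 2), amplitude_entropy(x),
                 tolerance = 1e-12)                    # range-relative bins
    expect_gte(amplitude_entropy(x), 0)
  }
  expect_error(amplitude_entropy(rnorm(10), M = 32L), class = "bp_invalid")
})

test_that("Higuchi dimension separates lines from noise", {
  expect_lt(abs(fractal_dimension(seq(0, 1, length.out = 500)) - 1), 0.05)
  set.seed(33)
  expect_gt(fractal_dimension(rnorm(1000)), 1.5)
  expect_equal(fractal_dimension(rep(2, 100)), 1)
  expect_true(is.na(fractal_dimension(rnorm(10))))
})

test_that("autocorrelation feature follows the biased estimator", {
  x <- rnorm(100)
  expect_equal(autocorr_feature(x, lag = 0L), 1)
  n <- 1000; P <- 50
  s <- sin(2 * pi * seq_len(n) / P)
  expect_equal(autocorr_feature(s, lag = P), 1 - P / n, tolerance = 0.01)
  set.seed(34)
  w <- rnorm(4000)
  expect_lt(abs(autocorr_feature(w)), 3 / sqrt(4000))
  expect_true(is.na(autocorr_feature(rep(0, 50))))
})

test_that("Kaiser-Teager energy obeys its algebraic identities", {
  expect_equal(kaiser_teager_energy(rep(3, 50)), rep(0, 48))
  expect_equal(kaiser_teager_energy(as.numeric(1:50)), rep(1, 48))
  set.seed(35)
  for (i in 1:25) {
    s <- rnorm(sample(10:100, 1))
    expect_equal(kaiser_teager_energy(s), oracle_kte(s), tolerance = 1e-12)
    # quadratic amplitude scaling
    expect_equal(kaiser_teager_energy(2 * s), 4 * kaiser_teager_energy(s),
                 tolerance = 1e-12)
  }
})

test_that("SpO2 features: KTE stats, spectral entropy, AR(5) recovery", {
  f <- spo2_features(rep(c(96, 97, 98, 97), 100))
  expect_true(all(c("kte_mean", "spectral_entropy", "ar5") %in% names(f)))
  fr <- spo2_features(as.numeric(1:100))
  expect_equal(fr[["kte_mean"]], 1)
  expect_equal(fr[["kte_var"]], 0)
  # known AR(5) process, scaled-down replication count
  phi <- c(0.5, -0.3, 0.2, -0.1, 0.05)
  errs <- replicate(5, {
    set.seed(sample.int(1e6, 1))
    s <- as.numeric(stats::arima.sim(list(ar = phi), 1250))
    ar_coefficients(s, 5L) - phi
  })
  expect_true(all(abs(rowMeans(errs)) < 0.05))
  # package estimate agrees with the brute-force normal equations
  set.seed(36)
  s <- as.numeric(stats::arima.sim(list(ar = phi), 600))
  expect_equal(ar_coefficients(s), oracle_ar(s), tolerance = 1e-10)
  expect_true(all(is.na(ar_coefficients(rep(5, 100)))))
})

test_that("QTc uses Bazett and medians across beats", {
  fid <- data.frame(beat = 1:4,
                    r_peak = c(0L, 250L, 500L, 750L),
                    qrs_onset = c(-10L, 240L, 490L, 740L),
                    qrs_offset = c(10L, 260L, 510L, 760L),
                    t_peak = c(80L, 330L, 580L, 830L),
                    t_end = c(85L, 240L + 95L, 490L + 100L, 740L + 105L),
                    t_amp = c(0.3, 0.30, 0.31, 0.32))
  # beats 2-4 at RR = 1 s; QT = 0.38, 0.40, 0.42 s -> median QTc 0.40
  out <- ecg_beat_features(fid, 2:4)
  expect_equal(out[["qtc"]], 0.40)
  expect_equal(out[["t_amp"]], 0.31)
  # single beat at RR = 0.64 s, QT = 0.40 -> 0.50
  fid2 <- data.frame(beat = 1:2, r_peak = c(0L, 160L),
                     qrs_onset = c(-5L, 155L), qrs_offset = c(5L, 165L),
                     t_peak = c(60L, 220L), t_end = c(90L, 155L + 100L),
                     t_amp = c(0.3, 0.3))
  expect_equal(ecg_beat_features(fid2, 2L)[["qtc"]], 0.40 / 0.8)
  # all T ends missing -> flagged missing
  fid$t_end <- NA_integer_
  expect_true(is.na(ecg_beat_features(fid, 2:4)[["qtc"]]))
})

test_that("timing features recover constructed delays", {
  fid <- data.frame(beat = 1:5,
                    r_peak = as.integer(seq(0, by = 188, length.out = 5)),
                    qrs_onset = 0L, qrs_offset = 0L, t_peak = 0L,
                    t_end = as.integer(seq(0, by = 188, length.out = 5)) + 85L,
                    t_amp = 0.3)
  fids <- list(fid, fid, fid, fid)
  # RR = 0.752 s -> just under 80 bpm; use exact 0.75 s
  fid75 <- within(fid, {
    r_peak <- as.integer(seq(0, by = 188, length.out = 5))
  })
  fid75$r_peak <- as.integer((0:4) * 188)
  tf <- timing_features(list(fid75, fid75, fid75, fid75), 2:5, 1L,
                        spo2_peaks = fid75$r_peak[2:5] + 50L)
  expect_equal(tf[["heart_rate"]], 60 / (188 / 250))
  expect_equal(tf[["pat"]], 0.2)
  # SpO2 peak 120 ms after T end
  tf2 <- timing_features(list(fid75, fid75, fid75, fid75), 2:5, 1L,
                         spo2_peaks = fid75$t_end[2:5] + 30L)
  expect_equal(tf2[["t2spo2"]], 0.12)
  tf3 <- timing_features(list(fid75, fid75, fid75, fid75), 2:5, 1L,
                         spo2_peaks = rep(NA_integer_, 4))
  expect_true(is.na(tf3[["pat"]]))
})

test_that("demographic encoding matches the stated codes", {
  e <- encode_demographics(subject_info(65, 27, "female", "White"))
  expect_equal(e[["gender_code"]], 1)
  expect_equal(unname(e[c("race_white", "race_hispanic", "race_asian",
                          "race_black")]), c(1, 0, 0, 0))
  e2 <- encode_demographics(subject_info(50, 30, "male", "Black"))
  expect_equal(e2[["gender_code"]], 2)
  expect_equal(unname(e2[c("race_white", "race_hispanic", "race_asian",
                           "race_black")]), c(0, 0, 0, 1))
  e3 <- encode_demographics(subject_info())
  expect_true(is.na(e3[["gender_code"]]))
  expect_equal(sum(e3[c("race_white", "race_hispanic", "race_asian",
                        "race_black")]), 0)
})

test_that("the schema holds 48 entries and the default selection 34", {
  expect_equal(length(feature_schema()), 48L)
  expect_equal(anyDuplicated(feature_schema()), 0L)
  rep <- select_features()
  expect_equal(length(rep$selected), 34L)
  expect_setequal(c(rep$selected, rep$excluded), feature_schema())
  expect_length(intersect(rep$selected, rep$excluded), 0)
  expect_error(
    select_features(as.data.frame(matrix(numeric(0), 0, 48,
                                         dimnames = list(NULL, feature_schema())))),
    class = "bp_invalid")
})

test_that("assembled vectors are complete, deterministic, NA-propagating", {
  s <- clean_subject()
  d <- clean_delineation()
  beats <- assemble_beats(d, n = record_length(s$record))
  sq <- gold_standard_bp(build_sequences(beats, 5L), beats, s$record$abp)
  ft <- sequence_features(s$record, d, beats, sq)
  expect_true(all(feature_schema() %in% colnames(ft)))
  expect_gt(nrow(ft), 3)
  # pure function: identical on repeated call
  ft2 <- sequence_features(s$record, d, beats, sq)
  expect_identical(ft, ft2)
  # physiology lands where it should
  expect_equal(ft$heart_rate[1], 60 / median(diff(s$truth$beats$r_idx) / 250),
               tolerance = 0.05)
  expect_equal(mean(ft$pat) * 1000, mean(s$truth$beats$pat_ms),
               tolerance = 0.05)
  # knocking out one lead's T ends hits only that lead's beat features
  d3 <- d
  d3$ecg[[3]]$t_end <- NA_integer_
  d3$ecg[[3]]$t_amp <- NA_real_
  ft3 <- sequence_features(s$record, d3, beats, sq)
  expect_true(all(is.na(ft3$qtc_l3)))
  expect_equal(ft3$qtc_l2, ft$qtc_l2)
  expect_equal(ft3$mobility_l3, ft$mobility_l3)
})

test_that("data-driven selection ranks a pure-noise feature low", {
  hits <- 0L
  for (sd in 1:5) {
    X <- toy_features(400L, p = 8L, seed = sd)
    fn <- paste0("f", 1:8)   # f1..f7 all drive y below; f8 is pure noise
    y <- with(X, f1 + f2 + f3 + f4 + f5 + f6 + f7 + rnorm(400, 0, 0.3))
    m <- train_forest(X, y, n_trees = 80L, seed = sd,
                      feature_names = fn, importance = TRUE)
    rk <- rank(m$oob_importance)
    if (rk[["f8"]] <= 2L) hits <- hits + 1L   # bottom quartile of 8
    sel <- select_features(importance = m$oob_importance, n_keep = 4L)
    expect_length(sel$selected, 4L)
  }
  expect_gte(hits, 4L)
})
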