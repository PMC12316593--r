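test_that("a noise-free fixed-rate subject hits programmed pressures exactly", {
  s <- simulate_subject_record(deterministic_config(), 1L)
  tr <- s$truth$beats
  expect_true(all(tr$sys == tr$sys[1]))
  abp <- s$record$abp
  for (k in seq_len(nrow(tr))[-nrow(tr)]) {
    seg <- abp[(tr$abp_valley[k] + 1L):tr$abp_valley[k + 1L]]
    expect_equal(max(seg), 120)
    expect_equal(min(seg), 80)
  }
})

test_that("programmed PAT places the SpO2 peak 50 samples after R", {
  s <- simulate_subject_record(deterministic_config(pat_ms = 200), 1L)
  tr <- s$truth$beats
  expect_true(all(tr$spo2_peak - tr$r_idx == 50L))
  # and the waveform argmax agrees with the recorded fiducial
  for (k in c(2L, 10L)) {
    lo <- tr$spo2_valley[k] + 1L
    hi <- tr$spo2_valley[k + 1L]
    seg <- s$record$spo2[lo:hi]
    expect_equal(lo - 1L + which.max(seg) - 1L, tr$spo2_peak[k])
  }
})

test_that("ground-truth fiducials sit on waveform extrema (clean record)", {
  s <- clean_subject()
  tr <- s$truth$beats
  rec <- s$record
  for (k in seq(2, nrow(tr) - 1, by = 7)) {
    r <- tr$r_idx[k]
    win <- (r - 4L):(r + 6L)
    expect_lte(abs(which.max(rec$ecg[win, 2]) + win[1] - 1L - 1L - r), 1L)
    v <- tr$abp_valley[k]
    win <- (v - 3L):(v + 7L)
    expect_lte(abs(which.min(rec$abp[win]) + win[1] - 1L - 1L - v), 1L)
  }
})

test_that("same seed reproduces the identical record", {
  cfg <- simulation_config(n_subjects = 2L, duration_s = 12, seed = 9L)
  a <- simulate_subject_record(cfg, 2L)
  b <- simulate_subject_record(cfg, 2L)
  expect_identical(a$record$ecg, b$record$ecg)
  expect_identical(a$truth$beats, b$truth$beats)
})

test_that("cohorts have distinct subjects and reproducible offsets", {
  cfg <- simulation_config(n_subjects = 40L, duration_s = 10, seed = 3L)
  co <- simulate_cohort(cfg)
  ids <- vapply(co, function(s) s$record$subject_id, character(1))
  expect_equal(length(unique(ids)), 40L)
  co2 <- simulate_cohort(cfg)
  expect_identical(co[[17]]$record$abp, co2[[17]]$record$abp)
  offs <- vapply(co, function(s) s$truth$params$sys_off, numeric(1))
  # CLT bound on the mean of N(0, 10) offsets
  expect_lt(abs(mean(offs)), 3 * 10 / sqrt(40))
  expect_gt(sd(offs), 2)  # offsets genuinely vary between subjects
  expect_error(simulate_cohort(simulation_config(n_subjects = 0L)),
               class = "bp_invalid")
})

test_that("the PAT map is monotone: higher pressure, shorter PAT", {
  lo <- simulate_subject_record(deterministic_config(), 1L)
  cfg_hi <- deterministic_config()
  cfg_hi$sys_base <- 180
  cfg_hi$pat_b <- 0.8
  cfg_lo <- deterministic_config()
  cfg_lo$pat_b <- 0.8
  hi <- simulate_subject_record(cfg_hi, 1L)
  lo <- simulate_subject_record(cfg_lo, 1L)
  expect_lt(mean(hi$truth$beats$pat_ms), mean(lo$truth$beats$pat_ms))
})

test_that("inject_noise touches only the selected channel and span", {
  s <- clean_subject()
  rec <- s$record
  n <- record_length(rec)
  out <- inject_noise(rec, "baseline_wander", channel = 2L,
                      span = c(1000L, 3000L), seed = 4L)
  expect_equal(out$record$ecg[, 1], rec$ecg[, 1])
  expect_equal(out$record$spo2, rec$spo2)
  expect_equal(out$record$ecg[1:1000, 2], rec$ecg[1:1000, 2])
  expect_false(isTRUE(all.equal(out$record$ecg[1001:3000, 2],
                                rec$ecg[1001:3000, 2])))
  lab <- out$labels
  expect_true(all(lab$channel == "ecg_II"))
  affected <- lab$start[lab$noisy]
  expect_true(all(affected < 3000 & affected + 1000 > 1000))
  expect_error(inject_noise(rec, "sparkles", 1L, c(0L, 100L)),
               class = "bp_invalid")
})

test_that("flat saturation over a whole channel marks every window noisy", {
  s <- clean_subject()
  n <- record_length(s$record)
  out <- inject_noise(s$record, "flat_saturation", channel = "abp",
                      span = c(0L, n), seed = 1L)
  expect_true(all(out$labels$noisy))
  # and the spo2/ecg labels of the record remain clean in the merged truth
  expect_true(all(out$labels$channel == "abp"))
})

test_that("0 dB jitter raises the above-12 Hz band energy in every window", {
  s <- clean_subject()
  rec <- s$record
  fs <- rec$fs
  out <- inject_noise(rec, "hf_jitter", channel = 2L,
                      span = c(0L, record_length(rec)), seed = 2L, snr_db = 0)
  band_energy <- function(x) {
    p <- Mod(fft(x - mean(x)))^2
    f <- (seq_along(p) - 1) * fs / length(p)
    sum(p[f >= 12 & f <= fs / 2])
  }
  for (st in out$labels$start[out$labels$noisy]) {
    a <- window_samples(rec, 2L, st)
    b <- window_samples(out$record, 2L, st)
    expect_gt(band_energy(b), band_energy(a))
  }
})

test_that("too-short durations fail loudly", {
  cfg <- simulation_config(n_subjects = 1L, duration_s = 1.5)
  expect_error(simulate_subject_record(cfg, 1L), class = "bp_invalid")
})
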