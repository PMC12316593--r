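test_that("window segmentation follows the 4 s / 3.5 s stride rule", {
  mk <- function(sec) {
    n <- round(sec * 250)
    x <- sin(2 * pi * seq_len(n) / 250)
    waveform_record("s", 250, cbind(x, x, x, x), 97 + 0 * x, 100 + x)
  }
  w10 <- segment_quality_windows(mk(10))
  expect_equal(sort(unique(w10$start)), c(0L, 875L))
  expect_equal(nrow(w10), 2L * 6L)
  expect_equal(nrow(segment_quality_windows(mk(4))), 1L * 6L)
  expect_warning(w39 <- segment_quality_windows(mk(3.9)),
                 class = "bp_short_record")
  expect_equal(nrow(w39), 0L)
})

test_that("hard screens catch flat runs and out-of-range samples", {
  expect_true(screen_hard_artifacts(rep(1.3, 1000), "ecg")[["flat_flag"]])
  w <- sin(seq_len(1000) / 20)
  expect_false(any(screen_hard_artifacts(w, "ecg")))
  spo2 <- 97 + w
  spo2[500] <- 105
  sc <- screen_hard_artifacts(spo2, "spo2")
  expect_true(sc[["range_flag"]])
  abp <- 100 + 10 * w
  abp[7] <- -3
  expect_true(screen_hard_artifacts(abp, "abp")[["range_flag"]])
  # rail-pinned run shorter than 0.5 s does not trip the flat screen
  spo2b <- 97 + w
  spo2b[1:50] <- 100
  expect_false(screen_hard_artifacts(spo2b, "spo2")[["flat_flag"]])
  # clean simulated ECG window passes both screens
  x <- window_samples(clean_subject()$record, "ecg_II", 875L)
  expect_false(any(screen_hard_artifacts(x, "ecg")))
})

test_that("periodicity measure matches its formula and properties", {
  expect_equal(periodicity_measure(c(800, 800, 800)), 100)
  expect_equal(periodicity_measure(c(700, 800, 900)), 87.5)
  expect_error(periodicity_measure(800), class = "bp_insufficient_beats")
  expect_error(periodicity_measure(c(0, 0)), class = "bp_invalid")
  set.seed(11)
  for (i in 1:20) {
    I <- runif(sample(2:12, 1), 500, 1200)
    pm <- periodicity_measure(I)
    expect_equal(pm, oracle_pm(I), tolerance = 1e-12)
    expect_equal(periodicity_measure(I * runif(1, 0.1, 10)), pm,
                 tolerance = 1e-9)                    # scale invariance
    expect_lte(pm, 100)
    expect_equal(pm == 100, sd(I) == 0)
  }
})

test_that("quality features behave on constructed windows", {
  fs <- 250
  # identical repeated QRS template -> perfect successive correlation
  tpl <- exp(-((-30:30)^2) / 18)
  win <- rep(0, 1000)
  peaks <- seq(100, 900, by = 200)
  for (p in peaks) win[p + (-30:30)] <- tpl
  f <- sqi_features(win, peaks - 1L, fs)
  expect_equal(f[["corr_measure"]], 1)
  expect_equal(f[["peak_stability"]], 1)  # equal R heights: sd = 0
  expect_equal(f[["dp_stability"]], 1)
  expect_gt(f[["pm"]], 99.9)
  # pure 50 Hz sinusoid: all energy above 12 Hz -> e12 is the global max
  x50 <- sin(2 * pi * 50 * seq_len(1000) / fs)
  f50 <- sqi_features(x50, integer(0), fs)
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:999) / 999)
  P <- Mod(fft((x50 - mean(x50)) * hann))^2
  half <- P[1:501]
  expect_equal(f50[["e12"]], max(half / sum(half)), tolerance = 1e-12)
  expect_error(sqi_features(win, c(10L, 2000L)), class = "bp_index")
  # fewer than 2 peaks: beat features flagged absent
  f1 <- sqi_features(win, peaks[1] - 1L, fs)
  expect_true(is.na(f1[["corr_measure"]]))
  expect_false(is.na(f1[["e12"]]))
})

test_that("hybrid net shapes follow the stated convolution arithmetic", {
  # 1000 -> conv(500) -> 501 -> pool2(ceil) -> 251 -> conv(250) -> 2 -> pool -> 1
  set.seed(1)
  w <- bpwave:::.cpp_convnet_init(1000L, 6L, 16L, 500L, 32L, 250L, 32L)
  expect_equal(dim(w$W1), c(500L, 16L))
  expect_equal(dim(w$W2), c(250L * 16L, 32L))
  expect_equal(dim(w$W3), c(1L * 32L + 6L, 32L))
  # an input too short for the stack is rejected
  expect_error(bpwave:::.cpp_convnet_init(300L, 6L, 16L, 500L, 32L, 250L, 32L))
})

test_that("untrained and trained models emit probabilities in [0, 1]", {
  set.seed(2)
  X <- matrix(rnorm(6 * 1000), 6, 1000)
  H <- matrix(rnorm(36), 6, 6)
  w <- bpwave:::.cpp_convnet_init(1000L, 6L, 16L, 500L, 32L, 250L, 32L)
  p <- bpwave:::.cpp_convnet_predict(w, bpwave:::.prep_conv_input(X), H)
  expect_true(all(p >= 0 & p <= 1))
  y <- c(0, 1, 0, 1, 0, 1)
  m <- train_noise_classifier(X, H, y, arch = list(epochs = 2), seed = 1L)
  p2 <- predict(m, X, H)
  expect_true(all(p2 >= 0 & p2 <= 1))
  expect_error(train_noise_classifier(X, H, rep(1, 6)),
               class = "bp_single_class")
})

test_that("fusion is all-channel and monotone", {
  s <- clean_subject()
  rec <- s$record
  base <- classify_and_fuse(rec)
  # interior of a clean record is clean
  mid <- 3000:8000
  expect_true(mean(base$clean_mask[mid]) > 0.95)
  # flat ABP (one channel) kills the overlapping segment for all channels
  noisy <- inject_noise(rec, "flat_saturation", "abp",
                        c(3500L, 6000L), seed = 1L)$record
  fused <- classify_and_fuse(noisy)
  expect_true(all(!fused$clean_mask[3600:5900]))
  # monotone: the noisy record's clean set is a subset of the clean one's
  expect_true(all(fused$clean_mask <= base$clean_mask))
  # one noisy ECG lead is enough to exclude the segment
  noisy2 <- inject_noise(rec, "loose_lead", "ecg_III",
                         c(4000L, 5000L), seed = 2L)$record
  fused2 <- classify_and_fuse(noisy2)
  expect_true(all(fused2$clean_mask <= base$clean_mask))
})

test_that("record_quality_features flags injected windows via hard screens", {
  s <- clean_subject()
  noisy <- inject_noise(s$record, "flat_saturation", "spo2",
                        c(0L, record_length(s$record)), seed = 1L)$record
  qf <- record_quality_features(noisy)
  spo2_rows <- qf$channel == "spo2"
  expect_true(all(qf$flat_flag[spo2_rows] | qf$range_flag[spo2_rows]))
  # interior ECG windows stay clean (the record tail after the last beat is
  # legitimately flat and may be flagged)
  interior <- qf$channel == "ecg_II" & qf$start + 1000 < 14000
  expect_false(any(qf$flat_flag[interior]))
})
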