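# Shared fixtures, built in code and memoized for the duration of the test
# session (simulation + delineation of even short records is not free).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# fully deterministic config: fixed HR 60, constant 120/80, fixed PAT 200 ms
deterministic_config <- function(duration_s = 30, pat_ms = 200) {
  simulation_config(
    n_subjects = 1L, duration_s = duration_s,
    hr_base_range = c(60, 60), hr_resp_amp_bpm = 0, rr_jitter_sd = 0,
    sys_base = 120, sys_age_slope = 0, subject_offset_sd = 0,
    drift_amp = 0, bp_beat_noise_sd = 0,
    pp_base = 40, pp_slope = 0,
    pat_a = pat_ms, pat_a_sd = 0, pat_b = 0,
    seed = 42L)
}

clean_subject <- function() cached("clean_subject", {
  simulate_subject_record(simulation_config(n_subjects = 1L, duration_s = 60,
                                            seed = 7L), 1L)
})

clean_delineation <- function() cached("clean_delineation", {
  delineate_record(clean_subject()$record)
})

# synthetic beat table with b valid contiguous beats, 100 samples each
toy_beats <- function(b, valid = rep(TRUE, b)) {
  bt <- data.frame(beat = seq_len(b),
                   r_peak = 100L * seq_len(b) + 30L,
                   ecg_start = 100L * (seq_len(b) - 1L),
                   ecg_end = 100L * seq_len(b),
                   spo2_start = 100L * (seq_len(b) - 1L) + 10L,
                   spo2_end = 100L * seq_len(b) + 10L,
                   abp_start = 100L * (seq_len(b) - 1L) + 20L,
                   abp_end = 100L * seq_len(b) + 20L,
                   t_end = 100L * seq_len(b), valid = valid)
  class(bt) <- c("beat_table", "data.frame")
  bt
}

# ABP trace matching toy_beats extents with programmed per-beat sys/dia
toy_abp <- function(beats, sys, dia) {
  n <- max(beats$abp_end) + 10L
  abp <- rep(dia[1], n)
  for (k in seq_len(nrow(beats))) {
    seg <- (beats$abp_start[k] + 1L):beats$abp_end[k]
    m <- length(seg)
    shape <- c(seq(0, 1, length.out = floor(m / 2)),
               seq(1, 0, length.out = m - floor(m / 2)))
    abp[seg] <- dia[k] + (sys[k] - dia[k]) * shape
  }
  abp
}

# small feature frame with controllable metadata for model-layer tests
toy_features <- function(n, p = 6L, seed = 1L, subjects = 1L) {
  set.seed(seed)
  X <- as.data.frame(matrix(rnorm(n * p), n, p,
                            dimnames = list(NULL, paste0("f", seq_len(p)))))
  X$subject_id <- rep_len(sprintf("S%02d", seq_len(subjects)), n)
  X$run <- 1L
  X$win_index <- stats::ave(seq_len(n), X$subject_id, FUN = seq_along)
  X$gold_sys <- 120 + 3 * X$f1 + rnorm(n, 0, 0.5)
  X$gold_dia <- 80 + 2 * X$f2 + rnorm(n, 0, 0.5)
  X
}
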