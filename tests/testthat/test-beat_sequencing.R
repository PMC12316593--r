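test_that("a clean record yields one beat fewer than detected fiducials", {
  s <- clean_subject()
  d <- clean_delineation()
  beats <- assemble_beats(d, n = record_length(s$record))
  ref <- which.max(vapply(d$ecg, nrow, integer(1)))
  expect_equal(nrow(beats), nrow(d$ecg[[ref]]) - 1L)
  expect_gt(mean(beats$valid), 0.9)
  # extents chain: each beat starts where the previous one ends
  expect_true(all(diff(beats$ecg_start) > 0))
  expect_equal(beats$ecg_start[-1], beats$ecg_end[-nrow(beats)])
})

test_that("a noisy mid-segment invalidates exactly the covered beats", {
  s <- clean_subject()
  d <- clean_delineation()
  n <- record_length(s$record)
  mask <- rep(TRUE, n)
  mask[5000:7000] <- FALSE
  all_clean <- assemble_beats(d, clean_mask = rep(TRUE, n))
  some <- assemble_beats(d, clean_mask = mask)
  lo <- pmin(all_clean$ecg_start, all_clean$spo2_start, all_clean$abp_start)
  hi <- pmax(all_clean$ecg_end, all_clean$spo2_end, all_clean$abp_end)
  inside <- !is.na(lo) & !is.na(hi) & hi > 4999 & lo < 7000
  expect_true(all(!some$valid[inside]))
  expect_equal(some$valid[!inside], all_clean$valid[!inside])
})

test_that("a missing pulse beat invalidates the beat on all channels", {
  s <- clean_subject()
  d <- clean_delineation()
  d2 <- d
  drop <- 10L
  d2$spo2 <- d2$spo2[-drop, ]
  b1 <- assemble_beats(d, n = record_length(s$record))
  b2 <- assemble_beats(d2, n = record_length(s$record))
  expect_lt(sum(b2$valid), sum(b1$valid))
})

test_that("sequence packing follows the stride rules", {
  b12 <- toy_beats(12L)
  non <- build_sequences(b12, 5L, "non_overlapping")
  expect_equal(nrow(non), 2L)
  expect_equal(non$first_beat, c(1L, 6L))
  expect_equal(non$last_beat, c(5L, 10L))
  sli <- build_sequences(b12, 5L, "sliding")
  expect_equal(nrow(sli), 8L)   # 12 - 5 + 1
  expect_equal(sli$win_index, 1:8)
  expect_equal(nrow(build_sequences(toy_beats(4L), 5L)), 0L)
  expect_error(build_sequences(b12, 7L), class = "bp_invalid")
})

test_that("sequences never span an invalid beat and stay disjoint", {
  set.seed(21)
  for (i in 1:10) {
    b <- toy_beats(40L, valid = runif(40) > 0.25)
    for (L in c(1L, 5L, 10L)) {
      sq <- build_sequences(b, L, "non_overlapping")
      if (!nrow(sq)) next
      used <- unlist(lapply(seq_len(nrow(sq)), function(j)
        sq$first_beat[j]:sq$last_beat[j]))
      expect_equal(anyDuplicated(used), 0L)        # pairwise disjoint
      expect_true(all(b$valid[used]))              # only valid beats
      for (j in seq_len(nrow(sq)))                 # contiguous indices
        expect_equal(sq$last_beat[j] - sq$first_beat[j] + 1L, L)
    }
  }
})

test_that("gold-standard labels are per-beat extreme medians with range rule", {
  b5 <- toy_beats(5L)
  sys <- c(118, 120, 122, 124, 126)
  dia <- c(78, 80, 82, 84, 86)
  abp <- toy_abp(b5, sys, dia)
  sq <- build_sequences(b5, 5L, "non_overlapping")
  out <- gold_standard_bp(sq, b5, abp)
  expect_equal(out$gold_sys, 122)
  expect_equal(out$gold_dia, 82)
  expect_true(out$accepted)
  # single-beat sequence is the identity
  sq1 <- build_sequences(b5, 1L, "non_overlapping")
  out1 <- gold_standard_bp(sq1, b5, abp)
  expect_equal(out1$gold_sys, sys)
  expect_equal(out1$gold_dia, dia)
  # median systolic above 220 is rejected
  hi <- gold_standard_bp(sq, b5, toy_abp(b5, sys + 110, dia))
  expect_false(hi$accepted)
  # boundary values are inclusive
  edge <- gold_standard_bp(sq1, b5, toy_abp(b5, rep(220, 5), rep(40, 5)))
  expect_true(all(edge$accepted))
  # even count: mean of the middle two
  sq4 <- build_sequences(toy_beats(4L), 1L)
  b4 <- toy_beats(4L)
  out4 <- gold_standard_bp(data.frame(seq_id = 1L, first_beat = 1L,
                                      last_beat = 4L, run = 1L,
                                      win_index = 1L),
                           b4, toy_abp(b4, c(110, 112, 118, 120), rep(70, 4)))
  expect_equal(out4$gold_sys, 115)
})

test_that("simulator sequences keep a 10 mmHg pulse-pressure floor", {
  s <- clean_subject()
  d <- clean_delineation()
  beats <- assemble_beats(d, n = record_length(s$record))
  sq <- gold_standard_bp(build_sequences(beats, 5L), beats, s$record$abp)
  expect_true(all(sq$gold_sys >= sq$gold_dia + 10))
})
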