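#' Assemble per-beat extents across all six channels
#'
#' A beat's ECG extent runs from the end of the previous beat's T wave to the
#' end of the current beat's T wave (shared by all four leads, taken from a
#' reference lead); the SpO2 and ABP extents run between consecutive pulse
#' valleys. Pulse beats are matched to the ECG beat whose R peak precedes
#' their valley by 0-500 ms. A beat is valid only when its extent is certain
#' on all six channels (all fiducials present and matched) and every sample
#' of the union extent is clean; invalid beats are excluded downstream along
#' with any sequence containing them.
#'
#' @param delin Output of [delineate_record()] (or a compatible list with
#'   `ecg` = list of 4 `ecg_fiducials`, `spo2`, `abp`).
#' @param clean_mask Per-sample logical mask (e.g. from [classify_and_fuse()]);
#'   `NULL` means all clean.
#' @param n Record length in samples (required when `clean_mask` is `NULL`).
#' @param fs Sampling rate, Hz.
#' @return A `beat_table` data frame, one row per ECG beat of the reference
#'   lead starting with the second: 0-based extents `ecg_start`, `ecg_end`,
#'   `spo2_start`, `spo2_end`, `abp_start`, `abp_end`, the reference `r_peak`,
#'   and `valid`.
#' @export
assemble_beats <- function(delin, clean_mask = NULL, n = NULL, fs = BP_FS) {
  ref <- which.max(vapply(delin$ecg, nrow, integer(1L)))
  ef <- delin$ecg[[ref]]
  if (is.null(clean_mask)) {
    if (is.null(n)) .bp_stop("bp_invalid", "need clean_mask or n")
    clean_mask <- rep(TRUE, n)
  }
  n <- length(clean_mask)
  empty <- data.frame(beat = integer(0), r_peak = integer(0),
                      ecg_start = integer(0), ecg_end = integer(0),
                      spo2_start = integer(0), spo2_end = integer(0),
                      abp_start = integer(0), abp_end = integer(0),
                      t_end = integer(0), valid = logical(0))
  class(empty) <- c("beat_table", "data.frame")
  if (nrow(ef) < 2L) return(empty)

  max_lag <- round(0.5 * fs)
  match_pulse <- function(r, pf) {
    # valley within (0, 500 ms] after the R peak
    d <- pf$valley - r
    ok <- which(d >= 0 & d <= max_lag)
    if (!length(ok)) return(NA_integer_)
    ok[which.min(d[ok])]
  }

  nb <- nrow(ef) - 1L
  out <- data.frame(beat = seq_len(nb),
                    r_peak = ef$r_peak[-1L],
                    ecg_start = ef$t_end[-nrow(ef)],
                    ecg_end = ef$t_end[-1L],
                    spo2_start = NA_integer_, spo2_end = NA_integer_,
                    abp_start = NA_integer_, abp_end = NA_integer_,
                    t_end = ef$t_end[-1L], valid = FALSE)
  other <- setdiff(seq_len(4L), ref)
  for (k in seq_len(nb)) {
    r <- out$r_peak[k]
    if (is.na(out$ecg_start[k]) || is.na(out$ecg_end[k]) ||
        out$ecg_end[k] <= out$ecg_start[k]) next
    # every other lead must have a matching R peak (within 100 ms)
    lead_ok <- all(vapply(other, function(l) {
      any(abs(delin$ecg[[l]]$r_peak - r) <= round(0.1 * fs))
    }, logical(1L)))
    if (!lead_ok) next
    js <- match_pulse(r, delin$spo2)
    ja <- match_pulse(r, delin$abp)
    if (is.na(js) || is.na(ja)) next
    if (js >= nrow(delin$spo2) || ja >= nrow(delin$abp)) next
    s0 <- delin$spo2$valley[js]; s1 <- delin$spo2$valley[js + 1L]
    a0 <- delin$abp$valley[ja]; a1 <- delin$abp$valley[ja + 1L]
    if (any(is.na(c(s0, s1, a0, a1)))) next
    out$spo2_start[k] <- s0; out$spo2_end[k] <- s1
    out$abp_start[k] <- a0; out$abp_end[k] <- a1
    lo <- min(out$ecg_start[k], s0, a0) + 1L
    hi <- min(n, max(out$ecg_end[k], s1, a1))
    out$valid[k] <- all(clean_mask[lo:hi])
  }
  class(out) <- c("beat_table", "data.frame")
  out
}

#' Build fixed-length beat sequences
#'
#' Sequences are built inside contiguous runs of valid beats (consecutive
#' beat indices, so no gaps). In `non_overlapping` mode runs are packed
#' greedily left to right with stride `L`; in `sliding` mode the window
#' advances one beat at a time and the window index within each run is kept
#' for overlap-aware cross-validation filtering.
#'
#' @param beats A `beat_table` from [assemble_beats()].
#' @param L Window length in beats; one of 1, 5, 10, 20, 30, 50.
#' @param mode `"non_overlapping"` or `"sliding"`.
#' @return A `beat_sequences` data frame: `seq_id`, `first_beat`,
#'   `last_beat` (inclusive beat indices into `beats`), `run`, `win_index`.
#' @export
build_sequences <- function(beats, L,
                            mode = c("non_overlapping", "sliding")) {
  mode <- match.arg(mode)
  if (!L %in% c(1L, 5L, 10L, 20L, 30L, 50L))
    .bp_stop("bp_invalid", "L must be one of 1, 5, 10, 20, 30, 50")
  v <- which(beats$valid)
  out <- data.frame(seq_id = integer(0), first_beat = integer(0),
                    last_beat = integer(0), run = integer(0),
                    win_index = integer(0))
  if (length(v)) {
    run_id <- cumsum(c(1L, diff(v) != 1L))
    sid <- 0L
    for (rn in unique(run_id)) {
      rv <- v[run_id == rn]
      m <- length(rv)
      if (m < L) next
      starts <- if (mode == "non_overlapping") seq(1L, m - L + 1L, by = L)
                else seq_len(m - L + 1L)
      for (w in seq_along(starts)) {
        sid <- sid + 1L
        out <- rbind(out, data.frame(
          seq_id = sid, first_beat = rv[starts[w]],
          last_beat = rv[starts[w] + L - 1L], run = rn, win_index = w))
      }
    }
  }
  attr(out, "L") <- L
  attr(out, "mode") <- mode
  class(out) <- c("beat_sequences", "data.frame")
  out
}

#' Gold-standard pressures for beat sequences
#'
#' Per beat, systolic = maximum and diastolic = minimum ABP amplitude between
#' consecutive valleys; the sequence label is the median across its beats
#' (mean of the middle two for even counts). Sequences are accepted only when
#' systolic lies in \[80, 220\] and diastolic in \[40, 120\] mmHg (inclusive).
#'
#' @param sequences A `beat_sequences` data frame.
#' @param beats The `beat_table` the sequences index into.
#' @param abp The ABP channel samples.
#' @return `sequences` augmented with `gold_sys`, `gold_dia`, `accepted`.
#' @export
gold_standard_bp <- function(sequences, beats, abp) {
  per_beat <- function(k) {
    seg <- abp[(beats$abp_start[k] + 1L):beats$abp_end[k]]
    c(max(seg), min(seg))
  }
  gs <- gd <- rep(NA_real_, nrow(sequences))
  for (i in seq_len(nrow(sequences))) {
    ks <- sequences$first_beat[i]:sequences$last_beat[i]
    sysdia <- vapply(ks, per_beat, numeric(2L))
    gs[i] <- median(sysdia[1L, ])
    gd[i] <- median(sysdia[2L, ])
  }
  sequences$gold_sys <- gs
  sequences$gold_dia <- gd
  sequences$accepted <- gs >= 80 & gs <= 220 & gd >= 40 & gd <= 120
  sequences
}
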