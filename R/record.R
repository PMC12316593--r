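#' Subject demographics
#'
#' Container for the per-subject characteristics used as model features:
#' age (years), body mass index (kg/m^2), gender and self-declared race.
#' Gender and race are restricted categorical variables; `NA` marks a missing
#' value (unavailable, or outside the recognized categories).
#'
#' @param age Age in years (`NA` allowed); must be non-negative when present.
#' @param bmi Body mass index in kg/m^2 (`NA` allowed); must be positive when
#'   present.
#' @param gender One of `"female"`, `"male"` or `NA`.
#' @param race One of `"Asian"`, `"Black"`, `"Hispanic"`, `"White"` or `NA`.
#' @return An object of class `subject_info`.
#' @export
subject_info <- function(age = NA_real_, bmi = NA_real_, gender = NA_character_,
                         race = NA_character_) {
  age <- as.numeric(age); bmi <- as.numeric(bmi)
  if (!is.na(age) && age < 0) .bp_stop("bp_invalid", "age must be >= 0")
  if (!is.na(bmi) && bmi <= 0) .bp_stop("bp_invalid", "bmi must be > 0")
  gender <- as.character(gender)
  if (!is.na(gender) && !gender %in% c("female", "male"))
    .bp_stop("bp_invalid", "gender must be 'female', 'male' or NA")
  race <- as.character(race)
  if (!is.na(race) && !race %in% c("Asian", "Black", "Hispanic", "White"))
    .bp_stop("bp_invalid", "race must be Asian/Black/Hispanic/White or NA")
  structure(list(age = age, bmi = bmi, gender = gender, race = race),
            class = "subject_info")
}

#' Multichannel waveform record
#'
#' A synchronized block of six physiological channels: four ECG leads (mV,
#' three limb plus one precordial), one SpO2 plethysmographic channel (%) and
#' one intra-arterial blood pressure channel (mmHg), together with the
#' sampling rate and subject demographics. All channels must be the same
#' length. Sample indexing everywhere in this package is 0-based with
#' half-open extents `[start, end)`.
#'
#' @param subject_id Opaque subject identifier.
#' @param fs Sampling rate in Hz (must be positive).
#' @param ecg Numeric matrix with 4 columns (one per lead) in mV, or a list of
#'   4 equal-length vectors.
#' @param spo2 Numeric vector, percent.
#' @param abp Numeric vector, mmHg.
#' @param subject A [subject_info()] object.
#' @param lead_labels Character vector of 4 lead labels; the 4th is treated as
#'   the precordial lead by convention.
#' @param scale_factors Optional named per-channel multipliers applied at
#'   calibration time (manufacturer scale factors). Stored for provenance.
#' @param paced Logical; whether the subject has a pacemaker (drives the
#'   pacing-spike suppression filter during delineation).
#' @return An object of class `waveform_record`.
#' @export
waveform_record <- function(subject_id, fs, ecg, spo2, abp,
                            subject = subject_info(),
                            lead_labels = c("I", "II", "III", "V"),
                            scale_factors = NULL, paced = FALSE) {
  if (is.list(ecg) && !is.matrix(ecg)) ecg <- do.call(cbind, ecg)
  ecg <- as.matrix(ecg)
  if (ncol(ecg) != 4L)
    .bp_stop("bp_format", "ecg must have exactly 4 leads, got %d", ncol(ecg))
  fs <- as.numeric(fs)
  if (!is.finite(fs) || fs <= 0)
    .bp_stop("bp_invalid_record", "fs must be a positive number")
  n <- nrow(ecg)
  if (n < 1L) .bp_stop("bp_invalid_record", "channels must be non-empty")
  if (length(spo2) != n || length(abp) != n)
    .bp_stop("bp_invalid_record",
             "all 6 channels must have the same length (ecg %d, spo2 %d, abp %d)",
             n, length(spo2), length(abp))
  if (length(lead_labels) != 4L)
    .bp_stop("bp_format", "lead_labels must have length 4")
  colnames(ecg) <- paste0("ecg_", lead_labels)
  structure(list(subject_id = as.character(subject_id), fs = fs, ecg = ecg,
                 spo2 = as.numeric(spo2), abp = as.numeric(abp),
                 subject = subject, lead_labels = as.character(lead_labels),
                 scale_factors = scale_factors, paced = isTRUE(paced)),
            class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record> subject %s: 6 channels x %d samples @ %g Hz (%.1f s)%s\n",
              x$subject_id, record_length(x), x$fs,
              record_length(x) / x$fs, if (x$paced) ", paced" else ""))
  invisible(x)
}

#' Number of samples per channel of a record
#' @param record A [waveform_record()].
#' @return Integer sample count.
#' @export
record_length <- function(record) nrow(record$ecg)

#' All six channels of a record as a named list
#'
#' Channel names are `ecg_<label>` for the four ECG leads, then `spo2`, `abp`.
#' @param record A [waveform_record()].
#' @return Named list of 6 numeric vectors.
#' @export
record_channels <- function(record) {
  out <- c(lapply(seq_len(4L), function(j) record$ecg[, j]),
           list(record$spo2), list(record$abp))
  names(out) <- c(colnames(record$ecg), "spo2", "abp")
  out
}

#' Kind ("ecg", "spo2" or "abp") of each channel of a record
#' @param record A [waveform_record()].
#' @return Named character vector of length 6.
#' @export
channel_kinds <- function(record) {
  setNames(c(rep("ecg", 4L), "spo2", "abp"), names(record_channels(record)))
}
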