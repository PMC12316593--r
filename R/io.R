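#' Write a waveform record to a labeled CSV file
#'
#' The dialect is one header row of channel labels (`ecg_<lead>` columns,
#' `spo2`, `abp`) preceded by `#`-prefixed key=value metadata lines carrying
#' the sampling rate, subject id, demographics and pacing flag. This keeps a
#' record fully self-contained in a single plain-text file.
#'
#' @param record A [waveform_record()].
#' @param path Output file path.
#' @param digits Significant digits used when formatting samples.
#' @return `path`, invisibly.
#' @export
write_waveform_record <- function(record, path, digits = 10) {
  meta <- c(fs = record$fs, subject_id = record$subject_id,
            age = record$subject$age, bmi = record$subject$bmi,
            gender = record$subject$gender, race = record$subject$race,
            paced = record$paced,
            lead_labels = paste(record$lead_labels, collapse = ";"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s=%s", names(meta), as.character(meta)), con)
  df <- data.frame(record$ecg, spo2 = record$spo2, abp = record$abp,
                   check.names = FALSE)
  writeLines(paste(colnames(df), collapse = ","), con)
  mat <- vapply(df, function(col) format(col, digits = digits, trim = TRUE,
                                         scientific = FALSE),
                character(nrow(df)))
  writeLines(apply(mat, 1L, paste, collapse = ","), con)
  invisible(path)
}

.parse_csv_meta <- function(path) {
  lines <- readLines(path, n = 50L)
  meta_lines <- grep("^#", lines, value = TRUE)
  out <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      out[[substr(kv, 1L, eq - 1L)]] <- substr(kv, eq + 1L, nchar(kv))
  }
  out
}

#' Read a multichannel waveform record
#'
#' Reads the labeled-CSV dialect written by [write_waveform_record()], or a
#' minimal WFDB-style pair (a `.hea` text header naming the signals plus a
#' plain-text sample matrix). Channel labels must resolve to 4 ECG leads plus
#' one SpO2 and one ABP channel; manufacturer scale factors, when present in
#' the metadata/header, are applied so that samples come back calibrated in
#' mV, percent and mmHg.
#'
#' @param path Path to the CSV file (or WFDB `.hea` header).
#' @param format `"csv"` or `"wfdb"`.
#' @return A [waveform_record()] with the file's sampling rate preserved.
#' @export
read_waveform_record <- function(path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) .bp_stop("bp_io", "file not found: %s", path)
  if (format == "wfdb") return(.read_wfdb_record(path))
  meta <- .parse_csv_meta(path)
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  .record_from_table(df, meta, path)
}

.record_from_table <- function(df, meta, path) {
  nm <- tolower(names(df))
  spo2_col <- which(nm == "spo2")
  abp_col <- which(nm == "abp")
  ecg_cols <- grep("^ecg", nm)
  if (length(ecg_cols) == 0L)  # fall back: all non-pulse columns are ECG
    ecg_cols <- setdiff(seq_along(nm), c(spo2_col, abp_col))
  if (length(spo2_col) != 1L || length(abp_col) != 1L ||
      length(ecg_cols) != 4L)
    .bp_stop("bp_format",
             "%s: need 4 ECG + spo2 + abp channels, found %d ECG, %d spo2, %d abp",
             path, length(ecg_cols), length(spo2_col), length(abp_col))
  num <- vapply(df, is.numeric, logical(1L))
  if (!all(num[c(ecg_cols, spo2_col, abp_col)]))
    .bp_stop("bp_parse", "%s: non-numeric samples in channel columns", path)
  getm <- function(key, default = NA) {
    if (!is.null(meta[[key]])) meta[[key]] else default
  }
  sf <- meta[["scale_factors"]]
  scl <- if (!is.null(sf)) as.numeric(strsplit(sf, ";")[[1]]) else rep(1, 6)
  ecg <- as.matrix(df[, ecg_cols]) %*% diag(scl[1:4], 4L)
  labels <- getm("lead_labels", NA)
  labels <- if (!is.na(labels)) strsplit(labels, ";")[[1]] else
    sub("^ecg_?", "", names(df)[ecg_cols])
  if (!length(labels) == 4L || any(labels == ""))
    labels <- c("I", "II", "III", "V")
  waveform_record(
    subject_id = getm("subject_id", "unknown"),
    fs = as.numeric(getm("fs", BP_FS)),
    ecg = ecg,
    spo2 = df[[spo2_col]] * scl[5L],
    abp = df[[abp_col]] * scl[6L],
    subject = subject_info(
      age = suppressWarnings(as.numeric(getm("age"))),
      bmi = suppressWarnings(as.numeric(getm("bmi"))),
      gender = {g <- getm("gender", NA); if (is.na(g) || g == "NA") NA else g},
      race = {r <- getm("race", NA); if (is.na(r) || r == "NA") NA else r}),
    lead_labels = labels,
    scale_factors = if (!is.null(sf)) scl else NULL,
    paced = isTRUE(getm("paced", "FALSE") %in% c("TRUE", "true", "1")))
}

# Minimal WFDB-style import: `<record>.hea` header with one line per signal
# ("file gain units description"), samples in a whitespace-delimited text
# matrix (one column per signal). Gains divide raw samples into physical
# units, following the WFDB convention.
.read_wfdb_record <- function(hea_path) {
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  top <- strsplit(trimws(lines[1L]), "\\s+")[[1]]
  if (length(top) < 3L) .bp_stop("bp_format", "malformed WFDB header")
  n_sig <- as.integer(top[2L]); fs <- as.numeric(top[3L])
  sig_lines <- lines[seq(2L, 1L + n_sig)]
  parts <- lapply(sig_lines, function(x) strsplit(trimws(x), "\\s+")[[1]])
  dat_file <- parts[[1L]][1L]
  gains <- vapply(parts, function(p)
    suppressWarnings(as.numeric(sub("\\(.*", "", p[2L]))), numeric(1L))
  gains[!is.finite(gains) | gains == 0] <- 1
  desc <- vapply(parts, function(p) paste(p[-(1:2)], collapse = " "),
                 character(1L))
  dat_path <- file.path(dirname(hea_path), dat_file)
  if (!file.exists(dat_path)) .bp_stop("bp_io", "missing sample file %s", dat_path)
  raw <- as.matrix(read.table(dat_path))
  if (ncol(raw) != n_sig)
    .bp_stop("bp_format", "sample matrix has %d columns, header says %d",
             ncol(raw), n_sig)
  phys <- sweep(raw, 2L, gains, "/")
  df <- as.data.frame(phys)
  names(df) <- ifelse(grepl("spo2|pleth", tolower(desc)), "spo2",
               ifelse(grepl("abp|art|pressure", tolower(desc)), "abp",
                      paste0("ecg_", desc)))
  .record_from_table(df, list(fs = as.character(fs),
                              subject_id = sub("\\.hea$", "", basename(hea_path))),
                     hea_path)
}

# Blackman-windowed sinc low-pass interpolation kernel for rational
# resampling by p/q at the p-fold upsampled rate. Half-width `half` input
# samples; long enough that the passband stays flat below ~0.45 of the lower
# Nyquist pair.
.resample_kernel <- function(p, q, half = 32L) {
  m <- max(p, q)
  N <- 2L * half * m + 1L
  k <- seq_len(N) - 1L - (N - 1L) / 2
  fc <- 0.5 / m
  h <- 2 * fc * ifelse(k == 0, 1, sin(2 * pi * fc * k) / (2 * pi * fc * k))
  w <- 0.42 - 0.5 * cos(2 * pi * (seq_len(N) - 1L) / (N - 1L)) +
    0.08 * cos(4 * pi * (seq_len(N) - 1L) / (N - 1L))
  h * w * p
}

.fft_conv_full <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nfft <- stats::nextn(n, 2L)
  y <- Re(fft(fft(c(x, rep(0, nfft - length(x)))) *
              fft(c(h, rep(0, nfft - length(h)))), inverse = TRUE)) / nfft
  y[seq_len(n)]
}

.resample_vector <- function(x, p, q, half = 32L) {
  n <- length(x)
  out_n <- round(n * p / q)
  pad <- half + 2L
  # odd (point-symmetric) reflection keeps value and slope continuous
  left <- 2 * x[1L] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  xp <- c(left, x, right)
  up <- numeric(length(xp) * p)
  up[seq(1L, length(up), by = p)] <- xp
  h <- .resample_kernel(p, q, half)
  y <- .fft_conv_full(up, h)
  delay <- (length(h) - 1L) / 2 + pad * p
  idx <- delay + 1L + seq(0L, by = q, length.out = out_n)
  y[idx]
}

#' Resample a record to the canonical 250 Hz rate
#'
#' Records at 240 Hz (one of the two monitor rates) are converted by rational
#' 25/24 polyphase-style resampling (zero-stuffing, a long Blackman-windowed
#' sinc low-pass, decimation), which is drift-free because the ratio is
#' exact. 250 Hz input is returned unchanged. Other positive rates are
#' accepted with a warning and resampled by the nearest small rational ratio.
#'
#' @param record A [waveform_record()].
#' @return The record with all 6 channels at 250 Hz; total duration preserved
#'   to within one sample.
#' @export
resample_to_250 <- function(record) {
  if (!inherits(record, "waveform_record"))
    .bp_stop("bp_invalid_record", "not a waveform_record")
  fs <- record$fs
  if (fs <= 0) .bp_stop("bp_invalid_record", "fs must be positive")
  if (fs == BP_FS) return(record)
  if (!fs %in% c(240, BP_FS))
    .bp_warn("bp_resample", "unusual sampling rate %g Hz; resampling anyway", fs)
  fsr <- round(fs)
  if (abs(fs - fsr) > 1e-6)
    .bp_stop("bp_invalid_record", "non-integer sampling rates are not supported")
  g <- .gcd(BP_FS, fsr)
  p <- BP_FS %/% g; q <- fsr %/% g
  res <- function(x) .resample_vector(x, p, q)
  ecg <- apply(record$ecg, 2L, res)
  waveform_record(record$subject_id, BP_FS, ecg, res(record$spo2),
                  res(record$abp), record$subject, record$lead_labels,
                  record$scale_factors, record$paced)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)
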