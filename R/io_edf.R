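#' EEG recording container
#'
#' A single-channel EEG recording: an amplitude series in microvolts with its
#' sampling rate and minimal subject metadata.
#'
#' @param samples Numeric vector of amplitudes (microvolts). Must be finite.
#' @param fs_hz Sampling rate in Hz (> 0).
#' @param subject_id Subject identifier string.
#' @param cohort One of `"younger"`, `"older"`, `"unknown"`.
#' @param channel_name EEG channel label (e.g. `"C3"`).
#'
#' @return An object of class `"eeg_recording"`.
#' @export
#' @examples
#' rec <- eeg_recording(sin(2 * pi * 10 * seq(0, 1, by = 1 / 500)), 500)
#' rec
eeg_recording <- function(samples, fs_hz, subject_id = "S001",
                          cohort = c("unknown", "younger", "older"),
                          channel_name = "C3") {
  cohort <- match.arg(cohort)
  stop_if_not_scalar_number(fs_hz, "fs_hz")
  if (fs_hz <= 0) stop("`fs_hz` must be positive", call. = FALSE)
  samples <- as.numeric(samples)
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("`samples` must be finite", call. = FALSE)
  }
  structure(
    list(samples = samples, fs_hz = fs_hz, subject_id = as.character(subject_id),
         cohort = cohort, channel_name = as.character(channel_name)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %s [%s] channel %s: %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, x$cohort, x$channel_name, length(x$samples), x$fs_hz,
    length(x$samples) / x$fs_hz
  ))
  invisible(x)
}

# ---- EDF (European Data Format, 16-bit) ------------------------------------
#
# Minimal single/multi-channel EDF support. The container stores one header of
# 256 bytes, one 256-byte block per signal, and int16 little-endian data
# records of fixed duration (1 s here). Physical calibration is linear between
# (phys_min, phys_max) and (dig_min, dig_max).

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16 bits over a configurable symmetric physical
#' range (default +/- 200 microvolts). The last data record is zero-padded if
#' the recording length is not a whole number of records; [read_edf()] of a
#' padded file returns the padded length.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @param phys_range Symmetric physical range in microvolts (scalar, > 0).
#' @param record_duration_s Duration of one EDF data record in seconds.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, phys_range = 200, record_duration_s = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  stop_if_not_scalar_number(phys_range, "phys_range")
  spr <- rec$fs_hz * record_duration_s
  if (abs(spr - round(spr)) > 1e-9) {
    stop("fs_hz * record_duration_s must be an integer number of samples",
         call. = FALSE)
  }
  spr <- as.integer(round(spr))
  n_rec <- as.integer(ceiling(length(rec$samples) / spr))
  n_sig <- 1L

  dig_min <- -32768; dig_max <- 32767
  pmin <- -abs(phys_range); pmax <- abs(phys_range)
  x <- c(rec$samples, numeric(n_rec * spr - length(rec$samples)))
  dig <- round((x - pmin) / (pmax - pmin) * (dig_max - dig_min) + dig_min)
  dig <- pmin(pmax(dig, dig_min), dig_max)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(rec$subject_id, 80),
    pad_field(paste0("cohort=", rec$cohort), 80),
    pad_field("01.01.00", 8),
    pad_field("00.00.00", 8),
    pad_field(256 * (1 + n_sig), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field(format(record_duration_s), 8),
    pad_field(n_sig, 4)
  )
  sig <- paste0(
    pad_field(rec$channel_name, 16),
    pad_field("", 80),
    pad_field("uV", 8),
    pad_field(format(pmin), 8),
    pad_field(format(pmax), 8),
    pad_field(dig_min, 8),
    pad_field(dig_max, 8),
    pad_field("", 80),
    pad_field(spr, 8),
    pad_field("", 32)
  )
  writeChar(paste0(hdr, sig), con, eos = NULL)
  writeBin(as.integer(dig), con, size = 2L, endian = "little")
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(n) {
    raw <- readBin(con, "raw", n)
    trimws(rawToChar(raw))
  }
  version <- rd(8)
  if (version != "0") stop("malformed EDF header: bad version field", call. = FALSE)
  patient <- rd(80); recording <- rd(80)
  rd(8); rd(8) # start date/time, unused
  hdr_bytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  n_sig <- suppressWarnings(as.integer(rd(4)))
  if (anyNA(c(hdr_bytes, n_rec, n_sig)) || is.na(rec_dur) || n_sig < 1L) {
    stop("malformed EDF header: unparsable numeric fields", call. = FALSE)
  }
  per_field <- function(width) {
    vapply(seq_len(n_sig), function(i) {
      trimws(rawToChar(readBin(con, "raw", width)))
    }, character(1))
  }
  labels <- per_field(16); per_field(80)
  dims <- per_field(8)
  pmin <- as.numeric(per_field(8)); pmax <- as.numeric(per_field(8))
  dmin <- as.numeric(per_field(8)); dmax <- as.numeric(per_field(8))
  per_field(80)
  spr <- as.integer(per_field(8)); per_field(32)
  list(patient = patient, recording = recording, n_rec = n_rec,
       rec_dur = rec_dur, n_sig = n_sig, labels = labels, dims = dims,
       pmin = pmin, pmax = pmax, dmin = dmin, dmax = dmax, spr = spr,
       hdr_bytes = hdr_bytes)
}

#' Read one channel of an EDF file
#'
#' @param path Path to an EDF file.
#' @param channel_name Channel label to extract. May be omitted for
#'   single-channel files; for multi-channel files it is required, and an
#'   unknown label raises an error naming the available channels.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, channel_name = NULL) {
  if (!file.exists(path)) stop(sprintf("EDF file not found: %s", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  if (is.null(channel_name)) {
    if (h$n_sig > 1L) {
      stop(sprintf(
        "multi-channel EDF: select `channel_name` among: %s",
        paste(h$labels, collapse = ", ")
      ), call. = FALSE)
    }
    ch <- 1L
  } else {
    ch <- match(channel_name, h$labels)
    if (is.na(ch)) {
      stop(sprintf("channel '%s' not in EDF; available: %s",
                   channel_name, paste(h$labels, collapse = ", ")), call. = FALSE)
    }
  }
  per_rec <- sum(h$spr)
  dig <- readBin(con, "integer", n = h$n_rec * per_rec, size = 2L,
                 endian = "little")
  if (length(dig) != h$n_rec * per_rec) {
    stop("malformed EDF: truncated data section", call. = FALSE)
  }
  offs <- c(0L, cumsum(h$spr))
  idx <- as.vector(outer(seq_len(h$spr[ch]) + offs[ch], (0:(h$n_rec - 1L)) * per_rec, `+`))
  d <- dig[idx]
  phys <- (d - h$dmin[ch]) * (h$pmax[ch] - h$pmin[ch]) /
    (h$dmax[ch] - h$dmin[ch]) + h$pmin[ch]
  cohort <- sub("^cohort=", "", h$recording)
  if (!cohort %in% c("younger", "older")) cohort <- "unknown"
  eeg_recording(phys, fs_hz = h$spr[ch] / h$rec_dur,
                subject_id = h$patient, cohort = cohort,
                channel_name = h$labels[ch])
}
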