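#' Write an ECG record as CSV plus JSON sidecar
#'
#' The plain-text dialect stores the trace as a two-column CSV
#' (`time_s`, `voltage_uV`) next to a JSON sidecar (same path, `.json`
#' extension) holding `fs`, the beat sample indices, the onset time, the
#' group label and the record id.
#'
#' @param record An [ecg_record()].
#' @param path Output path for the CSV file (the sidecar replaces the
#'   extension with `.json`).
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  df <- data.frame(
    time_s = (seq_along(record$samples) - 1L) / record$fs,
    voltage_uV = record$samples
  )
  write.csv(df, path, row.names = FALSE)
  meta <- list(fs = record$fs, beats = record$beat_indices,
               onset = record$onset_time, label = record$label,
               record_id = record$record_id)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[^.]*$", ".json", path)

read_record_csv <- function(path) {
  side <- sidecar_path(path)
  if (!file.exists(side)) {
    abort(sprintf("Missing JSON sidecar for %s", path), class = "vf_io_error")
  }
  df <- read.csv(path)
  if (!all(c("time_s", "voltage_uV") %in% names(df))) {
    abort("CSV must have columns `time_s` and `voltage_uV`.",
          class = "vf_format_error")
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  onset <- meta$onset
  if (is.null(onset) || length(onset) == 0 || all(is.na(onset))) onset <- NULL
  ecg_record(df$voltage_uV, fs = meta$fs,
             beat_indices = as.integer(meta$beats %||% integer()),
             onset_time = onset, label = meta$label %||% "control",
             record_id = meta$record_id %||% basename(path))
}

#' Read an ECG record (synthetic CSV dialect or WFDB)
#'
#' Dispatches on the file extension: `.csv` reads the synthetic CSV + JSON
#' sidecar dialect written by [write_record_csv()]; anything else is treated
#' as a WFDB record name (path without extension, or the `.hea` file) and
#' read with the built-in WFDB loader (signal formats 16 and 212, MIT
#' annotation files).
#'
#' @param path Path to a `.csv` file or a WFDB record (with or without
#'   `.hea`).
#' @param ... Passed to [read_wfdb()] for WFDB input.
#' @return An [ecg_record()] with samples in uV.
#' @export
read_record <- function(path, ...) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    read_record_csv(path)
  } else {
    read_wfdb(sub("\\.hea$", "", path), ...)
  }
}

#' Minimal WFDB reader (formats 16 and 212, MIT annotations)
#'
#' Reads the header (`.hea`), the first signal of the binary signal file and,
#' when present, the annotation file. Sample values are converted to uV via
#' `(adu - baseline) / gain` (gain in adu/mV, so the result is scaled by
#' 1000). Beat annotations (codes 1-13, 25, 34, 35, 38) become
#' `beat_indices`; a VF-onset marker (code 32, "[") becomes `onset_time` and
#' flips the label to `"VF"`.
#'
#' @param record_name WFDB record path without extension.
#' @param annotator Annotation file extension (default `"atr"`); `NULL`
#'   skips annotations.
#' @return An [ecg_record()].
#' @export
read_wfdb <- function(record_name, annotator = "atr") {
  hea <- paste0(record_name, ".hea")
  if (!file.exists(hea)) {
    abort(sprintf("Header file not found: %s", hea), class = "vf_io_error")
  }
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(hdr[2])
  fs <- if (length(hdr) >= 3) as.numeric(sub("/.*", "", hdr[3])) else 250
  nsamp <- if (length(hdr) >= 4) as.integer(hdr[4]) else NA_integer_
  sig <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  dat_file <- file.path(dirname(record_name), sig[1])
  fmt <- as.integer(sub("x.*|:.*|\\+.*", "", sig[2]))
  gain_field <- if (length(sig) >= 3) sig[3] else "200"
  gain <- as.numeric(sub("\\(.*", "", sub("/.*", "", gain_field)))
  if (!is.finite(gain) || gain == 0) gain <- 200
  baseline <- if (grepl("\\(", gain_field)) {
    as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_field))
  } else 0
  if (!file.exists(dat_file)) {
    abort(sprintf("Signal file not found: %s", dat_file), class = "vf_io_error")
  }
  raw <- readBin(dat_file, "raw", n = file.info(dat_file)$size)
  adu <- decode_wfdb_signal(raw, fmt, nsig)
  if (!is.na(nsamp) && length(adu) < nsamp) {
    abort(sprintf("Signal file %s shorter than header declares.", dat_file),
          class = "vf_format_error")
  }
  if (!is.na(nsamp)) adu <- adu[seq_len(nsamp)]
  uv <- (adu - baseline) / gain * 1000

  beat_idx <- integer()
  onset <- NULL
  label <- "control"
  if (!is.null(annotator)) {
    ann_file <- paste0(record_name, ".", annotator)
    if (!file.exists(ann_file)) {
      abort(sprintf("Annotation file not found: %s", ann_file),
            class = "vf_io_error")
    }
    ann <- read_mit_annotations(ann_file)
    beat_codes <- c(1:13, 25, 34, 35, 38)
    beat_idx <- ann$sample[ann$code %in% beat_codes] + 1L
    von <- ann$sample[ann$code == 32L]
    if (length(von) > 0) {
      onset <- von[1] / fs
      label <- "VF"
    }
  }
  ecg_record(uv, fs = fs, beat_indices = beat_idx, onset_time = onset,
             label = label, record_id = basename(record_name))
}

# First-signal adu values from a WFDB .dat payload (format 16 or 212).
decode_wfdb_signal <- function(raw, fmt, nsig) {
  if (fmt == 16) {
    v <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                 signed = TRUE, endian = "little")
    if (nsig > 1) v <- v[seq(1L, length(v), by = nsig)]
    v
  } else if (fmt == 212) {
    b <- as.integer(raw)
    n_pairs <- length(b) %/% 3L
    b <- b[seq_len(3L * n_pairs)]
    b1 <- b[seq(1, length(b), 3)]
    b2 <- b[seq(2, length(b), 3)]
    b3 <- b[seq(3, length(b), 3)]
    s1 <- bitwAnd(b2, 15L) * 256L + b1
    s2 <- bitwAnd(bitwShiftR(b2, 4L), 15L) * 256L + b3
    s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
    s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
    v <- as.vector(rbind(s1, s2))
    if (nsig > 1) v <- v[seq(1L, length(v), by = nsig)]
    v
  } else {
    abort(sprintf("Unsupported WFDB signal format %d.", fmt),
          class = "vf_format_error")
  }
}

# MIT annotation atoms: 16-bit little-endian words; top 6 bits = code,
# low 10 bits = time increment. Handles SKIP (59) long intervals; NUM/SUB/
# CHN/AUX modifiers are consumed and ignored.
read_mit_annotations <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  b <- as.integer(raw)
  n <- length(b) %/% 2L
  samples <- integer(0)
  codes <- integer(0)
  t_cur <- 0
  i <- 1L
  while (i + 1L <= 2L * n) {
    lo <- b[i]; hi <- b[i + 1L]
    code <- bitwShiftR(hi, 2L)
    inc <- bitwAnd(hi, 3L) * 256L + lo
    i <- i + 2L
    if (code == 0L && inc == 0L) break          # EOF
    if (code == 59L) {                          # SKIP: 4-byte interval follows
      if (inc == 0L && i + 3L <= length(b)) {
        interval <- b[i + 1L] * 65536L * 256L + b[i] * 65536L +
          b[i + 3L] * 256L + b[i + 2L]
        t_cur <- t_cur + interval
        i <- i + 4L
      }
      next
    }
    if (code %in% c(60L, 61L, 62L)) next        # NUM / SUB / CHN
    if (code == 63L) {                          # AUX: inc = byte count
      i <- i + inc + (inc %% 2L)
      next
    }
    t_cur <- t_cur + inc
    samples <- c(samples, t_cur)
    codes <- c(codes, code)
  }
  list(sample = samples, code = codes)
}

#' Write a WFDB-compatible record (format 16) with annotations
#'
#' Writes `<name>.hea`, `<name>.dat` (16-bit little-endian, single signal)
#' and `<name>.atr` (MIT annotation format: NORMAL beats at the record's
#' beat indices, a VF-onset marker when present).
#'
#' @param record An [ecg_record()].
#' @param record_name Output path without extension.
#' @param gain Gain in adu/mV used for quantisation (default 200).
#' @return `record_name`, invisibly.
#' @export
write_wfdb <- function(record, record_name, gain = 200) {
  stopifnot(inherits(record, "ecg_record"))
  adu <- as.integer(round(record$samples / 1000 * gain))
  adu <- pmax(pmin(adu, 32767L), -32768L)
  dat <- paste0(record_name, ".dat")
  writeBin(adu, dat, size = 2L, endian = "little")
  hea <- c(
    sprintf("%s 1 %g %d", basename(record_name), record$fs,
            length(adu)),
    sprintf("%s.dat 16 %g(0) 16 0 %d 0 0 ECG", basename(record_name),
            gain, adu[1])
  )
  writeLines(hea, paste0(record_name, ".hea"))

  events <- data.frame(sample = record$beat_indices - 1L,
                       code = rep(1L, length(record$beat_indices)))
  if (!is.null(record$onset_time)) {
    events <- rbind(events, data.frame(
      sample = as.integer(round(record$onset_time * record$fs)), code = 32L))
    events <- events[order(events$sample), ]
  }
  con <- file(paste0(record_name, ".atr"), "wb")
  on.exit(close(con))
  t_prev <- 0L
  for (k in seq_len(nrow(events))) {
    inc <- events$sample[k] - t_prev
    while (inc > 1023L) {  # SKIP atom for long gaps
      writeBin(as.raw(c(0L, bitwShiftL(59L, 2L))), con)
      writeBin(as.raw(c(bitwAnd(bitwShiftR(inc, 16L), 255L),
                        bitwShiftR(inc, 24L),
                        bitwAnd(inc, 255L),
                        bitwAnd(bitwShiftR(inc, 8L), 255L))), con)
      t_prev <- t_prev + inc
      inc <- 0L
    }
    writeBin(as.raw(c(bitwAnd(inc, 255L),
                      bitwShiftL(events$code[k], 2L) +
                        bitwShiftR(inc, 8L))), con)
    t_prev <- events$sample[k]
  }
  writeBin(as.raw(c(0L, 0L)), con)
  invisible(record_name)
}

#' Trim a record to its 120-s analysis window
#'
#' For VF records the analysis ("required") window is the 120 s between
#' 150 s and 30 s before VF onset; the final 30 s before onset (the
#' "forecast" window) is never used for features. For control records the
#' window is 120 s starting at `control_offset` (default: record start).
#' Windows are half-open `[start, end)` in seconds; a beat exactly at the
#' window end is excluded, one exactly at the start is kept. Beats are
#' re-indexed to the trimmed record. Records already trimmed are returned
#' unchanged, so windowing is idempotent.
#'
#' @param record An [ecg_record()].
#' @param control_offset Start (s) of the control window.
#' @return A trimmed [ecg_record()] (attribute `"windowed"` set).
#' @export
required_window <- function(record, control_offset = 0) {
  stopifnot(inherits(record, "ecg_record"))
  if (isTRUE(attr(record, "windowed"))) return(record)
  dur <- record_duration(record)
  if (record$label == "VF") {
    if (is.null(record$onset_time) || record$onset_time < 150) {
      abort(sprintf(
        "record %s excluded: VF onset %s is under the 150 s required length",
        record$record_id,
        if (is.null(record$onset_time)) "missing"
        else sprintf("%.1f s", record$onset_time)),
        class = "vf_exclusion_error", record_id = record$record_id)
    }
    start <- record$onset_time - 150
    end <- record$onset_time - 30
  } else {
    if (dur < control_offset + 120) {
      abort(sprintf("record %s excluded: shorter than the 120 s window",
                    record$record_id),
            class = "vf_exclusion_error", record_id = record$record_id)
    }
    start <- control_offset
    end <- control_offset + 120
  }
  # half-open sample range [start_idx, end_idx) on the 0-based sample grid
  start_idx <- floor(start * record$fs)
  end_idx <- floor(end * record$fs)
  samples <- record$samples[(start_idx + 1L):min(end_idx, length(record$samples))]
  keep <- record$beat_indices > start_idx & record$beat_indices <= start_idx + length(samples)
  # a beat exactly at the window end sample is excluded by the half-open rule
  keep <- keep & (record$beat_indices - 1L) < end_idx
  beats <- record$beat_indices[keep] - start_idx
  out <- ecg_record(samples, fs = record$fs, beat_indices = beats,
                    onset_time = NULL, label = record$label,
                    record_id = record$record_id)
  attr(out, "windowed") <- TRUE
  attr(out, "window") <- c(start = start, end = end)
  truth <- attr(record, "truth")
  if (!is.null(truth)) {
    tkeep <- truth$beat_times >= start & truth$beat_times < end
    attr(out, "truth") <- list(
      beat_times = truth$beat_times[tkeep] - start,
      r_amp_true = truth$r_amp_true[tkeep],
      qrs_area_true = truth$qrs_area_true[tkeep]
    )
  }
  out
}

#' Derive the RR series from a record's beat annotations
#'
#' @param record An [ecg_record()] with at least 3 annotated beats.
#' @return An [rr_series()]: `rr(i) = (t(i+1) - t(i)) * 1000` ms, `t` the
#'   interval end times in seconds.
#' @export
#' @examples
#' rec <- ecg_record(numeric(500), fs = 250, beat_indices = c(1L, 201L, 401L))
#' rr_from_beats(rec)
rr_from_beats <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  if (length(record$beat_indices) < 3) {
    abort(sprintf("record %s: need at least 3 beats to form an RR series",
                  record$record_id),
          class = "vf_insufficient_data")
  }
  bt <- beat_times(record)
  rr_series(diff(bt) * 1000, t = bt[-1L])
}
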