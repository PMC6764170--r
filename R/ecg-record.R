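#' ECG record container
#'
#' A light S3 container for a uniformly sampled single-lead ECG voltage trace
#' with beat annotations, an optional VF-onset marker and a group label.
#' Voltages are stored in microvolts, beat positions as 1-based sample
#' indices of the annotated R peaks.
#'
#' @param samples Numeric vector of voltages, in uV.
#' @param fs Sampling rate in Hz (> 0).
#' @param beat_indices Integer vector of R-peak sample positions (1-based,
#'   strictly increasing, inside the record).
#' @param onset_time VF onset in seconds from record start, or `NULL` for
#'   records without a fibrillation event (controls).
#' @param label Group label, `"VF"` or `"control"`.
#' @param record_id Identifier used in feature tables and error messages.
#'
#' @return An object of class `ecg_record`.
#' @export
#' @examples
#' rec <- ecg_record(sin(seq(0, 2 * pi, length.out = 250)), fs = 250,
#'                   beat_indices = 63L, record_id = "toy")
#' rec
ecg_record <- function(samples, fs, beat_indices = integer(),
                       onset_time = NULL, label = c("control", "VF"),
                       record_id = "record") {
  label <- match.arg(label)
  samples <- as.numeric(samples)
  beat_indices <- as.integer(beat_indices)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number.", class = "vf_invalid_parameter")
  }
  if (length(beat_indices) > 0) {
    if (any(diff(beat_indices) <= 0)) {
      abort("`beat_indices` must be strictly increasing.",
            class = "vf_invalid_parameter")
    }
    if (beat_indices[1] < 1L || beat_indices[length(beat_indices)] > length(samples)) {
      abort("`beat_indices` must lie inside the record.",
            class = "vf_invalid_parameter")
    }
  }
  duration <- length(samples) / fs
  if (!is.null(onset_time)) {
    if (!is.finite(onset_time) || onset_time < 0 || onset_time > duration) {
      abort("`onset_time` must lie within the record duration.",
            class = "vf_invalid_parameter")
    }
  }
  structure(
    list(samples = samples, fs = fs, beat_indices = beat_indices,
         onset_time = onset_time, label = label, record_id = record_id),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  cat(sprintf("<ecg_record> %s [%s]: %.1f s at %g Hz, %d beats%s\n",
              x$record_id, x$label, dur, x$fs, length(x$beat_indices),
              if (is.null(x$onset_time)) ""
              else sprintf(", VF onset at %.1f s", x$onset_time)))
  invisible(x)
}

#' @export
format.ecg_record <- function(x, ...) {
  sprintf("<ecg_record %s>", x$record_id)
}

record_duration <- function(record) length(record$samples) / record$fs

# Beat times in seconds (1-based sample index convention: sample 1 is t = 0).
beat_times <- function(record) (record$beat_indices - 1L) / record$fs

#' RR-interval series
#'
#' An ordered series of R-peak to R-peak (RR) intervals, the raw material of
#' all HRV features. Stored as a tibble with columns `rr` (interval length,
#' ms) and `t` (interval end time, s) so it pipes directly into the feature
#' functions and ggplot2.
#'
#' @param rr Numeric vector of RR intervals in milliseconds (all > 0).
#' @param t Interval end times in seconds; defaults to the cumulative sum of
#'   `rr` (first beat at time 0).
#'
#' @return A tibble of class `rr_series` with columns `rr` and `t`.
#' @export
#' @examples
#' rr_series(c(800, 810, 790))
rr_series <- function(rr, t = cumsum(rr) / 1000) {
  rr <- as.numeric(rr)
  if (length(rr) == 0 || any(!is.finite(rr)) || any(rr <= 0)) {
    abort("RR intervals must be positive and finite.",
          class = "vf_invalid_parameter")
  }
  if (length(t) != length(rr) || any(diff(t) <= 0)) {
    abort("`t` must be increasing and match `rr` in length.",
          class = "vf_invalid_parameter")
  }
  out <- tibble(rr = rr, t = as.numeric(t))
  class(out) <- c("rr_series", class(out))
  out
}

# Coerce data-frame-like or bare numeric input to an RR vector.
as_rr_vector <- function(rr) {
  if (is.data.frame(rr)) {
    if (!"rr" %in% names(rr)) {
      abort("Data-frame input must have an `rr` column.",
            class = "vf_invalid_parameter")
    }
    as.numeric(rr$rr)
  } else {
    as.numeric(rr)
  }
}
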