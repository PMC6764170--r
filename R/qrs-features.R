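#' Detect R peaks in an ECG record
#'
#' When the record carries beat annotations they are returned unchanged
#' (annotations are authoritative, mirroring cardiologist-annotated
#' databases). Otherwise a Pan-Tompkins-style detector runs: 5-15 Hz
#' Butterworth band-pass (zero-phase), derivative, squaring, 150-ms moving
#' average, adaptive threshold with a 200-ms refractory period, and
#' refinement of each detection to the local maximum of the raw signal.
#'
#' @param record An [ecg_record()] at least 2 s long.
#' @param use_annotations Return `beat_indices` verbatim when present
#'   (default `TRUE`).
#' @return Integer vector of R-peak sample indices (1-based). Empty, with a
#'   warning, when no peak clears the threshold.
#' @export
detect_r_peaks <- function(record, use_annotations = TRUE) {
  stopifnot(inherits(record, "ecg_record"))
  if (use_annotations && length(record$beat_indices) > 0) {
    return(record$beat_indices)
  }
  x <- record$samples
  fs <- record$fs
  if (length(x) < 2 * fs) {
    abort("Record must be at least 2 s long for peak detection.",
          class = "vf_insufficient_data")
  }
  if (all(x == x[1])) {
    warn("Flat signal: no R peaks detected.")
    return(integer())
  }
  bp <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, x)
  sq <- c(0, diff(xf))^2
  win <- max(1L, as.integer(round(0.15 * fs)))
  ma <- stats::filter(sq, rep(1 / win, win), sides = 2)
  ma[is.na(ma)] <- 0
  ma <- as.numeric(ma)
  thr <- 0.2 * quantile(ma, 0.995)
  if (!is.finite(thr) || thr <= 0) {
    warn("No energy above the detection threshold; no R peaks detected.")
    return(integer())
  }
  above <- ma > thr
  # rising edges of the above-threshold regions
  starts <- which(diff(c(FALSE, above)) == 1)
  ends <- which(diff(c(above, FALSE)) == -1)
  refr <- as.integer(round(0.2 * fs))
  peaks <- integer()
  last <- -refr
  half <- as.integer(round(0.1 * fs))
  for (k in seq_along(starts)) {
    lo <- starts[k]; hi <- ends[k]
    cand <- lo - 1L + which.max(ma[lo:hi])
    # refine on the raw trace around the energy peak
    rlo <- max(1L, cand - half); rhi <- min(length(x), cand + half)
    seg <- x[rlo:rhi]
    cand <- rlo - 1L + which.max(abs(seg - median(seg)))
    if (cand - last >= refr) {
      peaks <- c(peaks, cand)
      last <- cand
    }
  }
  if (length(peaks) == 0) warn("No R peaks detected above threshold.")
  peaks
}

#' Delineate the QRS window around an R peak
#'
#' Finds the PQ-junction and J-point boundaries by scanning outward from
#' the R peak (starting 16 ms away, up to `scan_ms`) for the nearest sample
#' where the smoothed slope magnitude drops below `slope_frac` of its local
#' maximum while the signal sits within `amp_frac` of the R amplitude from
#' the local baseline level. When a side finds no such point the fixed
#' `fallback_ms` offset is used. The per-beat baseline is the mean of the
#' 40-ms segment ending at the PQ junction.
#'
#' @param record An [ecg_record()].
#' @param r_index R-peak sample index (1-based).
#' @param scan_ms Maximum scan distance from R, ms (default 120).
#' @param fallback_ms Fixed boundary offset when the scan fails, ms
#'   (default 60).
#' @param slope_frac,amp_frac Relative slope and amplitude thresholds.
#' @return A list of class `qrs_window`: `pq_index`, `j_index`, `r_index`,
#'   `baseline` (uV), `fallback` (logical pair). `NULL` (with a log
#'   message) when the window would cross the record edge.
#' @export
qrs_window <- function(record, r_index, scan_ms = 120, fallback_ms = 60,
                       slope_frac = 0.05, amp_frac = 0.12) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$samples
  fs <- record$fs
  scan <- as.integer(round(scan_ms / 1000 * fs))
  if (r_index - scan < 1L || r_index + scan > length(x)) {
    inform(sprintf("record %s: beat at sample %d too close to the edge; skipped",
                   record$record_id, r_index))
    return(NULL)
  }
  idx <- (r_index - scan):(r_index + scan)
  seg <- x[idx]
  dseg <- diff(seg)
  slope <- abs(c(dseg[1], dseg))
  # 5-sample rolling mean of the slope magnitude (cumsum form, edge-shrunk)
  L <- length(slope)
  cs <- cumsum(c(0, slope))
  lo <- pmax(seq_len(L) - 3L, 0L)
  hi <- pmin(seq_len(L) + 2L, L)
  sm <- (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
  thr <- slope_frac * max(sm)
  quiet_level <- median(seg)
  r_amp <- abs(x[r_index] - quiet_level)
  start_off <- max(1L, as.integer(round(0.016 * fs)))

  find_boundary <- function(offsets) {
    for (o in offsets) {
      k <- scan + 1L + o  # position in seg of R + o
      if (sm[k] <= thr && abs(seg[k] - quiet_level) <= amp_frac * r_amp) {
        return(r_index + o)
      }
    }
    NA_integer_
  }
  pq <- find_boundary(-(start_off:scan))
  jp <- find_boundary(start_off:scan)
  fb <- as.integer(round(fallback_ms / 1000 * fs))
  fallback <- c(pq = is.na(pq), j = is.na(jp))
  if (is.na(pq)) pq <- r_index - fb
  if (is.na(jp)) jp <- r_index + fb
  if (pq < 1L || jp > length(x)) {
    inform(sprintf("record %s: beat at sample %d too close to the edge; skipped",
                   record$record_id, r_index))
    return(NULL)
  }
  base_n <- as.integer(round(0.04 * fs))
  base_lo <- max(1L, pq - base_n + 1L)
  structure(
    list(pq_index = as.integer(pq), j_index = as.integer(jp),
         r_index = as.integer(r_index),
         baseline = mean(x[base_lo:pq]), fallback = fallback),
    class = "qrs_window"
  )
}

#' Signed area of a QRS complex
#'
#' Weighted sum of the baseline-corrected samples between the PQ junction
#' and the J point: `sum(weight * (x - baseline))` over `[pq_index,
#' j_index]`. The default weight is uniform (1); pass a function of the
#' within-window sample positions for other kernels. The sign is preserved:
#' net-downward complexes give negative areas.
#'
#' @param record An [ecg_record()].
#' @param w A [qrs_window()].
#' @param weight `NULL` for uniform weights, or `function(k)` over
#'   1..window length.
#' @return Signed area in uV-samples.
#' @export
signed_area <- function(record, w, weight = NULL) {
  stopifnot(inherits(w, "qrs_window"))
  seg <- record$samples[w$pq_index:w$j_index] - w$baseline
  if (is.null(weight)) sum(seg) else sum(weight(seq_along(seg)) * seg)
}

#' R-peak amplitude within a QRS window
#'
#' Maximum baseline-corrected sample value between the window boundaries.
#'
#' @inheritParams signed_area
#' @return Amplitude in uV.
#' @export
r_amplitude <- function(record, w) {
  stopifnot(inherits(w, "qrs_window"))
  max(record$samples[w$pq_index:w$j_index] - w$baseline)
}

#' Aggregate per-beat areas and amplitudes into the 4 QRS shape features
#'
#' `qrsam` and `qrsasd` are the mean and population SD of the *absolute*
#' signed areas; `rpampm` and `rpampsd` the mean and population SD of the
#' amplitudes (no absolute value).
#'
#' @param areas Per-beat signed areas (uV-samples).
#' @param amps Per-beat R amplitudes (uV).
#' @return A one-row tibble with columns `qrsam`, `qrsasd`, `rpampm`,
#'   `rpampsd`.
#' @export
#' @examples
#' qrs_shape_features(c(-100, 100), c(500, 700))
qrs_shape_features <- function(areas, amps) {
  if (length(areas) < 2 || length(amps) < 2) {
    abort("Need at least 2 beats for QRS shape features.",
          class = "vf_insufficient_data")
  }
  a <- abs(areas)
  tibble(
    qrsam = mean(a),
    qrsasd = sd_pop(a),
    rpampm = mean(amps),
    rpampsd = sd_pop(amps)
  )
}

#' Per-beat QRS diagnostics table
#'
#' Runs detection and delineation over every beat of a record and returns
#' one row per usable beat, for audit and for [qrs_features()].
#'
#' @param record An [ecg_record()].
#' @param ... Passed to [qrs_window()].
#' @return A tibble: `record_id`, `beat`, `r_index`, `pq_index`, `j_index`,
#'   `area`, `amplitude`.
#' @export
qrs_beat_table <- function(record, ...) {
  peaks <- detect_r_peaks(record)
  nb <- length(peaks)
  beat <- integer(nb); pq <- integer(nb); jp <- integer(nb)
  area <- numeric(nb); amp <- numeric(nb)
  kept <- 0L
  for (b in seq_len(nb)) {
    w <- qrs_window(record, peaks[b], ...)
    if (is.null(w)) next
    kept <- kept + 1L
    beat[kept] <- b
    pq[kept] <- w$pq_index
    jp[kept] <- w$j_index
    area[kept] <- signed_area(record, w)
    amp[kept] <- r_amplitude(record, w)
  }
  i <- seq_len(kept)
  tibble(record_id = record$record_id, beat = beat[i],
         r_index = peaks[beat[i]], pq_index = pq[i], j_index = jp[i],
         area = area[i], amplitude = amp[i])
}

#' The 4 QRS shape features of a record
#'
#' @param record An [ecg_record()] (typically already trimmed with
#'   [required_window()]).
#' @param ... Passed to [qrs_window()].
#' @return A one-row tibble with columns `qrsam`, `qrsasd`, `rpampm`,
#'   `rpampsd` (uV-sample / uV units).
#' @export
qrs_features <- function(record, ...) {
  tab <- qrs_beat_table(record, ...)
  if (nrow(tab) < 2) {
    abort(sprintf("record %s: fewer than 2 usable beats", record$record_id),
          class = "vf_insufficient_data")
  }
  qrs_shape_features(tab$area, tab$amplitude)
}
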