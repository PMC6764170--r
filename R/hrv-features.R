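#' Time-domain HRV features
#'
#' Computes the four time-domain features from an RR series:
#' * `mean_nn`: mean NN (RR) interval, ms.
#' * `sdnn`: population (1/N) SD of the intervals, ms.
#' * `rmssd`: root mean square of the successive differences, ms (mean taken
#'   over the N-1 differences).
#' * `pnn50`: percentage of successive differences exceeding 50 ms in
#'   magnitude. The denominator is, by the printed definition, the total
#'   number of RR intervals N; set `pnn50_denominator = "differences"` for
#'   the N-1 convention used by some toolkits.
#'
#' @param rr An [rr_series()], a data frame with an `rr` column, or a bare
#'   numeric vector of intervals in ms (N >= 2).
#' @param pnn50_denominator `"intervals"` (N, default) or `"differences"`
#'   (N-1).
#' @return A one-row tibble with columns `mean_nn`, `sdnn`, `rmssd`,
#'   `pnn50`.
#' @export
#' @examples
#' hrv_time_domain(c(700, 800, 900))
hrv_time_domain <- function(rr, pnn50_denominator = c("intervals", "differences")) {
  pnn50_denominator <- match.arg(pnn50_denominator)
  x <- as_rr_vector(rr)
  if (length(x) < 2) {
    abort("Need at least 2 RR intervals for time-domain features.",
          class = "vf_insufficient_data")
  }
  d <- diff(x)
  denom <- if (pnn50_denominator == "intervals") length(x) else length(d)
  tibble(
    mean_nn = mean(x),
    sdnn = sd_pop(x),
    rmssd = sqrt(mean(d^2)),
    pnn50 = 100 * sum(abs(d) > 50) / denom
  )
}

#' Welch power spectral density estimate
#'
#' Welch's averaged-periodogram PSD with a Hann window, segment length
#' `nfft` and fractional `overlap`. Each segment is demeaned before
#' windowing; the one-sided PSD is returned, normalised so that
#' `sum(psd) * fs / nfft` equals the signal's variance-based total power.
#'
#' @param x Numeric signal (length >= `nfft`).
#' @param fs Sampling rate, Hz.
#' @param nfft Segment length in samples (default 256).
#' @param overlap Fractional segment overlap (default 0.5).
#' @return A tibble with columns `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, nfft = 256, overlap = 0.5) {
  n <- length(x)
  if (n < nfft) {
    abort(sprintf("Signal (%d samples) shorter than one %d-point segment.",
                  n, nfft),
          class = "vf_insufficient_data")
  }
  step <- max(1L, as.integer(round(nfft * (1 - overlap))))
  starts <- seq(1L, n - nfft + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nfft - 1L)) / (nfft - 1L))  # Hann
  U <- sum(w^2)
  acc <- numeric(nfft)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1L)]
    seg <- seg - mean(seg)
    acc <- acc + Mod(fft(seg * w))^2 / (fs * U)
  }
  pxx <- acc / length(starts)
  half <- seq_len(nfft %/% 2L + 1L)
  p <- pxx[half]
  p[2:(nfft %/% 2L)] <- 2 * p[2:(nfft %/% 2L)]
  tibble(freq = (half - 1L) * fs / nfft, psd = p)
}

#' Frequency-domain HRV features
#'
#' Resamples the RR tachogram to an even grid by cubic-spline
#' interpolation, removes a linear trend, estimates the PSD with Welch's
#' periodogram (Hann window, 256 points, 50% overlap) and integrates it
#' over the three conventional bands: VLF (0, 0.04], LF (0.04, 0.15] and
#' HF (0.15, 0.4] Hz. Powers are in ms^2; `lf_hf` is the LF/HF ratio,
#' `NA` (with a warning) when HF power is zero.
#'
#' @param rr An [rr_series()] (the interval end times are needed). A bare
#'   numeric vector is assumed evenly spaced at its own mean interval.
#' @param resample_fs Tachogram resampling rate, Hz (default 4: the
#'   conventional choice, making one 256-point Welch segment 64 s).
#' @param nfft,overlap Welch parameters, see [welch_psd()].
#' @return A one-row tibble with columns `vlf`, `lf`, `hf`, `lf_hf`.
#' @export
#' @examples
#' rr <- generate_rr(group_params(lf_mod_amp = 30), duration = 120, seed = 1)
#' hrv_frequency_domain(rr)
hrv_frequency_domain <- function(rr, resample_fs = 4, nfft = 256,
                                 overlap = 0.5) {
  x <- as_rr_vector(rr)
  t <- if (is.data.frame(rr) && "t" %in% names(rr)) rr$t else cumsum(x) / 1000
  span <- t[length(t)] - t[1]
  if (span < nfft / resample_fs) {
    abort(sprintf("RR series spans %.1f s; need at least %.0f s.",
                  span, nfft / resample_fs),
          class = "vf_insufficient_data")
  }
  grid <- seq(t[1], t[length(t)], by = 1 / resample_fs)
  tach <- spline(t, x, xout = grid)$y
  # linear detrend (removes the DC component along with any drift)
  k <- seq_along(tach)
  fit <- lm.fit(cbind(1, k), tach)
  tach <- tach - fit$fitted.values
  psd <- welch_psd(tach, fs = resample_fs, nfft = nfft, overlap = overlap)
  df <- resample_fs / nfft
  band <- function(lo, hi) sum(psd$psd[psd$freq > lo & psd$freq <= hi]) * df
  vlf <- band(0, 0.04)
  lf <- band(0.04, 0.15)
  hf <- band(0.15, 0.4)
  lf_hf <- if (hf == 0) {
    warn("HF power is zero; LF/HF is undefined and reported as NA.")
    NA_real_
  } else lf / hf
  tibble(vlf = vlf, lf = lf, hf = hf, lf_hf = lf_hf)
}

#' Poincare-plot HRV features
#'
#' Dispersions of the Poincare plot (RR(i) vs RR(i+1)):
#' `sd1 = sqrt(Var(RR(i) - RR(i+1)) / 2)` (population variance over the
#' successive differences) measures short-term variability perpendicular to
#' the identity line; `sd2 = sqrt(2 sdnn^2 - sd1^2)` the spread along it.
#' A negative radicand from floating error is clamped to zero with a
#' warning; `sd1_sd2` is `NA` (with a warning) when `sd2` is zero.
#'
#' @inheritParams hrv_time_domain
#' @return A one-row tibble with columns `sd1`, `sd2`, `sd1_sd2`.
#' @export
#' @examples
#' hrv_poincare(c(800, 850, 790, 820, 805))
hrv_poincare <- function(rr) {
  x <- as_rr_vector(rr)
  if (length(x) < 3) {
    abort("Need at least 3 RR intervals for Poincare features.",
          class = "vf_insufficient_data")
  }
  d <- x[-length(x)] - x[-1L]
  sd1 <- sqrt(var_pop(d) / 2)
  rad <- 2 * sd_pop(x)^2 - sd1^2
  if (rad < 0) {
    if (rad < -1e-9 * max(sd1^2, 1)) {
      warn(sprintf("SD2 radicand negative (%.3g); clamped to 0.", rad))
    }
    rad <- 0
  }
  sd2 <- sqrt(rad)
  sd1_sd2 <- if (sd2 == 0) {
    warn("SD2 is zero; SD1/SD2 is undefined and reported as NA.")
    NA_real_
  } else sd1 / sd2
  tibble(sd1 = sd1, sd2 = sd2, sd1_sd2 = sd1_sd2)
}

# Canonical column order of the 11 HRV features.
hrv_feature_names <- function() {
  c("mean_nn", "sdnn", "rmssd", "pnn50", "vlf", "lf", "hf", "lf_hf",
    "sd1", "sd2", "sd1_sd2")
}

qrs_feature_names <- function() c("qrsam", "qrsasd", "rpampm", "rpampsd")

# Display names used in exported feature tables.
feature_display_names <- function() {
  c(mean_nn = "Mean NN", sdnn = "SDNN", rmssd = "RMSSD", pnn50 = "pNN50",
    vlf = "VLF", lf = "LF", hf = "HF", lf_hf = "LF/HF", sd1 = "SD1",
    sd2 = "SD2", sd1_sd2 = "SD1/SD2", qrsam = "QRSaM", qrsasd = "QRSaSD",
    rpampm = "RPampM", rpampsd = "RPampSD")
}

#' All 11 HRV features of an RR series
#'
#' Binds [hrv_time_domain()], [hrv_frequency_domain()] and
#' [hrv_poincare()] into one row. When the series is too short for the
#' spectral estimate the frequency columns are `NA` and a warning is
#' raised; the other features are still returned.
#'
#' @inheritParams hrv_frequency_domain
#' @param pnn50_denominator See [hrv_time_domain()].
#' @return A one-row tibble with the 11 HRV feature columns.
#' @export
hrv_features <- function(rr, resample_fs = 4, nfft = 256, overlap = 0.5,
                         pnn50_denominator = "intervals") {
  td <- hrv_time_domain(rr, pnn50_denominator = pnn50_denominator)
  fd <- tryCatch(
    hrv_frequency_domain(rr, resample_fs = resample_fs, nfft = nfft,
                         overlap = overlap),
    vf_insufficient_data = function(e) {
      warn(conditionMessage(e))
      tibble(vlf = NA_real_, lf = NA_real_, hf = NA_real_, lf_hf = NA_real_)
    }
  )
  pc <- hrv_poincare(rr)
  dplyr::bind_cols(td, fd, pc)[, hrv_feature_names()]
}
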