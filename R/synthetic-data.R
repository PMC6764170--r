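#' Group parameters for the synthetic ECG/RR generator
#'
#' Bundles the generating parameters of one subject group. The RR model is a
#' mean interval plus low-frequency (LF) and high-frequency (HF) sinusoidal
#' modulation plus white Gaussian jitter; the ECG model places a P-QRS-T
#' wave template at each beat with sinusoidally modulated R amplitude,
#' per-beat QRS width jitter and additive sample noise.
#'
#' @param mean_rr Mean RR interval, ms.
#' @param lf_mod_amp,lf_mod_freq LF modulation amplitude (ms) and frequency
#'   (Hz, must lie in the LF band (0.04, 0.15)).
#' @param hf_mod_amp,hf_mod_freq HF modulation amplitude (ms) and frequency
#'   (Hz, must lie in the HF band (0.15, 0.4)).
#' @param rr_noise_sd SD of the white RR jitter, ms.
#' @param r_amp_base Baseline R-peak amplitude, uV.
#' @param r_amp_mod_depth Fractional depth of the sinusoidal R-amplitude
#'   modulation (0 <= depth < 1), driven at `lf_mod_freq`.
#' @param qrs_width Nominal QRS duration, ms.
#' @param area_jitter_sd SD of the per-beat fractional QRS width jitter.
#' @param ecg_noise_sd SD of the additive white sample noise, uV.
#' @param label Group label, `"VF"` or `"control"`.
#' @param rr_scale_sdlog,qrs_scale_sdlog,rr_mean_sdlog Log-scale SDs of the
#'   per-record heterogeneity multipliers applied by [generate_cohort()] to
#'   the RR modulation/noise amplitudes, to the QRS shape parameters and to
#'   the mean RR interval. Zero (the default) makes every record in a group
#'   identically distributed.
#'
#' @return A list of class `group_params`.
#' @export
group_params <- function(mean_rr = 800, lf_mod_amp = 0, lf_mod_freq = 0.095,
                         hf_mod_amp = 0, hf_mod_freq = 0.25,
                         rr_noise_sd = 0, r_amp_base = 1000,
                         r_amp_mod_depth = 0, qrs_width = 80,
                         area_jitter_sd = 0, ecg_noise_sd = 0,
                         label = c("control", "VF"),
                         rr_scale_sdlog = 0, qrs_scale_sdlog = 0,
                         rr_mean_sdlog = 0) {
  label <- match.arg(label)
  p <- list(mean_rr = mean_rr, lf_mod_amp = lf_mod_amp,
            lf_mod_freq = lf_mod_freq, hf_mod_amp = hf_mod_amp,
            hf_mod_freq = hf_mod_freq, rr_noise_sd = rr_noise_sd,
            r_amp_base = r_amp_base, r_amp_mod_depth = r_amp_mod_depth,
            qrs_width = qrs_width, area_jitter_sd = area_jitter_sd,
            ecg_noise_sd = ecg_noise_sd, label = label,
            rr_scale_sdlog = rr_scale_sdlog, qrs_scale_sdlog = qrs_scale_sdlog,
            rr_mean_sdlog = rr_mean_sdlog)
  if (p$mean_rr <= 0 || p$qrs_width <= 0) {
    abort("`mean_rr` and `qrs_width` must be positive.",
          class = "vf_invalid_parameter")
  }
  sds <- c(p$rr_noise_sd, p$area_jitter_sd, p$ecg_noise_sd,
           p$rr_scale_sdlog, p$qrs_scale_sdlog, p$rr_mean_sdlog)
  if (any(sds < 0)) {
    abort("All SD parameters must be non-negative.",
          class = "vf_invalid_parameter")
  }
  if (p$r_amp_mod_depth < 0 || p$r_amp_mod_depth >= 1) {
    abort("`r_amp_mod_depth` must lie in [0, 1).",
          class = "vf_invalid_parameter")
  }
  if (p$lf_mod_freq <= 0.04 || p$lf_mod_freq >= 0.15) {
    abort("`lf_mod_freq` must lie in the LF band (0.04, 0.15) Hz.",
          class = "vf_invalid_parameter")
  }
  if (p$hf_mod_freq <= 0.15 || p$hf_mod_freq >= 0.4) {
    abort("`hf_mod_freq` must lie in the HF band (0.15, 0.4) Hz.",
          class = "vf_invalid_parameter")
  }
  structure(p, class = "group_params")
}

#' Generator presets for the two study groups
#'
#' Three named parameterisations of the two-group generator:
#'
#' * `"calibrated"`: group differences follow the direction pattern observed
#'   between VF-prone and control subjects -- higher SDNN, RMSSD, pNN50,
#'   SD1, SD2, QRS-area SD and R-amplitude mean/SD in the VF group -- with
#'   moderate overlap on the HRV features and wide separation on the QRS
#'   shape features.
#' * `"separable"`: the same group structure with little between-record
#'   heterogeneity, so both feature families separate the groups cleanly.
#' * `"null"`: both groups share the control parameters; any detected
#'   difference is a false positive.
#'
#' @param preset One of `"calibrated"`, `"separable"`, `"null"`.
#' @return A list with elements `vf` and `control`, each a [group_params()].
#' @export
#' @examples
#' preset_params("null")$vf$rr_noise_sd
preset_params <- function(preset = c("calibrated", "separable", "null")) {
  preset <- match.arg(preset)
  control <- group_params(
    mean_rr = 790, lf_mod_amp = 15, lf_mod_freq = 0.095,
    hf_mod_amp = 10, hf_mod_freq = 0.25, rr_noise_sd = 18,
    r_amp_base = 800, r_amp_mod_depth = 0.04, qrs_width = 80,
    area_jitter_sd = 0.03, ecg_noise_sd = 8, label = "control",
    rr_scale_sdlog = 0.45, qrs_scale_sdlog = 0.18, rr_mean_sdlog = 0.08
  )
  vf <- group_params(
    mean_rr = 800, lf_mod_amp = 35, lf_mod_freq = 0.095,
    hf_mod_amp = 25, hf_mod_freq = 0.25, rr_noise_sd = 65,
    r_amp_base = 2000, r_amp_mod_depth = 0.18, qrs_width = 85,
    area_jitter_sd = 0.12, ecg_noise_sd = 15, label = "VF",
    rr_scale_sdlog = 0.55, qrs_scale_sdlog = 0.20, rr_mean_sdlog = 0.08
  )
  switch(preset,
    calibrated = list(vf = vf, control = control),
    separable = {
      vf$rr_scale_sdlog <- 0.10; vf$qrs_scale_sdlog <- 0.10
      control$rr_scale_sdlog <- 0.10; control$qrs_scale_sdlog <- 0.10
      list(vf = vf, control = control)
    },
    null = {
      vf_null <- control
      vf_null$label <- "VF"
      list(vf = vf_null, control = control)
    }
  )
}

#' Generate a synthetic RR-interval series
#'
#' Draws beat-to-beat intervals from the group's RR model
#' `RR(t) = mean_rr + lf_amp sin(2 pi f_lf t) + hf_amp sin(2 pi f_hf t) + e`,
#' with `e ~ N(0, rr_noise_sd^2)`, evaluated at the (cumulatively built)
#' beat times, until the beat times cover `duration`.
#'
#' @param params A [group_params()].
#' @param duration Target length in seconds (>= 120 so a full analysis
#'   window fits).
#' @param seed Integer seed; identical seeds give bit-identical series.
#' @return An [rr_series()] with attribute `"truth"`, a list carrying
#'   `beat_times` (s) and `rr_true` (ms).
#' @export
#' @examples
#' rr <- generate_rr(group_params(mean_rr = 800), duration = 120, seed = 1)
#' nrow(rr)
generate_rr <- function(params, duration = 120, seed = 1) {
  stopifnot(inherits(params, "group_params"))
  if (!is.finite(duration) || duration <= 0 || params$mean_rr <= 0) {
    abort("`duration` and `mean_rr` must be positive.",
          class = "vf_invalid_parameter")
  }
  if (duration < 120) {
    abort("`duration` must be at least 120 s to fill an analysis window.",
          class = "vf_invalid_parameter")
  }
  # Upper bound on beats needed, with margin for slow modulation troughs.
  n_max <- ceiling(duration * 1000 / params$mean_rr * 1.5) + 10L
  eps <- with_seed(seed, rnorm(n_max, 0, params$rr_noise_sd))
  beat_t <- numeric(n_max + 1L)
  rr <- numeric(n_max)
  t_i <- 0
  i <- 0L
  while (t_i < duration && i < n_max) {
    i <- i + 1L
    rr_i <- params$mean_rr +
      params$lf_mod_amp * sin(2 * pi * params$lf_mod_freq * t_i) +
      params$hf_mod_amp * sin(2 * pi * params$hf_mod_freq * t_i) +
      eps[i]
    if (rr_i < 200) rr_i <- 200  # refractory floor: keep intervals physical
    rr[i] <- rr_i
    t_i <- t_i + rr_i / 1000
    beat_t[i + 1L] <- t_i
  }
  rr <- rr[seq_len(i)]
  beat_t <- beat_t[seq_len(i + 1L)]
  out <- rr_series(rr, t = beat_t[-1L])
  attr(out, "truth") <- list(beat_times = beat_t, rr_true = rr)
  out
}

# P-QRS-T template geometry, relative to the R peak. Amplitudes of Q/S scale
# with the per-beat R amplitude; P/T with the group baseline amplitude.
# Widths of Q/R/S scale with the (jittered) QRS width.
template_waves <- function(r_amp, base_amp, qrs_width_s) {
  list(
    P = list(c = -0.16, s = 0.025, a = 0.12 * base_amp),
    Q = list(c = -qrs_width_s / 3.2, s = qrs_width_s / 12, a = -0.15 * r_amp),
    R = list(c = 0, s = qrs_width_s / 8, a = r_amp),
    S = list(c = qrs_width_s / 3.2, s = qrs_width_s / 12, a = -0.20 * r_amp),
    T = list(c = 0.24, s = 0.05, a = 0.18 * base_amp)
  )
}

#' Synthesize an ECG record from an RR series
#'
#' Places one beat template at every truth beat time of `rr`. The default
#' template is a sum of Gaussian-shaped P, Q, R, S and T waves; `"triangle"`
#' and `"square"` replace the whole beat by a single triangular or
#' rectangular QRS pulse (useful for analytic area checks). Per beat, the R
#' amplitude is `r_amp_base * (1 + r_amp_mod_depth * sin(2 pi f_lf t_i))`
#' and the QRS width is scaled by `(1 + jitter)`,
#' `jitter ~ N(0, area_jitter_sd^2)`; white `N(0, ecg_noise_sd^2)` noise is
#' added to every sample.
#'
#' @param rr An [rr_series()] (typically from [generate_rr()]).
#' @param params A [group_params()].
#' @param fs Sampling rate in Hz (>= 100).
#' @param seed Integer seed.
#' @param template `"gaussian"`, `"triangle"` or `"square"`.
#' @param label,record_id,onset_time Passed through to the record.
#' @return An [ecg_record()] with attribute `"truth"`: per-beat analytic R
#'   amplitude (`r_amp_true`, uV), discrete noise-free QRS signed area
#'   (`qrs_area_true`, uV-samples), `beat_times` and `rr_true`.
#' @export
#' @examples
#' rr <- generate_rr(group_params(), duration = 120, seed = 1)
#' rec <- synthesize_ecg(rr, group_params(), fs = 250, seed = 1)
synthesize_ecg <- function(rr, params, fs = 250, seed = 1,
                           template = c("gaussian", "triangle", "square"),
                           label = params$label, record_id = "synthetic",
                           onset_time = NULL) {
  stopifnot(inherits(params, "group_params"))
  template <- match.arg(template)
  if (fs < 100) {
    abort("`fs` must be at least 100 Hz.", class = "vf_invalid_parameter")
  }
  rr_v <- as_rr_vector(rr)
  if (length(rr_v) < 1) {
    abort("RR series must contain at least one interval.",
          class = "vf_invalid_parameter")
  }
  truth_in <- attr(rr, "truth")
  beat_t <- if (!is.null(truth_in)) truth_in$beat_times else c(0, cumsum(rr_v) / 1000)
  if (min(diff(beat_t)) * 1000 < params$qrs_width) {
    abort("RR intervals shorter than one beat template.",
          class = "vf_invalid_parameter")
  }
  duration <- max(beat_t) + 0.5
  n <- floor(duration * fs)
  t_grid <- (seq_len(n) - 1L) / fs
  n_beats <- length(beat_t)

  jit <- with_seed(seed, list(
    w = rnorm(n_beats, 0, params$area_jitter_sd),
    noise = rnorm(n, 0, params$ecg_noise_sd)
  ))
  # keep the width physical under extreme jitter draws
  wscale <- pmax(1 + jit$w, 0.3)
  r_amp <- params$r_amp_base *
    (1 + params$r_amp_mod_depth * sin(2 * pi * params$lf_mod_freq * beat_t))

  x <- numeric(n)
  qrs_area_true <- numeric(n_beats)
  qw_s <- params$qrs_width / 1000
  for (b in seq_len(n_beats)) {
    tb <- beat_t[b]
    qb <- qw_s * wscale[b]
    # support of the whole template around this beat
    lo <- max(1L, floor((tb - 0.45) * fs) + 1L)
    hi <- min(n, ceiling((tb + 0.55) * fs) + 1L)
    if (lo > hi) next
    tt <- t_grid[lo:hi] - tb
    seg <- numeric(length(tt))
    if (template == "gaussian") {
      waves <- template_waves(r_amp[b], params$r_amp_base, qb)
      for (w in waves) {
        seg <- seg + w$a * exp(-((tt - w$c)^2) / (2 * w$s^2))
      }
    } else if (template == "triangle") {
      half <- qb / 2
      seg <- r_amp[b] * pmax(0, 1 - abs(tt) / half)
    } else {
      seg <- ifelse(abs(tt) <= qb / 2, r_amp[b], 0)
    }
    x[lo:hi] <- x[lo:hi] + seg
    # truth signed area: noise-free samples within +/- one QRS width
    in_qrs <- abs(tt) <= qb
    qrs_area_true[b] <- sum(seg[in_qrs])
  }
  x <- x + jit$noise

  beat_idx <- round(beat_t * fs) + 1L
  keep <- beat_idx >= 1L & beat_idx <= n
  rec <- ecg_record(x, fs = fs, beat_indices = beat_idx[keep],
                    onset_time = onset_time, label = label,
                    record_id = record_id)
  attr(rec, "truth") <- list(
    beat_times = beat_t[keep], rr_true = rr_v,
    r_amp_true = r_amp[keep], qrs_area_true = qrs_area_true[keep],
    onset_time = onset_time
  )
  rec
}

# Scale a group's parameters by per-record heterogeneity multipliers.
scale_params <- function(params, u_rr, u_qrs, u_mean = 1) {
  params$mean_rr <- params$mean_rr * u_mean
  params$lf_mod_amp <- params$lf_mod_amp * u_rr
  params$hf_mod_amp <- params$hf_mod_amp * u_rr
  params$rr_noise_sd <- params$rr_noise_sd * u_rr
  params$r_amp_base <- params$r_amp_base * u_qrs
  params$area_jitter_sd <- params$area_jitter_sd * u_qrs
  params$r_amp_mod_depth <- min(params$r_amp_mod_depth * u_qrs, 0.95)
  params
}

#' Generate a labeled two-group cohort of synthetic ECG records
#'
#' Produces `n_vf` VF-prone and `n_control` control records (defaults match
#' the 27/28 study group sizes). VF records carry a VF-onset marker placed
#' uniformly at least 150 s after record start, so the full 120-s analysis
#' window ending 30 s before onset exists; control records are 125 s long.
#' A master seed fans out to per-record child seeds, so cohorts are
#' reproducible and records independent. Per record, lognormal
#' heterogeneity multipliers (`rr_scale_sdlog`, `qrs_scale_sdlog`) scale the
#' RR modulation/noise amplitudes and the QRS shape parameters, creating
#' between-subject spread within each group.
#'
#' @param n_vf,n_control Group sizes (>= 1).
#' @param vf_params,control_params [group_params()] for the two groups;
#'   default to the `"calibrated"` preset.
#' @param seed Master integer seed.
#' @param fs Sampling rate in Hz.
#' @param template Beat template, see [synthesize_ecg()].
#' @return A list of [ecg_record()]s, each with its `"truth"` attribute.
#' @export
#' @examples
#' cohort <- generate_cohort(2, 2, seed = 1)
#' vapply(cohort, function(r) r$label, "")
generate_cohort <- function(n_vf = 27, n_control = 28,
                            vf_params = preset_params("calibrated")$vf,
                            control_params = preset_params("calibrated")$control,
                            seed = 1, fs = 250,
                            template = "gaussian") {
  if (n_vf < 1 || n_control < 1) {
    abort("Both group sizes must be at least 1.",
          class = "vf_invalid_parameter")
  }
  n_tot <- n_vf + n_control
  draws <- with_seed(seed, list(
    child = sample.int(.Machine$integer.max - 1L, 2L * n_tot),
    onset = runif(n_vf, 150, 170),
    u_rr_vf = exp(rnorm(n_vf, 0, vf_params$rr_scale_sdlog)),
    u_qrs_vf = exp(rnorm(n_vf, 0, vf_params$qrs_scale_sdlog)),
    u_rr_ct = exp(rnorm(n_control, 0, control_params$rr_scale_sdlog)),
    u_qrs_ct = exp(rnorm(n_control, 0, control_params$qrs_scale_sdlog)),
    u_mean_vf = exp(rnorm(n_vf, 0, vf_params$rr_mean_sdlog)),
    u_mean_ct = exp(rnorm(n_control, 0, control_params$rr_mean_sdlog))
  ))
  make_one <- function(i, params, u_rr, u_qrs, u_mean, onset, id) {
    p_i <- scale_params(params, u_rr, u_qrs, u_mean)
    dur <- if (is.null(onset)) 125 else onset + 2
    rr <- generate_rr(p_i, duration = dur, seed = draws$child[2L * i - 1L])
    if (!is.null(onset) && max(attr(rr, "truth")$beat_times) < onset - 150) {
      abort(sprintf("record %s: analysis window cannot fit before onset", id),
            class = "vf_generation_error")
    }
    synthesize_ecg(rr, p_i, fs = fs, seed = draws$child[2L * i],
                   template = template, label = params$label,
                   record_id = id, onset_time = onset)
  }
  vf_recs <- lapply(seq_len(n_vf), function(j) {
    make_one(j, vf_params, draws$u_rr_vf[j], draws$u_qrs_vf[j],
             draws$u_mean_vf[j], draws$onset[j], sprintf("VF%03d", j))
  })
  ct_recs <- lapply(seq_len(n_control), function(j) {
    make_one(n_vf + j, control_params, draws$u_rr_ct[j], draws$u_qrs_ct[j],
             draws$u_mean_ct[j], NULL, sprintf("CT%03d", j))
  })
  c(vf_recs, ct_recs)
}
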