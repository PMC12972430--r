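#' Construct a force-time trace
#'
#' A `force_trace` is a uniformly sampled force signal with its sampling
#' rate, resting baseline, and muscle metadata (name, mass, optimal length
#' L0) attached. The underlying samples are a tibble with columns `time_s`
#' and `force_mN`, retrievable with [as_tibble()][tibble::as_tibble].
#'
#' @param time_s Time vector (s), uniformly spaced at `1 / sampling_rate`.
#' @param force_mN Force vector (mN), same length as `time_s`.
#' @param sampling_rate Sampling rate (Hz).
#' @param muscle Muscle name (e.g. `"edl"`, `"soleus"`).
#' @param mass_g Muscle mass (g) or `NA`.
#' @param l0_cm Optimal length (cm) or `NA`.
#' @param baseline Resting baseline force (mN).
#' @param protocol Protocol label (`"twitch"`, `"force_frequency"`,
#'   `"fatigue"`, `"recovery"`) or `NA`.
#' @return An object of class `force_trace`.
#' @export
force_trace <- function(time_s, force_mN, sampling_rate,
                        muscle = NA_character_, mass_g = NA_real_,
                        l0_cm = NA_real_, baseline = 0,
                        protocol = NA_character_) {
  if (length(time_s) != length(force_mN)) {
    abort("`time_s` and `force_mN` must have equal length.",
          class = "mf_trace_error")
  }
  if (length(time_s) > 1L) {
    step <- diff(time_s)
    if (any(step <= 0) ||
        max(abs(step - 1 / sampling_rate)) > 1e-9 * max(1, 1 / sampling_rate)) {
      abort("`time_s` must increase with constant step 1 / sampling_rate.",
            class = "mf_trace_error")
    }
  }
  if (any(!is.finite(force_mN))) {
    abort("Force samples must all be finite.", class = "mf_trace_error")
  }
  structure(
    list(data = tibble::tibble(time_s = time_s, force_mN = force_mN),
         sampling_rate = sampling_rate, muscle = muscle, mass_g = mass_g,
         l0_cm = l0_cm, baseline = baseline, protocol = protocol),
    class = "force_trace"
  )
}

#' @exportS3Method tibble::as_tibble
as_tibble.force_trace <- function(x, ...) x$data

#' @export
print.force_trace <- function(x, ...) {
  dur <- if (nrow(x$data)) max(x$data$time_s) else 0
  cat(sprintf(
    "<force_trace> %s | %s | %d samples @ %g Hz (%.3f s) | peak %.2f mN\n",
    x$muscle %||% "?", x$protocol %||% "?", nrow(x$data), x$sampling_rate,
    dur, if (nrow(x$data)) max(x$data$force_mN) else NA_real_
  ))
  invisible(x)
}

# Unnormalized twitch kernel; zero before the stimulus at t = 0.
twitch_kernel <- function(t, params) {
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- params$amplitude_A *
    (exp(-t[pos] / params$tau_relax) - exp(-t[pos] / params$tau_contract))
  out
}

#' Closed-form peak time and peak force of the twitch kernel
#'
#' The kernel `A * (exp(-t/tau_r) - exp(-t/tau_c))` peaks at
#' `t_p = tau_c * tau_r / (tau_r - tau_c) * log(tau_r / tau_c)`.
#'
#' @param params A [twitch_params()] object.
#' @return `twitch_peak_time()`: the peak time (s); `twitch_peak_force()`:
#'   the kernel value at the peak (mN).
#' @export
twitch_peak_time <- function(params) {
  tc <- params$tau_contract; tr <- params$tau_relax
  tc * tr / (tr - tc) * log(tr / tc)
}

#' @rdname twitch_peak_time
#' @export
twitch_peak_force <- function(params) {
  twitch_kernel(twitch_peak_time(params), params)
}

#' Simulate a single-twitch force trace
#'
#' Samples the twitch kernel at the configured sampling rate, with optional
#' additive white noise. The trace is zero before the stimulus at `t = 0`.
#'
#' @param params A [twitch_params()] object.
#' @param duration Trace duration (s); default covers the relaxation tail.
#' @param noise_sd Additive white-noise standard deviation (mN).
#' @param pre_s Quiescent pre-stimulus window (s) retained in the trace.
#' @return A [force_trace()] with `protocol = "twitch"`, plus an event table
#'   in attribute `"events"`.
#' @export
#' @examples
#' tw <- simulate_twitch(twitch_params(amplitude_A = 10, tau_contract = 0.01,
#'                                     tau_relax = 0.05, sampling_rate = 10000))
#' max(as_tibble(tw)$force_mN)  # ~ 5.35 mN
simulate_twitch <- function(params, duration = NULL, noise_sd = 0, pre_s = 0) {
  stopifnot(inherits(params, "twitch_params"))
  duration <- duration %||% (8 * params$tau_relax)
  fs <- params$sampling_rate
  t <- seq(-pre_s, duration, by = 1 / fs)
  f <- twitch_kernel(t, params)
  if (noise_sd > 0) f <- f + rnorm(length(f), 0, noise_sd)
  tr <- force_trace(t + pre_s, f, fs, protocol = "twitch")
  attr(tr, "events") <- tibble::tibble(protocol = "twitch", onset_s = pre_s,
                                       freq_hz = NA_real_, duration_s = 0)
  tr
}

# Unsaturated pulse-train drive: sum of twitch kernels at the pulse times.
tetanus_drive <- function(t, params, freq, duration) {
  pulses <- seq(0, duration - 1e-12, by = 1 / freq)
  if (length(pulses) == 0L) pulses <- 0
  u <- numeric(length(t))
  for (p0 in pulses) u <- u + twitch_kernel(t - p0, params)
  u
}

#' Simulate a tetanic contraction
#'
#' A pulse train at `freq` Hz for `duration` seconds drives the muscle
#' through linear summation of twitch kernels; the output force saturates
#' through `F = f_max * U / (U + k_half)`, which guarantees a plateau below
#' `f_max` and a monotone, sigmoidal force-frequency relation.
#'
#' @inheritParams simulate_twitch
#' @param freq Stimulation frequency (Hz), >= 1.
#' @param duration Train duration (s).
#' @param tail_s Relaxation tail retained after the last pulse (s).
#' @return A [force_trace()] with `protocol = "force_frequency"` and an
#'   event table in attribute `"events"`.
#' @export
simulate_tetanus <- function(params, freq, duration, noise_sd = 0,
                             tail_s = 0.5) {
  stopifnot(inherits(params, "twitch_params"))
  if (freq < 1) abort("`freq` must be >= 1 Hz.", class = "mf_param_error")
  if (duration < 1 / freq) {
    warn("Train shorter than one inter-pulse interval; returning a single-pulse trace.")
  }
  fs <- params$sampling_rate
  t <- seq(0, duration + tail_s, by = 1 / fs)
  u <- tetanus_drive(t, params, freq, duration)
  f <- params$f_max * u / (u + params$k_half)
  if (noise_sd > 0) f <- f + rnorm(length(f), 0, noise_sd)
  tr <- force_trace(t, f, fs, protocol = "force_frequency")
  attr(tr, "events") <- tibble::tibble(protocol = "force_frequency",
                                       onset_s = 0, freq_hz = freq,
                                       duration_s = duration)
  tr
}

# Saturated single-train template used by the fatigue and recovery
# protocols: waveform, peak, and trapezoidal area over the train window.
tetanus_template <- function(params, freq, duration, tail_s) {
  fs <- params$sampling_rate
  t <- seq(0, duration + tail_s, by = 1 / fs)
  u <- tetanus_drive(t, params, freq, duration)
  f <- params$f_max * u / (u + params$k_half)
  in_train <- t <= duration
  list(force = f, n = length(f), peak = max(f),
       auc = trapz(t[in_train], f[in_train]))
}

# Place scaled copies of a template waveform at sample offsets in a zero
# trace of n_total samples.
place_trains <- function(n_total, template, onset_idx, scales) {
  f <- numeric(n_total)
  for (j in seq_along(onset_idx)) {
    i0 <- onset_idx[j]
    idx <- i0:min(i0 + template$n - 1L, n_total)
    f[idx] <- f[idx] + scales[j] * template$force[seq_along(idx)]
  }
  f
}

#' Simulate a fatigue protocol trace
#'
#' Delivers `fr$n_contractions` tetani at `fr$train_freq` Hz separated by
#' `fr$rest_between` seconds of rest; the k-th tetanus is scaled by
#' [fatigue_scale()] `s_k = r + (1 - r) exp(-(k - 1) / kappa)`. Peak noise
#' multiplies each contraction's scale by `1 + N(0, peak_cv)`.
#'
#' @param params A [twitch_params()] object.
#' @param fr A [fatigue_recovery_params()] object.
#' @param peak_cv Coefficient of variation of per-contraction peak noise.
#' @param noise_sd Additive white-noise standard deviation (mN).
#' @return A list with elements `trace` ([force_trace()]) and `events`
#'   (tibble: `protocol`, `onset_s`, `freq_hz`, `duration_s`).
#' @export
simulate_fatigue_protocol <- function(params, fr, peak_cv = 0, noise_sd = 0) {
  stopifnot(inherits(params, "twitch_params"),
            inherits(fr, "fatigue_recovery_params"))
  fs <- params$sampling_rate
  period <- fr$train_duration + fr$rest_between
  tmpl <- tetanus_template(params, fr$train_freq, fr$train_duration,
                           tail_s = min(fr$rest_between, 2))
  k <- seq_len(fr$n_contractions)
  onsets <- (k - 1) * period
  scales <- fatigue_scale(k, fr$decay_floor_r, fr$decay_kappa)
  if (peak_cv > 0) scales <- scales * pmax(0, 1 + rnorm(length(k), 0, peak_cv))
  n_total <- round(fr$n_contractions * period * fs) + 1L
  f <- place_trains(n_total, tmpl, round(onsets * fs) + 1L, scales)
  if (noise_sd > 0) f <- f + rnorm(n_total, 0, noise_sd)
  t <- seq(0, by = 1 / fs, length.out = n_total)
  list(
    trace = force_trace(t, f, fs, protocol = "fatigue"),
    events = tibble::tibble(protocol = "fatigue", onset_s = onsets,
                            freq_hz = fr$train_freq,
                            duration_s = fr$train_duration)
  )
}

#' Simulate a post-fatigue recovery protocol trace
#'
#' Delivers `fr$n_recovery_stims` tetani at times `i * fr$recovery_interval`
#' after the end of fatigue (time zero of this trace); the stimulation at
#' time `t` is scaled by [recovery_scale()]
#' `s(t) = end_scale + (plateau - end_scale)(1 - exp(-t / tau))`.
#'
#' @inheritParams simulate_fatigue_protocol
#' @param end_scale Force fraction (of baseline) at the end of fatigue,
#'   in `[0, 1]`.
#' @param freq Stimulation frequency (Hz); defaults to `fr$train_freq`.
#' @return A list with elements `trace` and `events` as in
#'   [simulate_fatigue_protocol()].
#' @export
simulate_recovery_protocol <- function(params, fr, end_scale,
                                       freq = fr$train_freq,
                                       peak_cv = 0, noise_sd = 0) {
  stopifnot(inherits(params, "twitch_params"),
            inherits(fr, "fatigue_recovery_params"))
  if (end_scale < 0 || end_scale > 1) {
    abort("`end_scale` must lie in [0, 1].", class = "mf_param_error")
  }
  fs <- params$sampling_rate
  i <- seq_len(fr$n_recovery_stims)
  onsets <- i * fr$recovery_interval
  scales <- recovery_scale(onsets, end_scale, fr$recovery_plateau,
                           fr$recovery_tau)
  if (peak_cv > 0) scales <- scales * pmax(0, 1 + rnorm(length(i), 0, peak_cv))
  tmpl <- tetanus_template(params, freq, fr$train_duration, tail_s = 2)
  n_total <- round((max(onsets) + fr$train_duration + 2) * fs) + 1L
  f <- place_trains(n_total, tmpl, round(onsets * fs) + 1L, scales)
  if (noise_sd > 0) f <- f + rnorm(n_total, 0, noise_sd)
  t <- seq(0, by = 1 / fs, length.out = n_total)
  list(
    trace = force_trace(t, f, fs, protocol = "recovery"),
    events = tibble::tibble(protocol = "recovery", onset_s = onsets,
                            freq_hz = freq, duration_s = fr$train_duration)
  )
}

#' Trace-free envelope simulation of the fatigue and recovery protocols
#'
#' Returns the per-contraction peak forces and envelope quantities the full
#' trace simulation would produce, without materializing any trace: peaks
#' share the exact closed forms [fatigue_scale()] and [recovery_scale()] with
#' the trace generators, scaled by the saturated single-train template peak.
#' Intended for large Monte-Carlo studies (power curves, null calibrations)
#' where only protocol-level summaries are needed; agreement with full-trace
#' extraction is part of the test-suite.
#'
#' @inheritParams simulate_fatigue_protocol
#' @param recovery_freq Recovery stimulation frequency (Hz).
#' @return A list: `fatigue_peaks`, `fatigue_auc_envelope` (sum of
#'   per-train trapezoidal areas, mN s), `baseline_force` (first-contraction
#'   peak, mN), `end_force` (last fatigue peak, mN), `recovery_peaks`,
#'   `recovery_times` (s since fatigue end).
#' @export
simulate_protocol_peaks <- function(params, fr, recovery_freq = fr$train_freq,
                                    peak_cv = 0) {
  stopifnot(inherits(params, "twitch_params"),
            inherits(fr, "fatigue_recovery_params"))
  tmpl_f <- tetanus_template(params, fr$train_freq, fr$train_duration,
                             tail_s = min(fr$rest_between, 2))
  k <- seq_len(fr$n_contractions)
  s_k <- fatigue_scale(k, fr$decay_floor_r, fr$decay_kappa)
  if (peak_cv > 0) s_k <- s_k * pmax(0, 1 + rnorm(length(k), 0, peak_cv))
  fatigue_peaks <- tmpl_f$peak * s_k
  end_scale <- s_k[length(s_k)]

  i <- seq_len(fr$n_recovery_stims)
  t_i <- i * fr$recovery_interval
  s_t <- recovery_scale(t_i, min(end_scale, 1), fr$recovery_plateau,
                        fr$recovery_tau)
  if (peak_cv > 0) s_t <- s_t * pmax(0, 1 + rnorm(length(i), 0, peak_cv))
  tmpl_r <- if (recovery_freq == fr$train_freq) tmpl_f else
    tetanus_template(params, recovery_freq, fr$train_duration, tail_s = 2)

  list(
    fatigue_peaks = fatigue_peaks,
    fatigue_auc_envelope = tmpl_f$auc * sum(s_k),
    baseline_force = fatigue_peaks[1L],
    end_force = fatigue_peaks[length(fatigue_peaks)],
    recovery_peaks = tmpl_r$peak * s_t,
    recovery_times = t_i
  )
}

# Trapezoidal rule on (x, y).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
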