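#' Twitch kinetics from a force-time trace
#'
#' Extracts peak twitch force (Pt), time to peak, rate of force development
#' (RFD), and half-relaxation time (HRT) from a single-pulse trace:
#' \itemize{
#'   \item Pt: maximum baseline-subtracted force after the stimulus onset;
#'   \item RFD: maximum of the first time-derivative (central differences,
#'     optionally after moving-average smoothing) on the rising phase;
#'   \item HRT: time from the peak sample to the first crossing of Pt/2
#'     during relaxation, linearly interpolated between bracketing samples.
#' }
#' If the force never returns below Pt/2 within the analysis window, HRT is
#' reported missing with a warning; a nonpositive Pt makes all metrics
#' missing.
#'
#' @param trace A [force_trace()].
#' @param onset_s Stimulus onset time (s); default 0.
#' @param baseline Resting baseline (mN); defaults to the trace's baseline.
#' @param window_s Analysis window after onset (s); default to trace end.
#' @param smooth_ms Moving-average window (ms) applied before
#'   differentiation; 0 (default) disables smoothing. Use ~5 ms for noisy
#'   traces.
#' @return A one-row tibble: `pt_mN`, `time_to_peak_s`, `rfd_mN_s`, `hrt_s`.
#' @export
#' @examples
#' tw <- simulate_twitch(twitch_params(amplitude_A = 10, tau_contract = 0.01,
#'                                     tau_relax = 0.05, sampling_rate = 10000))
#' twitch_metrics(tw)
twitch_metrics <- function(trace, onset_s = 0, baseline = NULL,
                           window_s = NULL, smooth_ms = 0) {
  stopifnot(inherits(trace, "force_trace"))
  baseline <- baseline %||% trace$baseline %||% 0
  t <- trace$data$time_s
  f <- trace$data$force_mN - baseline
  end_s <- if (is.null(window_s)) max(t) else onset_s + window_s
  keep <- t >= onset_s & t <= end_s
  t <- t[keep]; f <- f[keep]
  empty <- tibble::tibble(pt_mN = NA_real_, time_to_peak_s = NA_real_,
                          rfd_mN_s = NA_real_, hrt_s = NA_real_)
  if (length(t) < 3L) return(empty)
  if (smooth_ms > 0) {
    w <- max(1L, round(smooth_ms / 1000 * trace$sampling_rate))
    if (w %% 2L == 0L) w <- w + 1L
    f <- as.numeric(stats::filter(f, rep(1 / w, w), sides = 2))
    ok <- !is.na(f)
    t <- t[ok]; f <- f[ok]
  }
  ipk <- which.max(f)
  pt <- f[ipk]
  if (!is.finite(pt) || pt <= 0) {
    warn("Nonpositive peak twitch force; twitch metrics reported missing.")
    return(empty)
  }
  # central differences on the rising phase
  n <- length(f)
  d <- rep(NA_real_, n)
  if (n >= 3L) d[2:(n - 1)] <- (f[3:n] - f[1:(n - 2)]) * trace$sampling_rate / 2
  rise <- d[seq_len(ipk)]
  rfd <- if (all(is.na(rise))) NA_real_ else max(rise, na.rm = TRUE)
  # half-relaxation: first crossing of pt/2 after the peak
  half <- pt / 2
  post <- f[ipk:n]
  below <- which(post < half)
  if (length(below) == 0L) {
    warn("Force never falls below half of peak within the window; HRT missing.")
    hrt <- NA_real_
  } else {
    i2 <- below[1L]                      # first sample below half (local idx)
    if (i2 == 1L) {
      hrt <- 0
    } else {
      f1 <- post[i2 - 1L]; f2 <- post[i2]
      t1 <- t[ipk + i2 - 2L]; t2 <- t[ipk + i2 - 1L]
      hrt <- (t1 + (f1 - half) / (f1 - f2) * (t2 - t1)) - t[ipk]
    }
  }
  tibble::tibble(pt_mN = pt, time_to_peak_s = t[ipk] - onset_s,
                 rfd_mN_s = rfd, hrt_s = hrt)
}

#' Force-frequency relation and maximal tetanic force
#'
#' Computes the peak baseline-subtracted force at each stimulation frequency
#' and the maximal tetanic force P0 (the maximum across the series).
#'
#' @param traces A named list of [force_trace()] objects, names = frequency
#'   in Hz; or a tibble with columns `freq_hz`, `peak_mN`.
#' @param protocol_freqs Optional numeric vector of the protocol's
#'   frequencies; a warning reports any missing from `traces`.
#' @param baseline Resting baseline (mN) subtracted before peak extraction.
#' @return A tibble `freq_hz`, `peak_mN`, sorted by frequency, with the
#'   maximal tetanic force attached as attribute `"p0_mN"`.
#' @export
force_frequency <- function(traces, protocol_freqs = NULL, baseline = 0) {
  if (inherits(traces, "data.frame")) {
    ff <- tibble::as_tibble(traces)[c("freq_hz", "peak_mN")]
  } else {
    ff <- tibble::tibble(
      freq_hz = as.numeric(names(traces)),
      peak_mN = vapply(traces, function(tr) {
        max(tr$data$force_mN - (baseline %||% 0))
      }, numeric(1))
    )
  }
  if (!is.null(protocol_freqs)) {
    miss <- setdiff(protocol_freqs, ff$freq_hz)
    if (length(miss)) {
      warn(paste0("Missing traces for frequencies: ",
                  paste(miss, collapse = ", "),
                  " Hz; P0 computed on the available set."))
    }
  }
  ff <- dplyr::arrange(ff, .data$freq_hz)
  attr(ff, "p0_mN") <- max(ff$peak_mN)
  ff
}

#' Physiological cross-sectional area
#'
#' `PCSA = mass / (L0 * 1.06)` with muscle density 1.06 g/cm^3.
#'
#' @param mass_g Muscle mass (g), > 0.
#' @param l0_cm Optimal length (cm), > 0.
#' @return PCSA in cm^2.
#' @export
pcsa <- function(mass_g, l0_cm) {
  if (any(!is.finite(mass_g)) || any(!is.finite(l0_cm)) ||
      any(mass_g <= 0) || any(l0_cm <= 0)) {
    abort("`mass_g` and `l0_cm` must be positive and finite.",
          class = "mf_input_error")
  }
  mass_g / (l0_cm * 1.06)
}

#' Specific tetanic force
#'
#' Maximal tetanic force normalized to PCSA, with mN converted to N:
#' `(P0 / 1000) / PCSA`, in N/cm^2.
#'
#' @param p0_mN Maximal tetanic force (mN).
#' @param pcsa_cm2 Physiological cross-sectional area (cm^2), > 0.
#' @return Specific force in N/cm^2.
#' @export
specific_force <- function(p0_mN, pcsa_cm2) {
  if (any(!is.finite(pcsa_cm2)) || any(pcsa_cm2 <= 0)) {
    abort("`pcsa_cm2` must be positive and finite.", class = "mf_input_error")
  }
  (p0_mN / 1000) / pcsa_cm2
}

# Peak within each event's search window [onset, onset + duration + tail].
# Windows are located by index arithmetic (the trace is uniformly sampled).
event_peaks <- function(trace, events, baseline, tail_s = 0.5) {
  fs <- trace$sampling_rate
  f <- trace$data$force_mN - baseline
  t0 <- trace$data$time_s[1L]
  n <- length(f)
  vapply(seq_len(nrow(events)), function(i) {
    i0 <- max(1L, round((events$onset_s[i] - t0) * fs) + 1L)
    i1 <- min(n, round((events$onset_s[i] + events$duration_s[i] + tail_s - t0) * fs) + 1L)
    if (i0 > i1) return(NA_real_)
    max(f[i0:i1])
  }, numeric(1))
}

#' Fatigue analysis: per-contraction peaks and force-time AUC
#'
#' Extracts the peak force of every fatigue contraction (maximum within
#' `[onset, onset + duration + 0.5 s]`, so relaxation tails do not bleed
#' across the 5 s rests) and the total area under the baseline-subtracted
#' force-time curve (trapezoidal rule, negative excursions clamped to 0)
#' from the first event onset to the last event end. A peaks-only envelope
#' AUC (sum of peak x train duration) is provided as a secondary output.
#'
#' @param trace A [force_trace()] of the fatigue protocol.
#' @param events Event tibble (`protocol`, `onset_s`, `freq_hz`,
#'   `duration_s`); only rows with `protocol == "fatigue"` are used.
#' @param baseline Resting baseline (mN); defaults to the trace's baseline.
#' @return A list of class `fatigue_result`: `peaks_mN`, `baseline_force_mN`
#'   (first-contraction peak), `auc_mNs`, `auc_envelope_mNs`.
#' @export
fatigue_analysis <- function(trace, events, baseline = NULL) {
  stopifnot(inherits(trace, "force_trace"))
  ev <- events[events$protocol == "fatigue", , drop = FALSE]
  if (nrow(ev) == 0L) {
    abort("No fatigue events in the protocol.", class = "mf_input_error")
  }
  baseline <- baseline %||% trace$baseline %||% 0
  peaks <- event_peaks(trace, ev, baseline)
  t <- trace$data$time_s
  f <- pmax(trace$data$force_mN - baseline, 0)
  t0 <- min(ev$onset_s)
  t1 <- max(ev$onset_s + ev$duration_s)
  keep <- t >= t0 & t <= t1
  structure(
    list(peaks_mN = peaks, baseline_force_mN = peaks[1L],
         auc_mNs = trapz(t[keep], f[keep]),
         auc_envelope_mNs = sum(peaks * ev$duration_s)),
    class = "fatigue_result"
  )
}

#' Recovery kinetics from per-stimulation peak forces
#'
#' Core recovery computation shared by the trace and envelope paths. The
#' instantaneous rate series has one entry per consecutive pair of
#' contractions *including* the pair (fatigue end -> stimulation 1); the
#' initial recovery rate is that first entry,
#' `(peak_1 - fatigue_end_force) / (t_1 - fatigue_end_time)`. Percent force
#' recovered is, by default, the gain over the fatigue end expressed
#' relative to the pre-fatigue baseline force,
#' `100 (peak_last - fatigue_end_force) / baseline_force`; with
#' `pct_mode = "absolute"` it is `100 peak_last / baseline_force`.
#'
#' @param peaks_mN Per-stimulation peak forces (mN), in time order.
#' @param times_s Stimulation times (s) on the same clock as
#'   `fatigue_end_time`.
#' @param fatigue_end_force Force at the end of the fatigue protocol (mN).
#' @param baseline_force Pre-fatigue baseline force (mN), > 0.
#' @param fatigue_end_time Time of fatigue end (s); default 0.
#' @param pct_mode `"delta"` (default) or `"absolute"`; see Details.
#' @return A list of class `recovery_result`: `peaks_mN`, `times_s`,
#'   `rates_mN_s` (length = number of stimulations), `initial_rate_mN_s`,
#'   `pct_recovered`.
#' @export
recovery_rates <- function(peaks_mN, times_s, fatigue_end_force,
                           baseline_force, fatigue_end_time = 0,
                           pct_mode = c("delta", "absolute")) {
  pct_mode <- match.arg(pct_mode)
  if (!is.finite(baseline_force) || baseline_force <= 0) {
    abort("`baseline_force` must be positive.", class = "mf_input_error")
  }
  if (length(peaks_mN) != length(times_s) || length(peaks_mN) < 1L) {
    abort("Need >= 1 recovery peak with matching times.",
          class = "mf_input_error")
  }
  all_t <- c(fatigue_end_time, times_s)
  all_f <- c(fatigue_end_force, peaks_mN)
  rates <- diff(all_f) / diff(all_t)
  last <- peaks_mN[length(peaks_mN)]
  pct <- switch(pct_mode,
    delta = 100 * (last - fatigue_end_force) / baseline_force,
    absolute = 100 * last / baseline_force
  )
  structure(
    list(peaks_mN = peaks_mN, times_s = times_s, rates_mN_s = rates,
         initial_rate_mN_s = rates[1L], pct_recovered = pct,
         pct_mode = pct_mode),
    class = "recovery_result"
  )
}

#' Recovery analysis from a force-time trace
#'
#' Extracts per-stimulation peaks from the recovery trace and derives the
#' rate series via [recovery_rates()]. The trace clock starts at the end of
#' the fatigue protocol.
#'
#' @inheritParams fatigue_analysis
#' @inheritParams recovery_rates
#' @param expected_stims Expected number of stimulations; fewer events
#'   trigger a warning, and metrics are computed on the available set.
#' @return A `recovery_result`; see [recovery_rates()].
#' @export
recovery_analysis <- function(trace, events, fatigue_end_force,
                              baseline_force, baseline = NULL,
                              expected_stims = NULL,
                              pct_mode = c("delta", "absolute")) {
  stopifnot(inherits(trace, "force_trace"))
  ev <- events[events$protocol == "recovery", , drop = FALSE]
  if (nrow(ev) == 0L) {
    abort("No recovery events in the protocol.", class = "mf_input_error")
  }
  if (!is.null(expected_stims) && nrow(ev) < expected_stims) {
    warn(sprintf("Only %d of %d expected recovery stimulations present.",
                 nrow(ev), expected_stims))
  }
  baseline <- baseline %||% trace$baseline %||% 0
  peaks <- event_peaks(trace, ev, baseline, tail_s = 0.5)
  recovery_rates(peaks, ev$onset_s, fatigue_end_force, baseline_force,
                 fatigue_end_time = 0, pct_mode = pct_mode)
}

#' Assemble the full contractile profile of one muscle
#'
#' Runs every metric extractor over a muscle's protocol traces and returns
#' one tidy row. Any protocol may be absent (damaged-muscle handling): its
#' metrics are reported missing and downstream statistics accept the partial
#' profile.
#'
#' @param twitch A twitch [force_trace()], or `NULL`.
#' @param ff Named list of tetanic traces per frequency (names = Hz), or
#'   `NULL`.
#' @param fatigue List with `trace` and `events` (from
#'   [simulate_fatigue_protocol()] or [read_trace()]), or `NULL`.
#' @param recovery List with `trace` and `events`, or `NULL`.
#' @param mass_g,l0_cm Muscle mass (g) and optimal length (cm) for PCSA.
#' @param muscle Muscle label.
#' @param pct_mode Passed to [recovery_rates()].
#' @return A one-row tibble with `muscle`, `mass_g`, `l0_cm`, `pcsa_cm2`,
#'   twitch metrics, `p0_mN`, `sp0_N_cm2`, `fatigue_auc_mNs`,
#'   `fatigue_baseline_mN`, `fatigue_end_mN`, `initial_rate_mN_s`,
#'   `pct_recovered`, and list-columns `ff_peaks`, `fatigue_peaks`,
#'   `recovery_rate_series`.
#' @export
contractile_profile <- function(twitch = NULL, ff = NULL, fatigue = NULL,
                                recovery = NULL, mass_g = NA_real_,
                                l0_cm = NA_real_, muscle = NA_character_,
                                pct_mode = "delta") {
  pc <- if (is.finite(mass_g) && is.finite(l0_cm)) pcsa(mass_g, l0_cm) else NA_real_
  tw <- if (!is.null(twitch)) twitch_metrics(twitch) else
    tibble::tibble(pt_mN = NA_real_, time_to_peak_s = NA_real_,
                   rfd_mN_s = NA_real_, hrt_s = NA_real_)
  ffr <- if (!is.null(ff)) force_frequency(ff) else NULL
  p0 <- if (!is.null(ffr)) attr(ffr, "p0_mN") else NA_real_
  sp0 <- if (is.finite(p0) && is.finite(pc)) specific_force(p0, pc) else NA_real_
  fat <- if (!is.null(fatigue)) {
    fatigue_analysis(fatigue$trace, fatigue$events)
  } else NULL
  rec <- if (!is.null(recovery) && !is.null(fat)) {
    recovery_analysis(recovery$trace, recovery$events,
                      fatigue_end_force = fat$peaks_mN[length(fat$peaks_mN)],
                      baseline_force = fat$baseline_force_mN,
                      pct_mode = pct_mode)
  } else NULL
  tibble::tibble(
    muscle = muscle, mass_g = mass_g, l0_cm = l0_cm, pcsa_cm2 = pc,
    pt_mN = tw$pt_mN, time_to_peak_s = tw$time_to_peak_s,
    rfd_mN_s = tw$rfd_mN_s, hrt_s = tw$hrt_s,
    p0_mN = p0, sp0_N_cm2 = sp0,
    fatigue_auc_mNs = if (!is.null(fat)) fat$auc_mNs else NA_real_,
    fatigue_baseline_mN = if (!is.null(fat)) fat$baseline_force_mN else NA_real_,
    fatigue_end_mN = if (!is.null(fat)) fat$peaks_mN[length(fat$peaks_mN)] else NA_real_,
    initial_rate_mN_s = if (!is.null(rec)) rec$initial_rate_mN_s else NA_real_,
    pct_recovered = if (!is.null(rec)) rec$pct_recovered else NA_real_,
    ff_peaks = list(ffr),
    fatigue_peaks = list(if (!is.null(fat)) fat$peaks_mN else NULL),
    recovery_rate_series = list(if (!is.null(rec)) rec$rates_mN_s else NULL)
  )
}
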