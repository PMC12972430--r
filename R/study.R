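# End-to-end synthetic study: cohort -> traces -> metrics -> report.

twitch_params_from_row <- function(row) {
  twitch_params(amplitude_A = row$amplitude_A, tau_contract = row$tau_contract,
                tau_relax = row$tau_relax, f_max = row$f_max,
                k_half = row$k_half, sampling_rate = row$sampling_rate)
}

fr_params_from_row <- function(row, fatigue) {
  fatigue_recovery_params(
    n_contractions = fatigue$n_contractions, train_freq = fatigue$train_freq,
    train_duration = fatigue$train_duration, rest_between = fatigue$rest_between,
    decay_floor_r = row$decay_floor_r, decay_kappa = row$decay_kappa,
    n_recovery_stims = fatigue$n_recovery_stims,
    recovery_interval = fatigue$recovery_interval,
    recovery_tau = row$recovery_tau, recovery_plateau = row$recovery_plateau,
    allow_impaired = TRUE
  )
}

#' Simulate all protocol traces for one mouse x muscle
#'
#' Generates the twitch, force-frequency, fatigue and recovery traces for
#' one row of [cohort_trace_params()], seeding an independent random stream
#' from the root seed and the mouse/muscle indices.
#'
#' @param row One row of the trace-parameter table.
#' @param config The [sim_config()] the cohort was simulated under.
#' @param stream Integer stream indices identifying this mouse x muscle.
#' @return A list: `twitch` (trace), `ff` (named list of traces per Hz),
#'   `fatigue` and `recovery` (each `list(trace, events)`), `params`,
#'   `fr`.
#' @export
simulate_muscle_protocols <- function(row, config, stream = c(1L, 1L)) {
  params <- twitch_params_from_row(row)
  fr <- fr_params_from_row(row, config$fatigue)
  set.seed(stream_seed(config$seed, 10L, stream))
  nsd <- config$trace_noise_sd
  tw <- simulate_twitch(params, noise_sd = nsd)
  freqs <- config$muscles[[row$muscle]]$ff_freqs
  ff <- lapply(freqs, function(fq) {
    simulate_tetanus(params, fq, duration = 0.3, noise_sd = nsd, tail_s = 0.3)
  })
  names(ff) <- freqs
  fat <- simulate_fatigue_protocol(params, fr, peak_cv = config$peak_cv,
                                   noise_sd = nsd)
  end_scale <- fatigue_scale(fr$n_contractions, fr$decay_floor_r, fr$decay_kappa)
  rec <- simulate_recovery_protocol(params, fr, end_scale = end_scale,
                                    freq = row$recovery_freq,
                                    peak_cv = config$peak_cv, noise_sd = nsd)
  list(twitch = tw, ff = ff, fatigue = fat, recovery = rec,
       params = params, fr = fr)
}

# Envelope (trace-free) metrics for one mouse x muscle; shares the closed
# forms with the trace generators. Twitch/FF metrics still come from short
# traces (they are cheap); only the long fatigue/recovery traces are
# replaced by peak-level simulation.
simulate_muscle_envelope <- function(row, config, stream = c(1L, 1L)) {
  params <- twitch_params_from_row(row)
  fr <- fr_params_from_row(row, config$fatigue)
  set.seed(stream_seed(config$seed, 10L, stream))
  pk <- simulate_protocol_peaks(params, fr, recovery_freq = row$recovery_freq,
                                peak_cv = config$peak_cv)
  rec <- recovery_rates(pk$recovery_peaks, pk$recovery_times,
                        fatigue_end_force = pk$end_force,
                        baseline_force = pk$baseline_force)
  tw <- simulate_twitch(params, noise_sd = 0)
  twm <- twitch_metrics(tw)
  tibble::tibble(
    muscle = row$muscle, mass_g = row$mass_g, l0_cm = row$l0_cm,
    pcsa_cm2 = pcsa(row$mass_g, row$l0_cm),
    pt_mN = twm$pt_mN, time_to_peak_s = twm$time_to_peak_s,
    rfd_mN_s = twm$rfd_mN_s, hrt_s = twm$hrt_s,
    p0_mN = NA_real_, sp0_N_cm2 = NA_real_,
    fatigue_auc_mNs = pk$fatigue_auc_envelope,
    fatigue_baseline_mN = pk$baseline_force,
    fatigue_end_mN = pk$end_force,
    initial_rate_mN_s = rec$initial_rate_mN_s,
    pct_recovered = rec$pct_recovered,
    ff_peaks = list(NULL),
    fatigue_peaks = list(pk$fatigue_peaks),
    recovery_rate_series = list(rec$rates_mN_s)
  )
}

#' Extract contractile metrics for a whole simulated cohort
#'
#' For every mouse x muscle in [cohort_trace_params()], simulates the
#' protocol traces and extracts the full contractile profile. With
#' `mode = "envelope"` the long fatigue/recovery traces are replaced by the
#' trace-free peak-level path (see [simulate_protocol_peaks()]): fatigue AUC
#' is then the peaks-only envelope AUC. Intended for Monte-Carlo studies;
#' `mode = "trace"` is the default full path.
#'
#' @param cohort A tibble from [simulate_cohort()].
#' @param config The matching [sim_config()].
#' @param mode `"trace"` or `"envelope"`.
#' @param muscles Restrict to these muscles (default: all configured).
#' @return A tibble with one row per mouse x muscle: identifiers, condition
#'   factors, and all [contractile_profile()] columns.
#' @export
simulate_study_metrics <- function(cohort, config, mode = c("trace", "envelope"),
                                   muscles = NULL) {
  mode <- match.arg(mode)
  tp <- cohort_trace_params(cohort)
  if (!is.null(muscles) && nrow(tp)) tp <- tp[tp$muscle %in% muscles, , drop = FALSE]
  if (nrow(tp) == 0L) return(tibble::tibble())
  rows <- vector("list", nrow(tp))
  muscle_idx <- as.integer(factor(tp$muscle))
  mouse_idx <- as.integer(factor(tp$mouse_id))
  for (i in seq_len(nrow(tp))) {
    row <- tp[i, ]
    stream <- c(mouse_idx[i], muscle_idx[i])
    prof <- if (mode == "trace") {
      sim <- simulate_muscle_protocols(row, config, stream)
      contractile_profile(
        twitch = sim$twitch, ff = sim$ff, fatigue = sim$fatigue,
        recovery = sim$recovery, mass_g = row$mass_g, l0_cm = row$l0_cm,
        muscle = row$muscle
      )
    } else {
      simulate_muscle_envelope(row, config, stream)
    }
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(mouse_id = row$mouse_id, condition = row$condition,
                     frailty_class = row$frailty_class,
                     run_group = row$run_group),
      prof
    )
  }
  dplyr::bind_rows(rows)
}

#' Run the full synthetic study end to end
#'
#' Simulate the cohort, phenotype it, extract contractile metrics from the
#' simulated traces, and run the complete statistical analysis. Everything
#' is driven by the single seed in `config`; identical configurations give
#' identical results.
#'
#' @param config A [sim_config()].
#' @param mode Passed to [simulate_study_metrics()].
#' @return A list of class `mf_study`: `cohort`, `phenotypes`, `metrics`,
#'   `report` (see [run_full_analysis()]), and `config`.
#' @export
#' @examples
#' \donttest{
#' study <- run_full_study(sim_config(n_mice = 20, seed = 3))
#' study$report
#' }
run_full_study <- function(config = sim_config(), mode = "trace") {
  cohort <- simulate_cohort(config)
  phenotypes <- if (nrow(cohort) >= 2L) {
    phenotype_cohort(cohort, rate = config$marker_rate)
  } else {
    summarize_phenotypes(cohort)
  }
  metrics <- simulate_study_metrics(cohort, config, mode = mode)
  report <- run_full_analysis(phenotypes, metrics,
                              manifest = run_manifest(config))
  structure(list(cohort = cohort, phenotypes = phenotypes, metrics = metrics,
                 report = report, config = config),
            class = "mf_study")
}

#' @export
print.mf_study <- function(x, ...) {
  cat(sprintf("<mf_study> %d mice | seed %d\n", x$config$n_mice, x$config$seed))
  print(x$report)
  invisible(x)
}
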