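#' Simulation configuration for a synthetic frailty-contractility study
#'
#' `sim_config()` bundles every tunable of the synthetic-data generator:
#' cohort size, the latent-factor loading that correlates the five frailty
#' criteria, the adverse-tail rate used for marker assignment, the fraction
#' of mice assigned to the eccentric (downhill) running group, per-condition
#' multiplicative effect sizes on the contractile simulator parameters, and
#' the noise model (a coefficient of variation on per-contraction peak forces
#' plus additive white noise on trace samples).
#'
#' The five frailty criteria (treadmill distance, grip strength, rotarod
#' latency, body weight, frailty index) are generated from a shared latent
#' standard-normal frailty factor per mouse: performance criteria load
#' negatively (frailer mice perform worse), body weight and frailty index
#' positively. `latent_loading = 0` makes the criteria mutually independent.
#'
#' Effect sizes are multiplicative modifiers, one set per condition
#' (`low_control`, `low_run`, `high_control`, `high_run`), applied to the
#' per-mouse trace-simulator parameters. The defaults encode: running
#' increases twitch amplitude and mildly shortens the relaxation time
#' constant in both frailty groups; high-frailty mice carry smaller fast
#' muscles; and the high-frailty running condition additionally halves the
#' fatigue decay constant (faster fatigue), doubles the recovery time
#' constant (slower initial recovery), reduces the recovery plateau, and
#' shortens the relaxation time constant by 20% (shorter half-relaxation
#' time).
#'
#' @param n_mice Number of mice in the cohort (>= 0).
#' @param seed Integer root seed; all randomness in the generator flows from
#'   it via deterministic per-stream derivation (see [stream_seed()]).
#' @param latent_loading Correlation of each criterion with the shared latent
#'   frailty factor, in `[0, 1]`. Scalar or named vector over
#'   `c("treadmill", "grip", "rotarod", "body_weight", "fi")`.
#' @param marker_rate Adverse-tail fraction per criterion used for marker
#'   assignment (default 0.2: 20th/80th percentile rule).
#' @param run_fraction Fraction of the cohort assigned to the running group.
#' @param effect_sizes Named list of per-condition multiplier lists; see
#'   [default_effect_sizes()].
#' @param peak_cv Coefficient of variation of multiplicative noise on
#'   per-contraction peak forces.
#' @param trace_noise_sd Standard deviation (mN) of additive white noise on
#'   trace samples.
#' @param between_mouse_cv Coefficient of variation of per-mouse lognormal
#'   variation in force scale and muscle mass.
#' @param muscles Named list of per-muscle base parameters; see
#'   [default_muscle_params()].
#' @param fatigue A [fatigue_recovery_params()] object shared by both muscles.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_cohort()], [twitch_params()], [fatigue_recovery_params()]
#' @export
#' @examples
#' cfg <- sim_config(n_mice = 10, seed = 1)
#' cohort <- simulate_cohort(cfg)
sim_config <- function(n_mice = 47L,
                       seed = 1L,
                       latent_loading = 0.5,
                       marker_rate = 0.2,
                       run_fraction = 21 / 47,
                       effect_sizes = default_effect_sizes(),
                       peak_cv = 0.05,
                       trace_noise_sd = 0.1,
                       between_mouse_cv = 0.10,
                       muscles = default_muscle_params(),
                       fatigue = fatigue_recovery_params()) {
  if (length(latent_loading) == 1L) {
    latent_loading <- setNames(rep(latent_loading, 5L), criterion_names())
  }
  if (!setequal(names(latent_loading), criterion_names())) {
    abort("`latent_loading` must be scalar or named over the five criteria.")
  }
  latent_loading <- latent_loading[criterion_names()]
  cfg <- list(
    n_mice = as.integer(n_mice), seed = as.integer(seed),
    latent_loading = latent_loading, marker_rate = marker_rate,
    run_fraction = run_fraction, effect_sizes = effect_sizes,
    peak_cv = peak_cv, trace_noise_sd = trace_noise_sd,
    between_mouse_cv = between_mouse_cv,
    muscles = muscles, fatigue = fatigue
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  num_fields <- c(cfg$latent_loading, cfg$marker_rate, cfg$run_fraction,
                  cfg$peak_cv, cfg$trace_noise_sd, cfg$between_mouse_cv,
                  cfg$n_mice, cfg$seed)
  if (any(!is.finite(num_fields))) {
    abort("Non-finite value in simulation configuration.", class = "mf_config_error")
  }
  fr <- c(cfg$latent_loading, marker_rate = cfg$marker_rate,
          run_fraction = cfg$run_fraction)
  bad <- fr < 0 | fr > 1
  if (any(bad)) {
    abort(paste0("Fractions outside [0, 1]: ",
                 paste(names(fr)[bad], collapse = ", ")),
          class = "mf_config_error")
  }
  if (cfg$n_mice < 0) abort("`n_mice` must be >= 0.", class = "mf_config_error")
  invisible(cfg)
}

criterion_names <- function() c("treadmill", "grip", "rotarod", "body_weight", "fi")

#' Default per-condition effect-size multipliers
#'
#' One multiplier set per condition (frailty class x run group). Fields:
#' `amplitude` (twitch force scale), `tau_relax` (relaxation time constant;
#' < 1 shortens half-relaxation time), `mass` (muscle mass), `kappa` (fatigue
#' decay constant; < 1 means faster fatigue), `recovery_tau` (recovery time
#' constant; > 1 means slower recovery), `recovery_plateau` (fraction of
#' baseline force recovered at plateau).
#'
#' @return Named list with elements `low_control`, `low_run`, `high_control`,
#'   `high_run`.
#' @export
default_effect_sizes <- function() {
  base <- list(amplitude = 1, tau_relax = 1, mass = 1, kappa = 1,
               recovery_tau = 1, recovery_plateau = 1)
  list(
    low_control  = base,
    low_run      = modifyList(base, list(amplitude = 1.10, tau_relax = 0.92)),
    high_control = modifyList(base, list(mass = 0.88)),
    high_run     = modifyList(base, list(
      amplitude = 1.10, mass = 0.88, tau_relax = 0.80,
      kappa = 0.5, recovery_tau = 2.0, recovery_plateau = 0.85
    ))
  )
}

#' Default base contractile parameters per muscle
#'
#' Fast-twitch EDL and slow-twitch soleus base parameters: twitch kernel time
#' constants, force scale and saturation, force-frequency protocol
#' frequencies, recovery stimulation frequency, and typical mass and optimal
#' length used for PCSA.
#'
#' @return Named list with elements `edl` and `soleus`.
#' @export
default_muscle_params <- function() {
  list(
    edl = list(
      twitch = twitch_params(amplitude_A = 150, tau_contract = 0.010,
                             tau_relax = 0.050, f_max = 400, k_half = 300,
                             sampling_rate = 1000),
      ff_freqs = c(10, 40, 80, 120, 150, 180),
      recovery_freq = 80,
      mass_g = 0.0105, l0_cm = 1.25
    ),
    soleus = list(
      twitch = twitch_params(amplitude_A = 80, tau_contract = 0.030,
                             tau_relax = 0.120, f_max = 280, k_half = 150,
                             sampling_rate = 1000),
      ff_freqs = c(10, 40, 80, 100, 120, 150),
      recovery_freq = 150,
      mass_g = 0.0092, l0_cm = 1.05
    )
  )
}

#' Twitch kernel parameters
#'
#' Parameters of the phenomenological twitch kernel
#' `F(t) = A * (exp(-t / tau_relax) - exp(-t / tau_contract))` for `t >= 0`.
#' The kernel is deliberately left unnormalized: `A` is a force scale, not
#' the peak twitch force. The peak occurs at
#' `t_p = tau_contract * tau_relax / (tau_relax - tau_contract) * log(tau_relax / tau_contract)`
#' (see [twitch_peak_time()]), so peak force and maximal rate of force
#' development have simple closed forms used throughout the test-suite.
#'
#' @param amplitude_A Force scale (mN), >= 0.
#' @param tau_contract Contraction time constant (s); must be < `tau_relax`.
#' @param tau_relax Relaxation time constant (s).
#' @param f_max Tetanic saturation force (mN), > 0.
#' @param k_half Saturation constant (same units as the summed drive).
#' @param sampling_rate Sampling rate (Hz), >= 1000.
#' @return A list of class `twitch_params`.
#' @export
twitch_params <- function(amplitude_A = 150, tau_contract = 0.010,
                          tau_relax = 0.050, f_max = 400, k_half = 300,
                          sampling_rate = 1000) {
  p <- list(amplitude_A = amplitude_A, tau_contract = tau_contract,
            tau_relax = tau_relax, f_max = f_max, k_half = k_half,
            sampling_rate = sampling_rate)
  if (any(!is.finite(unlist(p)))) {
    abort("Non-finite twitch parameter.", class = "mf_param_error")
  }
  if (!(tau_contract > 0 && tau_contract < tau_relax)) {
    abort("Require 0 < tau_contract < tau_relax.", class = "mf_param_error")
  }
  if (amplitude_A < 0) abort("`amplitude_A` must be >= 0.", class = "mf_param_error")
  if (f_max <= 0) abort("`f_max` must be > 0.", class = "mf_param_error")
  if (sampling_rate < 1000) {
    abort("`sampling_rate` must be >= 1000 Hz.", class = "mf_param_error")
  }
  structure(p, class = "twitch_params")
}

#' Fatigue and recovery protocol parameters
#'
#' The fatigue protocol delivers `n_contractions` tetani at `train_freq`
#' (default 80 Hz) of `train_duration` seconds each, separated by
#' `rest_between` seconds of rest (default 5 s). The k-th contraction is
#' scaled by `s_k = r + (1 - r) * exp(-(k - 1) / kappa)` with floor
#' `r = decay_floor_r` and decay constant `kappa = decay_kappa`
#' (in contractions). Recovery delivers `n_recovery_stims` stimulations
#' (default 10) at `recovery_interval` seconds apart (default 300 s = 5 min);
#' the stimulation at time `t` is scaled by
#' `s(t) = end_scale + (recovery_plateau - end_scale) * (1 - exp(-t / recovery_tau))`.
#'
#' `recovery_plateau < decay_floor_r` encodes impaired recovery and is only
#' accepted with `allow_impaired = TRUE`.
#'
#' @param n_contractions Number of fatigue tetani (>= 1).
#' @param train_freq Stimulation frequency within each tetanus (Hz).
#' @param train_duration Duration of each tetanus (s).
#' @param rest_between Rest between fatigue tetani (s).
#' @param decay_floor_r Asymptotic force fraction `r` in `[0, 1]`.
#' @param decay_kappa Fatigue decay constant (contractions).
#' @param n_recovery_stims Number of recovery stimulations (>= 1).
#' @param recovery_interval Interval between recovery stimulations (s).
#' @param recovery_tau Recovery time constant (s).
#' @param recovery_plateau Recovery plateau as a fraction of baseline force.
#' @param allow_impaired Permit `recovery_plateau < decay_floor_r`.
#' @return A list of class `fatigue_recovery_params`.
#' @export
fatigue_recovery_params <- function(n_contractions = 60L, train_freq = 80,
                                    train_duration = 0.5, rest_between = 5,
                                    decay_floor_r = 0.35, decay_kappa = 20,
                                    n_recovery_stims = 10L,
                                    recovery_interval = 300,
                                    recovery_tau = 400,
                                    recovery_plateau = 0.85,
                                    allow_impaired = FALSE) {
  p <- list(n_contractions = as.integer(n_contractions),
            train_freq = train_freq, train_duration = train_duration,
            rest_between = rest_between, decay_floor_r = decay_floor_r,
            decay_kappa = decay_kappa,
            n_recovery_stims = as.integer(n_recovery_stims),
            recovery_interval = recovery_interval,
            recovery_tau = recovery_tau, recovery_plateau = recovery_plateau)
  if (any(!is.finite(unlist(p)))) {
    abort("Non-finite fatigue/recovery parameter.", class = "mf_param_error")
  }
  if (p$decay_floor_r < 0 || p$decay_floor_r > 1) {
    abort("`decay_floor_r` must lie in [0, 1].", class = "mf_param_error")
  }
  if (p$n_contractions < 1 || p$n_recovery_stims < 1) {
    abort("Counts must be >= 1.", class = "mf_param_error")
  }
  if (p$recovery_plateau < p$decay_floor_r && !allow_impaired) {
    abort(paste("`recovery_plateau` < `decay_floor_r` encodes impaired",
                "recovery; set `allow_impaired = TRUE` to simulate it."),
          class = "mf_param_error")
  }
  structure(p, class = "fatigue_recovery_params")
}

#' Derive a deterministic sub-stream seed from a root seed
#'
#' All randomness in the package flows from one root seed. Independent
#' streams (per cohort, mouse, muscle, protocol) are derived by folding
#' integer stream indices into the root seed with a Lehmer-style
#' multiply-add modulo 2^31 - 1, so the same root seed and indices always
#' reproduce the same stream, regardless of how many draws other streams
#' consumed.
#'
#' @param seed Integer root seed.
#' @param ... Integer stream indices.
#' @return An integer seed suitable for [set.seed()].
#' @export
stream_seed <- function(seed, ...) {
  m <- 2147483647
  s <- as.numeric(seed) %% m
  for (i in c(...)) {
    s <- (s * 48271 + as.numeric(i) + 1) %% m
  }
  as.integer(s)
}

#' Fatigue decay scale for contraction k
#'
#' `s_k = r + (1 - r) * exp(-(k - 1) / kappa)`: the fraction of baseline
#' force produced by the k-th tetanus of the fatigue protocol.
#'
#' @param k Contraction index (1-based); vectorized.
#' @param r Asymptotic floor fraction.
#' @param kappa Decay constant in contractions.
#' @return Numeric vector of scales in `[r, 1]`.
#' @export
fatigue_scale <- function(k, r, kappa) r + (1 - r) * exp(-(k - 1) / kappa)

#' Recovery scale at time t after fatigue end
#'
#' `s(t) = end_scale + (plateau - end_scale) * (1 - exp(-t / tau))`: the
#' fraction of baseline force produced by a recovery stimulation delivered
#' `t` seconds after the end of the fatigue protocol.
#'
#' @param t Time since fatigue end (s); vectorized.
#' @param end_scale Force fraction at fatigue end.
#' @param plateau Recovery plateau fraction.
#' @param tau Recovery time constant (s).
#' @return Numeric vector of scales.
#' @export
recovery_scale <- function(t, end_scale, plateau, tau) {
  if (tau <= 0) return(rep(plateau, length(t)))
  end_scale + (plateau - end_scale) * (1 - exp(-t / tau))
}
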