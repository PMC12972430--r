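# The synthetic-data generator: cohort structure, trace closed forms,
# determinism.

test_that("simulate_cohort produces the schema, handles n = 0, and is deterministic", {
  cfg <- sim_config(n_mice = 20, seed = 11)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co), 20)
  expect_named(co, c("mouse_id", "run_group", "body_weight_g",
                     "treadmill_distance_m", sprintf("grip_trial_%d", 1:5),
                     sprintf("rotarod_trial_%d", 1:3),
                     sprintf("fi_item_%02d", 1:28)))
  fi <- as.matrix(co[sprintf("fi_item_%02d", 1:28)])
  expect_true(all(fi %in% c(0, 0.5, 1)))
  expect_equal(sum(co$run_group == "run"), round(20 * 21 / 47))

  empty <- simulate_cohort(sim_config(n_mice = 0, seed = 1))
  expect_equal(nrow(empty), 0)
  expect_identical(names(empty), names(co))

  co2 <- simulate_cohort(sim_config(n_mice = 20, seed = 11))
  expect_identical(co, co2)
  expect_identical(cohort_trace_params(co), cohort_trace_params(co2))

  co3 <- simulate_cohort(sim_config(n_mice = 20, seed = 12))
  expect_false(identical(co$body_weight_g, co3$body_weight_g))
})

test_that("non-finite or out-of-range configuration is rejected", {
  expect_error(sim_config(marker_rate = NaN), class = "mf_config_error")
  expect_error(sim_config(run_fraction = 1.2), class = "mf_config_error")
  expect_error(sim_config(n_mice = -1), class = "mf_config_error")
  expect_error(twitch_params(tau_contract = 0.05, tau_relax = 0.01),
               class = "mf_param_error")
  expect_error(fatigue_recovery_params(decay_floor_r = 1.4),
               class = "mf_param_error")
  # impaired recovery (plateau below the fatigue floor) needs the flag
  expect_error(fatigue_recovery_params(recovery_plateau = 0.2),
               class = "mf_param_error")
  expect_s3_class(fatigue_recovery_params(recovery_plateau = 0.2,
                                          allow_impaired = TRUE),
                  "fatigue_recovery_params")
})

test_that("twitch trace matches the kernel's closed-form peak and scales linearly", {
  p <- twitch_params(amplitude_A = 10, tau_contract = 0.01, tau_relax = 0.05,
                     sampling_rate = 10000)
  tw <- as_tibble(simulate_twitch(p))
  ora <- oracle_twitch_peak(10, 0.01, 0.05)
  expect_equal(ora$t, 0.0201, tolerance = 1e-2)
  expect_equal(ora$f, 5.3499, tolerance = 1e-4)
  expect_equal(max(tw$force_mN), ora$f, tolerance = 1e-5)
  expect_equal(tw$time_s[which.max(tw$force_mN)], ora$t, tolerance = 1e-2)

  zero <- as_tibble(simulate_twitch(twitch_params(amplitude_A = 0)))
  expect_true(all(zero$force_mN == 0))

  p2 <- twitch_params(amplitude_A = 20, tau_contract = 0.01, tau_relax = 0.05,
                      sampling_rate = 10000)
  expect_equal(as_tibble(simulate_twitch(p2))$force_mN, 2 * tw$force_mN)
})

test_that("tetanic plateau saturates below f_max and grows with frequency", {
  p <- twitch_params()
  freqs <- c(10, 40, 80, 120, 150, 180)
  peaks <- vapply(freqs, function(fq) {
    max(as_tibble(simulate_tetanus(p, fq, duration = 0.3))$force_mN)
  }, numeric(1))
  expect_true(all(peaks < p$f_max))
  expect_true(all(diff(peaks) >= 0))
  # the slow soleus parameterization saturates at lower frequencies
  ps <- sim_config()$muscles$soleus$twitch
  peaks_sol <- vapply(c(10, 40, 80, 100, 120, 150), function(fq) {
    max(as_tibble(simulate_tetanus(ps, fq, duration = 0.3))$force_mN)
  }, numeric(1))
  expect_true(all(diff(peaks_sol) >= 0))
  expect_warning(simulate_tetanus(p, freq = 1, duration = 0.2),
                 "single-pulse")
})

test_that("fatigue protocol peaks follow s_k = r + (1 - r) exp(-(k - 1) / kappa)", {
  expect_equal(fatigue_scale(10, r = 0.4, kappa = 5),
               0.4 + 0.6 * exp(-9 / 5), tolerance = 1e-12)
  expect_equal(fatigue_scale(10, r = 0.4, kappa = 5), 0.4992, tolerance = 1e-3)

  p <- twitch_params()
  fr <- fatigue_recovery_params(n_contractions = 12, decay_kappa = 5,
                                decay_floor_r = 0.4)
  sim <- simulate_fatigue_protocol(p, fr)
  res <- fatigue_analysis(sim$trace, sim$events)
  expect_length(res$peaks_mN, 12)
  expect_true(all(diff(res$peaks_mN) <= 1e-9))  # nonincreasing without noise
  # constant envelope when r = 1
  fr1 <- fatigue_recovery_params(n_contractions = 6, decay_floor_r = 1,
                                 decay_kappa = 5, recovery_plateau = 1)
  sim1 <- simulate_fatigue_protocol(p, fr1)
  pk1 <- fatigue_analysis(sim1$trace, sim1$events)$peaks_mN
  expect_equal(max(pk1) - min(pk1), 0, tolerance = 1e-9)
})

test_that("recovery protocol peaks follow the saturating-exponential time course", {
  expect_equal(recovery_scale(300, end_scale = 0.4, plateau = 0.8, tau = 600),
               0.4 + 0.4 * (1 - exp(-0.5)), tolerance = 1e-12)
  expect_equal(recovery_scale(300, 0.4, 0.8, 600), 0.5574, tolerance = 1e-3)
  # limits: tau -> 0 jumps straight to plateau; plateau = end is flat
  expect_equal(recovery_scale(c(1, 100), 0.4, 0.8, 0), c(0.8, 0.8))
  expect_equal(recovery_scale(c(1, 100), 0.6, 0.6, 500), c(0.6, 0.6))

  p <- twitch_params()
  fr <- fatigue_recovery_params(n_recovery_stims = 4, recovery_interval = 30,
                                recovery_tau = 40, recovery_plateau = 0.8)
  sim <- simulate_recovery_protocol(p, fr, end_scale = 0.4)
  peaks <- vapply(seq_len(nrow(sim$events)), function(i) {
    d <- as_tibble(sim$trace)
    w <- d$time_s >= sim$events$onset_s[i] &
      d$time_s <= sim$events$onset_s[i] + sim$events$duration_s[i] + 0.5
    max(d$force_mN[w])
  }, numeric(1))
  tmpl_peak <- max(as_tibble(simulate_tetanus(p, fr$train_freq, fr$train_duration))$force_mN)
  expected <- tmpl_peak * recovery_scale(sim$events$onset_s, 0.4, 0.8, 40)
  expect_equal(peaks, expected, tolerance = 1e-6)
  expect_error(simulate_recovery_protocol(p, fr, end_scale = 1.2),
               class = "mf_param_error")
})

test_that("envelope path matches full-trace extraction on noiseless protocols", {
  p <- twitch_params()
  fr <- fatigue_recovery_params(n_contractions = 8, decay_kappa = 4,
                                decay_floor_r = 0.4, n_recovery_stims = 3,
                                recovery_interval = 20, recovery_tau = 30,
                                recovery_plateau = 0.8)
  env <- simulate_protocol_peaks(p, fr)
  sim <- simulate_fatigue_protocol(p, fr)
  res <- fatigue_analysis(sim$trace, sim$events)
  expect_equal(res$peaks_mN, env$fatigue_peaks, tolerance = 5e-3)
  expect_equal(res$auc_envelope_mNs / env$fatigue_auc_envelope, 1,
               tolerance = 0.2)  # envelope defs differ (peak x duration vs trapz)
  rec <- simulate_recovery_protocol(p, fr,
                                    end_scale = env$end_force / env$baseline_force *
                                      fatigue_scale(1, 0.4, 4))
  expect_length(env$recovery_peaks, 3)
})

test_that("under zero loading with theoretical flagging the High fraction matches the binomial closed form", {
  p_high <- 1 - 0.8^5 - 5 * 0.2 * 0.8^4
  expect_equal(p_high, 0.26272, tolerance = 1e-12)
  sim <- simulate_marker_split(n_cohorts = 400, n_mice = 47, seed = 99)
  expect_equal(mean(sim$n_high) / 47, p_high, tolerance = 0.05)
  expect_equal(sim$n_high + sim$n_low, rep(47, 400))
  # determinism of the replicate simulation
  sim2 <- simulate_marker_split(n_cohorts = 400, n_mice = 47, seed = 99)
  expect_identical(sim, sim2)
})

test_that("latent loading increases the dispersion of per-mouse marker counts", {
  count_var <- function(loading, seed) {
    v <- numeric(200)
    for (r in seq_len(200)) {
      co <- simulate_cohort(sim_config(n_mice = 47, seed = stream_seed(seed, r),
                                       latent_loading = loading))
      lat <- attr(co, "latent")
      z <- as.matrix(lat[c("treadmill", "grip", "rotarod", "body_weight", "fi")])
      v[r] <- var(rowSums(z > theoretical_thresholds()[1]))
    }
    mean(v)
  }
  expect_gt(count_var(0.8, 7), count_var(0, 7))
})
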