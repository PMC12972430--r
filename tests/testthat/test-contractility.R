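# Metric extraction from force-time traces: twitch kinetics, specific
# force, fatigue AUC, recovery kinetics, and their scaling properties.

test_that("HRT on a sampled exponential relaxation equals tau * log(2)", {
  tau <- 0.030
  fs <- 1000
  t <- seq(0, 0.5, by = 1 / fs)
  rise <- pmin(t / 0.01, 1)              # fast linear rise to the peak
  f <- 10 * rise * exp(-pmax(t - 0.01, 0) / tau)
  tr <- force_trace(t, f, fs)
  m <- twitch_metrics(tr)
  expect_equal(m$hrt_s, tau * log(2), tolerance = 1 / fs / (tau * log(2)))
  # convergence: finer sampling shrinks the error below one coarse sample
  fs2 <- 10000
  t2 <- seq(0, 0.5, by = 1 / fs2)
  f2 <- 10 * pmin(t2 / 0.01, 1) * exp(-pmax(t2 - 0.01, 0) / tau)
  m2 <- twitch_metrics(force_trace(t2, f2, fs2))
  expect_lt(abs(m2$hrt_s - tau * log(2)), abs(m$hrt_s - tau * log(2)) + 1e-9)
})

test_that("RFD matches the kernel's analytic maximal slope A (1/tau_c - 1/tau_r)", {
  p <- twitch_params(amplitude_A = 10, tau_contract = 0.01, tau_relax = 0.05,
                     sampling_rate = 10000)
  m <- twitch_metrics(simulate_twitch(p))
  expect_equal(m$rfd_mN_s, 10 * (1 / 0.01 - 1 / 0.05), tolerance = 0.02)
  expect_equal(m$pt_mN, oracle_twitch_peak(10, 0.01, 0.05)$f, tolerance = 1e-4)
})

test_that("degenerate twitch traces yield missing metrics with a warning", {
  t <- seq(0, 0.2, by = 1e-3)
  expect_warning(m <- twitch_metrics(force_trace(t, rep(0, length(t)), 1000)),
                 "Nonpositive")
  expect_true(all(is.na(unlist(m))))
  # force that never relaxes below half peak: HRT missing, Pt present
  expect_warning(m2 <- twitch_metrics(force_trace(t, pmin(t * 100, 1), 1000)),
                 "HRT")
  expect_false(is.na(m2$pt_mN))
  expect_true(is.na(m2$hrt_s))
})

test_that("force-frequency map reports peaks and P0 = max, warning on missing frequencies", {
  ff <- force_frequency(tibble::tibble(freq_hz = c(10, 80, 180),
                                       peak_mN = c(100, 300, 310)))
  expect_equal(attr(ff, "p0_mN"), 310)
  single <- force_frequency(tibble::tibble(freq_hz = 80, peak_mN = 250))
  expect_equal(attr(single, "p0_mN"), 250)
  p <- twitch_params()
  traces <- lapply(c(10, 80), function(fq) simulate_tetanus(p, fq, 0.3))
  names(traces) <- c(10, 80)
  expect_warning(ff2 <- force_frequency(traces, protocol_freqs = c(10, 40, 80)),
                 "Missing traces")
  expect_true(all(diff(ff2$peak_mN) >= 0))
})

test_that("PCSA and specific force follow the density-1.06 formulas", {
  expect_equal(pcsa(0.0106, 1.0), 0.01)
  expect_equal(pcsa(0.0212, 1.0), 0.02)
  expect_equal(pcsa(0.0106, 2.0), 0.005)
  expect_error(pcsa(0, 1), class = "mf_input_error")
  expect_equal(specific_force(400, 0.02), 20)
  expect_equal(specific_force(0, 0.02), 0)
  expect_equal(specific_force(800, 0.04), specific_force(400, 0.02))
  expect_error(specific_force(400, 0), class = "mf_input_error")
})

test_that("fatigue AUC is exact on a rectangle and < 0.1% off an exponential envelope", {
  fs <- 1000
  t <- seq(0, 60, by = 1 / fs)
  tr <- force_trace(t, rep(10, length(t)), fs)
  ev <- tibble::tibble(protocol = "fatigue", onset_s = 0, freq_hz = 80,
                       duration_s = 60)
  res <- fatigue_analysis(tr, ev)
  expect_equal(res$auc_mNs, 600, tolerance = 1e-9)

  zero <- fatigue_analysis(force_trace(t, rep(0, length(t)), fs), ev)
  expect_equal(zero$auc_mNs, 0)

  # exponentially decaying envelope: trapezoid vs closed-form integral
  tau <- 12
  f_exp <- 20 * exp(-t / tau)
  res_exp <- fatigue_analysis(force_trace(t, f_exp, fs), ev)
  analytic <- 20 * tau * (1 - exp(-60 / tau))
  expect_equal(res_exp$auc_mNs, analytic, tolerance = 1e-3)
  expect_error(fatigue_analysis(tr, ev[0, ]), class = "mf_input_error")
})

test_that("recovery rates include the fatigue-end pair and the closed-form percent recovered", {
  r1 <- recovery_rates(13, 300, fatigue_end_force = 10, baseline_force = 100)
  expect_equal(r1$initial_rate_mN_s, 0.01)
  expect_equal(r1$pct_recovered, 3)

  flat <- recovery_rates(rep(10, 5), (1:5) * 300, 10, 100)
  expect_true(all(flat$rates_mN_s == 0))
  expect_equal(flat$pct_recovered, 0)

  # simulated s(t) curve: end 0.4, plateau 0.8, tau = 600 s, baseline 100 mN
  t_i <- (1:10) * 300
  peaks <- 100 * recovery_scale(t_i, 0.4, 0.8, 600)
  rr <- recovery_rates(peaks, t_i, fatigue_end_force = 40, baseline_force = 100)
  expect_equal(rr$pct_recovered, 100 * 0.4 * (1 - exp(-3000 / 600)),
               tolerance = 1e-9)
  expect_equal(rr$pct_recovered, 39.73, tolerance = 1e-3)
  expect_length(rr$rates_mN_s, 10)
  abs_mode <- recovery_rates(peaks, t_i, 40, 100, pct_mode = "absolute")
  expect_equal(abs_mode$pct_recovered, peaks[10])
  expect_error(recovery_rates(peaks, t_i, 40, 0), class = "mf_input_error")
})

test_that("extracted fatigue peaks equal f_peak * s_k within 0.5%", {
  p <- twitch_params()
  fr <- fatigue_recovery_params(n_contractions = 15, decay_kappa = 6,
                                decay_floor_r = 0.35)
  sim <- simulate_fatigue_protocol(p, fr)
  res <- fatigue_analysis(sim$trace, sim$events)
  tmpl_peak <- res$peaks_mN[1] / fatigue_scale(1, 0.35, 6)
  expected <- tmpl_peak * fatigue_scale(1:15, 0.35, 6)
  expect_equal(res$peaks_mN / expected, rep(1, 15), tolerance = 5e-3)
})

test_that("metrics are equivariant under force rescaling", {
  p <- twitch_params(amplitude_A = 10, tau_contract = 0.01, tau_relax = 0.05,
                     sampling_rate = 10000)
  m1 <- twitch_metrics(simulate_twitch(p))
  m2 <- twitch_metrics(simulate_twitch(
    twitch_params(amplitude_A = 30, tau_contract = 0.01, tau_relax = 0.05,
                  sampling_rate = 10000)))
  expect_equal(m2$pt_mN, 3 * m1$pt_mN)
  expect_equal(m2$rfd_mN_s, 3 * m1$rfd_mN_s)
  expect_equal(m2$hrt_s, m1$hrt_s)
  expect_equal(m2$time_to_peak_s, m1$time_to_peak_s)

  fs <- 1000
  t <- seq(0, 30, by = 1 / fs)
  f <- 5 + 5 * sin(t / 3)^2
  ev <- tibble::tibble(protocol = "fatigue", onset_s = 0, freq_hz = 80,
                       duration_s = 30)
  a1 <- fatigue_analysis(force_trace(t, f, fs), ev)
  a2 <- fatigue_analysis(force_trace(t, 3 * f, fs), ev)
  expect_equal(a2$auc_mNs, 3 * a1$auc_mNs, tolerance = 1e-9)

  rr1 <- recovery_rates(c(50, 60, 70), (1:3) * 300, 40, 100)
  rr3 <- recovery_rates(3 * c(50, 60, 70), (1:3) * 300, 3 * 40, 3 * 100)
  expect_equal(rr3$rates_mN_s, 3 * rr1$rates_mN_s)
  expect_equal(rr3$pct_recovered, rr1$pct_recovered)
})

test_that("contractile_profile accepts partial (damaged-muscle) inputs", {
  p <- twitch_params()
  prof <- contractile_profile(twitch = simulate_twitch(p), mass_g = 0.0106,
                              l0_cm = 1.0, muscle = "edl")
  expect_equal(prof$pcsa_cm2, 0.01)
  expect_false(is.na(prof$pt_mN))
  expect_true(is.na(prof$p0_mN))
  expect_true(is.na(prof$fatigue_auc_mNs))
  expect_true(is.na(prof$pct_recovered))
})
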