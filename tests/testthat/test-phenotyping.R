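# Trial summaries, frailty index, percentile marker assignment and the
# High/Low classification rule.

test_that("grip summary trims one maximum and one minimum, with tie handling", {
  expect_equal(grip_trial_summary(c(10, 12, 11, 9, 13)), 11)
  expect_equal(grip_trial_summary(c(5, 5, 5, 5, 5)), 5)
  expect_equal(grip_trial_summary(c(1, 1, 2, 3, 3)), 2)  # one 1 and one 3 removed
  expect_error(grip_trial_summary(c(1, 2, 3)), class = "mf_input_error")
  expect_error(grip_trial_summary(c(1, 2, 3, 4, NA)), class = "mf_input_error")
})

test_that("rotarod summary is the mean of the three trials", {
  expect_equal(rotarod_summary(c(60, 90, 120)), 90)
  expect_equal(rotarod_summary(c(0, 0, 0)), 0)
  expect_equal(rotarod_summary(c(300, 300, 0)), 200)
  expect_error(rotarod_summary(c(10, 20)), class = "mf_input_error")
})

test_that("frailty index is the deficit sum over 28 and rejects invalid sheets", {
  expect_equal(frailty_index(rep(0, 28)), 0)
  expect_equal(frailty_index(rep(1, 28)), 1)
  sheet <- c(rep(1, 7), rep(0.5, 3), rep(0, 18))
  expect_equal(frailty_index(sheet), 8.5 / 28)
  expect_error(frailty_index(c(rep(0, 27), 0.7)), class = "mf_input_error")
  expect_error(frailty_index(rep(0, 27)), class = "mf_input_error")
})

make_phenotypes <- function(n, value_fun = function(i) as.numeric(i)) {
  v <- vapply(seq_len(n), value_fun, numeric(1))
  tibble::tibble(
    mouse_id = sprintf("m%02d", seq_len(n)),
    treadmill_distance_m = v, grip_summary = v, rotarod_summary = v,
    body_weight_g = v, fi_score = seq(0, 0.5, length.out = n)
  )
}

test_that("percentile thresholds interpolate order statistics and flag strictly beyond", {
  ph <- make_phenotypes(10)
  out <- assign_markers(ph)
  thr <- attr(out, "thresholds")
  expect_equal(thr[["grip"]], 2.8)
  expect_equal(thr[["grip"]], oracle_percentile(1:10, 0.2))
  expect_identical(which(out$flag_grip), 1:2)        # values 1 and 2 < 2.8
  expect_equal(thr[["body_weight"]], oracle_percentile(1:10, 0.8))
  expect_identical(which(out$flag_body_weight), 9:10)

  # all-identical criterion: nothing strictly beyond its own percentile
  ph2 <- make_phenotypes(10)
  ph2$grip_summary <- rep(7, 10)
  out2 <- assign_markers(ph2)
  expect_false(any(out2$flag_grip))
})

test_that("classification is High at >= 2 markers and partitions the cohort", {
  expect_equal(as.character(classify_frailty(c(0, 1, 2, 5))),
               c("Low", "Low", "High", "High"))
  expect_error(classify_frailty(c(1, 6)), class = "mf_input_error")
  ph <- make_phenotypes(15, function(i) rnorm(1))
  out <- assign_markers(ph)
  expect_equal(sum(out$frailty_class == "High") + sum(out$frailty_class == "Low"),
               15)
  expect_equal(out$n_markers,
               rowSums(as.matrix(out[grep("^flag_", names(out))])))
})

test_that("marker assignment is invariant to row order and monotone rescaling", {
  set.seed(42)
  for (rep in 1:5) {
    ph <- make_phenotypes(17, function(i) rnorm(1))
    ph$fi_score <- runif(17, 0, 0.5)
    base <- assign_markers(ph)
    # permutation invariance
    perm <- sample(17)
    out_p <- assign_markers(ph[perm, ])
    expect_equal(out_p$n_markers, base$n_markers[perm])
    # strictly monotone rescaling of a criterion preserves flags
    ph2 <- ph
    ph2$grip_summary <- exp(ph2$grip_summary / 10)
    ph2$body_weight_g <- 3 * ph2$body_weight_g + 7
    out_m <- assign_markers(ph2)
    expect_equal(out_m$flag_grip, base$flag_grip)
    expect_equal(out_m$flag_body_weight, base$flag_body_weight)
  }
})

test_that("the count strictly below the 20th percentile matches brute force on tie-free data", {
  set.seed(7)
  for (n in c(5, 10, 23, 47)) {
    x <- rnorm(n)
    th <- percentile_threshold(x, 0.2)
    expect_equal(th, oracle_percentile(x, 0.2))
    n_below <- sum(x < th)
    # rank of the threshold is 1 + (n - 1) * 0.2: strictly-below count is
    # bounded by the floor of that rank
    expect_lte(n_below, floor(1 + (n - 1) * 0.2))
    expect_gte(n_below, floor(1 + (n - 1) * 0.2) - 1)
  }
})

test_that("missing criterion values exclude a mouse from that criterion only", {
  ph <- make_phenotypes(10)
  ph$grip_summary[1] <- NA
  expect_warning(out <- assign_markers(ph), "missing")
  expect_false(out$flag_grip[1])
  expect_true(any(out$flag_treadmill))  # other criteria unaffected
  expect_error(assign_markers(make_phenotypes(1)), class = "mf_input_error")
})

test_that("per-mouse flag counts are Binomial(5, 0.2) under independence", {
  set.seed(123)
  counts <- integer(0)
  for (r in 1:300) {
    z <- matrix(rnorm(47 * 5), nrow = 47)
    counts <- c(counts, rowSums(z > qnorm(0.8)))
  }
  expect_equal(mean(counts), 5 * 0.2, tolerance = 0.02)
  expect_equal(var(counts), 5 * 0.2 * 0.8, tolerance = 0.05)
})
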