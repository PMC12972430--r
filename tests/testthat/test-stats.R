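# Factorial statistics: Type III two-way ANOVA, Sidak adjustment and post
# hoc, percent-change t-tests, repeated-measures recovery analysis.

balanced_2x2 <- function() {
  tibble::tibble(
    frailty_class = rep(c("Low", "High"), each = 4),
    run_group = rep(rep(c("control", "run"), each = 2), 2),
    y = c(1, 3, 1, 3, 1, 3, 5, 7)
  )
}

test_that("balanced 2x2 example decomposes into SS = 8/8/8 with error SS 8 (F = 4.00)", {
  a <- two_way_anova(balanced_2x2(), "y")
  tab <- tidy(a)
  expect_equal(tab$sumsq[tab$term %in% c("frailty", "run", "frailty:run")],
               c(8, 8, 8))
  expect_equal(tab$sumsq[tab$term == "residuals"], 8)
  expect_equal(tab$df[tab$term == "residuals"], 4)
  expect_equal(tab$statistic[tab$term != "residuals"], rep(4, 3),
               tolerance = 1e-12)
  g <- glance(a)
  expect_equal(g$nobs, 8)
})

test_that("identical observations give zero effect sums of squares", {
  d <- balanced_2x2()
  d$y <- 5
  expect_message(a <- two_way_anova(d, "y"), "Zero residual variance")
  tab <- tidy(a)
  expect_equal(tab$sumsq[tab$term != "residuals"], rep(0, 3), tolerance = 1e-20)
  expect_true(all(is.na(tab$statistic[tab$term != "residuals"])))
})

test_that("Type III F statistics match the model-comparison oracle on random unbalanced designs", {
  set.seed(20)
  for (r in 1:30) {
    n <- sample(c(19, 16, 7, 5))
    d <- tibble::tibble(
      frailty_class = rep(c("Low", "Low", "High", "High"), n),
      run_group = rep(c("control", "run", "control", "run"), n),
      y = rnorm(sum(n), mean = rnorm(4)[as.integer(factor(
        paste(rep(c("L", "L", "H", "H"), n), rep(c("c", "r", "c", "r"), n))))])
    )
    a <- tidy(two_way_anova(d, "y"))
    ora <- oracle_type3_F(d$frailty_class, d$run_group, d$y)
    expect_equal(sort(a$statistic[a$term != "residuals"]), sort(ora$F),
                 tolerance = 1e-8)
  }
})

test_that("empty cells raise an inestimability error naming the cell", {
  d <- balanced_2x2()
  d <- d[!(d$frailty_class == "High" & d$run_group == "run"), ]
  expect_error(two_way_anova(d, "y"), "High x run", class = "mf_design_error")
})

test_that("Sidak adjustment follows 1 - (1 - p)^m and is monotone", {
  expect_equal(sidak_adjust(0.01, 4), 1 - 0.99^4, tolerance = 1e-13)
  expect_equal(sidak_adjust(0, 10), 0)
  expect_equal(sidak_adjust(0.2, 1), 0.2)
  grid_p <- c(0, 1e-10, 1e-4, 0.01, 0.05, 0.3, 0.9, 1)
  for (m in c(1, 2, 4, 10)) {
    adj <- sidak_adjust(grid_p, m)
    expect_equal(adj, 1 - (1 - grid_p)^m, tolerance = 1e-14)
    expect_true(all(adj >= grid_p - 1e-15) && all(adj <= 1))
    expect_true(all(diff(adj) >= 0))
  }
  expect_true(all(sidak_adjust(grid_p, 4) >= sidak_adjust(grid_p, 2)))
})

test_that("Sidak post hoc gates on the interaction and uses the pooled residual error", {
  d <- balanced_2x2()
  a <- two_way_anova(d, "y")
  expect_equal(nrow(sidak_posthoc(a, gate = 0.05)), 0)  # p_int = 0.116
  ph <- sidak_posthoc(a, gate = NULL)
  expect_equal(nrow(ph), 2)
  expect_equal(ph$m, c(2, 2))
  # mse = 2, n = 2 per cell: se = sqrt(2 * (1/2 + 1/2)) = sqrt(2)
  expect_equal(ph$std.error, rep(sqrt(2), 2))
  expect_equal(ph$adj.p.value, sidak_adjust(ph$p.value, 2))
  ph4 <- sidak_posthoc(a, family = "all_cells", gate = NULL)
  expect_equal(nrow(ph4), 6)
  expect_equal(unique(ph4$m), 6)
})

test_that("percent-change t-test reproduces the pooled-variance hand computation", {
  # Low percent changes {-5, 0, 5}; High {-25, -20, -15}
  d <- tibble::tibble(
    frailty_class = rep(c("Low", "High"), each = 4),
    run_group = rep(c("control", "run", "run", "run"), 2),
    y = c(10, 9.5, 10, 10.5, 10, 7.5, 8, 8.5)
  )
  pc <- percent_change_test(d, "y")
  expect_equal(sort(pc$percent_changes$percent_change),
               sort(c(-5, 0, 5, -25, -20, -15)))
  ora <- oracle_pooled_t(c(-5, 0, 5), c(-25, -20, -15))
  expect_equal(pc$statistic, ora$t, tolerance = 1e-12)
  expect_equal(pc$df, 4)
  expect_equal(pc$p.value, ora$p, tolerance = 1e-12)
  expect_equal(pc$statistic, 4.899, tolerance = 1e-3)

  # run value equal to its control mean is exactly 0 percent change
  expect_true(0 %in% pc$percent_changes$percent_change)

  d0 <- d; d0$y[d0$frailty_class == "High" & d0$run_group == "control"] <- 0
  expect_error(percent_change_test(d0, "y"), class = "mf_design_error")
  d1 <- d[-(7:8), ]
  expect_error(percent_change_test(d1, "y"), class = "mf_design_error")
})

test_that("percent-change and interaction tests agree on the sign of the run-effect difference", {
  set.seed(31)
  for (r in 1:10) {
    base <- null_study_table()
    eff <- rnorm(1, 0, 2)
    mu <- 10 + ifelse(base$run_group == "run", 1, 0) +
      ifelse(base$frailty_class == "High" & base$run_group == "run", eff, 0)
    base$y <- rnorm(47, mu, 0.5)
    a <- two_way_anova(base, "y")
    pc <- percent_change_test(base, "y")
    cm <- tapply(base$y, list(base$frailty_class, base$run_group), mean)
    run_diff_low <- cm["Low", "run"] - cm["Low", "control"]
    run_diff_high <- cm["High", "run"] - cm["High", "control"]
    # estimate = mean Low pc - mean High pc; positive when the run effect is
    # weaker (or more negative) in the High stratum
    expect_equal(sign(pc$estimate),
                 sign(run_diff_low / cm["Low", "control"] -
                        run_diff_high / cm["High", "control"]))
  }
})

test_that("Type III equals sequential sums of squares on balanced designs", {
  set.seed(77)
  for (r in 1:5) {
    d <- tibble::tibble(
      frailty_class = rep(c("Low", "High"), each = 10),
      run_group = rep(rep(c("control", "run"), each = 5), 2),
      y = rnorm(20)
    )
    t3 <- tidy(two_way_anova(d, "y"))
    seqtab <- anova(lm(y ~ frailty_class * run_group, data = d))
    expect_equal(t3$sumsq[t3$term != "residuals"],
                 unname(seqtab$`Sum Sq`[1:3]), tolerance = 1e-10)
  }
})

test_that("recovery three-way gates correctly and localizes an injected first-contraction effect", {
  make_long <- function(effect1 = 0, seed = 1) {
    set.seed(seed)
    base <- null_study_table()
    long <- tidyr::expand_grid(base, contraction = 1:6)
    mu <- exp(-long$contraction / 3)
    hit <- long$frailty_class == "High" & long$run_group == "run" &
      long$contraction == 1
    long$rate <- rnorm(nrow(long), mu + ifelse(hit, effect1, 0), 0.05)
    long
  }
  # null: gate not triggered -> no stratified output
  r0 <- recovery_three_way(make_long(0, seed = 4))
  if (r0$three_way$p.value[r0$three_way$term == "contraction:frailty:run"] >= 0.05) {
    expect_null(r0$stratified)
  }
  # strong effect at contraction 1 in High-Run only
  r1 <- recovery_three_way(make_long(-0.4, seed = 5))
  p3 <- r1$three_way$p.value[r1$three_way$term == "contraction:frailty:run"]
  expect_lt(p3, 0.05)
  expect_false(is.null(r1$stratified))
  expect_true("High" %in% names(r1$posthoc))
  ph_high <- r1$posthoc$High
  sig <- ph_high$contraction[which(ph_high$adj.p.value < 0.05)]
  expect_true("1" %in% sig)
  # the Low stratum should not produce a per-contraction post hoc
  expect_false("Low" %in% names(r1$posthoc))
  # mice with incomplete series are excluded with a warning
  long_inc <- make_long(-0.4, seed = 5)
  long_inc <- long_inc[-1, ]
  expect_warning(recovery_three_way(long_inc), "incomplete")
})

test_that("run_full_analysis assembles a complete, deterministic report", {
  cfg <- sim_config(n_mice = 18, seed = 21)
  co <- simulate_cohort(cfg)
  ph <- phenotype_cohort(co)
  met <- simulate_study_metrics(co, cfg, mode = "envelope")
  rep1 <- run_full_analysis(ph, met)
  rep2 <- run_full_analysis(ph, met)
  expect_identical(lapply(rep1$outcomes, function(m) lapply(m, function(b) b$anova$table)),
                   lapply(rep2$outcomes, function(m) lapply(m, function(b) b$anova$table)))
  # one block per analyzable outcome per muscle
  expect_true(all(c("edl", "soleus") %in% names(rep1$outcomes)))
  expect_true(all(c("fatigue_auc_mNs", "hrt_s", "pct_recovered") %in%
                    names(rep1$outcomes$edl)))
  # empty metrics: phenotyping-only report
  rep0 <- run_full_analysis(ph, tibble::tibble())
  expect_false(rep0$has_contractility)
  expect_output(print(rep0), "No contractility data")
})
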