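# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Closed-form peak of the biexponential twitch kernel.
oracle_twitch_peak <- function(A, tc, tr) {
  tp <- tc * tr / (tr - tc) * log(tr / tc)
  list(t = tp, f = A * (exp(-tp / tr) - exp(-tp / tc)))
}

# Brute-force interpolated percentile at rank 1 + (n - 1) p.
oracle_percentile <- function(x, p) {
  s <- sort(x)
  h <- 1 + (length(s) - 1) * p
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Type III F statistics for a 2x2 factorial by explicit model comparison
# (RSS drop) on sum-to-zero coded design matrices; independent of car.
oracle_type3_F <- function(f, r, y) {
  a <- ifelse(f == levels(factor(f))[1], 1, -1)
  b <- ifelse(r == levels(factor(r))[1], 1, -1)
  X <- cbind(1, a, b, a * b)
  rss <- function(Xm) sum(lsfit(Xm, y, intercept = FALSE)$residuals^2)
  rss_full <- rss(X)
  df_res <- length(y) - ncol(X)
  mse <- rss_full / df_res
  ss <- vapply(2:4, function(j) rss(X[, -j, drop = FALSE]) - rss_full,
               numeric(1))
  list(F = ss / mse, ss = ss, mse = mse, df_res = df_res)
}

# Equal-variance two-sample t statistic.
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2,
       p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# A null analysis table at the study's unbalanced group sizes
# (Low-Control 19, Low-Run 16, High-Control 7, High-Run 5).
null_study_table <- function() {
  tibble::tibble(
    mouse_id = sprintf("m%02d", 1:47),
    frailty_class = rep(c("Low", "High"), c(35, 12)),
    run_group = c(rep(c("control", "run"), c(19, 16)),
                  rep(c("control", "run"), c(7, 5)))
  )
}
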