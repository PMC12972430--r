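#' Plot a force-time trace
#'
#' @param object A [force_trace()].
#' @param downsample Plot at most this many points (long protocol traces
#'   are thinned for display only).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.force_trace <- function(object, downsample = 20000L, ...) {
  d <- object$data
  if (nrow(d) > downsample) {
    d <- d[seq(1L, nrow(d), length.out = downsample), ]
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$force_mN)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "force (mN)",
                  title = sprintf("%s %s trace",
                                  object$muscle %||% "", object$protocol %||% "")) +
    ggplot2::theme_minimal()
}

#' Marker grid of a phenotyped cohort
#'
#' One column per mouse, one row per frailty criterion; flagged cells are
#' filled. Mice are ordered by marker count, mirroring the usual
#' group-allocation heat map.
#'
#' @param phenotypes Tibble from [phenotype_cohort()].
#' @return A ggplot object.
#' @export
plot_marker_grid <- function(phenotypes) {
  flag_cols <- grep("^flag_", names(phenotypes), value = TRUE)
  long <- tidyr::pivot_longer(
    dplyr::select(phenotypes, "mouse_id", "n_markers", "frailty_class",
                  dplyr::all_of(flag_cols)),
    cols = dplyr::all_of(flag_cols), names_to = "criterion",
    values_to = "flagged")
  long$criterion <- sub("^flag_", "", long$criterion)
  ord <- phenotypes$mouse_id[order(-phenotypes$n_markers)]
  long$mouse_id <- factor(long$mouse_id, levels = ord)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mouse_id, y = .data$criterion,
                                     fill = .data$flagged)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey95", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "mouse (sorted by marker count)", y = NULL,
                  fill = "positive marker") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Force-frequency curve
#'
#' @param ff Tibble from [force_frequency()] (columns `freq_hz`, `peak_mN`).
#' @return A ggplot object.
#' @export
plot_force_frequency <- function(ff) {
  ggplot2::ggplot(ff, ggplot2::aes(x = .data$freq_hz, y = .data$peak_mN)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "stimulation frequency (Hz)", y = "peak force (mN)") +
    ggplot2::theme_minimal()
}

#' Mean instantaneous recovery rates by condition
#'
#' @param long Long recovery-rate table from [recovery_rates_long()].
#' @return A ggplot object.
#' @export
plot_recovery_rates <- function(long) {
  sm <- dplyr::summarise(
    dplyr::group_by(long, .data$contraction, .data$frailty_class,
                    .data$run_group),
    rate = mean(.data$rate, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$contraction, y = .data$rate,
                                   color = .data$run_group)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~frailty_class) +
    ggplot2::labs(x = "contraction index", y = "recovery rate (mN/s)",
                  color = "group") +
    ggplot2::theme_minimal()
}

#' Power curve for the Frailty x Run interaction under graded effect sizes
#'
#' Monte-Carlo power of the two-way interaction test on a contractile
#' outcome as the high-frailty running effect multiplier grows. For each
#' multiplier `e`, the high-frailty running condition's fatigue decay
#' constant is divided by `e` and its recovery time constant multiplied by
#' `e` (so `e = 1` is the null and `e = 2` the default study effect);
#' cohorts are simulated through the envelope path and analyzed with
#' [two_way_anova()].
#'
#' @param multipliers Effect multipliers to scan.
#' @param n_reps Replicate cohorts per multiplier.
#' @param n_mice Cohort size.
#' @param outcomes Outcomes tested on the same simulated cohorts (default
#'   fatigue AUC and the initial recovery rate).
#' @param alpha Significance threshold.
#' @param seed Integer seed.
#' @return A tibble: `multiplier`, `outcome`, `n_reps`, `power`.
#' @export
power_curve <- function(multipliers = c(1, 1.5, 2), n_reps = 60L,
                        n_mice = 47L,
                        outcomes = c("fatigue_auc_mNs", "initial_rate_mN_s"),
                        alpha = 0.05, seed = 1L) {
  rows <- lapply(seq_along(multipliers), function(k) {
    e <- multipliers[k]
    es <- default_effect_sizes()
    es$high_run$kappa <- 1 / e
    es$high_run$recovery_tau <- e
    hits <- setNames(integer(length(outcomes)), outcomes)
    valid <- setNames(integer(length(outcomes)), outcomes)
    for (r in seq_len(n_reps)) {
      cfg <- sim_config(n_mice = n_mice,
                        seed = stream_seed(seed, 20L, k, r),
                        effect_sizes = es)
      cohort <- simulate_cohort(cfg)
      met <- simulate_study_metrics(cohort, cfg, mode = "envelope",
                                    muscles = "edl")
      for (oc in outcomes) {
        res <- tryCatch(two_way_anova(met, oc), error = function(e2) NULL)
        if (is.null(res)) next
        valid[[oc]] <- valid[[oc]] + 1L
        p <- res$table$p.value[res$table$term == "frailty:run"]
        if (is.finite(p) && p < alpha) hits[[oc]] <- hits[[oc]] + 1L
      }
    }
    tibble::tibble(multiplier = e, outcome = outcomes,
                   n_reps = unname(valid),
                   power = unname(hits) / pmax(unname(valid), 1L))
  })
  dplyr::bind_rows(rows)
}
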