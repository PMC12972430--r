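#' Summarize five grip-strength trials
#'
#' Removes exactly one instance of the maximum and one of the minimum (even
#' when duplicated) and returns the mean of the three remaining trials.
#'
#' @param trials Numeric vector of exactly 5 finite, nonnegative grip forces
#'   (gf).
#' @return The trimmed mean (gf).
#' @export
#' @examples
#' grip_trial_summary(c(10, 12, 11, 9, 13))  # 11
grip_trial_summary <- function(trials) {
  if (length(trials) != 5L || any(!is.finite(trials)) || any(trials < 0)) {
    abort("`trials` must be exactly 5 finite nonnegative grip forces.",
          class = "mf_input_error")
  }
  s <- sort(trials)
  mean(s[2:4])
}

#' Summarize three rotarod trials
#'
#' @param trials Numeric vector of exactly 3 finite, nonnegative latencies
#'   to fall (s).
#' @return The arithmetic mean latency (s).
#' @export
rotarod_summary <- function(trials) {
  if (length(trials) != 3L || any(!is.finite(trials)) || any(trials < 0)) {
    abort("`trials` must be exactly 3 finite nonnegative latencies.",
          class = "mf_input_error")
  }
  mean(trials)
}

#' Deficit-accumulation frailty index
#'
#' The frailty index is the sum of the 28 deficit item scores divided by 28.
#' Each item is scored 0 (no deficit), 0.5 (mild), or 1 (severe).
#'
#' @param sheet Numeric vector of exactly 28 item scores in `{0, 0.5, 1}`.
#' @return The frailty index, a fraction in `[0, 1]`.
#' @export
frailty_index <- function(sheet) {
  if (length(sheet) != 28L || any(is.na(sheet))) {
    abort("Deficit sheet must contain exactly 28 non-missing item scores.",
          class = "mf_input_error")
  }
  bad <- !sheet %in% c(0, 0.5, 1)
  if (any(bad)) {
    abort(paste0("Deficit scores outside {0, 0.5, 1} at item(s): ",
                 paste(which(bad), collapse = ", ")),
          class = "mf_input_error")
  }
  sum(sheet) / 28
}

#' Number of fi_item columns expected in a cohort table
#' @keywords internal
fi_item_cols <- function() sprintf("fi_item_%02d", 1:28)

#' Summarize raw phenotyping trials for a cohort
#'
#' Adds `grip_summary` (trimmed mean of the 5 grip trials),
#' `rotarod_summary` (mean of the 3 rotarod trials), and `fi_score`
#' (28-item deficit-accumulation frailty index) to a cohort table.
#'
#' @param cohort A cohort tibble in the [read_cohort()] schema.
#' @return A tibble with one row per mouse: `mouse_id`, `run_group`,
#'   `body_weight_g`, `treadmill_distance_m`, `grip_summary`,
#'   `rotarod_summary`, `fi_score`.
#' @export
summarize_phenotypes <- function(cohort) {
  grip_mat <- as.matrix(cohort[sprintf("grip_trial_%d", 1:5)])
  rot_mat <- as.matrix(cohort[sprintf("rotarod_trial_%d", 1:3)])
  fi_mat <- as.matrix(cohort[fi_item_cols()])
  tibble::tibble(
    mouse_id = cohort$mouse_id,
    run_group = cohort$run_group,
    body_weight_g = cohort$body_weight_g,
    treadmill_distance_m = cohort$treadmill_distance_m,
    grip_summary = apply(grip_mat, 1L, grip_trial_summary),
    rotarod_summary = apply(rot_mat, 1L, rotarod_summary),
    fi_score = apply(fi_mat, 1L, frailty_index)
  )
}

#' Cohort percentile threshold (linear interpolation between order statistics)
#'
#' The threshold at probability `p` is computed at rank `1 + (n - 1) * p`
#' with linear interpolation between the bracketing order statistics
#' (quantile type 7, the convention used throughout the package).
#'
#' @param x Numeric values (NAs dropped).
#' @param p Probability in `[0, 1]`.
#' @return The interpolated percentile.
#' @export
percentile_threshold <- function(x, p) {
  unname(quantile(x, probs = p, type = 7, na.rm = TRUE, names = FALSE))
}

#' Assign positive frailty markers by cohort percentiles
#'
#' A mouse receives a positive marker on a criterion when it falls strictly
#' below the cohort's 20th percentile for the physical performance tests
#' (treadmill distance, grip strength, rotarod latency) or strictly above
#' the 80th percentile for body weight or frailty index. Thresholds are
#' computed on the full cohort (including the mouse itself) by linear
#' interpolation between order statistics at rank `1 + (n - 1) p`; values
#' exactly equal to a threshold are not flagged, and tied values share a
#' fate. A missing criterion value excludes the mouse from that criterion's
#' percentile pool and cannot be flagged on it (a warning is issued).
#'
#' Alternatively, fixed `thresholds` may be supplied (e.g. theoretical
#' quantiles of a known generating distribution) instead of cohort
#' percentiles.
#'
#' @param phenotypes A tibble from [summarize_phenotypes()] (columns
#'   `mouse_id`, `treadmill_distance_m`, `grip_summary`, `rotarod_summary`,
#'   `body_weight_g`, `fi_score`).
#' @param rate Adverse-tail fraction (default 0.2: 20th/80th percentiles).
#' @param thresholds Optional named list/vector of fixed thresholds over
#'   `c("treadmill", "grip", "rotarod", "body_weight", "fi")`; overrides the
#'   cohort percentiles.
#' @return The input tibble with logical flag columns `flag_treadmill`,
#'   `flag_grip`, `flag_rotarod`, `flag_body_weight`, `flag_fi`, plus
#'   `n_markers` and `frailty_class` (`"Low"`/`"High"`). The thresholds used
#'   are attached as attribute `"thresholds"`.
#' @export
assign_markers <- function(phenotypes, rate = 0.2, thresholds = NULL) {
  cols <- c(treadmill = "treadmill_distance_m", grip = "grip_summary",
            rotarod = "rotarod_summary", body_weight = "body_weight_g",
            fi = "fi_score")
  missing_cols <- setdiff(unname(cols), names(phenotypes))
  if (length(missing_cols)) {
    abort(paste0("Missing phenotype columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "mf_input_error")
  }
  n <- nrow(phenotypes)
  if (is.null(thresholds) && n < 2L) {
    abort("Cohort percentile thresholds require at least 2 mice.",
          class = "mf_input_error")
  }
  lower_is_adverse <- c(treadmill = TRUE, grip = TRUE, rotarod = TRUE,
                        body_weight = FALSE, fi = FALSE)
  thr <- numeric(0)
  out <- phenotypes
  for (crit in names(cols)) {
    x <- phenotypes[[cols[[crit]]]]
    if (anyNA(x)) {
      warn(sprintf(
        "%d mice missing `%s`; excluded from that criterion's percentile pool and never flagged on it.",
        sum(is.na(x)), cols[[crit]]))
    }
    th <- if (!is.null(thresholds)) {
      thresholds[[crit]] %||%
        abort(sprintf("`thresholds` lacks criterion '%s'.", crit),
              class = "mf_input_error")
    } else if (lower_is_adverse[[crit]]) {
      percentile_threshold(x, rate)
    } else {
      percentile_threshold(x, 1 - rate)
    }
    flag <- if (lower_is_adverse[[crit]]) x < th else x > th
    flag[is.na(flag)] <- FALSE
    out[[paste0("flag_", crit)]] <- flag
    thr[[crit]] <- th
  }
  flag_cols <- paste0("flag_", names(cols))
  out$n_markers <- as.integer(rowSums(as.matrix(out[flag_cols])))
  out$frailty_class <- classify_frailty(out$n_markers)
  attr(out, "thresholds") <- thr
  out
}

#' Classify frailty from the positive-marker count
#'
#' Mice with 2 or more positive frailty markers are classified `"High"`;
#' mice with at most 1 marker are `"Low"`. The result is a factor with
#' levels `c("Low", "High")`, so every mouse receives exactly one class.
#'
#' @param n_markers Integer vector of marker counts in `0..5`.
#' @param min_markers Minimum marker count for the High class (default 2).
#' @return Factor with levels `"Low"`, `"High"`.
#' @export
classify_frailty <- function(n_markers, min_markers = 2L) {
  if (any(is.na(n_markers)) || any(n_markers < 0 | n_markers > 5)) {
    abort("`n_markers` must lie in 0..5.", class = "mf_input_error")
  }
  factor(ifelse(n_markers >= min_markers, "High", "Low"),
         levels = c("Low", "High"))
}

#' Full frailty phenotyping of a cohort table
#'
#' Convenience wrapper: [summarize_phenotypes()] then [assign_markers()].
#'
#' @inheritParams summarize_phenotypes
#' @inheritParams assign_markers
#' @return The phenotype tibble with summaries, flags, `n_markers`, and
#'   `frailty_class`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_mice = 12, seed = 7))
#' phenotype_cohort(cohort)
phenotype_cohort <- function(cohort, rate = 0.2, thresholds = NULL) {
  assign_markers(summarize_phenotypes(cohort), rate = rate,
                 thresholds = thresholds)
}
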