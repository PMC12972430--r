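#' Run manifest for reproducibility accounting
#'
#' Captures the seed, a configuration snapshot, the package version, and
#' optional input-file MD5 digests. The manifest is embedded in every study
#' report. Wall-clock stage timings are logged to standard error by the
#' command-line driver but never written into artifacts, so reruns under the
#' same seed are byte-identical.
#'
#' @param config A [sim_config()] or arbitrary named list snapshot.
#' @param inputs Character vector of input file paths to digest.
#' @return A list of class `mf_manifest`.
#' @export
run_manifest <- function(config = NULL, inputs = character(0)) {
  digests <- if (length(inputs)) {
    d <- tools::md5sum(inputs)
    setNames(unname(d), basename(names(d)))
  } else NULL
  structure(
    list(seed = config$seed %||% NA_integer_,
         config = unclass_deep(config),
         package_version = as.character(packageVersion("musclefrailty")),
         input_digests = digests),
    class = "mf_manifest"
  )
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

default_outcomes <- function() {
  c("mass_g", "pt_mN", "rfd_mN_s", "hrt_s", "p0_mN", "sp0_N_cm2",
    "fatigue_auc_mNs", "initial_rate_mN_s", "pct_recovered")
}

#' Full statistical analysis of a phenotyped, profiled study
#'
#' For every contractile outcome and muscle: an unbalanced two-way
#' Frailty x Run ANOVA (Type III), a Sidak post hoc gated on a significant
#' interaction, and the percent-change t-test between frailty strata. The
#' instantaneous recovery-rate series is analyzed per muscle with the
#' repeated-measures three-way ANOVA and its frailty-stratified follow-up.
#' Analyses that cannot be estimated on the available data (empty cells,
#' too few running mice) are recorded as skipped with the error message
#' rather than aborting the report.
#'
#' @param phenotypes Phenotype tibble from [phenotype_cohort()] (must carry
#'   `mouse_id`, `frailty_class`, `run_group`).
#' @param metrics Contractile metrics tibble with one row per
#'   mouse x muscle (e.g. from [simulate_study_metrics()]); may be empty.
#' @param outcomes Outcome columns to analyze; defaults to the intersection
#'   of the standard contractile outcomes with `names(metrics)`.
#' @param gate Interaction p-value gate for post hoc and stratified
#'   analyses.
#' @param manifest Optional [run_manifest()].
#' @return An object of class `mf_report`: list with `groups` (frailty x run
#'   counts), `outcomes` (nested list per muscle then outcome: `anova`,
#'   `posthoc`, `percent_change`, or `skipped` diagnostics), `recovery`
#'   (per muscle `mf_recovery_anova`), `missingness`, `join_failures`,
#'   `gate`, `manifest`, and `has_contractility`.
#' @export
run_full_analysis <- function(phenotypes, metrics, outcomes = NULL,
                              gate = 0.05, manifest = NULL) {
  groups <- if (nrow(phenotypes) && "frailty_class" %in% names(phenotypes)) {
    as.data.frame(table(frailty = phenotypes$frailty_class,
                        run = phenotypes$run_group))
  } else {
    data.frame()
  }
  has_contr <- !is.null(metrics) && nrow(metrics) > 0L
  join_failures <- character(0)
  out_list <- list()
  rec_list <- list()
  miss <- tibble::tibble()
  if (has_contr) {
    metrics <- tibble::as_tibble(metrics)
    join_failures <- setdiff(metrics$mouse_id, phenotypes$mouse_id)
    if (length(join_failures)) {
      warn(paste0("Metrics rows without phenotype record: ",
                  paste(unique(join_failures), collapse = ", ")))
    }
    if (!all(c("frailty_class", "run_group") %in% names(metrics))) {
      metrics <- dplyr::left_join(
        metrics,
        dplyr::select(phenotypes, "mouse_id", "frailty_class", "run_group"),
        by = "mouse_id")
    }
    outcomes <- outcomes %||% intersect(default_outcomes(), names(metrics))
    for (m in unique(metrics$muscle)) {
      dm <- metrics[metrics$muscle == m, , drop = FALSE]
      out_list[[m]] <- list()
      for (oc in outcomes) {
        blk <- list(outcome = oc, n = sum(is.finite(dm[[oc]])))
        blk$anova <- tryCatch(two_way_anova(dm, oc), error = function(e) e)
        if (inherits(blk$anova, "error")) {
          blk <- list(outcome = oc, skipped = conditionMessage(blk$anova))
        } else {
          blk$posthoc <- sidak_posthoc(blk$anova, gate = gate)
          blk$percent_change <- tryCatch(
            percent_change_test(dm, oc),
            error = function(e) conditionMessage(e))
        }
        out_list[[m]][[oc]] <- blk
        miss <- dplyr::bind_rows(miss, tibble::tibble(
          muscle = m, outcome = oc, n = nrow(dm),
          n_missing = sum(!is.finite(dm[[oc]]))))
      }
      if ("recovery_rate_series" %in% names(dm)) {
        long <- recovery_rates_long(dm)
        rec_list[[m]] <- tryCatch(
          recovery_three_way(long, gate = gate),
          error = function(e) conditionMessage(e))
      }
    }
  }
  structure(
    list(groups = groups, outcomes = out_list, recovery = rec_list,
         missingness = miss, join_failures = join_failures, gate = gate,
         manifest = manifest, has_contractility = has_contr),
    class = "mf_report"
  )
}

#' Unnest per-mouse recovery rate series into a long table
#'
#' @param metrics Metrics tibble with list-column `recovery_rate_series`.
#' @return Long tibble: `mouse_id`, `muscle`, `frailty_class`, `run_group`,
#'   `contraction` (integer index, 1 = initial rate), `rate`.
#' @export
recovery_rates_long <- function(metrics) {
  rows <- lapply(seq_len(nrow(metrics)), function(i) {
    r <- metrics$recovery_rate_series[[i]]
    if (is.null(r) || !length(r)) return(NULL)
    tibble::tibble(mouse_id = metrics$mouse_id[i], muscle = metrics$muscle[i],
                   frailty_class = metrics$frailty_class[i],
                   run_group = metrics$run_group[i],
                   contraction = seq_along(r), rate = r)
  })
  dplyr::bind_rows(rows)
}

#' @export
print.mf_report <- function(x, ...) {
  cat("== Frailty x Run study report ==\n")
  if (nrow(x$groups)) {
    cat("Group sizes:\n")
    print(x$groups, row.names = FALSE)
  }
  if (!x$has_contractility) {
    cat("No contractility data: phenotyping section only.\n")
    return(invisible(x))
  }
  for (m in names(x$outcomes)) {
    cat(sprintf("\n-- muscle: %s --\n", m))
    for (oc in names(x$outcomes[[m]])) {
      blk <- x$outcomes[[m]][[oc]]
      if (!is.null(blk$skipped)) {
        cat(sprintf("  %s: skipped (%s)\n", oc, blk$skipped))
        next
      }
      pint <- blk$anova$table$p.value[blk$anova$table$term == "frailty:run"]
      pcp <- if (is.character(blk$percent_change)) NA_real_ else blk$percent_change$p.value
      cat(sprintf("  %-20s interaction p = %-8.4g pct-change p = %-8.4g\n",
                  oc, pint, pcp))
    }
    if (!is.null(x$recovery[[m]]) && inherits(x$recovery[[m]], "mf_recovery_anova")) {
      r <- x$recovery[[m]]
      p3 <- r$three_way$p.value[r$three_way$term == "contraction:frailty:run"]
      cat(sprintf("  recovery 3-way interaction p = %.4g (%s)\n", p3,
                  if (is.null(r$stratified)) "no follow-up" else "stratified follow-up run"))
    }
  }
  invisible(x)
}

report_block_list <- function(blk) {
  if (!is.null(blk$skipped)) return(list(outcome = blk$outcome, skipped = blk$skipped))
  list(
    outcome = blk$outcome, n = blk$n,
    anova = as.list(tidy(blk$anova)),
    posthoc = as.list(blk$posthoc),
    percent_change = if (is.character(blk$percent_change)) {
      list(skipped = blk$percent_change)
    } else {
      as.list(tidy(blk$percent_change))
    }
  )
}

#' Write a study report as a machine-readable JSON document
#'
#' @param report An [run_full_analysis()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  body <- list(
    manifest = unclass_deep(report$manifest),
    gate = report$gate,
    groups = report$groups,
    has_contractility = report$has_contractility,
    outcomes = lapply(report$outcomes, function(mus) {
      lapply(mus, report_block_list)
    }),
    recovery = lapply(report$recovery, function(r) {
      if (is.character(r)) return(list(skipped = r))
      list(three_way = as.list(r$three_way),
           stratified = lapply(r$stratified %||% list(), as.list),
           posthoc = lapply(r$posthoc %||% list(), as.list),
           excluded = r$excluded)
    }),
    missingness = as.list(report$missingness),
    join_failures = report$join_failures
  )
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Write a human-readable markdown summary of a study report
#'
#' @inheritParams write_report_json
#' @export
report_markdown <- function(report, path) {
  lines <- c("# Frailty x Run study report", "")
  if (!is.null(report$manifest)) {
    lines <- c(lines, sprintf("Seed: %s | package %s", report$manifest$seed,
                              report$manifest$package_version), "")
  }
  if (nrow(report$groups)) {
    lines <- c(lines, "## Group sizes", "",
               "| Frailty | Run | n |", "|---|---|---|",
               sprintf("| %s | %s | %d |", report$groups$frailty,
                       report$groups$run, report$groups$Freq), "")
  }
  if (!report$has_contractility) {
    lines <- c(lines, "No contractility data: phenotyping section only.")
  } else {
    for (m in names(report$outcomes)) {
      lines <- c(lines, sprintf("## Muscle: %s", m), "",
                 "| outcome | frailty p | run p | interaction p | pct-change p |",
                 "|---|---|---|---|---|")
      for (oc in names(report$outcomes[[m]])) {
        blk <- report$outcomes[[m]][[oc]]
        if (!is.null(blk$skipped)) {
          lines <- c(lines, sprintf("| %s | skipped: %s | | | |", oc, blk$skipped))
          next
        }
        tb <- blk$anova$table
        gp <- function(tm) tb$p.value[tb$term == tm]
        pcp <- if (is.character(blk$percent_change)) NA else blk$percent_change$p.value
        lines <- c(lines, sprintf("| %s | %.4g | %.4g | %.4g | %.4g |", oc,
                                  gp("frailty"), gp("run"), gp("frailty:run"), pcp))
      }
      lines <- c(lines, "")
      r <- report$recovery[[m]]
      if (!is.null(r) && inherits(r, "mf_recovery_anova")) {
        p3 <- r$three_way$p.value[r$three_way$term == "contraction:frailty:run"]
        lines <- c(lines, sprintf(
          "Recovery three-way interaction p = %.4g; %s.", p3,
          if (is.null(r$stratified)) "no stratified follow-up"
          else paste("stratified follow-up:",
                     paste(names(r$stratified), collapse = ", "))), "")
      }
    }
  }
  lines <- c(lines, sprintf("Interaction gate threshold: %.3g", report$gate))
  writeLines(lines, path)
  invisible(path)
}
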