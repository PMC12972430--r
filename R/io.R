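# CSV formats for cohorts, deficit sheets, force traces and stimulation
# events. Validation collects every violation before failing, so malformed
# inputs surface in one pass. Numeric columns are serialized at full double
# precision (readr's default, >= 15 significant digits).

#' Write a cohort table to CSV
#'
#' Columns are written in the canonical schema order: `mouse_id`,
#' `run_group`, `body_weight_g`, `treadmill_distance_m`, `grip_trial_1..5`,
#' `rotarod_trial_1..3`, `fi_item_01..28`.
#'
#' @param cohort Cohort tibble.
#' @param path Output CSV path (gzip transparent via the `.gz` suffix).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  missing_cols <- setdiff(cohort_schema_cols(), names(cohort))
  if (length(missing_cols)) {
    abort(paste0("Cohort lacks columns: ", paste(missing_cols, collapse = ", ")),
          class = "mf_format_error")
  }
  readr::write_csv(cohort[cohort_schema_cols()], path)
  invisible(path)
}

#' Read and validate a cohort table
#'
#' All violations are collected and reported together: missing or extra
#' columns, duplicate mouse ids, deficit-item scores outside `{0, 0.5, 1}`
#' (reported with row and column), non-finite numeric values, and invalid
#' run-group labels. An empty file with a valid header yields an empty
#' cohort without error.
#'
#' @param path CSV path.
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Cohort file not found: %s", path), class = "mf_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  problems <- character(0)
  missing_cols <- setdiff(cohort_schema_cols(), names(df))
  if (length(missing_cols)) {
    problems <- c(problems, paste0("missing column(s): ",
                                   paste(missing_cols, collapse = ", ")))
  }
  if ("mouse_id" %in% names(df) && anyDuplicated(df$mouse_id)) {
    dups <- unique(df$mouse_id[duplicated(df$mouse_id)])
    problems <- c(problems, paste0("duplicate mouse_id: ",
                                   paste(dups, collapse = ", ")))
  }
  if ("run_group" %in% names(df)) {
    bad <- which(!df$run_group %in% c("control", "run"))
    if (length(bad)) {
      problems <- c(problems, paste0(
        "invalid run_group (must be 'control' or 'run') at row(s): ",
        paste(bad, collapse = ", ")))
    }
  }
  for (cl in intersect(fi_item_cols(), names(df))) {
    bad <- which(!df[[cl]] %in% c(0, 0.5, 1))
    if (length(bad)) {
      problems <- c(problems, sprintf(
        "deficit score outside {0, 0.5, 1} in column %s at row(s): %s",
        cl, paste(bad, collapse = ", ")))
    }
  }
  num_cols <- setdiff(intersect(cohort_schema_cols(), names(df)),
                      c("mouse_id", "run_group"))
  for (cl in num_cols) {
    bad <- which(!is.finite(df[[cl]]))
    if (length(bad)) {
      problems <- c(problems, sprintf(
        "non-finite value in column %s at row(s): %s",
        cl, paste(bad, collapse = ", ")))
    }
  }
  if (length(problems)) {
    abort(paste0("Invalid cohort file '", path, "':\n  - ",
                 paste(problems, collapse = "\n  - ")),
          class = "mf_validation_error")
  }
  tibble::as_tibble(df)[cohort_schema_cols()]
}

trace_meta_keys <- function() c("muscle", "mass_g", "l0_cm", "sampling_hz", "protocol")

#' Write a force trace to CSV with comment-prefixed metadata
#'
#' The file begins with `# key: value` metadata lines (`muscle`, `mass_g`,
#' `l0_cm`, `sampling_hz`, `protocol`) followed by a `time_s,force_mN` CSV
#' body written at full double precision.
#'
#' @param trace A [force_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "force_trace"))
  meta <- c(
    sprintf("# muscle: %s", trace$muscle),
    sprintf("# mass_g: %.10g", trace$mass_g),
    sprintf("# l0_cm: %.10g", trace$l0_cm),
    sprintf("# sampling_hz: %.10g", trace$sampling_rate),
    sprintf("# protocol: %s", trace$protocol)
  )
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines("time_s,force_mN", con)
  writeLines(paste(format(trace$data$time_s, digits = 12, trim = TRUE,
                          scientific = FALSE),
                   format(trace$data$force_mN, digits = 12, trim = TRUE,
                          scientific = FALSE), sep = ","), con)
  invisible(path)
}

#' Read a force trace and its stimulation events
#'
#' Validates that every metadata key is present, that the time column is
#' uniform at the declared sampling rate (relative tolerance 1e-9), and that
#' no event extends past the end of the trace.
#'
#' @param path Trace CSV path.
#' @param events_path Optional companion events CSV path.
#' @return A [force_trace()]; when `events_path` is given, the event tibble
#'   is attached as attribute `"events"`.
#' @export
read_trace <- function(path, events_path = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("Trace file not found: %s", path), class = "mf_io_error")
  }
  hdr <- readr::read_lines(path, n_max = 50L)
  meta_lines <- grep("^#", hdr, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) == 3L) meta[[trimws(kv[2])]] <- trimws(kv[3])
  }
  missing_keys <- setdiff(trace_meta_keys(), names(meta))
  if (length(missing_keys)) {
    abort(paste0("Trace metadata missing key(s): ",
                 paste0("# ", missing_keys, collapse = ", ")),
          class = "mf_format_error")
  }
  body <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  fs <- as.numeric(meta$sampling_hz)
  t <- body$time_s
  if (length(t) > 1L) {
    step <- diff(t)
    if (any(step <= 0) || max(abs(step - 1 / fs)) > 1e-9 * max(1, 1 / fs)) {
      abort("Non-uniform time steps beyond tolerance for declared sampling_hz.",
            class = "mf_format_error")
    }
  }
  tr <- force_trace(t, body$force_mN, fs, muscle = meta$muscle,
                    mass_g = as.numeric(meta$mass_g),
                    l0_cm = as.numeric(meta$l0_cm),
                    protocol = meta$protocol)
  if (!is.null(events_path)) {
    ev <- read_events(events_path)
    if (nrow(ev) && max(ev$onset_s) > max(t)) {
      abort("Stimulation event onset beyond the end of the trace.",
            class = "mf_format_error")
    }
    attr(tr, "events") <- ev
  }
  tr
}

#' Write / read a stimulation-events sidecar CSV
#'
#' Columns: `protocol`, `onset_s`, `freq_hz`, `duration_s`.
#'
#' @param events Event tibble.
#' @param path CSV path.
#' @return `write_events()`: `path` invisibly; `read_events()`: the event
#'   tibble, time-ordered.
#' @export
write_events <- function(events, path) {
  readr::write_csv(events[c("protocol", "onset_s", "freq_hz", "duration_s")],
                   path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Events file not found: %s", path), class = "mf_io_error")
  }
  ev <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("protocol", "onset_s", "freq_hz", "duration_s")
  missing_cols <- setdiff(need, names(ev))
  if (length(missing_cols)) {
    abort(paste0("Events file lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "mf_format_error")
  }
  ev <- ev[order(ev$onset_s), need]
  if (nrow(ev) > 1L &&
      any(ev$onset_s[-1] < (ev$onset_s + ev$duration_s)[-nrow(ev)])) {
    abort("Stimulation events overlap.", class = "mf_format_error")
  }
  tibble::as_tibble(ev)
}

#' Write a phenotype or metrics table to CSV
#'
#' List-columns (nested peak series) are dropped before writing.
#'
#' @param x Tibble.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  keep <- !vapply(x, is.list, logical(1))
  readr::write_csv(x[keep], path)
  invisible(path)
}

#' Read a simulation configuration from a key-value YAML file
#'
#' Keys mirror [sim_config()] argument names exactly; nested sections
#' (`effect_sizes`, `muscles`, `fatigue`) mirror the corresponding
#' constructor fields. Unknown keys are errors, so typos cannot silently
#' fall back to defaults.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's value.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path, seed = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path), class = "mf_io_error")
  }
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "mf_config_error")
  }
  if (!is.null(raw$fatigue)) {
    raw$fatigue <- do.call(fatigue_recovery_params, raw$fatigue)
  }
  if (!is.null(raw$muscles)) {
    raw$muscles <- lapply(raw$muscles, function(mu) {
      if (!is.null(mu$twitch)) mu$twitch <- do.call(twitch_params, mu$twitch)
      mu
    })
  }
  if (!is.null(raw$effect_sizes)) {
    base <- default_effect_sizes()
    for (cond in names(raw$effect_sizes)) {
      if (!cond %in% names(base)) {
        abort(sprintf("Unknown effect-size condition '%s'.", cond),
              class = "mf_config_error")
      }
      base[[cond]] <- modifyList(base[[cond]], raw$effect_sizes[[cond]])
    }
    raw$effect_sizes <- base
  }
  if (!is.null(raw$latent_loading)) raw$latent_loading <- unlist(raw$latent_loading)
  if (!is.null(seed)) raw$seed <- seed
  do.call(sim_config, raw)
}
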