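#' Three-way recovery analysis with frailty-stratified follow-up
#'
#' Analyzes the instantaneous recovery-rate curve with a repeated-measures
#' three-way ANOVA: Contraction as a within-subject factor (subject
#' blocking), Frailty and Run as between-subject factors, Type III sums of
#' squares with sum-to-zero coding. If the three-way
#' Contraction x Frailty x Run interaction is significant (p below `gate`),
#' separate two-way (Contraction x Run) repeated-measures ANOVAs are run
#' within each frailty stratum; if a stratum shows a Contraction x Run
#' interaction, per-contraction Run vs Control comparisons are performed
#' with a Sidak family equal to the number of contraction indices.
#'
#' No sphericity correction is applied by default; set `gg = TRUE` to use
#' Greenhouse-Geisser adjusted p-values for within-subject terms.
#'
#' Mice missing any contraction index are excluded from the analysis with a
#' warning (the repeated-measures model requires complete series).
#'
#' @param data Long tibble with one row per subject x contraction index.
#' @param outcome,contraction,subject,frailty,run Column names.
#' @param gate Interaction p-value threshold for the stratified follow-up
#'   (and for the per-contraction post hoc within a stratum).
#' @param gg Use Greenhouse-Geisser corrected p-values for within terms.
#' @return An object of class `mf_recovery_anova`: list with `three_way`
#'   (tibble: `term`, `sumsq`, `df`, `error_ss`, `den_df`, `statistic`,
#'   `p.value`), `stratified` (named list of per-stratum two-way tables, or
#'   `NULL` when the gate is not met), `posthoc` (named list of
#'   per-contraction Sidak comparisons per stratum), `excluded` (subject ids
#'   dropped for incomplete series), `n_contractions`, `gate`. Supports
#'   [tidy()].
#' @export
recovery_three_way <- function(data, outcome = "rate",
                               contraction = "contraction",
                               subject = "mouse_id",
                               frailty = "frailty_class", run = "run_group",
                               gate = 0.05, gg = FALSE) {
  d <- tibble::tibble(
    id = as.character(data[[subject]]),
    C_ = data[[contraction]],
    F_ = factor(data[[frailty]]),
    R_ = factor(data[[run]]),
    y = data[[outcome]]
  )
  lev <- sort(unique(d$C_))
  if (length(lev) < 2L) {
    abort("Need >= 2 contraction indices.", class = "mf_input_error")
  }
  wide <- tidyr::pivot_wider(d, id_cols = c("id", "F_", "R_"),
                             names_from = "C_", values_from = "y")
  ycols <- as.character(lev)
  complete <- stats::complete.cases(wide[ycols]) &
    apply(as.matrix(wide[ycols]), 1L, function(r) all(is.finite(r)))
  excluded <- wide$id[!complete]
  if (length(excluded)) {
    warn(sprintf("Excluding %d mice with incomplete contraction series: %s",
                 length(excluded), paste(excluded, collapse = ", ")))
  }
  wide <- wide[complete, , drop = FALSE]
  three_way <- rm_anova_table(wide, ycols, between = ~ F_ * R_, gg = gg)
  three_way$term <- rename_rm_terms(three_way$term)

  p3 <- three_way$p.value[three_way$term == "contraction:frailty:run"]
  stratified <- NULL
  posthoc <- NULL
  if (length(p3) == 1L && is.finite(p3) && p3 < gate) {
    stratified <- list()
    posthoc <- list()
    for (fl in levels(droplevels(wide$F_))) {
      sub <- wide[wide$F_ == fl, , drop = FALSE]
      tab <- rm_anova_table(sub, ycols, between = ~ R_, gg = gg)
      tab$term <- rename_rm_terms(tab$term)
      stratified[[fl]] <- tab
      p2 <- tab$p.value[tab$term == "contraction:run"]
      if (length(p2) == 1L && is.finite(p2) && p2 < gate) {
        posthoc[[fl]] <- per_contraction_sidak(sub, ycols)
      }
    }
  }
  structure(
    list(three_way = three_way, stratified = stratified, posthoc = posthoc,
         excluded = excluded, n_contractions = length(lev), gate = gate,
         n_subjects = nrow(wide)),
    class = "mf_recovery_anova"
  )
}

# Repeated-measures ANOVA via a multivariate linear model: Type III
# univariate tests with the contraction factor as the intra-subject design.
rm_anova_table <- function(wide, ycols, between, gg = FALSE) {
  Y <- as.matrix(wide[ycols])
  rhs <- all.vars(between)
  for (v in rhs) wide[[v]] <- droplevels(factor(wide[[v]]))
  contr <- lapply(rhs, function(v) "contr.sum")
  names(contr) <- rhs
  fml <- as.formula(paste("Y ~", deparse(between[[2]])))
  mod <- lm(fml, data = wide, contrasts = contr)
  idata <- data.frame(C_ = factor(ycols, levels = ycols))
  av <- car::Anova(mod, idata = idata, idesign = ~C_, type = 3)
  # HF epsilon > 1 is routinely clamped to 1; the warning is uninformative
  s <- withCallingHandlers(
    summary(av, multivariate = FALSE),
    warning = function(w) {
      if (grepl("HF eps", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  ut <- s$univariate.tests
  tab <- tibble::tibble(
    term = rownames(ut),
    sumsq = ut[, "Sum Sq"], df = ut[, "num Df"],
    error_ss = ut[, "Error SS"], den_df = ut[, "den Df"],
    statistic = ut[, "F value"], p.value = ut[, "Pr(>F)"]
  )
  tab <- tab[tab$term != "(Intercept)", , drop = FALSE]
  if (gg && !is.null(s$pval.adjustments) && nrow(s$pval.adjustments)) {
    adj <- s$pval.adjustments
    for (r in rownames(adj)) {
      tab$p.value[tab$term == r] <- adj[r, "Pr(>F[GG])"]
    }
  }
  tab
}

rename_rm_terms <- function(terms) {
  out <- gsub("F_", "frailty", terms, fixed = TRUE)
  out <- gsub("R_", "run", out, fixed = TRUE)
  out <- gsub("C_", "contraction", out, fixed = TRUE)
  # canonical order: contraction first in interaction labels
  vapply(strsplit(out, ":", fixed = TRUE), function(parts) {
    ord <- c("contraction", "frailty", "run")
    paste(parts[order(match(parts, ord))], collapse = ":")
  }, character(1))
}

# Per-contraction Run vs Control comparisons with Sidak family = number of
# contraction indices.
per_contraction_sidak <- function(wide, ycols) {
  m <- length(ycols)
  rows <- lapply(seq_along(ycols), function(j) {
    y <- wide[[ycols[j]]]
    g <- droplevels(factor(wide$R_))
    if (nlevels(g) < 2L || min(table(g)) < 2L) {
      return(tibble::tibble(contraction = ycols[j], estimate = NA_real_,
                            statistic = NA_real_, df = NA_real_,
                            p.value = NA_real_, adj.p.value = NA_real_, m = m))
    }
    tt <- t.test(y ~ g, var.equal = TRUE)
    est <- unname(diff(rev(tt$estimate)))
    tibble::tibble(contraction = ycols[j], estimate = est,
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p.value = tt$p.value,
                   adj.p.value = sidak_adjust(tt$p.value, m), m = m)
  })
  dplyr::bind_rows(rows)
}

#' @export
print.mf_recovery_anova <- function(x, ...) {
  cat(sprintf(
    "Repeated-measures three-way recovery ANOVA (%d mice, %d contractions)\n",
    x$n_subjects, x$n_contractions))
  print(as.data.frame(x$three_way), digits = 4, row.names = FALSE)
  if (is.null(x$stratified)) {
    cat(sprintf("Three-way interaction not below gate (%.2f): no stratified follow-up.\n",
                x$gate))
  } else {
    cat("Stratified follow-up run for strata:",
        paste(names(x$stratified), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mf_recovery_anova <- function(x, ...) {
  base <- dplyr::mutate(x$three_way, component = "three_way",
                        stratum = NA_character_)
  strat <- if (!is.null(x$stratified)) {
    dplyr::bind_rows(lapply(names(x$stratified), function(fl) {
      dplyr::mutate(x$stratified[[fl]], component = "stratified",
                    stratum = fl)
    }))
  }
  dplyr::bind_rows(base, strat)
}
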