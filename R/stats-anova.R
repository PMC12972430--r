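#' Unbalanced two-way ANOVA (Type III, sum-to-zero coding)
#'
#' Fits `outcome ~ frailty * run` with sum-to-zero factor contrasts and
#' computes Type III sums of squares, the convention that matches common
#' commercial statistics software on unbalanced 2x2 designs. Rows with a
#' missing outcome are dropped listwise for that outcome.
#'
#' @param data A tibble with factor columns (default `frailty_class`,
#'   `run_group`) and the outcome.
#' @param outcome Name of the outcome column (string).
#' @param frailty,run Names of the two between-subject factor columns.
#' @return An object of class `mf_anova`: list with `table` (tibble: `term`,
#'   `sumsq`, `df`, `meansq`, `statistic`, `p.value`), `fit` (the `lm`),
#'   `outcome`, `data` (the complete cases used), `residual_df`,
#'   `residual_ms`, and `cells` (per-cell n). Supports [tidy()] and
#'   [glance()].
#' @export
#' @examples
#' d <- tibble::tibble(
#'   frailty_class = rep(c("Low", "Low", "High", "High"), each = 2),
#'   run_group = rep(c("control", "run"), 4),
#'   y = c(1, 1, 3, 3, 1, 5, 3, 7)
#' )
#' tidy(two_way_anova(d, "y"))
two_way_anova <- function(data, outcome, frailty = "frailty_class",
                          run = "run_group") {
  need <- c(frailty, run, outcome)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "mf_input_error")
  }
  d <- tibble::tibble(
    F_ = droplevels(factor(data[[frailty]])),
    R_ = droplevels(factor(data[[run]])),
    y = data[[outcome]]
  )
  d <- d[is.finite(d$y), , drop = FALSE]
  cells <- table(d$F_, d$R_)
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)
    lab <- paste(rownames(cells)[empty[, 1]], colnames(cells)[empty[, 2]],
                 sep = " x ", collapse = "; ")
    abort(sprintf(
      "Interaction inestimable: empty design cell(s) %s for outcome '%s'.",
      lab, outcome), class = "mf_design_error")
  }
  if (nrow(d) - nlevels(d$F_) * nlevels(d$R_) < 1L) {
    abort("Insufficient residual degrees of freedom.", class = "mf_design_error")
  }
  fit <- lm(y ~ F_ * R_, data = d,
            contrasts = list(F_ = "contr.sum", R_ = "contr.sum"))
  rss <- sum(fit$residuals^2)
  zero_resid <- rss <= .Machine$double.eps * max(1, mean(d$y)^2) * nrow(d)
  if (!zero_resid) {
    a3 <- car::Anova(fit, type = 3)
    tab <- tibble::as_tibble(as.data.frame(a3), rownames = "term")
    names(tab) <- c("term", "sumsq", "df", "statistic", "p.value")
    tab <- tab[!tab$term %in% "(Intercept)", ]
    tab$term <- c("frailty", "run", "frailty:run", "residuals")[
      match(tab$term, c("F_", "R_", "F_:R_", "Residuals"))]
    tab$meansq <- tab$sumsq / tab$df
    res <- tab[tab$term == "residuals", ]
    tab <- tab[, c("term", "sumsq", "df", "meansq", "statistic", "p.value")]
  } else {
    # degenerate fit (zero residual variance): Type III SS by explicit
    # model comparison, F left undefined with a diagnostic
    inform(sprintf(
      "Zero residual variance for outcome '%s': F statistics undefined.",
      outcome))
    X <- stats::model.matrix(fit)
    drop_rss <- vapply(2:4, function(j) {
      sum(stats::lsfit(X[, -j, drop = FALSE], d$y,
                       intercept = FALSE)$residuals^2)
    }, numeric(1))
    df_res <- nrow(d) - 4L
    tab <- tibble::tibble(
      term = c("frailty", "run", "frailty:run", "residuals"),
      sumsq = c(drop_rss - rss, rss),
      df = c(1, 1, 1, df_res))
    tab$meansq <- tab$sumsq / tab$df
    tab$statistic <- NA_real_
    tab$p.value <- NA_real_
    res <- tab[tab$term == "residuals", ]
  }
  structure(
    list(table = tab, fit = fit, outcome = outcome, data = d,
         residual_df = res$df, residual_ms = res$meansq,
         cells = cells),
    class = "mf_anova"
  )
}

#' @export
print.mf_anova <- function(x, ...) {
  cat(sprintf("Two-way ANOVA (Type III) on '%s'  [n = %d]\n",
              x$outcome, nrow(x$data)))
  print(as.data.frame(x$table), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mf_anova <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.mf_anova <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
                 sigma = s$sigma, df.residual = x$residual_df,
                 nobs = nrow(x$data))
}

#' Sidak multiplicity adjustment
#'
#' `p_adj = 1 - (1 - p)^m`, capped at 1. Computed via `expm1`/`log1p` for
#' numerical accuracy at small `p`.
#'
#' @param p Unadjusted p-value(s) in `[0, 1]`.
#' @param m Family size (number of comparisons), >= 1.
#' @return Adjusted p-value(s), always in `[p, 1]`.
#' @export
sidak_adjust <- function(p, m) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].", class = "mf_input_error")
  }
  if (any(m < 1)) abort("`m` must be >= 1.", class = "mf_input_error")
  pmin(1, -expm1(m * log1p(-p)))
}

#' Sidak post hoc simple-effect comparisons
#'
#' Pairwise comparisons of Run vs Control within each frailty stratum
#' (the default family, m = 2) or all six pairwise cell comparisons
#' (`family = "all_cells"`), using the ANOVA residual mean square as the
#' pooled error term. By convention the post hoc is gated on a significant
#' interaction: the gate threshold is configurable and `gate = NULL`
#' disables it.
#'
#' @param anova An [two_way_anova()] result.
#' @param family `"run_within_frailty"` (default) or `"all_cells"`.
#' @param gate Interaction p-value threshold below which the post hoc runs
#'   (default 0.05); `NULL` to run unconditionally.
#' @return A tibble with one row per contrast: `contrast`, `estimate`,
#'   `std.error`, `statistic`, `df`, `p.value`, `adj.p.value`, `m`; or a
#'   0-row tibble when the gate is not met.
#' @export
sidak_posthoc <- function(anova, family = c("run_within_frailty", "all_cells"),
                          gate = 0.05) {
  stopifnot(inherits(anova, "mf_anova"))
  family <- match.arg(family)
  p_int <- anova$table$p.value[anova$table$term == "frailty:run"]
  if (!is.null(gate) && (is.na(p_int) || p_int >= gate)) {
    return(posthoc_empty())
  }
  d <- anova$data
  cm <- dplyr::summarise(dplyr::group_by(d, .data$F_, .data$R_),
                         mean = mean(.data$y), n = dplyr::n(),
                         .groups = "drop")
  mse <- anova$residual_ms
  df <- anova$residual_df
  pairs <- if (family == "run_within_frailty") {
    lapply(levels(d$F_), function(fl) {
      sub <- cm[cm$F_ == fl, ]
      if (nrow(sub) < 2L) {
        abort(sprintf("Post hoc family references empty cells in stratum %s.", fl),
              class = "mf_design_error")
      }
      list(label = sprintf("%s: %s - %s", fl, sub$R_[2], sub$R_[1]),
           est = sub$mean[2] - sub$mean[1],
           se = sqrt(mse * (1 / sub$n[1] + 1 / sub$n[2])))
    })
  } else {
    idx <- utils::combn(nrow(cm), 2, simplify = FALSE)
    lapply(idx, function(ij) {
      a <- cm[ij[1], ]; b <- cm[ij[2], ]
      list(label = sprintf("%s/%s - %s/%s", a$F_, a$R_, b$F_, b$R_),
           est = a$mean - b$mean,
           se = sqrt(mse * (1 / a$n + 1 / b$n)))
    })
  }
  m <- length(pairs)
  out <- dplyr::bind_rows(lapply(pairs, function(p) {
    tstat <- p$est / p$se
    pval <- 2 * pt(-abs(tstat), df)
    tibble::tibble(contrast = p$label, estimate = p$est, std.error = p$se,
                   statistic = tstat, df = df, p.value = pval,
                   adj.p.value = sidak_adjust(pval, m), m = m)
  }))
  out
}

posthoc_empty <- function() {
  tibble::tibble(contrast = character(0), estimate = numeric(0),
                 std.error = numeric(0), statistic = numeric(0),
                 df = numeric(0), p.value = numeric(0),
                 adj.p.value = numeric(0), m = integer(0))
}

#' Percent-change analysis between frailty strata
#'
#' For each frailty stratum, every running mouse's outcome is expressed as
#' the percent change from the mean of that stratum's sedentary controls:
#' `pc_i = 100 (x_i - mean(control)) / mean(control)`. The Low-stratum and
#' High-stratum percent changes are then compared with an unpaired
#' two-tailed t-test (Student's equal-variance test by default, the named
#' commercial software's default; `welch = TRUE` for the Welch variant).
#'
#' @inheritParams two_way_anova
#' @param welch Use the Welch (unequal-variance) t-test.
#' @return An object of class `mf_percent_change`: list with
#'   `percent_changes` (tibble: `mouse_id` if present, `frailty`,
#'   `percent_change`), `control_means`, `statistic`, `df`, `p.value`,
#'   `estimate` (mean Low minus mean High percent change), `method`.
#'   Supports [tidy()].
#' @export
percent_change_test <- function(data, outcome, frailty = "frailty_class",
                                run = "run_group", welch = FALSE) {
  d <- tibble::tibble(
    F_ = factor(data[[frailty]], levels = c("Low", "High")),
    R_ = tolower(as.character(data[[run]])),
    y = data[[outcome]]
  )
  if ("mouse_id" %in% names(data)) d$mouse_id <- data$mouse_id
  d <- d[is.finite(d$y) & !is.na(d$F_), , drop = FALSE]
  pcs <- list(); cmeans <- numeric(0)
  for (fl in levels(d$F_)) {
    ctrl <- d$y[d$F_ == fl & d$R_ == "control"]
    runy <- d[d$F_ == fl & d$R_ == "run", , drop = FALSE]
    if (length(ctrl) == 0L || !is.finite(mean(ctrl)) || mean(ctrl) == 0) {
      abort(sprintf(
        "Stratum %s: control mean is zero or unavailable; percent change undefined.",
        fl), class = "mf_design_error")
    }
    if (nrow(runy) < 2L) {
      abort(sprintf("Stratum %s: need >= 2 running mice.", fl),
            class = "mf_design_error")
    }
    cmeans[[fl]] <- mean(ctrl)
    pcs[[fl]] <- tibble::tibble(
      mouse_id = if ("mouse_id" %in% names(runy)) runy$mouse_id else NA_character_,
      frailty = fl,
      percent_change = 100 * (runy$y - mean(ctrl)) / mean(ctrl)
    )
  }
  pc <- dplyr::bind_rows(pcs)
  tt <- t.test(percent_change ~ factor(frailty, levels = c("Low", "High")),
               data = pc, var.equal = !welch)
  structure(
    list(percent_changes = pc, control_means = cmeans,
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p.value = tt$p.value,
         estimate = unname(tt$estimate[1] - tt$estimate[2]),
         method = if (welch) "welch" else "student", outcome = outcome),
    class = "mf_percent_change"
  )
}

#' @export
print.mf_percent_change <- function(x, ...) {
  cat(sprintf(
    "Percent-change t-test (%s) on '%s': t = %.3f, df = %.3g, p = %.4g\n",
    x$method, x$outcome, x$statistic, x$df, x$p.value))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mf_percent_change <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, estimate = x$estimate,
                 statistic = x$statistic, df = x$df, p.value = x$p.value,
                 method = x$method)
}
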