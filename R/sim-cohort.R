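#' Simulate a phenotyping cohort
#'
#' Generates one row per mouse with raw grip trials (5), rotarod trials (3),
#' treadmill distance, body weight, and 28 deficit-item scores, in the exact
#' [read_cohort()] schema. The five frailty criteria are driven by a shared
#' latent standard-normal frailty factor `Z` per mouse: criterion `j` gets a
#' standardized score `c_j = lambda_j Z + sqrt(1 - lambda_j^2) eps_j`
#' (so `c_j` is marginally standard normal and `latent_loading = 0` gives
#' independent criteria), which is then mapped to realistic units —
#' performance criteria decrease with `c_j` (frailer mice perform worse),
#' body weight and deficit burden increase with it. Run-group assignment
#' places `round(run_fraction * n)` mice in the running group at random.
#'
#' Two attributes are attached to the returned tibble:
#' \describe{
#'   \item{`latent`}{tibble of the latent factor `Z` and the five
#'     standardized criterion scores, used for theoretical-quantile marker
#'     flagging (see [theoretical_thresholds()]).}
#'   \item{`trace_params`}{per mouse x muscle contractile simulator
#'     parameters, derived from the mouse's condition (frailty class from
#'     the cohort's own percentile rule, crossed with run group) and the
#'     configured effect-size multipliers; see [cohort_trace_params()].}
#' }
#'
#' @param config A [sim_config()] object.
#' @return A cohort tibble (possibly 0-row) in the cohort-file schema.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_mice = 8, seed = 42))
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  n <- config$n_mice
  if (n == 0L) {
    empty <- empty_cohort()
    attr(empty, "latent") <- tibble::tibble(Z = numeric(0))
    attr(empty, "trace_params") <- tibble::tibble()
    return(empty)
  }
  set.seed(stream_seed(config$seed, 1L))
  lam <- config$latent_loading
  Z <- rnorm(n)
  crit <- vapply(criterion_names(), function(j) {
    lam[[j]] * Z + sqrt(1 - lam[[j]]^2) * rnorm(n)
  }, numeric(n))
  crit <- matrix(crit, nrow = n,
                 dimnames = list(NULL, criterion_names()))

  # Unit mappings: arbitrary but realistic; only ranks matter for marker
  # assignment. Performance tests use lognormal maps to stay positive.
  treadmill <- 420 * exp(-0.30 * crit[, "treadmill"])
  grip_mean <- 100 - 15 * crit[, "grip"]
  rotarod_mean <- 120 * exp(-0.35 * crit[, "rotarod"])
  body_weight <- 26 + 3.5 * crit[, "body_weight"]

  grip_trials <- matrix(rnorm(5L * n, mean = rep(grip_mean, each = 5L), sd = 6),
                        nrow = n, byrow = TRUE)
  grip_trials <- pmax(grip_trials, 0)
  rot_trials <- matrix(rnorm(3L * n, mean = rep(rotarod_mean, each = 3L), sd = 10),
                       nrow = n, byrow = TRUE)
  rot_trials <- pmax(rot_trials, 0)

  # 28 deficit items: per-item deficit probability rises with the frailty
  # criterion score; severe (1) deficits are a quarter of all deficits.
  q <- plogis(-1.5 + 1.0 * crit[, "fi"])
  u <- matrix(runif(28L * n), nrow = n)
  items <- matrix(0, nrow = n, ncol = 28L)
  items[u < q] <- 0.5
  items[u < 0.25 * q] <- 1

  n_run <- round(config$run_fraction * n)
  run_group <- rep("control", n)
  run_group[sample.int(n, n_run)] <- "run"

  cohort <- tibble::tibble(
    mouse_id = sprintf("m%03d", seq_len(n)),
    run_group = run_group,
    body_weight_g = round(body_weight, 3),
    treadmill_distance_m = round(treadmill, 3)
  )
  for (j in 1:5) cohort[[sprintf("grip_trial_%d", j)]] <- round(grip_trials[, j], 3)
  for (j in 1:3) cohort[[sprintf("rotarod_trial_%d", j)]] <- round(rot_trials[, j], 3)
  for (j in 1:28) cohort[[sprintf("fi_item_%02d", j)]] <- items[, j]

  attr(cohort, "latent") <- tibble::as_tibble(
    cbind(tibble::tibble(mouse_id = cohort$mouse_id, Z = Z),
          tibble::as_tibble(crit))
  )
  attr(cohort, "trace_params") <- derive_trace_params(cohort, config)
  cohort
}

empty_cohort <- function() {
  cols <- cohort_schema_cols()
  out <- lapply(cols, function(cl) if (cl %in% c("mouse_id", "run_group"))
    character(0) else numeric(0))
  names(out) <- cols
  tibble::as_tibble(out)
}

cohort_schema_cols <- function() {
  c("mouse_id", "run_group", "body_weight_g", "treadmill_distance_m",
    sprintf("grip_trial_%d", 1:5), sprintf("rotarod_trial_%d", 1:3),
    fi_item_cols())
}

# Per mouse x muscle simulator parameter assignments: condition =
# (cohort-percentile frailty class) x (run group), effect multipliers from
# config$effect_sizes, plus seeded per-mouse lognormal heterogeneity in
# force scale and muscle mass.
derive_trace_params <- function(cohort, config) {
  if (nrow(cohort) >= 2L) {
    pheno <- phenotype_cohort(cohort, rate = config$marker_rate)
  } else {
    pheno <- summarize_phenotypes(cohort)
    pheno$frailty_class <- factor("Low", levels = c("Low", "High"))
  }
  cond <- tolower(paste(pheno$frailty_class, pheno$run_group, sep = "_"))
  set.seed(stream_seed(config$seed, 2L))
  n <- nrow(cohort)
  cv <- config$between_mouse_cv
  sdlog <- sqrt(log(1 + cv^2))
  es_field <- function(field) {
    vapply(cond, function(cd) config$effect_sizes[[cd]][[field]], numeric(1))
  }
  es_amp <- es_field("amplitude"); es_taur <- es_field("tau_relax")
  es_mass <- es_field("mass"); es_kappa <- es_field("kappa")
  es_rtau <- es_field("recovery_tau"); es_rpl <- es_field("recovery_plateau")
  dplyr::bind_rows(lapply(names(config$muscles), function(m) {
    mu <- config$muscles[[m]]
    tw <- mu$twitch
    scale_mult <- exp(rnorm(n, -sdlog^2 / 2, sdlog))
    mass_mult <- exp(rnorm(n, -sdlog^2 / 2, sdlog * 0.8))
    tibble::tibble(
      mouse_id = cohort$mouse_id,
      muscle = m,
      condition = cond,
      frailty_class = as.character(pheno$frailty_class),
      run_group = pheno$run_group,
      amplitude_A = tw$amplitude_A * es_amp * scale_mult,
      tau_contract = tw$tau_contract,
      tau_relax = tw$tau_relax * es_taur,
      f_max = tw$f_max * es_amp * scale_mult,
      k_half = tw$k_half,
      sampling_rate = tw$sampling_rate,
      mass_g = mu$mass_g * es_mass * mass_mult,
      l0_cm = mu$l0_cm,
      decay_kappa = config$fatigue$decay_kappa * es_kappa,
      decay_floor_r = config$fatigue$decay_floor_r,
      recovery_tau = config$fatigue$recovery_tau * es_rtau,
      recovery_plateau = config$fatigue$recovery_plateau * es_rpl,
      recovery_freq = mu$recovery_freq
    )
  }))
}

#' Per-mouse contractile simulator parameter assignments of a cohort
#'
#' @param cohort A tibble from [simulate_cohort()].
#' @return The `trace_params` attribute: one row per mouse x muscle.
#' @export
cohort_trace_params <- function(cohort) {
  tp <- attr(cohort, "trace_params")
  if (is.null(tp)) {
    abort("Cohort carries no trace parameters (was it simulated?).",
          class = "mf_input_error")
  }
  tp
}

#' Theoretical adverse-tail thresholds on the standardized criterion scale
#'
#' On the latent standardized scale every criterion score is marginally
#' standard normal with the adverse direction pointing upward (frailer).
#' The theoretical threshold at adverse rate `rate` is therefore
#' `qnorm(1 - rate)` for every criterion.
#'
#' @param rate Adverse-tail fraction (default 0.2).
#' @return Named numeric vector of thresholds over the five criteria.
#' @export
theoretical_thresholds <- function(rate = 0.2) {
  setNames(rep(qnorm(1 - rate), 5L), criterion_names())
}

#' Simulate the High/Low frailty split under criterion independence
#'
#' Replicates the marker-and-classify rule on cohorts with five independent
#' standard-normal criteria, each flagged when it falls in the theoretical
#' adverse `rate` tail (rather than at cohort percentiles), and classifies a
#' mouse High at `>= 2` flags via [classify_frailty()]. With independent
#' criteria the per-mouse flag count is Binomial(5, rate), so the expected
#' High fraction has the closed form
#' `1 - (1 - rate)^5 - 5 rate (1 - rate)^4` (0.26272 at rate 0.2).
#'
#' @param n_cohorts Number of replicate cohorts.
#' @param n_mice Mice per cohort.
#' @param rate Adverse-tail flag probability per criterion.
#' @param seed Integer seed.
#' @return A tibble with one row per cohort: `cohort`, `n_high`, `n_low`.
#' @export
#' @examples
#' sim <- simulate_marker_split(200, 47, seed = 1)
#' mean(sim$n_high)  # ~ 47 * 0.26272 = 12.35
simulate_marker_split <- function(n_cohorts = 2000L, n_mice = 47L,
                                  rate = 0.2, seed = 1L) {
  set.seed(stream_seed(seed, 3L))
  th <- qnorm(1 - rate)
  n_high <- integer(n_cohorts)
  for (r in seq_len(n_cohorts)) {
    z <- matrix(rnorm(n_mice * 5L), nrow = n_mice)
    n_markers <- as.integer(rowSums(z > th))
    cls <- classify_frailty(n_markers)
    n_high[r] <- sum(cls == "High")
  }
  tibble::tibble(cohort = seq_len(n_cohorts), n_high = n_high,
                 n_low = n_mice - n_high)
}
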