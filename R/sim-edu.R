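#' Configuration for the EdU pulse/chase simulator
#'
#' Each animal carries `cells` progenitor cells per compartment; during a
#' pulse each cell is labeled independently with the compartment's
#' `label_prob`. In the chase arm, labeled cells propagate the label
#' according to the growth model (see [generate_edu_dataset()]), driven by
#' the compartment's true division rate in divisions per 24 h.
#'
#' @param n_animals animals per condition and arm.
#' @param compartments tibble with `compartment`, `cells`, `label_prob`,
#'   `rate` (divisions per day).
#' @param chase_hours chase duration in hours (>= 0).
#' @param conditions condition labels (the same truth is used in each; plant
#'   effects by passing distinct compartment tables per call).
#' @param growth `"multiplicative"` (default): expected EdU+ nuclei per
#'   labeled cell after the chase is rate * chase_hours / 24, the model
#'   under which the ratio estimator of [division_rate()] is unbiased;
#'   `"linear_plus_one"`: each labeled cell becomes a clone of expected size
#'   1 + rate * chase_hours / 24 (nuclei never lost).
#' @param seed integer seed.
#' @export
edu_sim_config <- function(n_animals = 30,
                           compartments = tibble::tibble(
                             compartment = c("distal", "midline"),
                             cells = 200,
                             label_prob = 0.05,
                             rate = c(1.0, 0.5)),
                           chase_hours = 36,
                           conditions = "control",
                           growth = c("multiplicative", "linear_plus_one"),
                           seed = 1) {
  growth <- match.arg(growth)
  if (any(compartments$label_prob < 0 | compartments$label_prob > 1)) {
    abort("edu_sim_config: label_prob must be in [0, 1].")
  }
  if (any(compartments$rate < 0)) abort("edu_sim_config: rates must be >= 0.")
  if (chase_hours < 0) abort("edu_sim_config: chase_hours must be >= 0.")
  structure(list(n_animals = n_animals, compartments = compartments,
                 chase_hours = chase_hours, conditions = conditions,
                 growth = growth, seed = seed),
            class = "edu_sim_config")
}

#' Generate EdU pulse and chase tables
#'
#' Draws, per animal and compartment, the number of labeled cells after a
#' pulse (Binomial(cells, label_prob)) and, in the chase arm, the number of
#' EdU+ nuclei after label propagation. Under the default multiplicative
#' model the chase count given L labeled cells is Poisson(L * rate *
#' chase_hours / 24); under `"linear_plus_one"` it is L + Poisson(L * rate *
#' chase_hours / 24), i.e. clones of expected size 1 + rate * t / 24.
#'
#' @param config an [edu_sim_config()].
#' @return List with `pulse` and `chase` EdU tibbles (`animal`, `condition`,
#'   `compartment`, `arm`, `edu_pos`, `total_cells`) and `truth` (the config
#'   rates and model).
#' @export
generate_edu_dataset <- function(config = edu_sim_config()) {
  stopifnot(inherits(config, "edu_sim_config"))
  set.seed(stage_seed(config$seed, "edu"))
  grid <- tidyr::expand_grid(condition = config$conditions,
                             config$compartments,
                             animal_idx = seq_len(config$n_animals))
  draw_arm <- function(arm) {
    lab <- rbinom(nrow(grid), size = grid$cells, prob = grid$label_prob)
    edu <- if (arm == "pulse") {
      lab
    } else {
      lam <- lab * grid$rate * config$chase_hours / 24
      extra <- rpois(nrow(grid), lam)
      if (config$growth == "multiplicative") {
        # expected nuclei per labeled cell = rate * t / 24
        extra
      } else {
        lab + extra
      }
    }
    tibble::tibble(animal = sprintf("%s_%s_a%03d", arm, grid$condition, grid$animal_idx),
                   condition = grid$condition,
                   compartment = grid$compartment,
                   arm = arm,
                   edu_pos = as.integer(edu),
                   total_cells = as.integer(grid$cells))
  }
  list(pulse = draw_arm("pulse"),
       chase = draw_arm("chase"),
       truth = list(rates = config$compartments, growth = config$growth,
                    chase_hours = config$chase_hours))
}

#' Configuration for the per-trial count simulator
#'
#' Control counts are drawn from a discretized normal (rounded, truncated at
#' 0) with the given mean and SD; the treatment condition applies either an
#' additive shift or plants a fraction of "exceeders" whose counts sit well
#' above the control exceedance cutoff.
#'
#' @param n_trials number of trials.
#' @param n_control,n_treatment animals per trial per condition (> 0).
#' @param control_mean,control_sd control count distribution.
#' @param effect list: `type` `"shift"` with `value` added to treatment
#'   counts, or `"exceeder"` with `value` = fraction of treatment animals
#'   pushed above mean + 2 SD.
#' @param seed integer seed.
#' @export
trial_config <- function(n_trials = 3, n_control = 10, n_treatment = 10,
                         control_mean = 10, control_sd = 3,
                         effect = list(type = "shift", value = 0),
                         seed = 1) {
  if (n_control < 1 || n_treatment < 1) {
    abort("trial_config: every condition needs at least one animal per trial.")
  }
  stopifnot(effect$type %in% c("shift", "exceeder"))
  structure(list(n_trials = n_trials, n_control = n_control,
                 n_treatment = n_treatment, control_mean = control_mean,
                 control_sd = control_sd, effect = effect, seed = seed),
            class = "trial_config")
}

#' Generate a long-format per-trial count table
#'
#' @param config a [trial_config()].
#' @return List with `trials` tibble (`trial`, `condition`, `animal`,
#'   `count`) and `truth` (the effect planted).
#' @export
generate_trial_counts <- function(config = trial_config()) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(stage_seed(config$seed, "trials"))
  draw_counts <- function(n) {
    pmax(0L, as.integer(round(rnorm(n, config$control_mean, config$control_sd))))
  }
  rows <- purrr::map(seq_len(config$n_trials), function(t) {
    ctl <- draw_counts(config$n_control)
    trt <- draw_counts(config$n_treatment)
    if (config$effect$type == "shift") {
      trt <- trt + as.integer(round(config$effect$value))
    } else if (config$effect$value > 0) {
      n_exc <- rbinom(1, config$n_treatment, config$effect$value)
      if (n_exc > 0) {
        bump <- as.integer(ceiling(config$control_mean + 2 * config$control_sd))
        idx <- seq_len(n_exc)
        trt[idx] <- bump + draw_counts(n_exc)
      }
    }
    tibble::tibble(
      trial = sprintf("T%02d", t),
      condition = rep(c("control", "treatment"),
                      c(config$n_control, config$n_treatment)),
      animal = sprintf("T%02d_a%03d", t,
                       seq_len(config$n_control + config$n_treatment)),
      count = c(ctl, trt))
  })
  list(trials = dplyr::bind_rows(rows), truth = list(effect = config$effect))
}
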