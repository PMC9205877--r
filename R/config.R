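## Study configuration: YAML-backed, schema-validated. The shipped default
## lives in inst/extdata/default_config.yaml; every numeric field is
## range-checked and unknown keys are rejected (typo guard).

default_config_path <- function()
  system.file("extdata", "default_config.yaml", package = "pddm", mustWork = TRUE)

# dotted-path -> c(min, max) range constraints (closed intervals);
# NA means unbounded on that side
.config_ranges <- list(
  "task.cooperative_p" = c(0, 1), "task.deceitful_p" = c(0, 1),
  "task.trials_per_opponent" = c(1, NA), "task.time_limit_s" = c(1e-6, NA),
  "task.opponent_rt_min_s" = c(0, NA), "task.opponent_rt_max_s" = c(0, NA),
  "cohort.n_subjects" = c(2, NA),
  "cohort.age_sd" = c(0, NA), "cohort.age_min" = c(0, NA),
  "cohort.age_max" = c(0, NA),
  "cohort.female_p" = c(0, 1), "cohort.believed_live_p" = c(0, 1),
  "cohort.trait_min" = c(0, NA), "cohort.trait_max" = c(0, NA),
  "cohort.panas_positive_sd" = c(0, NA), "cohort.panas_negative_sd" = c(0, NA),
  "cohort.disease_duration_sd" = c(0, NA), "cohort.seizure_free_sd" = c(0, NA),
  "cohort.medicated_p" = c(0, 1), "cohort.sam_sd" = c(0, NA),
  "cohort.invalid_rate" = c(0, 0.5),
  "cohort.effects.base_a" = c(1e-6, NA),
  "cohort.effects.base_w" = c(1e-6, 1 - 1e-6),
  "cohort.effects.base_t0" = c(0, NA),
  "cohort.effects.subject_v_sd" = c(0, NA),
  "cohort.effects.session_v_sd" = c(0, NA),
  "cohort.sim.dt" = c(1e-6, 0.1), "cohort.sim.max_t_s" = c(0.1, NA),
  "fit.restarts" = c(0, NA), "fit.rt_floor_s" = c(0, NA),
  "fit.reltol" = c(1e-12, 1e-2), "fit.quad_points" = c(3, 51),
  "fit.min_trials" = c(5, NA),
  "stats.alpha" = c(1e-6, 1 - 1e-6), "stats.screen_r2" = c(0, 1),
  "stats.pilot_sd" = c(1e-9, NA), "stats.power" = c(1e-6, 1 - 1e-6)
)

validate_node <- function(value, template, path) {
  if (is.list(template)) {
    if (!is.list(value))
      stop("config key '", path, "' must be a mapping")
    unknown <- setdiff(names(value), names(template))
    if (length(unknown))
      stop("unknown config key '", paste0(path, ".", unknown[1]),
           "' (did you misspell one of: ",
           paste(names(template), collapse = ", "), "?)")
    out <- template
    for (k in names(template)) {
      kp <- if (nzchar(path)) paste0(path, ".", k) else k
      out[[k]] <- if (k %in% names(value))
        validate_node(value[[k]], template[[k]], kp) else template[[k]]
    }
    return(out)
  }
  # leaf: type must match the template's
  if (is.numeric(template)) {
    if (!is.numeric(value) || length(value) != 1 || !is.finite(value))
      stop("config key '", path, "' must be a single finite number")
    r <- .config_ranges[[path]]
    if (!is.null(r)) {
      if (!is.na(r[1]) && value < r[1])
        stop("config key '", path, "' = ", value, " below its minimum ", r[1])
      if (!is.na(r[2]) && value > r[2])
        stop("config key '", path, "' = ", value, " above its maximum ", r[2])
    }
    return(value)
  }
  if (is.logical(template)) {
    if (!is.logical(value) || length(value) != 1 || is.na(value))
      stop("config key '", path, "' must be true or false")
    return(value)
  }
  if (is.character(template)) {
    if (!is.character(value) || length(value) != 1)
      stop("config key '", path, "' must be a single string")
    if (path == "task.tft_first" && !value %in% c("mirror", "cooperate", "deceive"))
      stop("config key 'task.tft_first' must be one of mirror/cooperate/deceive")
    return(value)
  }
  value
}

# cross-field checks that single-leaf ranges cannot express
validate_cross <- function(cfg) {
  with(cfg$task, {
    if (opponent_rt_max_s < opponent_rt_min_s)
      stop("config: opponent_rt_max_s must be >= opponent_rt_min_s")
  })
  if (cfg$cohort$age_max < cfg$cohort$age_min)
    stop("config: cohort.age_max must be >= cohort.age_min")
  if (cfg$cohort$trait_max <= cfg$cohort$trait_min)
    stop("config: cohort.trait_max must exceed cohort.trait_min")
  pm <- cfg$task$payoff
  payoff_matrix(pm$cooperate_cooperate, pm$cooperate_deceive,
                pm$deceive_cooperate, pm$deceive_deceive,
                enforce_dominance = cfg$task$enforce_dominance)
  invisible(cfg)
}

#' Load and validate a study configuration
#'
#' Reads a YAML configuration, validates it against the shipped schema
#' (unknown keys rejected with the offending key named, every numeric field
#' range-checked, cross-field constraints enforced) and fills omitted keys
#' from the package defaults.
#'
#' @param path path to a YAML file; `NULL` loads the shipped default.
#' @return a validated configuration list of class `"pd_config"`.
#' @export
load_study_config <- function(path = NULL) {
  template <- yaml::read_yaml(default_config_path())
  cfg <- if (is.null(path)) template else {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- yaml::read_yaml(path)
    validate_node(raw, template, "")
  }
  cfg <- validate_node(cfg, template, "")
  validate_cross(cfg)
  structure(cfg, class = c("pd_config", "list"))
}

#' Default study configuration, with optional overrides
#'
#' Convenience wrapper around the shipped default configuration. Overrides
#' are supplied as a nested list and validated like a user file.
#'
#' @param overrides nested list of keys to override, e.g.
#'   `list(cohort = list(n_subjects = 5))`.
#' @return a validated configuration list of class `"pd_config"`.
#' @export
study_config <- function(overrides = NULL) {
  cfg <- load_study_config(NULL)
  if (!is.null(overrides)) {
    merged <- utils::modifyList(unclass(cfg), overrides)
    cfg <- validate_node(merged, yaml::read_yaml(default_config_path()), "")
    validate_cross(cfg)
    cfg <- structure(cfg, class = c("pd_config", "list"))
  }
  cfg
}

#' @export
print.pd_config <- function(x, ...) {
  cat("Study configuration:",
      x$cohort$n_subjects, "subjects x 2 sessions x",
      8 * x$task$trials_per_opponent, "trials\n")
  cat("Payoff (player): CC", x$task$payoff$cooperate_cooperate,
      "CD", x$task$payoff$cooperate_deceive,
      "DC", x$task$payoff$deceive_cooperate,
      "DD", x$task$payoff$deceive_deceive, "\n")
  ef <- x$cohort$effects
  cat("Planted effects: bias shift", ef$bias_shift_tvns,
      ", drift shift", ef$drift_shift_tvns,
      ", neuroticism modulation", ef$neuroticism_modulation, "\n")
  invisible(x)
}

#' Engine pieces derived from a configuration
#'
#' `config_payoff()` builds the [payoff_matrix()] and `config_opponents()`
#' the [build_opponents()] table from a validated study configuration.
#'
#' @param cfg a [study_config()] configuration.
#' @return a `payoff_matrix` / opponents data frame respectively.
#' @export
config_payoff <- function(cfg) {
  pm <- cfg$task$payoff
  payoff_matrix(pm$cooperate_cooperate, pm$cooperate_deceive,
                pm$deceive_cooperate, pm$deceive_deceive,
                enforce_dominance = cfg$task$enforce_dominance)
}

#' @rdname config_payoff
#' @export
config_opponents <- function(cfg)
  build_opponents(cfg$task$cooperative_p, cfg$task$deceitful_p, cfg$task$tft_first)
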