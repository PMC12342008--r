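#' Run configuration: load, validate, save
#'
#' The whole run (simulator grid and tolerances, cohort generation, engine,
#' pipeline, prior and metric settings) is driven by one YAML file. Unknown
#' keys are rejected by name; omitted keys are filled with the documented
#' defaults; save -> load round-trips every field.
#'
#' @name run-config
NULL

default_run_config <- function() {
  list(
    seed = 1L,
    simulator = list(
      observation_grid = c(0, 2, 4, 8, 12, 16, 20, 24),
      solver_abs_tol = 1e-6,
      solver_rel_tol = 1e-6),
    cohort = list(
      n_patients = 20L,
      pop_scale = 0.35,
      biomarker_dropout = 0.2,
      timepoint_dropout = 0.2,
      noise_scale_range = c(0.05, 0.2)),
    prior = list(scale = 0.25, noise_loc = 0.2),
    engine = list(
      n_rounds = 10L, n_sims_per_round = 50L, n_atoms = 25L,
      hidden_units = 100L, steps_per_round = 120L,
      learning_rate = 1e-3, batch_size = 50L),
    pipeline = list(mode = "sbi", batch_size = 4L,
                    n_posterior_samples = 100L),
    sensitivity = list(range_fraction = 0.3,
                       output_weeks = c(4, 12, 24), n_base = 256L))
}

merge_config <- function(defaults, user, path = character(0)) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults))
      stop("unknown config key: ", full)
    if (is.list(defaults[[key]])) {
      if (!is.list(user[[key]]))
        stop("config key ", full, " must be a mapping")
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

validate_run_config <- function(cfg) {
  with(cfg, {
    stopifnot(prior$scale > 0, prior$noise_loc > 0,
              cohort$pop_scale >= 0,
              cohort$biomarker_dropout >= 0, cohort$biomarker_dropout < 1,
              cohort$timepoint_dropout >= 0, cohort$timepoint_dropout < 1,
              engine$n_rounds >= 1, engine$n_sims_per_round >= 1,
              engine$n_atoms >= 1, engine$n_atoms <= engine$n_sims_per_round,
              pipeline$mode %in% c("sbi", "npf", "baseline"),
              pipeline$batch_size >= 1,
              sensitivity$range_fraction > 0, sensitivity$range_fraction < 1)
  })
  cfg
}

#' @rdname run-config
#' @param path YAML file path.
#' @return `load_config` returns the validated config list with defaults
#'   filled in.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  validate_run_config(merge_config(default_run_config(), user))
}

#' @rdname run-config
#' @param config a run-config list.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# Materialize the simulator spec described by a run config.
spec_from_config <- function(cfg) {
  simulator_spec(observation_grid = cfg$simulator$observation_grid,
                 solver_abs_tol = cfg$simulator$solver_abs_tol,
                 solver_rel_tol = cfg$simulator$solver_rel_tol)
}
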