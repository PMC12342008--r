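#' Surrogate treatment-response simulator
#'
#' A deliberately small mechanistic ODE model standing in for a full
#' quantitative systems pharmacology model. Three states respond to an
#' exponential-onset drug effect `E(t) = Emax * (1 - exp(-k_on * t))`:
#' an inflammatory mediator `P`, an acute-phase biomarker `C` and a
#' degradation biomarker `M`, all initialized at their pre-treatment steady
#' state:
#' \deqn{dP/dt = k_p (1 - E(t)) - k_{dp} P}
#' \deqn{dC/dt = k_c P - k_{dc} C}
#' \deqn{dM/dt = k_m P - k_{dm} M}
#' Four observables are reported on the observation grid: `CRP_like = C`,
#' `MMP_like = M`, `CELL_like = L0 (1 + a_L P)` and
#' `SCORE_like = d0 + d1 log(1 + C) + d2 P`.
#'
#' @name surrogate-simulator
NULL

.VP_PARAMS <- c("k_p", "k_dp", "k_c", "k_dc", "k_m", "k_dm",
                "L0", "a_L", "d0", "d1", "d2", "Emax", "k_on")
.VP_BIOMARKERS <- c("CRP_like", "MMP_like", "CELL_like", "SCORE_like")
.VP_CORE_BIOMARKERS <- c("CRP_like", "SCORE_like")
.VP_FIT_SUBSET <- c("k_p", "k_dp", "k_c", "k_dc", "k_m", "Emax", "k_on")

#' Default reference parametrization (the "typical treated patient")
#'
#' @return Named numeric vector over all simulator parameters. Units: first-
#'   order rates are per week; `L0`, `d0`..`d2` are on the observable scales;
#'   `Emax` is a dimensionless fraction in `[0, 1)`.
#' @export
default_reference <- function() {
  c(k_p = 10, k_dp = 1, k_c = 2, k_dc = 0.5, k_m = 1, k_dm = 0.4,
    L0 = 2, a_L = 0.05, d0 = 2, d1 = 1.5, d2 = 0.1, Emax = 0.6, k_on = 0.5)
}

#' Construct a simulator specification
#'
#' Bundles the parameter space, the reference parametrization, the observable
#' names, the observation grid and the ODE solver tolerances.
#'
#' @param reference named numeric vector of strictly positive parameters; must
#'   cover every name in `parameter_names`.
#' @param parameter_names ordered parameter identifiers.
#' @param biomarker_names ordered observable identifiers.
#' @param observation_grid measurement times in weeks, strictly increasing,
#'   starting at 0 (baseline).
#' @param fit_subset parameters exposed to inference; the rest stay frozen at
#'   the reference.
#' @param core_biomarkers biomarkers never dropped by the cohort generator.
#' @param solver_abs_tol,solver_rel_tol positive solver tolerances.
#' @return An object of class `vp_simulator_spec`.
#' @export
simulator_spec <- function(reference = default_reference(),
                           parameter_names = names(reference),
                           biomarker_names = .VP_BIOMARKERS,
                           observation_grid = c(0, 2, 4, 8, 12, 16, 20, 24),
                           fit_subset = .VP_FIT_SUBSET,
                           core_biomarkers = .VP_CORE_BIOMARKERS,
                           solver_abs_tol = 1e-6,
                           solver_rel_tol = 1e-6) {
  stopifnot(is.numeric(reference), !is.null(names(reference)),
            all(parameter_names %in% names(reference)),
            all(reference > 0),
            solver_abs_tol > 0, solver_rel_tol > 0)
  if (length(observation_grid) < 2 || observation_grid[1] != 0 ||
      any(diff(observation_grid) <= 0))
    stop("observation_grid must be strictly increasing and start at 0")
  if (!all(fit_subset %in% parameter_names))
    stop("fit_subset must be a subset of parameter_names")
  if (!all(core_biomarkers %in% biomarker_names))
    stop("core_biomarkers must be a subset of biomarker_names")
  structure(list(
    parameter_names = parameter_names,
    reference = reference[parameter_names],
    biomarker_names = biomarker_names,
    core_biomarkers = core_biomarkers,
    fit_subset = fit_subset,
    observation_grid = as.numeric(observation_grid),
    solver_abs_tol = solver_abs_tol,
    solver_rel_tol = solver_rel_tol
  ), class = "vp_simulator_spec")
}

#' @export
print.vp_simulator_spec <- function(x, ...) {
  cat("Surrogate simulator spec:",
      length(x$parameter_names), "parameters,",
      length(x$biomarker_names), "biomarkers,",
      length(x$observation_grid), "observation times (weeks",
      paste(range(x$observation_grid), collapse = "-"), ")\n")
  cat("  fitting subset:", paste(x$fit_subset, collapse = ", "), "\n")
  invisible(x)
}

# Merge a (possibly partial) named parameter vector with the reference.
# Entries named "sigma" (the noise scale) are not simulator parameters and
# are ignored here.
complete_theta <- function(theta, spec) {
  full <- spec$reference
  theta <- theta[names(theta) != "sigma"]
  if (length(theta)) {
    unknown <- setdiff(names(theta), spec$parameter_names)
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    full[names(theta)] <- theta
  }
  full
}

validate_theta <- function(theta) {
  if (any(!is.finite(theta)) || any(theta[setdiff(names(theta), c("d0", "d1", "d2"))] <= 0))
    stop("simulator parameters must be finite and strictly positive")
  if (any(theta[c("d0", "d1", "d2")] < 0)) stop("d0, d1, d2 must be >= 0")
  if (theta[["Emax"]] < 0 || theta[["Emax"]] >= 1)
    stop("Emax must lie in [0, 1)")
  invisible(theta)
}

#' Simulate biomarker trajectories for one parametrization
#'
#' Solves the surrogate ODE system numerically (`deSolve::lsoda`) at the
#' spec's tolerances and evaluates the observables on the observation grid.
#' A partial `theta` (e.g. only the fitting subset) is completed with the
#' reference values.
#'
#' @param theta named numeric parameter vector (full or partial); an entry
#'   named `"sigma"` is ignored (it is the observation-noise scale).
#' @param spec a [simulator_spec()].
#' @param times optional observation times; defaults to the spec grid. Must be
#'   a subset of the grid by contract, though any non-negative times solve.
#' @return A `vp_trajectories` object: list with `times` and a numeric matrix
#'   `values` (times x biomarkers), or `NULL` on simulation failure (the
#'   caller must treat the draw as invalid).
#' @examples
#' spec <- simulator_spec()
#' tr <- simulate_trajectories(spec$reference, spec)
#' tr$values[, "CRP_like"]
#' @export
simulate_trajectories <- function(theta, spec, times = spec$observation_grid) {
  th <- complete_theta(theta, spec)
  ok <- tryCatch({ validate_theta(th); TRUE },
                 error = function(e) FALSE)
  if (!ok) return(NULL)

  p0 <- th[["k_p"]] / th[["k_dp"]]
  y0 <- c(P = p0,
          C = th[["k_c"]] * p0 / th[["k_dc"]],
          M = th[["k_m"]] * p0 / th[["k_dm"]])
  deriv <- function(t, y, pars) {
    E <- pars[["Emax"]] * (1 - exp(-pars[["k_on"]] * t))
    list(c(pars[["k_p"]] * (1 - E) - pars[["k_dp"]] * y[1],
           pars[["k_c"]] * y[1] - pars[["k_dc"]] * y[2],
           pars[["k_m"]] * y[1] - pars[["k_dm"]] * y[3]))
  }
  solve_times <- if (times[1] == 0) times else c(0, times)
  out <- tryCatch(
    deSolve::lsoda(y0, solve_times, deriv, th,
                   rtol = spec$solver_rel_tol, atol = spec$solver_abs_tol),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(out) || nrow(out) < length(solve_times) || any(!is.finite(out)))
    return(NULL)
  out <- out[match(times, out[, "time"]), , drop = FALSE]

  P <- out[, "P"]; C <- out[, "C"]; M <- out[, "M"]
  vals <- cbind(CRP_like   = C,
                MMP_like   = M,
                CELL_like  = th[["L0"]] * (1 + th[["a_L"]] * P),
                SCORE_like = th[["d0"]] + th[["d1"]] * log1p(C) + th[["d2"]] * P)
  vals <- vals[, spec$biomarker_names, drop = FALSE]
  if (any(!is.finite(vals)) || any(vals < 0)) return(NULL)
  rownames(vals) <- NULL
  structure(list(times = as.numeric(times), values = vals),
            class = "vp_trajectories")
}
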