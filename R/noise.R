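#' Stochastic simulator: multiplicative lognormal observation noise
#'
#' The deterministic simulator is wrapped into the stochastic simulator used
#' for inference training: every observed value `v` is replaced by
#' `v * exp(eps)`, `eps ~ Normal(0, sigma^2)`, independently per biomarker and
#' time point. The noise scale `sigma` is itself a fitting parameter (last
#' entry of the parameter vector), so the appropriate amount of measurement
#' noise is learned per patient.
#'
#' @name noisy-simulator
NULL

apply_noise_values <- function(values, sigma) {
  if (sigma == 0) return(values)
  values * exp(matrix(stats::rnorm(length(values), 0, sigma),
                      nrow(values), ncol(values)))
}

#' Apply multiplicative lognormal noise to trajectories
#'
#' @param traj a `vp_trajectories` object.
#' @param sigma noise scale (>= 0 on the log scale).
#' @param seed integer seed; draws are reproducible.
#' @return A `vp_trajectories` with noised values (strictly positive whenever
#'   the input is).
#' @export
apply_noise <- function(traj, sigma, seed) {
  if (!is.numeric(sigma) || sigma < 0) stop("sigma must be >= 0")
  vals <- with_seed(seed, apply_noise_values(traj$values, sigma))
  structure(list(times = traj$times, values = vals), class = "vp_trajectories")
}

#' One stochastic forward pass: parameters to normalized summary features
#'
#' Simulates the surrogate at `theta`, restricts the output to the target
#' patient's observation schedule (available biomarkers and their times),
#' applies multiplicative lognormal noise with `theta`'s `sigma`, summarizes,
#' and normalizes with the cohort normalization model. This is the simulated
#' observation `x` the inference engine trains on.
#'
#' @param theta named parameter vector including a `sigma` entry.
#' @param target the `vp_patient` whose observation schedule is imitated.
#' @param spec a [simulator_spec()].
#' @param normalizer the cohort `vp_normalizer`.
#' @param seed integer seed for the noise draws.
#' @return A normalized `vp_summary`, or `NULL` on simulation failure.
#' @export
stochastic_forward <- function(theta, target, spec, normalizer, seed) {
  sigma <- theta[["sigma"]]
  if (is.null(sigma) || is.na(sigma) || sigma < 0) stop("theta must carry sigma >= 0")
  tr <- simulate_trajectories(theta, spec)
  if (is.null(tr)) return(NULL)
  noisy <- with_seed(seed, apply_noise_values(tr$values, sigma))
  series <- list()
  for (b in intersect(spec$biomarker_names, names(target$series))) {
    tt <- target$series[[b]]$times
    idx <- match(tt, tr$times)
    if (any(is.na(idx))) stop("target times must lie on the observation grid")
    series[[b]] <- list(times = tt, values = noisy[idx, b])
  }
  if (!length(series)) stop("target patient has no biomarker on the spec layout")
  vals_ok <- all(vapply(series, function(s) all(is.finite(s$values)), logical(1)))
  if (!vals_ok) return(NULL)
  s <- summarize_patient(list(series = series), spec$biomarker_names)
  normalize_summary(s, normalizer)
}
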