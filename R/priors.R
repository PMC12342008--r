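#' Lognormal priors over virtual-patient parametrizations
#'
#' The prior over the fitted parameters (plus the observation-noise scale,
#' last dimension) is a product of independent lognormals. For a plain fit it
#' is centered on the reference parametrization (`loc = log theta_ref`); for
#' a nearest-patient fit it is centered on the learned parametrization of the
#' most similar already-fitted patient, with the same scale. The lognormal
#' keeps parameters positive and lets a single `scale` cover parameters
#' living on very different magnitudes.
#'
#' @name priors
NULL

#' Build a lognormal prior centered on a parametrization
#'
#' @param center named strictly positive vector over the fitted simulator
#'   parameters. If it carries a `sigma` entry (a learned parametrization
#'   from the knowledge container), that value centers the noise dimension;
#'   otherwise `noise_loc` does.
#' @param scale shared lognormal scale (default 0.25).
#' @param noise_loc center of the noise-scale dimension (default 0.2).
#' @return A `vp_prior`: list with `loc` (log-centers) and `scale` vectors,
#'   named; the noise dimension `sigma` is last.
#' @examples
#' prior_from_center(c(k_p = 10, Emax = 0.6))
#' @export
prior_from_center <- function(center, scale = 0.25, noise_loc = 0.2) {
  stopifnot(is.numeric(center), !is.null(names(center)), scale > 0,
            noise_loc > 0)
  if (any(!is.finite(center)) || any(center <= 0))
    stop("prior center must be strictly positive")
  if ("sigma" %in% names(center)) {
    noise_loc <- center[["sigma"]]
    center <- center[names(center) != "sigma"]
  }
  loc <- c(log(center), sigma = log(noise_loc))
  structure(list(loc = loc,
                 scale = stats::setNames(rep(scale, length(loc)), names(loc))),
            class = "vp_prior")
}

#' @export
print.vp_prior <- function(x, ...) {
  cat("Lognormal prior over", length(x$loc), "dimensions (scale",
      x$scale[[1]], "):\n  medians:\n")
  print(exp(x$loc))
  invisible(x)
}

#' Sample parameter vectors from a prior
#'
#' @param prior a `vp_prior`.
#' @param n number of draws.
#' @param seed integer seed.
#' @return Numeric matrix `n x dim` with parameter names as columns; all
#'   entries strictly positive.
#' @export
prior_sample <- function(prior, n, seed) {
  stopifnot(n >= 1)
  d <- length(prior$loc)
  with_seed(seed, {
    z <- matrix(stats::rnorm(n * d), n, d)
    th <- exp(sweep(sweep(z, 2, prior$scale, `*`), 2, prior$loc, `+`))
    colnames(th) <- names(prior$loc)
    th
  })
}

#' Prior log-density of a parameter vector
#'
#' Sum of independent lognormal log-densities; `-Inf` outside the positive
#' support.
#'
#' @param prior a `vp_prior`.
#' @param theta named vector (or matrix with named columns) on the prior's
#'   dimensions.
#' @return Log-density (vector when `theta` is a matrix).
#' @export
prior_log_density <- function(prior, theta) {
  if (is.null(dim(theta))) theta <- matrix(theta, 1,
                                           dimnames = list(NULL, names(theta)))
  theta <- theta[, names(prior$loc), drop = FALSE]
  apply(theta, 1, function(t) {
    if (any(!is.finite(t)) || any(t <= 0)) return(-Inf)
    sum(stats::dlnorm(t, prior$loc, prior$scale, log = TRUE))
  })
}
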