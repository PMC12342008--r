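#' Local-optimizer baseline fit
#'
#' A derivative-free point-estimate comparator: Nelder-Mead simplex descent
#' on the max-scaled fit loss, started from the reference parametrization,
#' with box bounds set twofold around the reference (`[ref/2, 2*ref]`,
#' `Emax` capped below 1) enforced through a logistic reparametrization.
#' The noise scale plays no role (evaluation is noise-free).
#'
#' @param patient a `vp_patient`.
#' @param spec a [simulator_spec()].
#' @param maxit Nelder-Mead iteration budget.
#' @return A `vp_fit_result` with `prior_source = "baseline"`, no posterior
#'   and `frac_better = NA`.
#' @export
fit_baseline <- function(patient, spec, maxit = 400) {
  ref <- spec$reference[spec$fit_subset]
  lower <- ref / 2
  upper <- ref * 2
  if ("Emax" %in% names(ref))
    upper[["Emax"]] <- min(upper[["Emax"]], 0.999)
  to_theta <- function(u) lower + (upper - lower) * stats::plogis(u)
  u0 <- stats::qlogis((ref - lower) / (upper - lower))
  loss_ref <- fit_loss(spec$reference, patient, spec)
  obj <- function(u) {
    l <- fit_loss(to_theta(u), patient, spec)
    if (!is.finite(l)) 1e6 else l
  }
  opt <- stats::optim(u0, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit))
  theta <- c(to_theta(opt$par), sigma = NA_real_)
  res <- structure(list(
    patient_id = patient$patient_id, posterior = NULL,
    theta_best = theta, loss_best = opt$value, loss_ref = loss_ref,
    gap = if (is.finite(loss_ref) && loss_ref > 0)
      (loss_ref - opt$value) / loss_ref else NA_real_,
    frac_better = NA_real_, prior_source = "baseline",
    gate_passed = NA, round_logs = list(), error = NULL),
    class = "vp_fit_result")
  res$gate_passed <- quality_gate(res)
  res
}
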