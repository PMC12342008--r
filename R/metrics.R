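#' Evaluation metrics for virtual-patient fits
#'
#' Fit quality compares the noise-free simulation to the patient's clinical
#' observations with a max-scaled squared loss,
#' \deqn{L(\theta, c) = \frac{1}{\sum_b T_b} \sum_b \sum_t
#'   \left(\frac{sim_{b,t}(\theta) - c_{b,t}}{\max_t c_{b,t}}\right)^2}
#' so biomarkers on different scales weigh equally. Performance against the
#' reference parametrization is the relative loss reduction
#' `gap = (L_ref - L) / L_ref` (1 = perfect fit, 0 = no improvement, < 0 =
#' worse than reference). For a learned posterior, the ultimate
#' parametrization is the best of `n` (default 100) posterior samples, and
#' the fraction of those samples beating the reference loss summarizes the
#' quality of the whole distribution.
#'
#' @name metrics
NULL

#' Max-scaled fit loss of a parametrization on a patient
#'
#' Simulation is noise-free (the noise scale models measurement error, not
#' biology) and evaluated exactly at the patient's observation times.
#' Biomarkers absent from the record contribute nothing; a biomarker whose
#' observed maximum is 0 is skipped with a warning.
#'
#' @param theta named parameter vector (partial vectors completed with the
#'   reference; a `sigma` entry is ignored).
#' @param patient a `vp_patient`.
#' @param spec a [simulator_spec()].
#' @return Nonnegative real, or `NA` if the simulation fails.
#' @examples
#' spec <- simulator_spec()
#' p <- generate_cohort(1, spec, seed = 3)$patients[[1]]
#' fit_loss(spec$reference, p, spec)
#' @export
fit_loss <- function(theta, patient, spec) {
  tr <- simulate_trajectories(theta, spec)
  if (is.null(tr)) return(NA_real_)
  num <- 0; n_obs <- 0L
  for (b in intersect(spec$biomarker_names, names(patient$series))) {
    s <- patient$series[[b]]
    cmax <- max(s$values)
    if (cmax == 0) {
      warning("biomarker ", b, " has observed max 0; skipped")
      next
    }
    idx <- match(s$times, tr$times)
    if (any(is.na(idx))) stop("observation times off the simulation grid")
    num <- num + sum(((tr$values[idx, b] - s$values) / cmax)^2)
    n_obs <- n_obs + length(s$times)
  }
  if (n_obs == 0L) return(NA_real_)
  num / n_obs
}

#' Relative loss reduction (gap) against the reference parametrization
#'
#' @inheritParams fit_loss
#' @param loss_ref optionally, the precomputed reference loss.
#' @return `(L_ref - L(theta)) / L_ref`, always <= 1; `NA` with a warning if
#'   the reference loss is 0 (reference already perfect).
#' @export
fit_gap <- function(theta, patient, spec,
                    loss_ref = fit_loss(spec$reference, patient, spec)) {
  if (!is.finite(loss_ref)) return(NA_real_)
  if (loss_ref == 0) {
    warning("reference loss is 0; gap undefined")
    return(NA_real_)
  }
  (loss_ref - fit_loss(theta, patient, spec)) / loss_ref
}

# Draw n posterior samples and evaluate the fit loss of each (noise-free).
evaluate_posterior_samples <- function(model, patient, spec, n, seed) {
  th <- posterior_sample(model, n, seed)
  losses <- apply(th, 1, fit_loss, patient = patient, spec = spec)
  if (all(is.na(losses))) stop("all posterior-sample simulations failed")
  list(theta = th, losses = losses)
}

#' Best parametrization out of n posterior samples
#'
#' @param model a `vp_posterior`.
#' @param patient a `vp_patient`.
#' @param spec a [simulator_spec()].
#' @param n number of posterior draws (default 100).
#' @param seed integer seed; with equal seeds, [frac_better()] uses the same
#'   draws.
#' @return List with `theta` (the argmin sample, ties by first occurrence)
#'   and `loss`.
#' @export
best_of_posterior <- function(model, patient, spec, n = 100, seed = 1L) {
  stopifnot(n >= 1)
  ev <- evaluate_posterior_samples(model, patient, spec, n, seed)
  k <- which.min(ev$losses)
  list(theta = ev$theta[k, ], loss = ev$losses[[k]])
}

#' Fraction of posterior samples beating the reference parametrization
#'
#' @inheritParams best_of_posterior
#' @param loss_ref optionally, the precomputed reference loss.
#' @return Fraction in `[0, 1]` of draws with strictly smaller loss than the
#'   reference.
#' @export
frac_better <- function(model, patient, spec, n = 100, seed = 1L,
                        loss_ref = fit_loss(spec$reference, patient, spec)) {
  ev <- evaluate_posterior_samples(model, patient, spec, n, seed)
  mean(ev$losses < loss_ref, na.rm = TRUE)
}

#' Population-level evaluation report
#'
#' Assembles per-patient metrics, pooled observed-vs-simulated value pairs
#' per biomarker (visual-predictive-check input) and week-24 endpoint
#' distributions, all at each patient's best parametrization.
#'
#' @param results list of `vp_fit_result` (see [run_pipeline()]).
#' @param cohort list of `vp_patient`, aligned with `results` by patient id.
#' @param spec a [simulator_spec()].
#' @param endpoint_week landmark week for the endpoint table (default 24).
#' @return A `vp_report`: list of data frames `per_patient`
#'   (patient_id, loss_ref, loss_fit, gap, frac_better, gate_passed,
#'   prior_source), `pooled_pairs` (patient_id, biomarker, time_weeks,
#'   observed, simulated) and `endpoints` (patient_id, biomarker, observed,
#'   simulated at the landmark week).
#' @export
evaluation_report <- function(results, cohort, spec, endpoint_week = 24) {
  ids_res <- vapply(results, function(r) r$patient_id, character(1))
  ids_coh <- vapply(cohort, function(p) p$patient_id, character(1))
  if (!setequal(ids_res, ids_coh) || anyDuplicated(ids_res))
    stop("results and cohort patient ids do not align")
  cohort <- cohort[match(ids_res, ids_coh)]

  per_patient <- do.call(rbind, lapply(results, function(r)
    data.frame(patient_id = r$patient_id,
               loss_ref = r$loss_ref, loss_fit = r$loss_best,
               gap = r$gap, frac_better = r$frac_better,
               gate_passed = r$gate_passed, prior_source = r$prior_source)))

  pooled <- list(); ends <- list()
  for (k in seq_along(results)) {
    r <- results[[k]]; p <- cohort[[k]]
    if (is.null(r$theta_best)) next
    tr <- simulate_trajectories(r$theta_best, spec)
    if (is.null(tr)) next
    for (b in intersect(spec$biomarker_names, names(p$series))) {
      s <- p$series[[b]]
      idx <- match(s$times, tr$times)
      pooled[[length(pooled) + 1L]] <- data.frame(
        patient_id = p$patient_id, biomarker = b, time_weeks = s$times,
        observed = s$values, simulated = tr$values[idx, b])
      at_end <- which(s$times == endpoint_week)
      if (length(at_end))
        ends[[length(ends) + 1L]] <- data.frame(
          patient_id = p$patient_id, biomarker = b,
          observed = s$values[at_end[1]],
          simulated = tr$values[match(endpoint_week, tr$times), b])
    }
  }
  structure(list(per_patient = per_patient,
                 pooled_pairs = do.call(rbind, pooled),
                 endpoints = do.call(rbind, ends)),
            class = "vp_report")
}

#' Write an evaluation report as CSV tables
#'
#' @param report a `vp_report`.
#' @param dir output directory (created if needed); writes
#'   `per_patient.csv`, `pooled_pairs.csv`, `endpoints.csv`.
#' @export
write_report_csv <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("per_patient", "pooled_pairs", "endpoints"))
    if (!is.null(report[[nm]]))
      utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  invisible(dir)
}
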