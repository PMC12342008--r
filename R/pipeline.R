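#' Cohort fitting: plain SBI and the nearest-patient-fit pipeline
#'
#' In `sbi` mode every patient is fitted independently with the
#' reference-centered prior. In `npf` mode fitting is a sequential
#' procedure: a knowledge container is initialized with the reference
#' patient; each step selects the batch of pending patients nearest to the
#' container, fits each with a prior centered on the learned parametrization
#' of its nearest container entry, and admits fits that beat the reference
#' loss (the quality gate) to the container for reuse by later batches.
#' Gate-failing fits stay in the learned virtual-patient population but
#' contribute no container entry.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param mode `"sbi"` or `"npf"`.
#' @param batch_size patients fitted per step in `npf` mode (default 4:
#'   small batches let the container grow before most patients are assigned
#'   priors).
#' @param engine a [engine_config()].
#' @param prior_scale shared lognormal prior scale (default 0.25).
#' @param noise_loc prior center of the noise-scale dimension (default 0.2).
#' @param n_posterior_samples draws for best-of-posterior evaluation
#'   (default 100).
#' @param seed master seed; per-patient seeds are derived from it and the
#'   patient id, so results are order-independent within a batch.
#' @return A `vp_pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("sbi", "npf"), batch_size = 4,
                            engine = engine_config(), prior_scale = 0.25,
                            noise_loc = 0.2, n_posterior_samples = 100,
                            seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(batch_size >= 1, prior_scale > 0, noise_loc > 0,
            n_posterior_samples >= 1)
  structure(list(mode = mode, batch_size = as.integer(batch_size),
                 engine = engine, prior_scale = prior_scale,
                 noise_loc = noise_loc,
                 n_posterior_samples = as.integer(n_posterior_samples),
                 seed = as.integer(seed)),
            class = "vp_pipeline_config")
}

#' Initialize the knowledge container with the reference patient
#'
#' The reference patient is the noise-free simulation of the reference
#' parametrization on the full observation grid, summarized and normalized
#' with the cohort model, paired with the reference parameters (and the
#' configured noise-scale center).
#'
#' @param spec a [simulator_spec()].
#' @param normalizer the cohort `vp_normalizer`.
#' @param noise_loc noise-scale value stored with the reference entry.
#' @return A `vp_container` with the single reference entry.
#' @export
init_container <- function(spec, normalizer, noise_loc = 0.2) {
  tr <- simulate_trajectories(spec$reference, spec)
  if (is.null(tr)) stop("reference simulation failed")
  series <- lapply(stats::setNames(spec$biomarker_names, spec$biomarker_names),
                   function(b) list(times = tr$times, values = tr$values[, b]))
  s <- summarize_patient(list(series = series), spec$biomarker_names)
  theta_ref <- c(spec$reference[spec$fit_subset], sigma = noise_loc)
  structure(list(
    entries = list(reference = list(summary = normalize_summary(s, normalizer),
                                    theta = theta_ref, loss = NA_real_)),
    reference_id = "reference"),
    class = "vp_container")
}

#' @export
print.vp_container <- function(x, ...) {
  cat("Knowledge container:", length(x$entries), "entries (",
      paste(names(x$entries), collapse = ", "), ")\n")
  invisible(x)
}

container_add <- function(container, patient_id, summary, theta, loss) {
  if (patient_id %in% names(container$entries))
    stop("container entries are immutable; ", patient_id, " already present")
  container$entries[[patient_id]] <-
    list(summary = summary, theta = theta, loss = loss)
  container
}

#' Select the batch of pending patients nearest to the container
#'
#' @param pending named list (by patient id) of normalized `vp_summary`.
#' @param container a `vp_container`.
#' @param batch_size number of patients to select.
#' @return Data frame `patient_id`, `nearest_id`, `distance`: the
#'   `batch_size` pending patients with smallest distance to their nearest
#'   container entry (ties by patient id), each paired with that entry.
#' @export
select_batch <- function(pending, container, batch_size) {
  stopifnot(length(pending) >= 1, batch_size >= 1)
  ids <- names(pending)
  nearest <- vapply(ids, function(id) nearest_entry(pending[[id]], container),
                    character(1))
  d <- vapply(ids, function(id)
    summary_distance(pending[[id]], container$entries[[nearest[[id]]]]$summary),
    numeric(1))
  o <- order(d, ids)
  take <- o[seq_len(min(batch_size, length(ids)))]
  data.frame(patient_id = ids[take], nearest_id = unname(nearest[take]),
             distance = unname(d[take]), stringsAsFactors = FALSE)
}

#' Quality gate: does a fit beat the reference parametrization?
#'
#' @param result a `vp_fit_result`.
#' @return `TRUE` iff the fit's best loss is strictly smaller than the
#'   patient's reference loss.
#' @export
quality_gate <- function(result) {
  isTRUE(is.finite(result$loss_best) && is.finite(result$loss_ref) &&
           result$loss_best < result$loss_ref)
}

# Fit + evaluate one patient; errors become a failed vp_fit_result.
fit_one <- function(patient, x_o, prior, prior_source, spec, normalizer, cfg) {
  pid <- patient$patient_id
  seed_fit <- derive_seed(cfg$seed, pid, "fit")
  forward <- function(theta, seed) {
    tryCatch(stochastic_forward(theta, patient, spec, normalizer, seed),
             error = function(e) NULL)
  }
  eng <- cfg$engine
  eng$seed <- seed_fit
  loss_ref <- tryCatch(fit_loss(spec$reference, patient, spec),
                       error = function(e) NA_real_)
  out <- tryCatch({
    fit <- fit_patient(x_o, prior, forward, eng)
    # one shared draw set: best-of-posterior and fraction-better are
    # computed from the same samples (seeds match by construction)
    ev <- evaluate_posterior_samples(fit$model, patient, spec,
                                     n = cfg$n_posterior_samples,
                                     seed = derive_seed(cfg$seed, pid, "eval"))
    k <- which.min(ev$losses)
    fb <- mean(ev$losses < loss_ref, na.rm = TRUE)
    res <- structure(list(
      patient_id = pid, posterior = fit$model, theta_best = ev$theta[k, ],
      loss_best = ev$losses[[k]], loss_ref = loss_ref,
      gap = if (loss_ref > 0) (loss_ref - ev$losses[[k]]) / loss_ref else NA_real_,
      frac_better = fb, prior_source = prior_source,
      gate_passed = NA, round_logs = fit$round_logs, error = NULL),
      class = "vp_fit_result")
    res$gate_passed <- quality_gate(res)
    res
  }, error = function(e) {
    structure(list(
      patient_id = pid, posterior = NULL, theta_best = NULL,
      loss_best = NA_real_, loss_ref = loss_ref, gap = NA_real_,
      frac_better = NA_real_, prior_source = prior_source,
      gate_passed = FALSE, round_logs = list(),
      error = conditionMessage(e)), class = "vp_fit_result")
  })
  out
}

#' @export
print.vp_fit_result <- function(x, ...) {
  cat("Fit", x$patient_id, "- loss", format(x$loss_best, digits = 4),
      "(ref", format(x$loss_ref, digits = 4), ") gap",
      format(x$gap, digits = 3), "frac_better", format(x$frac_better),
      "gate", x$gate_passed, "prior from", x$prior_source, "\n")
  if (!is.null(x$error)) cat("  FAILED:", x$error, "\n")
  invisible(x)
}

#' Fit a whole cohort
#'
#' @param cohort list of `vp_patient`.
#' @param spec a [simulator_spec()].
#' @param config a [pipeline_config()].
#' @param normalizer optionally a prefitted `vp_normalizer`; by default it is
#'   fitted on the cohort's raw summaries.
#' @param verbose emit one log line per fitted patient to `stderr`.
#' @return List of `vp_fit_result`, one per patient, in cohort order, with
#'   attribute `container` (the final knowledge container in `npf` mode).
#' @export
run_pipeline <- function(cohort, spec, config = pipeline_config(),
                         normalizer = NULL, verbose = FALSE) {
  stopifnot(length(cohort) >= 1)
  ids <- vapply(cohort, function(p) p$patient_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate patient ids")
  raw <- lapply(cohort, summarize_patient, biomarker_names = spec$biomarker_names)
  if (is.null(normalizer)) normalizer <- fit_normalizer(raw)
  summaries <- stats::setNames(lapply(raw, normalize_summary, normalizer = normalizer), ids)

  ref_center <- spec$reference[spec$fit_subset]
  ref_prior <- prior_from_center(ref_center, config$prior_scale, config$noise_loc)
  results <- stats::setNames(vector("list", length(ids)), ids)
  log_line <- function(r, src) if (verbose)
    message(sprintf("[%s] fit %s prior=%s loss=%.4g ref=%.4g gate=%s",
                    format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), r$patient_id,
                    src, r$loss_best, r$loss_ref, r$gate_passed))

  if (config$mode == "sbi") {
    for (k in seq_along(ids)) {
      results[[ids[k]]] <- fit_one(cohort[[k]], summaries[[ids[k]]],
                                   ref_prior, "reference", spec, normalizer,
                                   config)
      log_line(results[[ids[k]]], "reference")
    }
    container <- NULL
  } else {
    container <- init_container(spec, normalizer, config$noise_loc)
    pending <- summaries
    while (length(pending)) {
      batch <- select_batch(pending, container, config$batch_size)
      batch_results <- list()
      for (k in seq_len(nrow(batch))) {
        pid <- batch$patient_id[k]
        src <- batch$nearest_id[k]
        prior <- prior_from_center(container$entries[[src]]$theta,
                                   config$prior_scale, config$noise_loc)
        r <- fit_one(cohort[[match(pid, ids)]], summaries[[pid]], prior,
                     src, spec, normalizer, config)
        batch_results[[pid]] <- r
        log_line(r, src)
      }
      # container frozen during the batch; extended only after it completes
      for (pid in names(batch_results)) {
        r <- batch_results[[pid]]
        results[[pid]] <- r
        if (isTRUE(r$gate_passed))
          container <- container_add(container, pid, summaries[[pid]],
                                     r$theta_best, r$loss_best)
      }
      pending <- pending[setdiff(names(pending), batch$patient_id)]
    }
  }
  structure(unname(results[ids]), container = container)
}
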