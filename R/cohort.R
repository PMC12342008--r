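#' Patient records and synthetic cohorts
#'
#' A `vp_patient` holds one patient's observed biomarker time series with
#' per-biomarker missingness: a patient id and, per available biomarker, a
#' pair of vectors (times in weeks, strictly positive values). The synthetic
#' cohort generator emulates the structure of sparse clinical trial data:
#' large inter-patient variability around a reference parametrization,
#' multiplicative lognormal measurement noise, per-patient missing biomarkers
#' and locally missing time points.
#'
#' @name cohorts
NULL

#' Construct a patient record
#'
#' @param patient_id character id.
#' @param series named list; each element a list with numeric `times` and
#'   `values` of equal length. Values must be > 0, times within `[0, 24]`
#'   weeks, at most 8 points per biomarker.
#' @return A `vp_patient` object.
#' @export
patient_record <- function(patient_id, series) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L,
            is.list(series), length(series) >= 1L, !is.null(names(series)))
  for (b in names(series)) {
    s <- series[[b]]
    if (length(s$times) < 1L || length(s$times) != length(s$values))
      stop("biomarker ", b, ": times/values must be non-empty and aligned")
    if (length(s$times) > 8L)
      stop("biomarker ", b, ": at most 8 time points per biomarker")
    if (any(s$times < 0) || any(s$times > 24))
      stop("biomarker ", b, ": times must lie in [0, 24] weeks")
    if (any(!is.finite(s$values)) || any(s$values <= 0))
      stop("biomarker ", b, ": values must be finite and > 0")
  }
  structure(list(patient_id = patient_id, series = series),
            class = "vp_patient")
}

#' @export
print.vp_patient <- function(x, ...) {
  cat("Patient", x$patient_id, "-", length(x$series), "biomarker series:\n")
  for (b in names(x$series))
    cat("  ", b, ": ", length(x$series[[b]]$times), " obs (weeks ",
        paste(x$series[[b]]$times, collapse = ","), ")\n", sep = "")
  invisible(x)
}

#' Generate a synthetic patient cohort with ground truth
#'
#' Each patient's true parameters (fitting subset of the spec) are drawn
#' independently per parameter from `LogNormal(log(ref), pop_scale)`; `Emax`
#' draws are rejected until `Emax < 1` so that every generated patient is
#' simulable. Trajectories are simulated noise-free, then multiplicative
#' lognormal noise with a per-patient scale drawn uniformly from
#' `noise_scale_range` is applied. Non-core biomarkers are dropped per patient
#' with probability `biomarker_dropout`; non-baseline time points are dropped
#' independently per biomarker with probability `timepoint_dropout`.
#'
#' @param n_patients number of patients (>= 1).
#' @param spec a [simulator_spec()].
#' @param pop_scale lognormal population scale on the log of each fitted
#'   parameter (default 0.35, a heavy inter-patient variability setting).
#' @param biomarker_dropout probability in `[0, 1)` that a non-core biomarker
#'   is missing for a patient.
#' @param timepoint_dropout probability in `[0, 1)` that a non-baseline
#'   observation is missing.
#' @param noise_scale_range interval the per-patient lognormal noise scale is
#'   drawn from, uniformly.
#' @param seed integer seed; cohorts are bitwise reproducible from it.
#' @return List with `patients` (list of `vp_patient`) and `truth`, a data
#'   frame with one row per patient: the generating parameter values and the
#'   true noise scale `sigma`.
#' @examples
#' spec <- simulator_spec()
#' ch <- generate_cohort(3, spec, seed = 1)
#' ch$truth
#' @export
generate_cohort <- function(n_patients, spec,
                            pop_scale = 0.35,
                            biomarker_dropout = 0.2,
                            timepoint_dropout = 0.2,
                            noise_scale_range = c(0.05, 0.2),
                            seed = 1L) {
  stopifnot(n_patients >= 1,
            pop_scale >= 0,
            biomarker_dropout >= 0, biomarker_dropout < 1,
            timepoint_dropout >= 0, timepoint_dropout < 1,
            length(noise_scale_range) == 2L,
            noise_scale_range[1] >= 0,
            diff(noise_scale_range) >= 0)
  if (length(spec$core_biomarkers) == 0 && biomarker_dropout > 0)
    stop("degenerate config: every biomarker droppable")
  fit_names <- spec$fit_subset
  ref <- spec$reference[fit_names]
  ids <- sprintf("P%03d", seq_len(n_patients))

  patients <- vector("list", n_patients)
  truth <- matrix(NA_real_, n_patients, length(fit_names) + 1,
                  dimnames = list(ids, c(fit_names, "sigma")))
  noncore <- setdiff(spec$biomarker_names, spec$core_biomarkers)

  with_seed(seed, {
    for (i in seq_len(n_patients)) {
      repeat {
        th <- ref * exp(stats::rnorm(length(ref), 0, pop_scale))
        if (!("Emax" %in% fit_names) || th[["Emax"]] < 1) break
      }
      sig <- stats::runif(1, noise_scale_range[1], noise_scale_range[2])
      tr <- simulate_trajectories(th, spec)
      if (is.null(tr)) stop("internal: reference-bulk simulation failed")
      noisy <- apply_noise_values(tr$values, sig)

      keep_b <- spec$biomarker_names
      if (length(noncore) && biomarker_dropout > 0) {
        drop_b <- noncore[stats::runif(length(noncore)) < biomarker_dropout]
        keep_b <- setdiff(keep_b, drop_b)
      }
      series <- list()
      for (b in keep_b) {
        keep_t <- rep(TRUE, length(tr$times))
        if (timepoint_dropout > 0)
          keep_t[-1] <- stats::runif(length(tr$times) - 1) >= timepoint_dropout
        series[[b]] <- list(times = tr$times[keep_t],
                            values = unname(noisy[keep_t, b]))
      }
      patients[[i]] <- patient_record(ids[i], series)
      truth[i, ] <- c(th, sigma = sig)
    }
  })
  truth_df <- data.frame(patient_id = ids, truth, row.names = NULL,
                         check.names = FALSE)
  list(patients = patients, truth = truth_df)
}

#' Write / read a cohort as long-format CSV
#'
#' Columns: `patient_id, biomarker, time_weeks, value`.
#'
#' @param patients list of `vp_patient`.
#' @param path CSV file path.
#' @return `read_cohort_csv` returns a list of `vp_patient` ordered by id.
#' @export
write_cohort_csv <- function(patients, path) {
  rows <- do.call(rbind, lapply(patients, function(p) {
    do.call(rbind, lapply(names(p$series), function(b) {
      s <- p$series[[b]]
      data.frame(patient_id = p$patient_id, biomarker = b,
                 time_weeks = s$times, value = s$values)
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "biomarker", "time_weeks", "value")
  if (!all(need %in% names(df)))
    stop("cohort CSV must have columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$patient_id), function(d) {
    series <- lapply(split(d, d$biomarker), function(s) {
      o <- order(s$time_weeks)
      list(times = s$time_weeks[o], values = s$value[o])
    })
    patient_record(d$patient_id[1], series)
  })
}

#' Write the cohort ground truth as CSV
#' @param truth data frame as returned in `generate_cohort()$truth`.
#' @param path CSV file path.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
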