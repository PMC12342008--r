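#' HDF5 results exchange
#'
#' Fit results are exchanged as HDF5 files with one group per patient:
#' `/patients/<id>/{samples, parameter_names, theta_best, losses,
#' round_losses, gap, frac_better, prior_source}`, where `samples` is an
#' `n x dim` matrix of posterior draws, `losses` holds
#' `(loss_best, loss_ref)` and `round_losses` the mean training loss per
#' engine round. Numeric payloads round-trip bitwise.
#'
#' @name results-io
NULL

#' Write fit results to HDF5
#'
#' @param results list of `vp_fit_result` (see [run_pipeline()]).
#' @param path output `.h5` file (overwritten).
#' @param n_samples posterior draws exported per patient (default 100).
#' @param seed integer seed for the exported draws (per-patient streams are
#'   derived from it and the patient id).
#' @export
write_results <- function(results, path, n_samples = 100, seed = 1L) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "patients")
  for (r in results) {
    grp <- paste0("patients/", r$patient_id)
    rhdf5::h5createGroup(path, grp)
    if (!is.null(r$posterior)) {
      s <- posterior_sample(r$posterior, n_samples,
                            derive_seed(seed, r$patient_id, "export"))
      rhdf5::h5write(unclass(s), path, paste0(grp, "/samples"))
      rhdf5::h5write(colnames(s), path, paste0(grp, "/parameter_names"))
    }
    if (!is.null(r$theta_best)) {
      rhdf5::h5write(unname(r$theta_best), path, paste0(grp, "/theta_best"))
      if (is.null(r$posterior))
        rhdf5::h5write(names(r$theta_best), path, paste0(grp, "/parameter_names"))
    }
    if (length(r$round_logs))
      rhdf5::h5write(vapply(r$round_logs, function(l) mean(l$losses),
                            numeric(1)),
                     path, paste0(grp, "/round_losses"))
    rhdf5::h5write(c(r$loss_best, r$loss_ref), path, paste0(grp, "/losses"))
    rhdf5::h5write(as.numeric(r$gap), path, paste0(grp, "/gap"))
    rhdf5::h5write(as.numeric(r$frac_better), path, paste0(grp, "/frac_better"))
    rhdf5::h5write(as.character(r$prior_source), path, paste0(grp, "/prior_source"))
  }
  invisible(path)
}

#' Read fit results back from HDF5
#'
#' Each patient group is read independently: a corrupt or incomplete group
#' yields an entry with an `error` message while the others load normally.
#'
#' @param path `.h5` file written by [write_results()].
#' @return Named list (by patient id); each entry has `samples`,
#'   `parameter_names`, `theta_best`, `loss_best`, `loss_ref`, `gap`,
#'   `frac_better`, `prior_source` (or `error`).
#' @export
read_results <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  ids <- sort(ls$name[ls$group == "/patients"])
  out <- list()
  for (id in ids) {
    grp <- paste0("patients/", id)
    have <- ls$name[ls$group == paste0("/", grp)]
    out[[id]] <- tryCatch({
      need <- c("losses", "gap", "frac_better", "prior_source")
      if (!all(need %in% have))
        stop("missing datasets: ", paste(setdiff(need, have), collapse = ", "))
      losses <- rhdf5::h5read(path, paste0(grp, "/losses"))
      pn <- if ("parameter_names" %in% have)
        as.character(rhdf5::h5read(path, paste0(grp, "/parameter_names")))
      else NULL
      samples <- if ("samples" %in% have) {
        s <- rhdf5::h5read(path, paste0(grp, "/samples"))
        colnames(s) <- pn
        s
      } else NULL
      theta_best <- if ("theta_best" %in% have) {
        tb <- as.numeric(rhdf5::h5read(path, paste0(grp, "/theta_best")))
        names(tb) <- pn
        tb
      } else NULL
      round_losses <- if ("round_losses" %in% have)
        as.numeric(rhdf5::h5read(path, paste0(grp, "/round_losses")))
      else NULL
      list(patient_id = id, samples = samples, parameter_names = pn,
           theta_best = theta_best, round_losses = round_losses,
           loss_best = losses[1], loss_ref = losses[2],
           gap = as.numeric(rhdf5::h5read(path, paste0(grp, "/gap"))),
           frac_better = as.numeric(rhdf5::h5read(path, paste0(grp, "/frac_better"))),
           prior_source = as.character(rhdf5::h5read(path, paste0(grp, "/prior_source"))))
    }, error = function(e) list(patient_id = id, error = conditionMessage(e)))
  }
  out
}
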