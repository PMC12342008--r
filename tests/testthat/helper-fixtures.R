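# Shared fixtures: everything is generated in code at test time.

test_spec <- function(...) simulator_spec(...)

# A deterministic patient built directly from given series.
make_patient <- function(id = "T1", series = list(
  CRP_like = list(times = c(0, 4, 12, 24), values = c(40, 30, 20, 15)),
  SCORE_like = list(times = c(0, 12, 24), values = c(8, 6, 5)))) {
  patient_record(id, series)
}

# A noise-free synthetic patient whose observations are exactly the
# simulated trajectories at theta (full grid, all biomarkers).
exact_patient <- function(theta, spec, id = "EX") {
  tr <- simulate_trajectories(theta, spec)
  stopifnot(!is.null(tr))
  series <- lapply(stats::setNames(spec$biomarker_names, spec$biomarker_names),
                   function(b) list(times = tr$times, values = tr$values[, b]))
  patient_record(id, series)
}

# Random raw summary vectors over a given biomarker universe, with optional
# per-biomarker missingness.
random_summary <- function(biomarkers, p_missing = 0.3) {
  avail <- stats::runif(length(biomarkers)) >= p_missing
  if (!any(avail)) avail[sample(length(biomarkers), 1)] <- TRUE
  feats <- rep(NA_real_, 2 * length(biomarkers))
  names(feats) <- vpsbi:::feature_names(biomarkers)
  for (b in biomarkers[avail]) {
    feats[paste0(b, "_median")] <- stats::rnorm(1)
    feats[paste0(b, "_spread")] <- stats::rnorm(1)
  }
  vpsbi:::new_summary(feats, stats::setNames(avail, biomarkers),
                      normalized = TRUE)
}

# Brute-force reference implementation of the similarity metric: explicit
# loop over features of common biomarkers.
distance_oracle <- function(a, b) {
  av <- attr(a, "available") & attr(b, "available")
  if (!any(av)) return(Inf)
  cb <- names(av)[av]
  acc <- 0
  for (bm in cb)
    for (suf in c("_median", "_spread"))
      acc <- acc + (a[[paste0(bm, suf)]] - b[[paste0(bm, suf)]])^2
  sqrt(3 / (2 * length(cb)) * acc)
}

# Naive double-loop reference implementation of the max-scaled fit loss.
loss_oracle <- function(theta, patient, spec) {
  tr <- simulate_trajectories(theta, spec)
  total <- 0
  n <- 0
  for (b in names(patient$series)) {
    s <- patient$series[[b]]
    cmax <- max(s$values)
    for (k in seq_along(s$times)) {
      simv <- unname(tr$values[which(tr$times == s$times[k]), b])
      total <- total + ((simv - s$values[k]) / cmax)^2
      n <- n + 1
    }
  }
  total / n
}
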