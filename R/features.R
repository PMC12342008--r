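#' Summary features and missing-data-aware patient similarity
#'
#' Each biomarker time series is reduced to two statistics: its median and
#' its quantile spread (0.9-quantile minus 0.1-quantile, linear-interpolation
#' convention), giving a `2K`-dimensional representation for `K` available
#' biomarkers. Similarity between patients is the Euclidean distance in the
#' robustly normalized feature space, restricted to the biomarkers both
#' patients share and rescaled so the value is stable across different
#' overlap sizes:
#' \deqn{d(P_i, P_j) = \sqrt{\frac{3}{2|CB|} \sum_{b \in CB}
#'   (m_{i,b}-m_{j,b})^2 + (s_{i,b}-s_{j,b})^2}}
#' where `CB` is the set of common biomarkers.
#'
#' @name features
NULL

#' Summarize a patient record into a (median, spread) feature vector
#'
#' @param patient a `vp_patient` (or anything with a named `series` list).
#' @param biomarker_names the full biomarker universe defining the feature
#'   layout; biomarkers absent from the record are masked (`NA`).
#' @return A `vp_summary` object: named numeric vector of length
#'   `2 * length(biomarker_names)` with entries `<biomarker>_median`,
#'   `<biomarker>_spread` (`NA` where masked), attribute `available`
#'   (logical mask per biomarker) and `normalized = FALSE`.
#' @examples
#' p <- patient_record("A", list(CRP_like = list(times = 0:4, values = 1:5)))
#' summarize_patient(p, "CRP_like")
#' @export
summarize_patient <- function(patient, biomarker_names) {
  series <- patient$series
  if (is.null(series) || length(series) == 0)
    stop("empty patient record")
  feats <- rep(NA_real_, 2L * length(biomarker_names))
  names(feats) <- feature_names(biomarker_names)
  avail <- stats::setNames(biomarker_names %in% names(series), biomarker_names)
  for (b in intersect(biomarker_names, names(series))) {
    v <- series[[b]]$values
    q <- stats::quantile(v, c(0.1, 0.5, 0.9), names = FALSE, type = 7)
    feats[paste0(b, "_median")] <- q[2]
    feats[paste0(b, "_spread")] <- q[3] - q[1]
  }
  new_summary(feats, avail, normalized = FALSE)
}

feature_names <- function(biomarker_names)
  as.vector(rbind(paste0(biomarker_names, "_median"),
                  paste0(biomarker_names, "_spread")))

new_summary <- function(feats, avail, normalized) {
  structure(feats, available = avail, normalized = normalized,
            class = "vp_summary")
}

#' @export
print.vp_summary <- function(x, ...) {
  cat("Summary vector (", if (attr(x, "normalized")) "normalized" else "raw",
      "), ", sum(attr(x, "available")), " of ",
      length(attr(x, "available")), " biomarkers available\n", sep = "")
  print(unclass(x)[!is.na(unclass(x))])
  invisible(x)
}

#' Fit a robust per-feature normalization model on a cohort
#'
#' Location = per-feature median, scale = interquartile range, each computed
#' over the patients for whom the feature is available; a zero (or undefined)
#' IQR falls back to scale 1. Robust statistics are used because clinical
#' biomarkers are heavy-tailed.
#'
#' @param summaries list of raw `vp_summary` vectors (>= 2).
#' @return A `vp_normalizer`: list with numeric vectors `location` and
#'   `scale` over the feature layout.
#' @export
fit_normalizer <- function(summaries) {
  stopifnot(length(summaries) >= 2)
  mat <- do.call(rbind, lapply(summaries, unclass))
  loc <- apply(mat, 2, stats::median, na.rm = TRUE)
  sc <- apply(mat, 2, stats::IQR, na.rm = TRUE, type = 7)
  loc[!is.finite(loc)] <- 0
  sc[!is.finite(sc) | sc <= 0] <- 1
  structure(list(location = loc, scale = sc, features = colnames(mat)),
            class = "vp_normalizer")
}

#' Apply (or invert) a normalization model
#'
#' @param summary a `vp_summary`.
#' @param normalizer a `vp_normalizer` fitted on the same feature layout.
#' @return The normalized (resp. raw) `vp_summary`.
#' @export
normalize_summary <- function(summary, normalizer) {
  if (attr(summary, "normalized")) return(summary)
  stopifnot(identical(names(unclass(summary)), normalizer$features))
  z <- (unclass(summary) - normalizer$location) / normalizer$scale
  new_summary(z, attr(summary, "available"), normalized = TRUE)
}

#' @rdname normalize_summary
#' @export
denormalize_summary <- function(summary, normalizer) {
  if (!attr(summary, "normalized")) return(summary)
  x <- unclass(summary) * normalizer$scale + normalizer$location
  new_summary(x, attr(summary, "available"), normalized = FALSE)
}

#' Missing-data-aware distance between two summary vectors
#'
#' Both vectors must be normalized with the same model. If the patients share
#' no biomarker the pair is incomparable and `Inf` is returned (sorts after
#' every finite distance).
#'
#' @param a,b normalized `vp_summary` vectors on the same feature layout.
#' @return Nonnegative real, or `Inf` when no biomarker is shared.
#' @export
summary_distance <- function(a, b) {
  stopifnot(attr(a, "normalized"), attr(b, "normalized"))
  av <- attr(a, "available") & attr(b, "available")
  if (!any(av)) return(Inf)
  bs <- names(av)[av]
  idx <- feature_names(bs)
  da <- unclass(a)[idx]; db <- unclass(b)[idx]
  sqrt(3 / (2 * length(bs)) * sum((da - db)^2))
}

#' Nearest entry of a knowledge container
#'
#' @param query normalized `vp_summary`.
#' @param container a `vp_container` (see [init_container()]).
#' @return The patient id of the entry with minimal distance; ties broken by
#'   lexicographic id. If every entry is incomparable (no shared biomarker),
#'   falls back to the reference entry.
#' @export
nearest_entry <- function(query, container) {
  ids <- names(container$entries)
  stopifnot(length(ids) >= 1)
  d <- vapply(ids, function(id)
    summary_distance(query, container$entries[[id]]$summary), numeric(1))
  if (all(!is.finite(d))) return(container$reference_id)
  ids <- ids[order(d, ids)]
  ids[1]
}

#' Export summary vectors as a wide CSV
#'
#' One row per patient: `patient_id`, then `<biomarker>_median`,
#' `<biomarker>_spread` columns with empty cells for masked biomarkers.
#'
#' @param summaries named list (by patient id) of `vp_summary`.
#' @param path CSV file path.
#' @export
write_summaries_csv <- function(summaries, path) {
  mat <- do.call(rbind, lapply(summaries, unclass))
  df <- data.frame(patient_id = names(summaries), mat,
                   row.names = NULL, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
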