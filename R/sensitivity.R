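#' Global sensitivity analysis for fitting-parameter selection
#'
#' Total-order Sobol indices are estimated with Saltelli's sampling scheme
#' (base matrices A, B and the radial cross matrices AB_i) and the Jansen
#' estimator, with parameters varied uniformly within a +-30% interval
#' around the reference parametrization. Per-output indices are collapsed to
#' one value per parameter by variance-weighted aggregation:
#' \deqn{S^{agg}_{\theta_i} = \frac{\sum_j S_{X_j,\theta_i} Var(X_j)}
#'   {\sum_j Var(X_j)}}
#'
#' @name sensitivity
NULL

#' Total-order Sobol indices of a vector-valued function (Saltelli design)
#'
#' @param f function taking an `n x d` matrix of inputs in `[0,1]^d` (rows =
#'   evaluation points) and returning an `n x m` matrix of outputs; rows with
#'   any non-finite entry count as failures.
#' @param d input dimension.
#' @param N base sample size (the design has `N * (d + 2)` rows; powers of 2
#'   recommended).
#' @param seed integer seed (the design is deterministic given it).
#' @param max_failure_rate abort when more than this fraction of design rows
#'   fails.
#' @return List with `S` (`d x m` total-order indices), `V` (length-`m`
#'   output variances over the base matrices), `N`, `seed`.
#' @export
sobol_total_order <- function(f, d, N, seed = 1L, max_failure_rate = 0.05) {
  stopifnot(d >= 1, N >= 2)
  AB <- with_seed(seed, list(A = lhs::randomLHS(N, d), B = lhs::randomLHS(N, d)))
  A <- AB$A; B <- AB$B
  design <- rbind(A, B)
  for (i in seq_len(d)) {
    ABi <- A; ABi[, i] <- B[, i]
    design <- rbind(design, ABi)
  }
  Y <- f(design)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1)
  stopifnot(nrow(Y) == nrow(design))
  bad_row <- !apply(Y, 1, function(r) all(is.finite(r)))
  # a failed point invalidates its whole radial block (the A/B rows and all
  # AB_i rows sharing its index), so the Jansen pairs stay aligned
  fail_idx <- unique((which(bad_row) - 1L) %% N + 1L)
  if (length(fail_idx) / N > max_failure_rate)
    stop(sprintf("simulation failures on %d of %d design blocks (> %.0f%%)",
                 length(fail_idx), N, 100 * max_failure_rate))
  keep <- setdiff(seq_len(N), fail_idx)
  n <- length(keep)
  m <- ncol(Y)
  YA <- Y[keep, , drop = FALSE]
  YB <- Y[N + keep, , drop = FALSE]
  V <- apply(rbind(YA, YB), 2, stats::var)
  S <- matrix(NA_real_, d, m)
  for (i in seq_len(d)) {
    YABi <- Y[(i + 1L) * N + keep, , drop = FALSE]
    S[i, ] <- colSums((YA - YABi)^2) / (2 * n) / V
  }
  list(S = S, V = V, N = N, n_effective = n, seed = seed)
}

#' Sobol sensitivity of the surrogate simulator outputs
#'
#' Outputs are scalars of the treated simulation: by default each biomarker
#' at weeks 4, 12 and 24 (the analysis is performed during drug treatment).
#'
#' @param spec a [simulator_spec()].
#' @param parameter_subset parameters to vary (default: all).
#' @param range_fraction half-width of the uniform range as a fraction of the
#'   reference value (default 0.3, i.e. +-30%).
#' @param output_weeks time points defining the scalar outputs.
#' @param N base sample size of the Saltelli design.
#' @param seed integer seed.
#' @return A `vp_sobol` object: list with matrix `S`
#'   (parameters x outputs), output variances `V`, aggregated indices
#'   `S_agg`, output names, and sampling metadata.
#' @examples
#' \donttest{
#' sob <- saltelli_indices(simulator_spec(), N = 128, seed = 1)
#' sort(sob$S_agg, decreasing = TRUE)
#' }
#' @export
saltelli_indices <- function(spec, parameter_subset = spec$parameter_names,
                             range_fraction = 0.3,
                             output_weeks = c(4, 12, 24),
                             N = 256, seed = 1L) {
  stopifnot(range_fraction > 0, range_fraction < 1,
            all(parameter_subset %in% spec$parameter_names),
            all(output_weeks %in% spec$observation_grid))
  ref <- spec$reference[parameter_subset]
  lower <- ref * (1 - range_fraction)
  upper <- ref * (1 + range_fraction)
  out_names <- as.vector(outer(spec$biomarker_names, output_weeks,
                               function(b, w) paste0(b, "_w", w)))
  widx <- match(output_weeks, spec$observation_grid)
  f <- function(U) {
    t(apply(U, 1, function(u) {
      th <- lower + u * (upper - lower)
      names(th) <- parameter_subset
      tr <- simulate_trajectories(th, spec)
      if (is.null(tr)) return(rep(NA_real_, length(out_names)))
      as.vector(tr$values[widx, ])
    }))
  }
  res <- sobol_total_order(f, length(parameter_subset), N, seed)
  dimnames(res$S) <- list(parameter_subset, out_names)
  names(res$V) <- out_names
  s_agg <- vapply(parameter_subset, function(p) aggregate_index(res, p),
                  numeric(1))
  structure(c(res, list(S_agg = s_agg, range_fraction = range_fraction,
                        output_weeks = output_weeks)),
            class = "vp_sobol")
}

#' Variance-weighted aggregated total-order index of one parameter
#'
#' @param result a result of [sobol_total_order()] or [saltelli_indices()]
#'   (needs `S` and `V`).
#' @param parameter parameter identifier (row name of `S`) or index.
#' @return The aggregated index; errors if all output variances are 0.
#' @export
aggregate_index <- function(result, parameter) {
  s <- result$S[parameter, ]
  v <- result$V
  if (sum(v) <= 0) stop("all output variances are zero; aggregation undefined")
  sum(s * v) / sum(v)
}

#' Select fitting parameters: expert priority plus most sensitive
#'
#' @param result a `vp_sobol` (needs `S_agg`).
#' @param expert_list identifiers always included (expert priority).
#' @param k total number of parameters to select (>= `length(expert_list)`).
#' @return Character vector: the expert list followed by the
#'   `k - length(expert_list)` remaining parameters with largest aggregated
#'   index (ties by identifier).
#' @export
select_parameters <- function(result, expert_list = character(0), k) {
  s <- result$S_agg
  stopifnot(all(expert_list %in% names(s)), k >= length(expert_list))
  if (k > length(s)) stop("k exceeds the number of parameters")
  rest <- s[setdiff(names(s), expert_list)]
  o <- order(-rest, names(rest))
  c(expert_list, names(rest)[o][seq_len(k - length(expert_list))])
}

#' Export a Sobol result as a long-format CSV
#'
#' Columns: parameter, output, index, variance, aggregated.
#'
#' @param result a `vp_sobol`.
#' @param path CSV file path.
#' @export
write_sobol_csv <- function(result, path) {
  df <- expand.grid(parameter = rownames(result$S),
                    output = colnames(result$S), stringsAsFactors = FALSE)
  df$index <- as.vector(result$S)
  df$variance <- result$V[df$output]
  df$aggregated <- result$S_agg[df$parameter]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
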