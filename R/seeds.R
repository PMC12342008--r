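#' Derive a reproducible child seed
#'
#' All randomness in the package flows from a single master seed. Child seeds
#' for (patient, stage) pairs are derived by a stable string hash so that
#' results are independent of the order in which patients are processed.
#'
#' @param master integer master seed.
#' @param ... character or numeric tokens identifying the consumer, e.g.
#'   a patient id and a stage label such as `"fit"` or `"noise"`.
#' @return A single integer in `[1, 2^31 - 2]`, deterministic in its inputs.
#' @examples
#' derive_seed(1L, "P003", "fit")
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  key <- paste(c(format(master, scientific = FALSE), as.character(unlist(list(...)))),
               collapse = "\r")
  bytes <- utf8ToInt(key)
  h <- 17
  m <- 2147483629  # largest prime < 2^31, keeps arithmetic exact in doubles
  for (b in bytes) h <- (h * 31 + b) %% m
  as.integer(h + 1)
}

#' Evaluate an expression under a local RNG state
#'
#' Seeds the RNG, evaluates `expr`, and restores the caller's RNG state.
#' Used throughout so that library calls never perturb user seeds; also
#' handy when writing custom stochastic forward models.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}
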