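# Internals of the masked autoregressive estimator, then engine-level
# behaviour on small conditional-inference problems.

test_that("atomic-loss gradients match finite differences", {
  st <- vpsbi:::made_new(3, 4, 8, seed = 5)
  set.seed(9)
  Xe <- matrix(rnorm(6 * 4), 6, 4)
  Ze <- matrix(rnorm(6 * 3), 6, 3)
  lpe <- rnorm(6)
  for (M in c(3L, 1L)) {  # atomic and plain-likelihood branches
    out <- vpsbi:::made_loss_grad_cpp(st$net, Xe, Ze, lpe, M)
    for (nm in c("W1", "b1", "Wm", "bm", "Ws", "bs")) {
      idx <- sample(length(st$net[[nm]]), min(4, length(st$net[[nm]])))
      for (i in idx) {
        eps <- 1e-6
        net2 <- st$net
        net2[[nm]][i] <- net2[[nm]][i] + eps
        fd <- (vpsbi:::made_loss_grad_cpp(net2, Xe, Ze, lpe, M)$loss -
                 out$loss) / eps
        expect_equal(out$grads[[nm]][i], fd, tolerance = 1e-3)
      }
    }
  }
})

test_that("the estimator defines a normalized conditional density", {
  # 1-D case: integrate exp(log q(z | x)) over z numerically
  st <- vpsbi:::made_new(1, 2, 16, seed = 3)
  x <- c(0.3, -1.2)
  grid <- seq(-12, 12, length.out = 4001)
  lq <- vpsbi:::made_logprob(st, matrix(rep(x, each = length(grid)),
                                        length(grid)),
                             matrix(grid, ncol = 1))
  integral <- sum(exp(lq)) * diff(grid[1:2])
  expect_equal(integral, 1, tolerance = 1e-3)
})

test_that("samples agree with the density they claim (1-D moments)", {
  st <- vpsbi:::made_new(1, 1, 16, seed = 21)
  x <- 0.5
  s <- vpsbi:::made_sample_z(st, x, 20000, seed = 4)
  grid <- seq(-12, 12, length.out = 4001)
  lq <- vpsbi:::made_logprob(st, matrix(x, length(grid)), matrix(grid, ncol = 1))
  w <- exp(lq) / sum(exp(lq))
  expect_equal(mean(s), sum(w * grid), tolerance = 0.03)
  expect_equal(stats::sd(s), sqrt(sum(w * grid^2) - sum(w * grid)^2),
               tolerance = 0.03)
})

test_that("engine recovers the conjugate lognormal posterior", {
  loc0 <- log(2); s0 <- 0.25; sig <- 0.2
  x_o <- log(2.6)
  post_var <- 1 / (1 / s0^2 + 1 / sig^2)
  post_med <- exp(post_var * (loc0 / s0^2 + x_o / sig^2))
  prior <- structure(list(loc = c(rate = loc0), scale = c(rate = s0)),
                     class = "vp_prior")
  fwd <- function(theta, seed)
    with_seed(seed, log(theta[["rate"]]) + rnorm(1, 0, sig))
  fit <- fit_patient(x_o, prior, fwd, engine_config(seed = 11))
  s <- posterior_sample(fit$model, 2000, seed = 3)
  expect_lt(abs(stats::median(s[, "rate"]) / post_med - 1), 0.10)
  expect_equal(stats::sd(log(s[, "rate"])), sqrt(post_var), tolerance = 0.35)
})

test_that("a single round reduces to non-sequential estimation from the prior", {
  prior <- structure(list(loc = c(rate = log(2)), scale = c(rate = 0.25)),
                     class = "vp_prior")
  fwd <- function(theta, seed)
    with_seed(seed, log(theta[["rate"]]) + rnorm(1, 0, 0.3))
  fit <- fit_patient(log(2.2), prior, fwd,
                     engine_config(n_rounds = 1, n_sims_per_round = 60,
                                   seed = 2))
  expect_length(fit$round_logs, 1)
  expect_identical(fit$round_logs[[1]]$proposal_source, "prior")
  s <- posterior_sample(fit$model, 200, seed = 1)
  expect_true(all(s > 0))
})

test_that("posterior sampling honours its contracts", {
  prior <- structure(list(loc = c(a = 0, b = 0), scale = c(a = 0.3, b = 0.3)),
                     class = "vp_prior")
  st <- vpsbi:::made_new(2, 2, 16, seed = 8)
  model <- vpsbi:::new_posterior(st, c(0, 0), prior)
  s1 <- posterior_sample(model, 100, seed = 6)
  s2 <- posterior_sample(model, 100, seed = 6)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 100)
  expect_true(all(s1 > 0))
  expect_equal(colnames(s1), c("a", "b"))
  # density is finite on its own samples
  ld <- posterior_log_density(model, s1)
  expect_true(all(is.finite(ld)))
  expect_identical(posterior_log_density(model, c(a = -1, b = 1)), -Inf)
})

test_that("invalid simulations are dropped and total failure aborts", {
  prior <- structure(list(loc = c(rate = 0), scale = c(rate = 0.25)),
                     class = "vp_prior")
  flaky <- function(theta, seed)
    if (theta[["rate"]] > 1) NULL else log(theta[["rate"]])
  fit <- fit_patient(0, prior, flaky,
                     engine_config(n_rounds = 1, n_sims_per_round = 40,
                                   seed = 3))
  expect_gt(fit$round_logs[[1]]$n_invalid, 0)
  dead <- function(theta, seed) NULL
  expect_error(fit_patient(0, prior, dead,
                           engine_config(n_rounds = 1, seed = 3)),
               "invalid")
})

test_that("parameter ordering does not bias the marginals", {
  sig <- 0.15
  fwd2 <- function(theta, seed) with_seed(seed,
    c(log(theta[["a"]]), log(theta[["b"]])) + rnorm(2, 0, sig))
  x_o <- c(log(2.4), log(0.5))
  pr_ab <- structure(list(loc = c(a = log(2), b = log(0.6)),
                          scale = c(a = 0.25, b = 0.25)), class = "vp_prior")
  pr_ba <- structure(list(loc = pr_ab$loc[c("b", "a")],
                          scale = pr_ab$scale[c("b", "a")]), class = "vp_prior")
  fwd2_swapped <- function(theta, seed) fwd2(theta, seed)
  cfg <- engine_config(n_rounds = 4, seed = 19)
  fit1 <- fit_patient(x_o, pr_ab, fwd2, cfg)
  fit2 <- fit_patient(x_o[2:1], pr_ba,
                      function(theta, seed) fwd2(theta, seed)[2:1], cfg)
  s1 <- posterior_sample(fit1$model, 1500, seed = 5)
  s2 <- posterior_sample(fit2$model, 1500, seed = 5)
  for (p in c("a", "b"))
    expect_lt(abs(stats::median(s1[, p]) / stats::median(s2[, p]) - 1), 0.12)
})
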