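# R-side state management for the masked autoregressive density estimator.
# The estimator works on standardized coordinates: z = (log(theta) - loc)/scale
# under the fit's lognormal prior, so the prior is exactly N(0, I) there and
# the initial (near-zero-weight) network is approximately the prior.

made_new <- function(dim_z, dim_x, hidden, seed) {
  d <- dim_x + dim_z
  degrees <- (seq_len(hidden) - 1L) %% dim_z
  M1 <- matrix(1, hidden, d)
  for (i in seq_len(dim_z)) M1[, dim_x + i] <- as.numeric(degrees >= i)
  M2 <- matrix(0, dim_z, hidden)
  for (i in seq_len(dim_z)) M2[i, ] <- as.numeric(degrees < i)
  with_seed(seed, {
    net <- list(
      W1 = matrix(stats::rnorm(hidden * d, 0, 1 / sqrt(d)), hidden, d),
      b1 = rep(0, hidden),
      Wm = matrix(stats::rnorm(dim_z * hidden, 0, 0.01), dim_z, hidden),
      bm = rep(0, dim_z),
      Ws = matrix(stats::rnorm(dim_z * hidden, 0, 0.01), dim_z, hidden),
      bs = rep(0, dim_z),
      M1 = M1, M2 = M2)
  })
  adam <- list(t = 0,
               mW1 = net$W1 * 0, vW1 = net$W1 * 0,
               mb1 = net$b1 * 0, vb1 = net$b1 * 0,
               mWm = net$Wm * 0, vWm = net$Wm * 0,
               mbm = net$bm * 0, vbm = net$bm * 0,
               mWs = net$Ws * 0, vWs = net$Ws * 0,
               mbs = net$bs * 0, vbs = net$bs * 0)
  list(net = net, adam = adam, dim_z = dim_z, dim_x = dim_x, hidden = hidden)
}

made_train <- function(state, X, Z, logp, steps, batch, atoms, lr, seed) {
  out <- with_seed(seed,
    made_train_cpp(state$net, X, Z, logp, steps, batch, atoms, lr,
                   state$adam))
  state$net <- out$net
  state$adam <- out$adam
  state$last_losses <- as.numeric(out$step_loss)
  state
}

made_sample_z <- function(state, x, n, seed) {
  with_seed(seed, made_sample_cpp(state$net, matrix(x, nrow = 1), n))
}

made_logprob <- function(state, X, Z) {
  as.numeric(made_logprob_cpp(state$net, X, Z))
}
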