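# Independent oracles used across the suite.

# Straight-line transcription of the routing algorithm for one sample:
# explicit loops, no shared code with the package internals.
naive_routing <- function(u_hat, iterations) {
  n_in <- dim(u_hat)[1]; n_out <- dim(u_hat)[2]; d_out <- dim(u_hat)[3]
  b <- matrix(0, n_in, n_out)
  v <- matrix(0, n_out, d_out)
  for (m in seq_len(iterations)) {
    cc <- matrix(0, n_in, n_out)
    for (i in seq_len(n_in)) cc[i, ] <- exp(b[i, ]) / sum(exp(b[i, ]))
    for (j in seq_len(n_out)) {
      s <- rep(0, d_out)
      for (i in seq_len(n_in)) s <- s + cc[i, j] * u_hat[i, j, ]
      ns <- sqrt(sum(s^2))
      v[j, ] <- if (ns == 0) rep(0, d_out) else
        (ns^2 / (1 + ns^2)) * s / ns
    }
    for (i in seq_len(n_in)) for (j in seq_len(n_out))
      b[i, j] <- b[i, j] + sum(u_hat[i, j, ] * v[j, ])
  }
  v
}

# Brute-force AUC over all positive/negative pairs (ties count one half).
pairwise_auc <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Tiny architectures used by the gradient and smoke tests.
tiny_conv_hyper <- function(...) {
  conv_hyperparams(filters = 2L, kernel_size = 3L, hidden_nodes = 6L,
                   primarycaps_nodes = 8L, capsule_dim = 2L,
                   batch_size = 5L, ...)
}
tiny_rbm_hyper <- function(...) {
  rbm_hyperparams(hidden_sizes = c(6L, 4L), capsule_dim = 2L,
                  batch_size = 5L, rbm_epochs = 2L, ...)
}

# Finite-difference comparison helper: passes when the analytic gradient
# matches central differences up to numerical noise.
expect_grad_close <- function(num, ana, scale = 1e-3, floor = 1e-8) {
  expect_lt(abs(num - ana), floor + scale * max(abs(num), abs(ana)))
}
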