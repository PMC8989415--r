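# shared fixtures, built in code

# the 3-sample toy used throughout: rows 110, 011, 110
toy_matrix <- function() {
  matrix(c(1, 1, 0,
           0, 1, 1,
           1, 1, 0), nrow = 3, byrow = TRUE)
}

# random small indicator system with sparse couplings, on a scale where
# eps ~ 1/M keeps the expansion perturbative
random_system <- function(S, M = 300, h_sd = 150, J_sd = 500) {
  h <- rnorm(S, 0, h_sd)
  J <- matrix(0, S, S)
  if (S > 1) {
    pairs <- which(upper.tri(J), arr.ind = TRUE)
    sel <- sample(nrow(pairs), min(2L * S, nrow(pairs)))
    for (k in sel) {
      v <- rnorm(1, 0, J_sd)
      J[pairs[k, 1], pairs[k, 2]] <- v
      J[pairs[k, 2], pairs[k, 1]] <- v
    }
  }
  list(h = h, J = J, M = M)
}

# exact log-likelihood of binary data under the log-linear model with biases
# fixed at the independent-model saddle (logit of the marginals) plus a single
# interaction coefficient theta on `support`; used as the derivative oracle
# for the closed-form field
loglik_oracle <- function(x, support, theta) {
  N <- ncol(x)
  M <- nrow(x)
  p <- colSums(x) / M
  states <- 0:(2^N - 1)
  logw <- numeric(2^N)
  for (i in seq_len(N))
    logw <- logw + log(p[i] / (1 - p[i])) * (bitwAnd(states, 2^(i - 1)) > 0)
  mask <- sum(2^(support - 1))
  logw <- logw + theta * (bitwAnd(states, mask) == mask)
  logZ <- log(sum(exp(logw)))
  smask <- as.vector(x %*% 2^(seq_len(N) - 1))
  sum(logw[smask + 1]) - M * logZ
}
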