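# independent oracles kept free of the package's own recursions

# batch weighted-least-squares smoother: stacks the prior, transition and
# observation terms of the state-space model into one dense normal-equation
# system over all states and solves it directly. The solution equals the
# fixed-interval smoothed means.
batch_smooth_oracle <- function(y, model) {
  N <- length(y)
  d <- model$d
  phi <- model$phi
  H <- model$H
  Qi <- solve(model$Q)
  A <- matrix(0, N * d, N * d)
  b <- numeric(N * d)
  blk <- function(k) ((k - 1) * d + 1):(k * d)
  # prior on x_1 from the known x0
  W1 <- solve(phi %*% model$P0 %*% t(phi) + model$Q)
  A[blk(1), blk(1)] <- A[blk(1), blk(1)] + W1
  b[blk(1)] <- b[blk(1)] + W1 %*% (phi %*% model$x0)
  # transitions
  for (k in seq_len(N - 1)) {
    A[blk(k), blk(k)] <- A[blk(k), blk(k)] + t(phi) %*% Qi %*% phi
    A[blk(k + 1), blk(k + 1)] <- A[blk(k + 1), blk(k + 1)] + Qi
    A[blk(k), blk(k + 1)] <- A[blk(k), blk(k + 1)] - t(phi) %*% Qi
    A[blk(k + 1), blk(k)] <- A[blk(k + 1), blk(k)] - Qi %*% phi
  }
  # observations
  for (k in which(!is.na(y))) {
    A[blk(k), blk(k)] <- A[blk(k), blk(k)] + t(H) %*% H / model$R
    b[blk(k)] <- b[blk(k)] + t(H)[, 1] * y[k] / model$R
  }
  matrix(solve(A, b), nrow = d)
}

# random well-conditioned 2-state model instance for smoother equivalence
random_ss_instance <- function(N = 50) {
  d <- 2
  phi <- matrix(rnorm(4, sd = 0.5), d, d) + diag(0.5, d)
  Aq <- matrix(rnorm(4), d, d)
  Q <- Aq %*% t(Aq) + diag(0.1, d)
  P0 <- crossprod(matrix(rnorm(4), d, d)) + diag(1, d)
  model <- state_space_model(phi = phi, H = c(1, 0), Q = Q,
                             R = runif(1, 0.5, 2), x0 = rnorm(d),
                             P0 = P0)
  y <- rnorm(N, sd = 3)
  y[sample.int(N, round(0.2 * N))] <- NA
  if (all(is.na(y))) y[1] <- 0
  list(model = model, y = y)
}

# plain two-pass RMSE, coded independently of the package
rmse_oracle <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  sqrt(s / length(a))
}
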