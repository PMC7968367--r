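#' Linear-Gaussian state-space model
#'
#' Discrete-time model
#' \deqn{x_{k+1} = \Phi x_k + B u_k + w_k, \quad w_k \sim N(0, Q)}
#' \deqn{y_k = H x_k + v_k, \quad v_k \sim N(0, R)}
#' with scalar measurements. `x0`/`P0` describe the state at the (virtual)
#' index 0, one step before the first measurement.
#'
#' @param phi state transition matrix (d x d).
#' @param H measurement matrix (1 x d).
#' @param Q process-noise covariance (d x d, symmetric PSD).
#' @param R measurement-noise variance (scalar, > 0).
#' @param B input matrix (default zero: no exogenous input).
#' @param x0 initial state mean (length d).
#' @param P0 initial state covariance (d x d, symmetric PSD).
#' @return a `state_space_model` object.
#' @export
state_space_model <- function(phi, H, Q, R, B = NULL, x0, P0) {
  phi <- as.matrix(phi)
  d <- nrow(phi)
  H <- matrix(H, nrow = 1)
  Q <- as.matrix(Q)
  stopifnot(ncol(phi) == d, ncol(H) == d, nrow(Q) == d, ncol(Q) == d,
            length(R) == 1, R > 0, length(x0) == d,
            nrow(as.matrix(P0)) == d)
  if (max(abs(Q - t(Q))) > 1e-10) stop("Q must be symmetric")
  if (min(eigen(Q, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("Q must be positive semidefinite")
  P0 <- as.matrix(P0)
  if (max(abs(P0 - t(P0))) > 1e-10) stop("P0 must be symmetric")
  structure(list(phi = phi, H = H, Q = Q, R = as.numeric(R),
                 B = if (is.null(B)) matrix(0, d, 1) else as.matrix(B),
                 x0 = as.numeric(x0), P0 = P0, d = d),
            class = "state_space_model")
}

#' Default CGM state-space model (local linear trend)
#'
#' Two-state model, state = (glucose mg/dl, rate of change mg/dl per slot):
#' `phi = [[1, 1], [0, 1]]`, `H = [1, 0]`, and white-noise-jerk process
#' covariance `Q = q * [[1/3, 1/2], [1/2, 1]]` (the continuous-time
#' integrated-noise discretisation at unit slot spacing). This is the minimal
#' model that both tracks glucose dynamics and interpolates CGM gaps.
#'
#' @param q process-noise intensity (default 1: the glucose rate of change wanders by about 1 mg/dl per 5-min slot).
#' @param r measurement-noise variance in (mg/dl)^2 (default 25, i.e. a
#'   sensor noise standard deviation of about 5 mg/dl).
#' @param x0 initial state mean; default `c(first observation, 0)` is filled
#'   in by [smooth_cgm()].
#' @param p0 initial state variances (diffuse start, default `c(1e4, 1e2)`).
#' @return a [state_space_model()].
#' @export
cgm_model <- function(q = 1, r = 25, x0 = c(100, 0), p0 = c(1e4, 1e2)) {
  state_space_model(
    phi = matrix(c(1, 0, 1, 1), 2, 2),
    H = c(1, 0),
    Q = q * matrix(c(1 / 3, 1 / 2, 1 / 2, 1), 2, 2),
    R = r,
    x0 = x0,
    P0 = diag(p0))
}

#' Kalman filter with missing measurements
#'
#' Forward pass. Time update: `x_prior_k = phi x_post_{k-1} + B u_{k-1}`,
#' `P_prior_k = phi P_post_{k-1} phi' + Q`. Measure update at observed k:
#' `K_k = P_prior_k H' (H P_prior_k H' + R)^{-1}`,
#' `x_post_k = x_prior_k + K_k (y_k - H x_prior_k)`,
#' `P_post_k = (I - K_k H) P_prior_k`. At missing k the measure update is
#' skipped, so the posterior equals the prior.
#'
#' @param y numeric measurement vector; `NA` marks a missing sample.
#' @param model a [state_space_model()].
#' @param u optional exogenous input sequence (length of `y`), default zero.
#' @return a `filter_result`: matrices `x_prior`, `x_post` (d x N), arrays
#'   `P_prior`, `P_post` (d x d x N), `gain` (d x N), logical `observed`.
#' @export
kalman_filter <- function(y, model, u = NULL) {
  stopifnot(inherits(model, "state_space_model"))
  N <- length(y)
  observed <- !is.na(y)
  if (!any(observed)) stop("kalman_filter: no observations")
  if (any(!is.finite(y[observed])))
    stop("kalman_filter: non-finite measurement")
  d <- model$d
  phi <- model$phi; H <- model$H; Q <- model$Q; R <- model$R; B <- model$B
  if (is.null(u)) u <- numeric(N)
  x_prior <- x_post <- matrix(0, d, N)
  P_prior <- P_post <- array(0, dim = c(d, d, N))
  gain <- matrix(0, d, N)
  x <- model$x0
  P <- model$P0
  for (k in seq_len(N)) {
    xp <- phi %*% x + B * u[k]
    Pp <- phi %*% P %*% t(phi) + Q
    x_prior[, k] <- xp
    P_prior[, , k] <- Pp
    if (observed[k]) {
      S <- as.numeric(H %*% Pp %*% t(H)) + R
      K <- (Pp %*% t(H)) / S
      x <- xp + K %*% (y[k] - H %*% xp)
      P <- (diag(d) - K %*% H) %*% Pp
      gain[, k] <- K
    } else {
      x <- xp
      P <- Pp
    }
    x_post[, k] <- x
    P_post[, , k] <- P
  }
  structure(list(x_prior = x_prior, P_prior = P_prior,
                 x_post = x_post, P_post = P_post,
                 gain = gain, observed = observed, model = model),
            class = "filter_result")
}

#' Rauch-Tung-Striebel fixed-interval smoother
#'
#' Backward pass over a [kalman_filter()] result. With
#' `C_k = P_post_k phi' P_prior_{k+1}^{-1}`:
#' `x_smooth_k = x_post_k + C_k (x_smooth_{k+1} - x_prior_{k+1})`,
#' `P_smooth_k = P_post_k + C_k (P_smooth_{k+1} - P_prior_{k+1}) C_k'`;
#' at the last index smoothed equals filtered by construction.
#'
#' @param filt a `filter_result`.
#' @param pseudo_inverse use a Moore-Penrose pseudo-inverse when a one-step
#'   prior covariance is singular (default `FALSE`: singularity is an error
#'   naming the index).
#' @return a `smoothed_series`: `mean` and `variance` of the first (glucose)
#'   state component per index, plus full-state `x_smooth` (d x N) and
#'   `P_smooth` (d x d x N).
#' @export
rts_smooth <- function(filt, pseudo_inverse = FALSE) {
  stopifnot(inherits(filt, "filter_result"))
  model <- filt$model
  phi <- model$phi
  d <- model$d
  N <- ncol(filt$x_post)
  xs <- matrix(0, d, N)
  Ps <- array(0, dim = c(d, d, N))
  xs[, N] <- filt$x_post[, N]
  Ps[, , N] <- filt$P_post[, , N]
  if (N > 1) for (k in (N - 1):1) {
    Pp1 <- filt$P_prior[, , k + 1]
    Pinv <- tryCatch(solve(Pp1), error = function(e) {
      if (pseudo_inverse) pinv(Pp1)
      else stop(sprintf("rts_smooth: singular one-step covariance at index %d",
                        k + 1))
    })
    C <- filt$P_post[, , k] %*% t(phi) %*% Pinv
    xs[, k] <- filt$x_post[, k] + C %*% (xs[, k + 1] - filt$x_prior[, k + 1])
    Ps[, , k] <- filt$P_post[, , k] +
      C %*% (Ps[, , k + 1] - Pp1) %*% t(C)
  }
  structure(list(mean = xs[1, ], variance = pmax(Ps[1, 1, ], 0),
                 x_smooth = xs, P_smooth = Ps,
                 filtered_variance = filt$P_post[1, 1, ],
                 observed = filt$observed),
            class = "smoothed_series")
}

pinv <- function(A, tol = 1e-12) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' @export
print.smoothed_series <- function(x, ...) {
  cat(sprintf("<smoothed_series> %d indices, %d observed\n",
              length(x$mean), sum(x$observed)))
  cat(sprintf("  mean glucose %.1f mg/dl, mean posterior sd %.2f mg/dl\n",
              mean(x$mean), mean(sqrt(x$variance))))
  invisible(x)
}

#' Kalman-smooth the CGM channel of a patient series
#'
#' Runs the forward Kalman filter and RTS backward pass over the full grid of
#' one data file using the default local-linear-trend CGM model. Gaps receive
#' interpolated means with inflated variance (time-update-only propagation —
#' no measurement is ever fabricated). Call this separately on a patient's
#' training and test files so no information leaks across the split.
#'
#' @param series a [patient_series()] with at least 2 observed CGM values.
#' @param q process-noise intensity (default 1: the glucose rate of change wanders by about 1 mg/dl per 5-min slot).
#' @param r measurement-noise variance, (mg/dl)^2 (default 25).
#' @param p0 initial state variances (default `c(1e4, 1e2)`).
#' @return a `smoothed_series` (glucose posterior mean and variance per slot).
#' @export
smooth_cgm <- function(series, q = 1, r = 25, p0 = c(1e4, 1e2)) {
  stopifnot(inherits(series, "patient_series"))
  y <- series$cgm
  if (sum(!is.na(y)) < 2L)
    stop("smooth_cgm: need at least 2 observed CGM values")
  model <- cgm_model(q = q, r = r,
                     x0 = c(y[which(!is.na(y))[1]], 0), p0 = p0)
  rts_smooth(kalman_filter(y, model))
}
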