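# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: conjugate closed forms, numerical
# quadrature, and time-domain simulation.

## A random linear-Gaussian regression problem with its exact conjugate
## posterior and log evidence at a known noise precision.
conjugate_problem <- function(seed, n = 30, p = 4, prior_var = 2,
                              sigma2 = 0.25) {
  set.seed(seed)
  A <- matrix(rnorm(n * p), n, p)
  theta <- rnorm(p)
  y <- as.numeric(A %*% theta) + rnorm(n, sd = sqrt(sigma2))
  nm <- paste0("b", seq_len(p))
  prior <- gaussian_density(setNames(rnorm(p, sd = 0.3), nm), diag(prior_var, p))
  sol <- conjugate_solve(A, y, prior, 1 / sigma2)
  list(A = A, y = y, prior = prior, sigma2 = sigma2, lambda = -log(sigma2),
       posterior = sol$posterior, log_evidence = sol$log_evidence)
}

## exact Gaussian linear-model solution under noise precision pe
conjugate_solve <- function(A, y, prior, pe) {
  n <- nrow(A)
  P0 <- solve(prior$cov)
  H <- crossprod(A) * pe + P0
  Sq <- solve(H)
  mq <- as.numeric(Sq %*% (crossprod(A, y) * pe + P0 %*% prior$mean))
  logev <- -n / 2 * log(2 * pi) + n / 2 * log(pe) -
    pe / 2 * sum(y^2) - 0.5 * sum(prior$mean * (P0 %*% prior$mean)) +
    0.5 * sum(mq * (H %*% mq)) +
    0.5 * determinant(Sq)$modulus - 0.5 * determinant(prior$cov)$modulus
  list(posterior = gaussian_density(mq, Sq, names = prior$names),
       log_evidence = as.numeric(logev))
}

## settings that pin the noise log-precision at its true value, so the
## variational fit is comparable with the known-precision conjugate solution
pinned_settings <- function(lambda) {
  dcm_settings(hyper_mean = lambda, hyper_var = 1e-8)
}

## Transfer-function oracle: Fourier transform (trapezoid rule) of the
## simulated impulse response of the linearised system.
transfer_oracle_mass <- function(model, freqs, dt = 1e-5, t_end = 0.4) {
  J <- jacobian_mass(model, fixed_point(model, 0))
  B <- matrix(c(rep(0, 4), model$kappa * model$B_weights))
  C <- cbind(model$Lw, matrix(0, nrow(model$Lw), 4))
  nst <- round(t_end / dt)
  eg <- eigen(J)
  Ad <- Re(eg$vectors %*% diag(exp(eg$values * dt)) %*% solve(eg$vectors))
  nc <- nrow(C)
  h <- matrix(0, nst + 1, nc)
  x <- B
  for (k in 0:nst) {
    h[k + 1, ] <- as.numeric(C %*% x)
    x <- Ad %*% x
  }
  ts <- (0:nst) * dt
  w_trap <- c(0.5, rep(1, nst - 1), 0.5)
  om <- 2 * pi * freqs
  out <- matrix(0 + 0i, length(om), nc)
  for (ch in seq_len(nc)) {
    out[, ch] <- vapply(om, function(w) {
      sum(w_trap * h[, ch] * exp(-1i * w * ts)) * dt
    }, complex(1))
  }
  out
}

## Welch cross-spectral oracle: long time-domain simulation of the
## linearised system driven by white noise (exact discretisation of the
## continuous-time stochastic system via the integrated process-noise
## covariance), with one shared white channel-noise process. Pink spectral
## components must be disabled in `model` before calling.
welch_csd_oracle <- function(model, dt = 2.5e-4, nsteps = 3e5, seed = 1,
                             nseg = 4096) {
  J <- jacobian_mass(model, fixed_point(model, 0))
  B <- c(rep(0, 4), model$kappa * model$B_weights)
  C <- cbind(model$Lw, matrix(0, nrow(model$Lw), 4))
  nc <- nrow(C)
  gu <- exp(model$alpha_u)
  gn <- exp(model$alpha_n)
  eg <- eigen(J); V <- eg$vectors; Vi <- solve(V)
  ## Simpson integration of e^{Js} B B' e^{J's} over one step
  npt <- 200
  ss <- seq(0, dt, length.out = npt + 1)
  wq <- c(1, rep(c(4, 2), npt / 2 - 1), 4, 1) * (dt / npt) / 3
  Qd <- matrix(0, 8, 8)
  for (i in seq_along(ss)) {
    E <- Re(V %*% diag(exp(eg$values * ss[i])) %*% Vi)
    v <- E %*% B
    Qd <- Qd + wq[i] * tcrossprod(v)
  }
  Qd <- Qd * gu
  eQ <- eigen(Qd, symmetric = TRUE)
  L <- eQ$vectors %*% diag(sqrt(pmax(eQ$values, 0)))
  Ad <- Re(V %*% diag(exp(eg$values * dt)) %*% Vi)
  set.seed(seed)
  W <- L %*% matrix(rnorm(8 * nsteps), 8)
  x <- rep(0, 8)
  Y <- matrix(0, nc, nsteps)
  for (k in seq_len(nsteps)) {
    x <- Ad %*% x + W[, k]
    Y[, k] <- C %*% x
  }
  shared <- rnorm(nsteps, sd = sqrt(gn / dt))
  Y <- Y + matrix(rep(shared, each = nc), nc)
  ## Welch with Hann window, 50% overlap, two-sided PSD per Hz
  step <- nseg / 2
  nwin <- floor((nsteps - nseg) / step) + 1
  han <- 0.5 * (1 - cos(2 * pi * (0:(nseg - 1)) / nseg))
  U <- sum(han^2)
  acc <- array(0 + 0i, c(nseg, nc, nc))
  for (wix in seq_len(nwin)) {
    idx <- (wix - 1) * step + seq_len(nseg)
    Fts <- lapply(seq_len(nc), function(ch) fft(Y[ch, idx] * han))
    for (l in seq_len(nc)) for (mm in seq_len(nc)) {
      acc[, l, mm] <- acc[, l, mm] + Fts[[l]] * Conj(Fts[[mm]])
    }
  }
  list(freqs = (0:(nseg - 1)) / (nseg * dt),
       csd = acc * dt / (U * nwin))
}

## small helper: is a free-energy trajectory monotone non-decreasing?
expect_monotone <- function(trajectory, tol = 1e-9) {
  expect_true(all(diff(trajectory) >= -tol))
}
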