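# Variational Laplace: Gauss-Newton ascent on a free-energy (evidence) bound
# with Levenberg-Marquardt regularisation, alternating parameter and
# noise-hyperparameter updates.

#' Inversion settings
#'
#' Collects the numerical settings of the Variational-Laplace scheme.
#'
#' @param max_iter Iteration budget (outer Gauss-Newton iterations).
#' @param tol_nats Convergence threshold: stop when `|dF| < tol_nats` over
#'   `tol_run` consecutive accepted iterations.
#' @param tol_run Length of the convergence run.
#' @param lm_init Initial Levenberg-Marquardt damping (halved on acceptance,
#'   multiplied by 8 on rejection).
#' @param fd_step Central finite-difference step on the log-scaled
#'   parameters.
#' @param hyper_mean,hyper_var Gaussian hyperprior on the log-precision(s)
#'   `lambda` of the observation noise (weakly informative by default).
#' @param seed Optional integer seed recorded with the fit (the scheme
#'   itself is deterministic).
#' @return A list of class `dcm_settings`.
#' @export
dcm_settings <- function(max_iter = 64, tol_nats = 0.01, tol_run = 4,
                         lm_init = 1 / 8, fd_step = 1e-4,
                         hyper_mean = 0, hyper_var = 16, seed = NULL) {
  structure(list(max_iter = as.integer(max_iter), tol_nats = tol_nats,
                 tol_run = as.integer(tol_run), lm_init = lm_init,
                 fd_step = fd_step, hyper_mean = hyper_mean,
                 hyper_var = hyper_var, seed = seed),
            class = "dcm_settings")
}

#' Gaussian log-likelihood of observed cross-spectra
#'
#' Stacks the real and imaginary parts of the upper-triangular cross-spectra
#' into one residual vector and evaluates a Gaussian log-density with
#' isotropic covariance `exp(-lambda)` per noise component (a single shared
#' component by default; optionally one per channel pair).
#'
#' @param data Observed `spectral_data`.
#' @param prediction Predicted `spectral_data` on the same frequencies and
#'   channels.
#' @param lambda Log-precision(s): length 1, or one per upper-triangular
#'   channel pair.
#' @return Scalar log-likelihood (nats).
#' @export
loglik_csd <- function(data, prediction, lambda = 0) {
  check_same_grid(data, prediction)
  e <- stack_csd(data) - stack_csd(prediction)
  ci <- csd_comp_index(data, n_comp = length(lambda))
  pe <- exp(lambda)[ci]
  sum(-0.5 * log(2 * pi) + 0.5 * lambda[ci] - 0.5 * pe * e^2)
}

check_same_grid <- function(a, b) {
  if (!isTRUE(all.equal(a$freqs, b$freqs))) stop_dcm("frequency grids differ")
  if (length(a$channels) != length(b$channels)) stop_dcm("channel counts differ")
  invisible(TRUE)
}

## map each stacked residual element to a noise component
csd_comp_index <- function(x, n_comp = 1) {
  n <- length(x$channels); nf <- length(x$freqs)
  npair <- n * (n + 1) / 2
  if (n_comp == 1) return(rep(1L, n_stacked(x)))
  if (n_comp != npair) stop_dcm("lambda must have length 1 or %d", npair)
  pair_of <- function(i, j) {  # index of pair (i, j), i <= j, in stacking order
    sum((n + 1) - seq_len(i - 1)) - (n - i + 1) + (j - i + 1)
  }
  idx <- c()
  for (i in seq_len(n)) for (j in i:n) idx <- c(idx, rep(pair_of(i, j), nf))
  if (n > 1) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    idx <- c(idx, rep(pair_of(i, j), nf))
  }
  as.integer(idx)
}

## joint free energy given residual e, Jacobian J and current (mu, lambda)
vl_objective <- function(e, J, mu, lambda, prior, hyper, comp_index) {
  n <- length(e)
  pe <- exp(lambda)[comp_index]
  P0 <- inv_sym(prior$cov)
  dtheta <- mu - prior$mean
  H <- symm(crossprod(J, J * pe)) + P0
  cholH <- tryCatch(chol(H), error = function(e2) NULL)
  if (is.null(cholH)) return(list(F = -Inf))
  Sq <- chol2inv(cholH)
  ld_Sq <- -2 * sum(log(diag(cholH)))
  nj <- tabulate(comp_index, nbins = length(lambda))
  Sj <- vapply(seq_along(lambda), function(j) sum(e[comp_index == j]^2), 0)
  ph <- 1 / hyper$var
  dl <- lambda - hyper$mean
  shq <- 1 / (0.5 * exp(lambda) * Sj + ph)
  Fv <- -0.5 * n * log(2 * pi) + 0.5 * sum(nj * lambda) - 0.5 * sum(pe * e^2) -
    0.5 * sum(dtheta * (P0 %*% dtheta)) - 0.5 * logdet(prior$cov) +
    0.5 * ld_Sq -
    0.5 * sum(ph * dl^2) - 0.5 * sum(log(hyper$var)) + 0.5 * sum(log(shq))
  list(F = Fv, Sq = Sq, H = H, pe = pe, Sj = Sj, nj = nj, shq = shq)
}

## central finite-difference Jacobian of g at theta
fd_jacobian <- function(g_fun, theta, h, n_out) {
  p <- length(theta)
  J <- matrix(0, n_out, p)
  for (i in seq_len(p)) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    J[, i] <- (g_fun(tp) - g_fun(tm)) / (2 * h)
  }
  J
}

#' Variational-Laplace fit of a nonlinear-Gaussian model
#'
#' Generic engine behind [dcm_fit()]: maximises the Laplace free energy of
#' the model `y = g(theta) + e`, `e ~ N(0, exp(-lambda) I)`, over a Gaussian
#' posterior on `theta` and the log-precision(s) `lambda`, by Gauss-Newton
#' ascent with Levenberg-Marquardt damping. Steps are accepted only if they
#' increase the free energy, so the recorded trajectory is monotone
#' non-decreasing. On linear-Gaussian problems with a (near-)fixed `lambda`
#' the converged free energy equals the exact log evidence and the posterior
#' the conjugate posterior.
#'
#' @param y Numeric data vector.
#' @param g_fun Forward model: function from a named parameter vector to a
#'   prediction vector of `length(y)`.
#' @param prior `gaussian_density` over the parameters.
#' @param settings A [dcm_settings()] list.
#' @param n_lambda Number of noise components (log-precisions).
#' @param comp_index Integer vector assigning each element of `y` to a noise
#'   component (defaults to a single shared component).
#' @return List with `posterior`, `hyper_posterior` (both
#'   `gaussian_density`), `free_energy`, `trajectory` (free energy per
#'   accepted iteration), `iterations`, and `prediction` (at the posterior
#'   mean).
#' @export
vl_fit <- function(y, g_fun, prior, settings = dcm_settings(),
                   n_lambda = 1, comp_index = NULL) {
  if (!length(y)) stop_dcm("empty data")
  mu <- prior$mean
  p <- length(mu)
  if (is.null(comp_index)) comp_index <- rep(1L, length(y))
  n_lambda <- max(n_lambda, max(comp_index))
  hyper <- list(mean = rep(settings$hyper_mean, n_lambda),
                var = rep(settings$hyper_var, n_lambda))
  lambda <- hyper$mean

  eval_state <- function(mu, lambda) {
    gpred <- tryCatch(g_fun(mu), error = function(err) err)
    if (inherits(gpred, "error") || !is_finite_all(gpred)) return(NULL)
    e <- y - gpred
    J <- tryCatch(fd_jacobian(g_fun, mu, settings$fd_step, length(y)),
                  error = function(err) NULL)
    if (is.null(J) || !is_finite_all(J)) return(NULL)
    obj <- vl_objective(e, J, mu, lambda, prior, hyper, comp_index)
    if (!is.finite(obj$F)) return(NULL)
    c(list(mu = mu, lambda = lambda, e = e, J = J, g = gpred), obj)
  }

  st <- eval_state(mu, lambda)
  if (is.null(st)) {
    stop_dcm(paste("forward model fails at the prior mean;",
                   "revise the priors (e.g. shrink connection gains)"),
             class = "dcm_instability")
  }
  P0 <- inv_sym(prior$cov)
  tau <- settings$lm_init
  trajectory <- st$F
  run <- 0L
  iter <- 0L
  while (iter < settings$max_iter) {
    iter <- iter + 1L
    improved <- FALSE
    ## --- parameter (Gauss-Newton / LM) step ---
    grad <- crossprod(st$J, st$pe * st$e) - P0 %*% (st$mu - prior$mean)
    H <- st$H
    for (try in 1:8) {
      Hd <- H + tau * diag(pmax(diag(H), 1e-12), p)
      step <- tryCatch(solve(Hd, grad), error = function(e2) NULL)
      if (!is.null(step)) {
        cand <- eval_state(st$mu + as.numeric(step), st$lambda)
        if (!is.null(cand) && cand$F > st$F) {
          st <- cand
          tau <- tau / 2
          improved <- TRUE
          break
        }
      }
      tau <- tau * 8
    }
    ## --- hyperparameter (log-precision) step ---
    lam <- st$lambda
    ph <- 1 / hyper$var
    for (j in seq_len(n_lambda)) {
      for (newton in 1:8) {
        gl <- 0.5 * st$nj[j] - 0.5 * exp(lam[j]) * st$Sj[j] -
          ph[j] * (lam[j] - hyper$mean[j])
        hl <- 0.5 * exp(lam[j]) * st$Sj[j] + ph[j]
        dstep <- gl / hl
        if (abs(dstep) < 1e-10) break
        lam[j] <- lam[j] + sign(dstep) * min(abs(dstep), 4)
      }
    }
    if (any(lam != st$lambda)) {
      obj <- vl_objective(st$e, st$J, st$mu, lam, prior, hyper, comp_index)
      if (is.finite(obj$F) && obj$F > st$F) {
        st <- c(list(mu = st$mu, lambda = lam, e = st$e, J = st$J, g = st$g), obj)
        improved <- TRUE
      }
    }
    dF <- st$F - trajectory[length(trajectory)]
    trajectory <- c(trajectory, st$F)
    run <- if (abs(dF) < settings$tol_nats) run + 1L else 0L
    if (run >= settings$tol_run) break
    if (!improved && tau > 1e12) break
  }
  posterior <- gaussian_density(st$mu, symm(st$Sq), names = prior$names)
  hyper_posterior <- gaussian_density(st$lambda, diag(st$shq, n_lambda),
                                      names = paste0("lambda", seq_len(n_lambda)))
  list(posterior = posterior, hyper_posterior = hyper_posterior,
       free_energy = st$F, trajectory = trajectory, iterations = iter,
       prediction = st$g, residual = st$e)
}

#' Laplace free energy of a candidate posterior
#'
#' Evaluates the free-energy (log-evidence) bound for a given approximate
#' posterior `q` over forward-model parameters: the log-likelihood of the
#' data at the posterior mean, penalised by the complexity terms that
#' compare `q` with the prior. With `q` equal to the Gauss-Newton posterior
#' this is the quantity [vl_fit()] maximises; on linear-Gaussian problems it
#' equals the exact log marginal likelihood.
#'
#' @param q Approximate posterior (`gaussian_density`) over the free
#'   parameters.
#' @param prior Prior `gaussian_density` over the same parameters.
#' @param data Observed `spectral_data`.
#' @param model A `dcm_model` whose free parameters `q` covers.
#' @param lambda Log-precision(s) of observation noise (treated as fixed).
#' @return Free energy in nats.
#' @export
free_energy <- function(q, prior, data, model, lambda = 0) {
  q <- align_density(q, prior$names)
  pred <- predict_csd(apply_theta(model, q$mean), data$freqs)
  ll <- loglik_csd(data, pred, lambda)
  P0 <- inv_sym(prior$cov)
  d <- q$mean - prior$mean
  ll - 0.5 * sum(d * (P0 %*% d)) - 0.5 * logdet(prior$cov) + 0.5 * logdet(q$cov)
}
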