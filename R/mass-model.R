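#' Centred sigmoid firing-rate function
#'
#' Maps mean depolarization to population firing rate. The logistic is
#' centred so that `sigmoid(0, r, eta) == 0`, which makes the origin a fixed
#' point of the mass-model dynamics in the absence of input and allows exact
#' linearisation around rest.
#'
#' @param v Depolarization (mV); vectorised.
#' @param r Sigmoid slope (mV^-1), must be positive.
#' @param eta Sigmoid inflection point (mV).
#' @return Firing rate (dimensionless), in (-sigmoid0, 1 - sigmoid0).
#' @examples
#' sigmoid(0, 0.54, 0)        # exactly 0
#' sigmoid(1e3, 0.54, 0)      # saturates at 0.5 for eta = 0
#' @export
sigmoid <- function(v, r, eta = 0) {
  if (r <= 0) stop_dcm("sigmoid slope r must be positive")
  plogis(r * (v - eta)) - plogis(-r * eta)
}

## derivative of the centred sigmoid w.r.t. v
dsigmoid <- function(v, r, eta = 0) {
  p <- plogis(r * (v - eta))
  r * p * (1 - p)
}

## Signed gain matrix of the four-population circuit: entry [q, p] multiplies
## sigma(v_p) in the drift of population q. Excitatory and inhibitory roles
## are fixed by the circuit topology; gains themselves are positive.
mass_gain_matrix <- function(a) {
  G <- matrix(0, 4, 4)
  G[1, 1] <- -a[["a11"]]; G[1, 4] <- +a[["a14"]]
  G[2, 2] <- -a[["a22"]]; G[2, 3] <- +a[["a23"]]
  G[3, 1] <- -a[["a31"]]; G[3, 2] <- -a[["a32"]]
  G[3, 3] <- -a[["a33"]]; G[3, 4] <- +a[["a34"]]
  G[4, 1] <- -a[["a41"]]; G[4, 4] <- -a[["a44"]]
  G
}

MASS_GAIN_NAMES <- c("a11", "a14", "a23", "a22", "a32",
                     "a31", "a33", "a34", "a41", "a44")

#' Four-population neural-mass model
#'
#' Constructs a convolution-type neural mass with four populations (two
#' pyramidal subpopulations plus excitatory and inhibitory interneuron
#' pools). Each population's mean depolarization obeys second-order synaptic
#' dynamics, \eqn{\ddot v_q = \kappa_q f_q(v, U) - 2\kappa_q \dot v_q -
#' \kappa_q^2 v_q}, where \eqn{f_q} mixes sigmoid firing rates of afferent
#' populations through ten signed connection gains and exogenous input `U`
#' enters populations according to `B_weights` (population 1 only, by
#' default).
#'
#' Positive parameters (rate constants, gains, spectral amplitudes) are
#' stored as prior-mean base values; model inversion estimates dimensionless
#' log-scalings of these bases, so Gaussian priors act multiplicatively and
#' positivity is automatic.
#'
#' @param kappa Postsynaptic rate constants for the four populations (s^-1).
#'   Defaults give 2 ms kinetics for the fast pair (populations 1, 4) and
#'   10 ms for the slow pair (populations 2, 3).
#' @param a Named vector of the ten connection gains
#'   (`a11, a14, a23, a22, a32, a31, a33, a34, a41, a44`), dimensionless.
#' @param r,eta Sigmoid slope (mV^-1) and inflection (mV).
#' @param Lw Observation weight matrix, channels x 4 populations. Each row is
#'   one channel's lead weights onto the population depolarizations.
#' @param B_weights Input weight per population (default `c(1, 0, 0, 0)`:
#'   exogenous input drives population 1 only).
#' @param alpha_u,beta_u White and pink amplitudes of the exogenous input
#'   spectrum, stored on the log scale (0 means unit amplitude).
#' @param alpha_n,beta_n White and pink amplitudes of channel noise
#'   (log scale).
#' @param channels Optional channel labels (defaults to `ch1`, ...).
#' @return An object of class `c("dcm_mass", "dcm_model")`.
#' @examples
#' m <- mass_model()
#' m
#' @export
mass_model <- function(kappa = c(500, 100, 100, 500),
                       a = c(a11 = 1000, a14 = 2000, a23 = 600, a22 = 400,
                             a32 = 600, a31 = 400, a33 = 400, a34 = 1500,
                             a41 = 2000, a44 = 1000),
                       r = 0.54, eta = 0,
                       Lw = matrix(4000 * c(0.2, 0, 0.2, 0.6), 1, 4),
                       alpha_u = 0, beta_u = 0,
                       alpha_n = log(0.01), beta_n = log(0.01),
                       B_weights = c(1, 0, 0, 0), channels = NULL) {
  kappa <- as.numeric(kappa)
  if (length(kappa) != 4 || any(kappa <= 0)) stop_dcm("kappa must be 4 positive rate constants")
  a <- unlist(a)[MASS_GAIN_NAMES]
  if (anyNA(a) || any(a < 0)) stop_dcm("a must contain non-negative gains %s",
                                       paste(MASS_GAIN_NAMES, collapse = ", "))
  Lw <- as.matrix(Lw)
  if (ncol(Lw) != 4) stop_dcm("Lw must have 4 columns (one per population)")
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(Lw)))
  B_weights <- as.numeric(B_weights)
  if (length(B_weights) != 4) stop_dcm("B_weights must have length 4")
  structure(list(kappa = kappa, a = a, r = r, eta = eta, Lw = Lw,
                 alpha_u = alpha_u, beta_u = beta_u,
                 alpha_n = alpha_n, beta_n = beta_n,
                 B_weights = B_weights,
                 channels = as.character(channels)),
            class = c("dcm_mass", "dcm_model"))
}

#' @export
print.dcm_mass <- function(x, ...) {
  cat("Four-population neural-mass model\n")
  cat("  kappa (s^-1):", paste(signif(x$kappa, 4), collapse = ", "), "\n")
  cat("  gains:", paste(names(x$a), signif(x$a, 3), sep = "=", collapse = " "), "\n")
  cat("  sigmoid: r =", x$r, " eta =", x$eta, "\n")
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

## Names of the log-scaling parameters a fit may free up.
#' Free-parameter names of a model
#'
#' Returns the names of the dimensionless log-scaling parameters that
#' `dcm_fit()` can estimate for a given forward model.
#'
#' @param model A `dcm_model`.
#' @return Character vector of parameter names.
#' @export
free_param_names <- function(model) UseMethod("free_param_names")

#' @export
free_param_names.dcm_mass <- function(model) {
  c(paste0("kappa", 1:4), MASS_GAIN_NAMES, "alpha_u", "beta_u", "alpha_n", "beta_n")
}

## Apply a named vector of log-scalings to the base model, returning a new
## model whose positive parameters are base * exp(theta). Spectral amplitudes
## are stored on the log scale already, so scalings add.
apply_theta <- function(model, theta) UseMethod("apply_theta")

#' @export
apply_theta.dcm_mass <- function(model, theta) {
  if (length(theta) == 0) return(model)
  nm <- names(theta)
  unknown <- setdiff(nm, free_param_names(model))
  if (length(unknown)) stop_dcm("unknown parameters: %s", paste(unknown, collapse = ", "))
  m <- model
  for (i in 1:4) {
    key <- paste0("kappa", i)
    if (key %in% nm) m$kappa[i] <- m$kappa[i] * exp(theta[[key]])
  }
  for (key in intersect(MASS_GAIN_NAMES, nm)) m$a[[key]] <- m$a[[key]] * exp(theta[[key]])
  for (key in intersect(c("alpha_u", "beta_u", "alpha_n", "beta_n"), nm)) {
    m[[key]] <- m[[key]] + theta[[key]]
  }
  m
}

#' Drift of the neural-mass state equations
#'
#' Evaluates the time derivative of the 8-dimensional state
#' \eqn{(v_1..v_4, \dot v_1..\dot v_4)} under the second-order convolution
#' dynamics.
#'
#' @param state Numeric length-8 state vector.
#' @param model A `dcm_mass` model.
#' @param U Exogenous input to population 1 (scalar).
#' @return Length-8 derivative vector.
#' @examples
#' drift_mass(rep(0, 8), mass_model(), 0)  # origin is a fixed point
#' @export
drift_mass <- function(state, model, U = 0) {
  if (!is_finite_all(state)) stop_dcm("non-finite state: numerical blow-up")
  v <- state[1:4]; vd <- state[5:8]
  G <- mass_gain_matrix(model$a)
  f <- as.numeric(G %*% sigmoid(v, model$r, model$eta)) + model$B_weights * U
  k <- model$kappa
  c(vd, k * f - 2 * k * vd - k^2 * v)
}

#' Equilibrium depolarizations of the mass model
#'
#' Finds the fixed point of the population dynamics for a constant input by
#' Newton iteration started at the origin. With the centred sigmoid and zero
#' input the origin itself is the equilibrium.
#'
#' @param model A `dcm_mass` model.
#' @param U0 Constant exogenous input.
#' @param tol Convergence tolerance on the drift residual.
#' @param max_iter Newton iteration budget.
#' @return Length-4 vector of equilibrium depolarizations `v*`.
#' @export
fixed_point <- function(model, U0 = 0, tol = 1e-12, max_iter = 64) {
  if (U0 == 0) return(rep(0, 4))   # centred sigmoid: exact
  k <- model$kappa
  v <- rep(0, 4)
  G <- mass_gain_matrix(model$a)
  for (iter in seq_len(max_iter)) {
    fv <- as.numeric(G %*% sigmoid(v, model$r, model$eta)) + model$B_weights * U0 - k * v
    if (!is_finite_all(fv)) {
      stop_dcm("fixed-point iteration diverged (population %d non-finite)",
               which(!is.finite(fv))[1])
    }
    if (max(abs(fv)) < tol) return(v)
    J <- G * rep(dsigmoid(v, model$r, model$eta), each = 4) - diag(k)
    step <- tryCatch(solve(J, fv), error = function(e) NULL)
    if (is.null(step)) stop_dcm("singular Newton system in fixed_point")
    v <- v - step
  }
  fv <- as.numeric(G %*% sigmoid(v, model$r, model$eta)) + model$B_weights * U0 - k * v
  if (max(abs(fv)) < 1e-6) return(v)
  stop_dcm("fixed_point did not converge (worst residual on population %d)",
           which.max(abs(fv)))
}

#' Jacobian of the mass-model dynamics at an equilibrium
#'
#' Linearises the 8-dimensional state equations around a fixed point. The
#' matrix has the second-order block structure
#' \eqn{[[0, I], [\kappa \circ \partial f/\partial v - \kappa^2 I,
#' -2\kappa I]]}.
#'
#' @param model A `dcm_mass` model.
#' @param vstar Length-4 equilibrium depolarizations (default origin).
#' @return 8 x 8 real matrix.
#' @export
jacobian_mass <- function(model, vstar = rep(0, 4)) {
  k <- model$kappa
  G <- mass_gain_matrix(model$a)
  dfdv <- G * rep(dsigmoid(vstar, model$r, model$eta), each = 4)
  rbind(cbind(matrix(0, 4, 4), diag(4)),
        cbind(k * dfdv - diag(k^2), diag(-2 * k)))
}

## Shared linear-system transfer evaluation: T(omega) = C (i w I - J)^-1 B,
## vectorised over omega via eigendecomposition when J is well conditioned.
transfer_linear <- function(J, B, C, omega) {
  n <- nrow(J)
  eg <- eigen(J)
  V <- eg$vectors
  Vi <- tryCatch(solve(V), error = function(e) NULL)
  kv <- if (is.null(Vi)) Inf else sqrt(sum(Mod(V)^2)) * sqrt(sum(Mod(Vi)^2))
  use_eigen <- is.finite(kv) && kv < 1e10
  Tc <- matrix(0 + 0i, length(omega), nrow(C))
  if (use_eigen) {
    W <- C %*% V            # channels x n
    z <- Vi %*% B           # n x 1
    for (j in seq_len(n)) {
      Tc <- Tc + outer(1 / (1i * omega - eg$values[j]), W[, j] * z[j])
    }
  } else {
    for (i in seq_along(omega)) {
      Tc[i, ] <- C %*% solve(diag(1i * omega[i], n) - J, B)
    }
  }
  Tc
}

#' Transfer function of the linearised mass model
#'
#' Linearises the mass model around its resting fixed point and returns the
#' frequency response from the exogenous input to each observed channel,
#' \eqn{T(\omega) = C (i\omega I - J)^{-1} B}, where `B` injects the input
#' into the \eqn{\dot v_1} equation scaled by \eqn{\kappa_1} and `C` reads
#' the weighted population depolarizations.
#'
#' @param model A `dcm_mass` model.
#' @param omega Angular frequencies (rad/s); vectorised.
#' @param vstar Optional equilibrium (default: fixed point at zero input).
#' @return Complex matrix, `length(omega)` x channels.
#' @export
transfer_mass <- function(model, omega, vstar = NULL) {
  if (is.null(vstar)) vstar <- fixed_point(model, 0)
  J <- jacobian_mass(model, vstar)
  ev <- eigen(J, only.values = TRUE)$values
  if (max(Re(ev)) >= -1e-9) {
    stop_dcm(paste("linearised mass model is unstable (max Re eigenvalue %.3g);",
                   "consider shrinking connection-gain priors"), max(Re(ev)),
             class = "dcm_instability")
  }
  B <- c(rep(0, 4), model$kappa * model$B_weights)
  C <- cbind(model$Lw, matrix(0, nrow(model$Lw), 4))
  transfer_linear(J, B, C, omega)
}
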