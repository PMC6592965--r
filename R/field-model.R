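FIELD_KERNEL_NAMES <- c("alpha11", "alpha14", "alpha12", "alpha22", "alpha21",
                        "alpha23", "alpha33", "alpha41", "alpha32", "alpha44")

## Default sign of each connectivity kernel: sources 1 and 2 project
## inhibition, self-connections are inhibitory (recurrent gain control),
## kernels 1<-4 and 2<-3 are the excitatory drives. The sign matrix is a
## configuration default, not an estimated quantity.
FIELD_KERNEL_SIGNS <- c(alpha11 = -1, alpha14 = +1, alpha12 = -1, alpha22 = -1,
                        alpha21 = -1, alpha23 = +1, alpha33 = -1, alpha41 = -1,
                        alpha32 = -1, alpha44 = -1)

## (target, source) population index of each named kernel
FIELD_KERNEL_INDEX <- cbind(target = c(1, 1, 1, 2, 2, 2, 3, 4, 3, 4),
                            source = c(1, 4, 2, 2, 1, 3, 3, 1, 2, 4))

#' Four-population neural-field model
#'
#' Constructs a spatially extended variant of the four-population circuit on
#' a bounded one-dimensional cortical patch. Lateral connectivity between
#' populations follows exponentially decaying kernels
#' \eqn{\alpha\,e^{-c|x|}} with axonal conduction delay \eqn{|x|/s}; the
#' patch supports cosine modes with wavenumbers \eqn{k_j = j\pi/L}. The
#' sensor sees each population through a Gaussian lead field with spatial
#' dispersion `phi` and per-population contribution weights `q` (inhibitory
#' interneurons generate no appreciable dipole, hence a zero default
#' weight for population 2).
#'
#' @param kappa Postsynaptic rate constants (s^-1); defaults are 1/2, 1/35,
#'   1/35, 1/2 ms^-1.
#' @param alpha Named amplitudes of the ten intrinsic connectivity kernels
#'   (a.u.).
#' @param c_diag,c_offdiag Spatial decay of self- and between-population
#'   kernels (mm^-1).
#' @param s Conduction speed (m/s).
#' @param r,eta Firing-rate sigmoid slope (mV^-1) and inflection (mV).
#' @param phi Lead-field dispersion (mm).
#' @param q Length-4 population contribution weights.
#' @param lead_gain Overall observation gain (a.u.), scales the signal part
#'   of the spectrum.
#' @param alpha_u,beta_u,alpha_n,beta_n Input and channel-noise spectral
#'   amplitudes (log scale).
#' @param patch_length Spatial domain size L (mm).
#' @param n_modes Number of retained cosine modes (wavenumbers).
#' @param channels Channel labels (single sensor by default).
#' @return An object of class `c("dcm_field", "dcm_model")`.
#' @examples
#' field_model()
#' @export
field_model <- function(kappa = c(500, 1000 / 35, 1000 / 35, 500),
                        alpha = c(alpha11 = 108, alpha14 = 45, alpha12 = 1.89,
                                  alpha22 = 162, alpha21 = 18, alpha23 = 45,
                                  alpha33 = 36, alpha41 = 18, alpha32 = 9,
                                  alpha44 = 18),
                        c_diag = 2, c_offdiag = 0.6, s = 0.3,
                        r = 0.54, eta = 0, phi = sqrt(2) / 16,
                        q = c(0.2, 0, 0.2, 0.6), lead_gain = 4000,
                        alpha_u = 0, beta_u = 0,
                        alpha_n = log(0.01), beta_n = log(0.01),
                        patch_length = 10, n_modes = 32,
                        channels = "sensor") {
  kappa <- as.numeric(kappa)
  if (length(kappa) != 4 || any(kappa <= 0)) stop_dcm("kappa must be 4 positive rate constants")
  alpha <- unlist(alpha)[FIELD_KERNEL_NAMES]
  if (anyNA(alpha) || any(alpha < 0)) {
    stop_dcm("alpha must contain non-negative amplitudes %s",
             paste(FIELD_KERNEL_NAMES, collapse = ", "))
  }
  if (c_diag <= 0 || c_offdiag <= 0) stop_dcm("kernel decays must be positive")
  if (s <= 0) stop_dcm("conduction speed must be positive")
  if (n_modes < 1) stop_dcm("n_modes must be at least 1")
  q <- as.numeric(q)
  if (length(q) != 4 || !is_finite_all(q)) stop_dcm("q must be 4 finite weights")
  structure(list(kappa = kappa, alpha = alpha, c_diag = c_diag,
                 c_offdiag = c_offdiag, s = s, r = r, eta = eta, phi = phi,
                 q = q, lead_gain = lead_gain,
                 alpha_u = alpha_u, beta_u = beta_u,
                 alpha_n = alpha_n, beta_n = beta_n,
                 patch_length = patch_length, n_modes = as.integer(n_modes),
                 channels = as.character(channels)),
            class = c("dcm_field", "dcm_model"))
}

#' @export
print.dcm_field <- function(x, ...) {
  cat("Four-population neural-field model\n")
  cat("  kappa (s^-1):", paste(signif(x$kappa, 4), collapse = ", "), "\n")
  cat("  kernel amplitudes:",
      paste(names(x$alpha), signif(x$alpha, 3), sep = "=", collapse = " "), "\n")
  cat(sprintf("  decays: %.3g (self) / %.3g (lateral) mm^-1; speed %.3g m/s\n",
              x$c_diag, x$c_offdiag, x$s))
  cat(sprintf("  patch %g mm, %d modes; lead dispersion %.4g mm\n",
              x$patch_length, x$n_modes, x$phi))
  invisible(x)
}

#' @export
free_param_names.dcm_field <- function(model) {
  c(paste0("kappa", 1:4), FIELD_KERNEL_NAMES, "alpha_u", "beta_u", "alpha_n", "beta_n")
}

#' @export
apply_theta.dcm_field <- function(model, theta) {
  if (length(theta) == 0) return(model)
  nm <- names(theta)
  unknown <- setdiff(nm, free_param_names(model))
  if (length(unknown)) stop_dcm("unknown parameters: %s", paste(unknown, collapse = ", "))
  m <- model
  for (i in 1:4) {
    key <- paste0("kappa", i)
    if (key %in% nm) m$kappa[i] <- m$kappa[i] * exp(theta[[key]])
  }
  for (key in intersect(FIELD_KERNEL_NAMES, nm)) m$alpha[[key]] <- m$alpha[[key]] * exp(theta[[key]])
  for (key in intersect(c("alpha_u", "beta_u", "alpha_n", "beta_n"), nm)) {
    m[[key]] <- m[[key]] + theta[[key]]
  }
  m
}

#' Fourier transform of a delayed exponential connectivity kernel
#'
#' Closed form of the spatial Fourier transform of \eqn{\alpha e^{-c|x|}}
#' with axonal delay \eqn{|x|/s}:
#' \deqn{2\alpha (c + i\omega/s) / ((c + i\omega/s)^2 + k^2).}
#' At \eqn{k = 0, \omega = 0} this reduces to the total kernel mass
#' \eqn{2\alpha/c}; as \eqn{s \to \infty} it becomes the delay-free
#' Lorentzian \eqn{2\alpha c/(c^2 + k^2)}.
#'
#' @param alpha Kernel amplitude (a.u.).
#' @param c Spatial decay (mm^-1), positive.
#' @param s Conduction speed in mm/s (same spatial units as `c`).
#' @param k Wavenumber (mm^-1).
#' @param omega Angular frequency (rad/s).
#' @return Complex coupling value (vectorised over `k` and/or `omega`).
#' @examples
#' kernel_ft_field(1, 0.6, 300, 0, 0)  # 2/0.6
#' @export
kernel_ft_field <- function(alpha, c, s, k, omega) {
  if (any(c <= 0)) stop_dcm("kernel decay c must be positive")
  if (any(s <= 0)) stop_dcm("conduction speed s must be positive")
  cz <- c + 1i * omega / s
  2 * alpha * cz / (cz^2 + k^2)
}

## Wavenumber grid of the bounded patch: cosine modes k_j = j pi / L.
field_wavenumbers <- function(model) {
  (seq_len(model$n_modes) - 1) * pi / model$patch_length
}

## Signed, k- and omega-dependent effective gain matrix. Each kernel's
## Fourier transform is normalised by its total mass 2 alpha / c so that at
## k = 0, omega = 0 the effective gain equals alpha itself, matching the
## point-source (mass model) linearisation.
field_gain_matrix <- function(model, k, omega) {
  G <- matrix(0 + 0i, 4, 4)
  for (j in seq_along(FIELD_KERNEL_NAMES)) {
    nm <- FIELD_KERNEL_NAMES[j]
    tg <- FIELD_KERNEL_INDEX[j, "target"]; sc <- FIELD_KERNEL_INDEX[j, "source"]
    cc <- if (tg == sc) model$c_diag else model$c_offdiag
    ft <- kernel_ft_field(model$alpha[[nm]], cc, model$s * 1000, k, omega)
    G[tg, sc] <- G[tg, sc] + FIELD_KERNEL_SIGNS[[nm]] * ft * cc / 2
  }
  G
}

## delay-free Jacobian of the field dynamics at wavenumber k (stability proxy)
field_jacobian_k <- function(model, k) {
  kap <- model$kappa
  G0 <- Re(field_gain_matrix(model, k, 0))
  dfdv <- G0 * dsigmoid(0, model$r, model$eta)
  rbind(cbind(matrix(0, 4, 4), diag(4)),
        cbind(kap * dfdv - diag(kap^2), diag(-2 * kap)))
}

#' Transfer function of the linearised field model at one wavenumber
#'
#' Builds the wavenumber-dependent linearisation by replacing each
#' connection gain with the (normalised) Fourier transform of its delayed
#' exponential kernel, and returns
#' \eqn{T_r(k,\omega) = L_r(k,\varphi)\, Q\, (i\omega I - J(k,\omega))^{-1} B}
#' with Gaussian lead field \eqn{L_r(k,\varphi) = \exp(-\varphi^2 k^2 / 2)}.
#'
#' @param model A `dcm_field` model.
#' @param k Single wavenumber (mm^-1).
#' @param omega Angular frequencies (rad/s); vectorised.
#' @return Complex matrix `length(omega)` x channels.
#' @export
transfer_field <- function(model, k, omega) {
  kap <- model$kappa
  ev <- eigen(field_jacobian_k(model, k), only.values = TRUE)$values
  if (max(Re(ev)) >= -1e-9) {
    stop_dcm("field model unstable at wavenumber k = %.4g mm^-1 (max Re eigenvalue %.3g)",
             k, max(Re(ev)), class = "dcm_instability")
  }
  lead <- exp(-model$phi^2 * k^2 / 2) * model$lead_gain
  B <- c(rep(0, 4), kap[1], 0, 0, 0)
  Crow <- c(model$q, rep(0, 4)) * lead
  sig1 <- dsigmoid(0, model$r, model$eta)
  out <- matrix(0 + 0i, length(omega), 1)
  for (i in seq_along(omega)) {
    G <- field_gain_matrix(model, k, omega[i]) * sig1
    J <- rbind(cbind(matrix(0, 4, 4), diag(4)),
               cbind(kap * G - diag(kap^2), diag(-2 * kap)))
    out[i, 1] <- sum(Crow * solve(diag(1i * omega[i], 8) - J, B))
  }
  colnames(out) <- model$channels
  out
}

#' @export
predict_csd.dcm_field <- function(model, freqs) {
  freqs <- as.numeric(freqs)
  if (any(freqs <= 0)) stop_dcm("frequencies must be positive")
  omega <- 2 * pi * freqs
  gu <- one_over_f_spectrum(model$alpha_u, model$beta_u, freqs)
  gn <- one_over_f_spectrum(model$alpha_n, model$beta_n, freqs)
  nf <- length(freqs)
  acc <- rep(0 + 0i, nf)
  for (k in field_wavenumbers(model)) {
    Tk <- transfer_field(model, k, omega)[, 1]
    acc <- acc + Tk * gu * Conj(Tk)
  }
  csd <- array(acc + gn, c(nf, 1, 1))
  spectral_data(freqs, csd, model$channels, validate = FALSE)
}
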