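#' Cross-spectral data container
#'
#' Holds complex cross-spectral densities on a frequency grid: a
#' `freq x channel x channel` complex array that is Hermitian at every
#' frequency.
#'
#' @param freqs Frequencies in Hz (strictly positive, increasing).
#' @param csd Complex array `length(freqs) x n x n`, or for a single channel
#'   a numeric/complex vector of auto-spectra.
#' @param channels Channel labels (default `ch1`, ...).
#' @param validate Check the Hermitian invariants (default `TRUE`).
#' @return An object of class `spectral_data`.
#' @export
spectral_data <- function(freqs, csd, channels = NULL, validate = TRUE) {
  freqs <- as.numeric(freqs)
  if (any(freqs <= 0)) stop_dcm("frequencies must be positive (Hz)")
  if (is.null(dim(csd))) csd <- array(csd, c(length(csd), 1, 1))
  if (length(dim(csd)) != 3 || dim(csd)[2] != dim(csd)[3]) {
    stop_dcm("csd must be a freq x channel x channel array")
  }
  if (dim(csd)[1] != length(freqs)) stop_dcm("csd first dimension must match freqs")
  n <- dim(csd)[2]
  if (is.null(channels)) channels <- paste0("ch", seq_len(n))
  if (length(channels) != n) stop_dcm("channel labels do not match csd dimension")
  storage.mode(csd) <- "complex"
  if (validate) {
    for (i in seq_along(freqs)) {
      S <- csd[i, , , drop = TRUE]
      if (n == 1) S <- matrix(S, 1, 1)
      if (max(Mod(S - Conj(t(S)))) > 1e-8 * max(1, max(Mod(S)))) {
        stop_dcm("csd is not Hermitian at %g Hz", freqs[i])
      }
    }
  }
  structure(list(freqs = freqs, csd = csd, channels = as.character(channels)),
            class = "spectral_data")
}

#' @export
print.spectral_data <- function(x, ...) {
  cat(sprintf("Cross-spectral data: %d frequencies (%.3g-%.3g Hz), %d channel(s): %s\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$channels), paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' @export
plot.spectral_data <- function(x, log = "y", ...) {
  n <- length(x$channels)
  A <- sapply(seq_len(n), function(i) Re(x$csd[, i, i]))
  matplot(x$freqs, A, type = "l", lty = 1, log = log,
          xlab = "Frequency (Hz)", ylab = "Auto-spectral density", ...)
  legend("topright", legend = x$channels, col = seq_len(n), lty = 1, bty = "n")
  invisible(x)
}

## number of real-valued data points in the stacked Re/Im representation
n_stacked <- function(x) {
  n <- length(x$channels)
  length(x$freqs) * (n * (n + 1) / 2 + n * (n - 1) / 2)
}

## Stack upper-triangular cross-spectra into a real vector:
## Re for all pairs i <= j, Im for pairs i < j (diagonal Im is identically 0).
stack_csd <- function(x) {
  n <- length(x$channels)
  out <- c()
  for (i in seq_len(n)) for (j in i:n) out <- c(out, Re(x$csd[, i, j]))
  if (n > 1) for (i in seq_len(n - 1)) for (j in (i + 1):n) out <- c(out, Im(x$csd[, i, j]))
  out
}

## inverse of stack_csd
unstack_csd <- function(vec, freqs, channels) {
  n <- length(channels); nf <- length(freqs)
  csd <- array(0 + 0i, c(nf, n, n))
  pos <- 0
  for (i in seq_len(n)) for (j in i:n) {
    re <- vec[pos + seq_len(nf)]; pos <- pos + nf
    csd[, i, j] <- csd[, i, j] + re
    if (i != j) csd[, j, i] <- csd[, j, i] + re
  }
  if (n > 1) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    im <- vec[pos + seq_len(nf)]; pos <- pos + nf
    csd[, i, j] <- csd[, i, j] + 1i * im
    csd[, j, i] <- csd[, j, i] - 1i * im
  }
  spectral_data(freqs, csd, channels, validate = FALSE)
}

#' White-plus-pink (1/f) spectral density
#'
#' Evaluates \eqn{\exp(\alpha) + \exp(\beta)/f}: a mixture of a white
#' component and a pink component, with amplitudes stored on the log scale so
#' Gaussian priors on \eqn{\alpha, \beta} act multiplicatively.
#'
#' @param alpha Log amplitude of the white component.
#' @param beta Log amplitude of the pink component.
#' @param freq Frequency (Hz), strictly positive; vectorised.
#' @return Spectral density on the natural scale.
#' @examples
#' one_over_f_spectrum(log(1), log(2), 2)  # 1 + 2/2 = 2
#' @export
one_over_f_spectrum <- function(alpha, beta, freq) {
  if (any(freq <= 0)) stop_dcm("frequency must be positive")
  exp(alpha) + exp(beta) / freq
}

#' Predicted cross-spectral density of a forward model
#'
#' Maps model parameters to the complex cross-spectral density over a
#' frequency grid: \eqn{g_{lm}(\omega) = \sum_k T_l(k,\omega)\, g_u(\omega)\,
#' T_m(k,\omega)^\dagger + g_n(\omega)}, where the transfer functions come
#' from the linearised dynamics, \eqn{g_u} is the white-plus-pink input
#' spectrum and \eqn{g_n} is channel noise added to every element. For the
#' point-source mass model the wavenumber sum has a single term.
#'
#' @param model A `dcm_mass` or `dcm_field` model.
#' @param freqs Frequencies in Hz.
#' @return A `spectral_data` object with the predicted CSD.
#' @examples
#' p <- predict_csd(mass_model(), seq(4, 100, 4))
#' @export
predict_csd <- function(model, freqs) UseMethod("predict_csd")

#' @export
predict_csd.dcm_mass <- function(model, freqs) {
  freqs <- as.numeric(freqs)
  if (any(freqs <= 0)) stop_dcm("frequencies must be positive")
  Tt <- transfer_mass(model, 2 * pi * freqs)      # nf x nc
  gu <- one_over_f_spectrum(model$alpha_u, model$beta_u, freqs)
  gn <- one_over_f_spectrum(model$alpha_n, model$beta_n, freqs)
  nc <- ncol(Tt); nf <- length(freqs)
  csd <- array(0 + 0i, c(nf, nc, nc))
  for (l in seq_len(nc)) for (m in seq_len(nc)) {
    csd[, l, m] <- Tt[, l] * gu * Conj(Tt[, m]) + gn
  }
  spectral_data(freqs, csd, model$channels, validate = FALSE)
}

#' @export
predict.dcm_model <- function(object, freqs = seq(4, 100, by = 1), ...) {
  predict_csd(object, freqs)
}
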