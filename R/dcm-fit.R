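#' Default priors over a model's free parameters
#'
#' Builds a Gaussian prior over the requested log-scaling parameters of a
#' forward model. Log-scalings have prior mean 0 (no scaling of the base
#' model) and a shrinkage variance of 1/4 on kinetic and connection
#' parameters (about +/-64% at one prior SD) and 1 on the input/noise
#' spectral amplitudes, which are typically less well constrained a priori.
#'
#' @param model A `dcm_model`.
#' @param free Names of the free parameters (default: connection gains plus
#'   the four spectral amplitudes).
#' @param var_scaling Prior variance of kinetic/connection log-scalings.
#' @param var_spectral Prior variance of log spectral amplitudes.
#' @return A `gaussian_density`.
#' @export
dcm_priors <- function(model, free = NULL, var_scaling = 1 / 4, var_spectral = 1) {
  all_names <- free_param_names(model)
  if (is.null(free)) {
    free <- setdiff(all_names, paste0("kappa", 1:4))
  }
  unknown <- setdiff(free, all_names)
  if (length(unknown)) stop_dcm("unknown free parameters: %s", paste(unknown, collapse = ", "))
  v <- ifelse(free %in% c("alpha_u", "beta_u", "alpha_n", "beta_n"),
              var_spectral, var_scaling)
  gaussian_density(setNames(rep(0, length(free)), free), v)
}

#' Fit a forward model to observed cross-spectra
#'
#' The central model-fitting function of the package: inverts a neural-mass
#' or neural-field model given complex cross-spectral data, using
#' Variational Laplace ([vl_fit()]) to maximise a free-energy bound on the
#' log model evidence over the model's log-scaling parameters and noise
#' log-precision.
#'
#' @param data A `spectral_data` object (or path to a spectra file).
#' @param model A `dcm_model`; its channel dimension must match the data.
#' @param priors Optional `gaussian_density` over the free parameters
#'   (default [dcm_priors()] for `model`).
#' @param settings A [dcm_settings()] list.
#' @param n_lambda Number of observation-noise components (1 = shared).
#' @return An object of class `dcm_fit` with components `posterior`,
#'   `hyper_posterior`, `free_energy`, `trajectory`, `model` (the base
#'   model), `model_map` (base model with posterior-mean scalings applied),
#'   `data`, and `prediction`.
#' @seealso [summary.dcm_fit()], [predict.dcm_fit()], [reduce_model()],
#'   [peb_fit()]
#' @examples
#' \donttest{
#' truth <- c(a14 = 0.3)
#' sim <- simulate_subject(mass_model(), freqs = seq(6, 90, 3),
#'                         theta = truth, noise_sd = 0.05, seed = 1)
#' fit <- dcm_fit(sim$data, mass_model(),
#'                priors = dcm_priors(mass_model(), free = c("a14", "a41")))
#' summary(fit)
#' }
#' @export
dcm_fit <- function(data, model, priors = NULL, settings = dcm_settings(),
                    n_lambda = 1) {
  if (is.character(data)) data <- read_spectra(data)
  stopifnot(inherits(data, "spectral_data"), inherits(model, "dcm_model"))
  if (length(data$channels) != length(model$channels)) {
    stop_dcm("data has %d channel(s) but the model observes %d",
             length(data$channels), length(model$channels))
  }
  if (is.null(priors)) priors <- dcm_priors(model)
  y <- stack_csd(data)
  freqs <- data$freqs
  g_fun <- function(theta) {
    stack_csd(predict_csd(apply_theta(model, theta), freqs))
  }
  comp_index <- csd_comp_index(data, n_comp = n_lambda)
  res <- vl_fit(y, g_fun, priors, settings = settings,
                n_lambda = n_lambda, comp_index = comp_index)
  model_map <- apply_theta(model, res$posterior$mean)
  structure(list(posterior = res$posterior,
                 hyper_posterior = res$hyper_posterior,
                 free_energy = res$free_energy,
                 trajectory = res$trajectory,
                 iterations = res$iterations,
                 prior = priors, model = model, model_map = model_map,
                 data = data,
                 prediction = predict_csd(model_map, freqs),
                 settings = settings),
            class = "dcm_fit")
}

#' @export
print.dcm_fit <- function(x, ...) {
  cat("Spectral DCM fit (", class(x$model)[1], ")\n", sep = "")
  cat(sprintf("  %d free parameters, %d frequencies, %d channel(s)\n",
              length(x$posterior$mean), length(x$data$freqs),
              length(x$data$channels)))
  cat(sprintf("  free energy: %.3f nats after %d iterations\n",
              x$free_energy, x$iterations))
  invisible(x)
}

#' Summary of a spectral DCM fit
#'
#' @param object A `dcm_fit`.
#' @param level Credible-interval level (default 0.90).
#' @param ... Unused.
#' @return An object of class `summary.dcm_fit`: the parameter table
#'   (posterior mean, SD, credible bounds) plus evidence diagnostics.
#' @export
summary.dcm_fit <- function(object, level = 0.90, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  mu <- object$posterior$mean
  sdv <- sqrt(pmax(diag(object$posterior$cov), 0))
  tab <- data.frame(mean = mu, sd = sdv,
                    lower = mu - z * sdv, upper = mu + z * sdv,
                    row.names = object$posterior$names)
  out <- list(parameters = tab, level = level,
              free_energy = object$free_energy,
              lambda = object$hyper_posterior$mean,
              iterations = object$iterations)
  class(out) <- "summary.dcm_fit"
  out
}

#' @export
print.summary.dcm_fit <- function(x, ...) {
  cat(sprintf("Posterior over log-scaling parameters (%d%% credible intervals):\n",
              round(100 * x$level)))
  print(round(x$parameters, 4))
  cat(sprintf("Noise log-precision: %s\n",
              paste(signif(x$lambda, 4), collapse = ", ")))
  cat(sprintf("Free energy: %.3f nats (%d iterations)\n",
              x$free_energy, x$iterations))
  invisible(x)
}

#' @export
coef.dcm_fit <- function(object, ...) object$posterior$mean

#' @export
vcov.dcm_fit <- function(object, ...) {
  V <- object$posterior$cov
  dimnames(V) <- list(object$posterior$names, object$posterior$names)
  V
}

#' @export
logLik.dcm_fit <- function(object, ...) {
  ll <- loglik_csd(object$data, object$prediction,
                   object$hyper_posterior$mean)
  structure(ll, df = length(object$posterior$mean), class = "logLik")
}

#' Predicted cross-spectra of a fitted model
#'
#' @param object A `dcm_fit`.
#' @param freqs Frequencies in Hz (default: the fitted data's grid).
#' @param ... Unused.
#' @return A `spectral_data` with the posterior-mean prediction.
#' @export
predict.dcm_fit <- function(object, freqs = NULL, ...) {
  if (is.null(freqs)) return(object$prediction)
  predict_csd(object$model_map, freqs)
}

#' @export
fitted.dcm_fit <- function(object, ...) object$prediction

#' @export
residuals.dcm_fit <- function(object, ...) {
  stack_csd(object$data) - stack_csd(object$prediction)
}

#' @export
plot.dcm_fit <- function(x, log = "y", ...) {
  n <- length(x$data$channels)
  op <- par(mfrow = c(1, n)); on.exit(par(op))
  for (i in seq_len(n)) {
    obs <- Re(x$data$csd[, i, i])
    fit <- Re(x$prediction$csd[, i, i])
    ok <- if (log == "y") obs > 0 & fit > 0 else rep(TRUE, length(obs))
    matplot(x$data$freqs[ok], cbind(obs[ok], fit[ok]), type = "l", lty = c(1, 2),
            col = c("grey40", "red"), log = log, xlab = "Frequency (Hz)",
            ylab = "Auto-spectral density", main = x$data$channels[i], ...)
    legend("topright", c("data", "fit"), lty = c(1, 2),
           col = c("grey40", "red"), bty = "n")
  }
  invisible(x)
}

#' Simulate replicate datasets from a fitted model
#'
#' Draws replicate cross-spectral datasets from the fitted model: the
#' posterior-mean prediction plus complex Gaussian noise at the fitted noise
#' precision.
#'
#' @param object A `dcm_fit`.
#' @param nsim Number of replicates.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `spectral_data` objects.
#' @export
simulate.dcm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  noise_sd <- exp(-object$hyper_posterior$mean[1] / 2)
  lapply(seq_len(nsim), function(i) {
    add_csd_noise(object$prediction, noise_sd)
  })
}

#' Extract the free energy (log-evidence bound)
#'
#' @param object A fitted object (`dcm_fit`, `dcm_peb` or
#'   `laminar_assignment`).
#' @return Free energy in nats.
#' @export
free_energy_of <- function(object) {
  if (!is.null(object$free_energy)) return(object$free_energy)
  stop_dcm("object carries no free energy")
}
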