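# Bayesian model reduction: closed-form posterior and evidence change when
# a full model's prior is replaced by a reduced prior, using only the full
# model's posterior.

#' Bayesian model reduction
#'
#' Computes, in closed form from Gaussian precisions, the posterior and the
#' log-evidence change that would result from refitting the model under a
#' different (reduced) prior — without touching the data. For any model
#' whose likelihood is Gaussian in the parameters (e.g. linear regression,
#' or the local Laplace approximation of a nonlinear model) the result is
#' exact: it equals direct inversion under the reduced prior.
#'
#' @param full_prior,full_posterior Prior and posterior `gaussian_density`
#'   of the full model (same parameter names).
#' @param reduced_prior The reduced prior; parameters "switched off" are
#'   conventionally given a near-zero prior variance (e.g. `1e-8`).
#' @return List with `posterior` (the reduced posterior,
#'   `gaussian_density`) and `delta_F` (log-evidence change, nats).
#' @examples
#' pr <- gaussian_density(c(b1 = 0, b2 = 0), diag(2))
#' po <- gaussian_density(c(b1 = 1, b2 = 0.1), 0.1 * diag(2))
#' reduce_model(pr, po, pr)$delta_F  # identical prior: exactly 0
#' @export
reduce_model <- function(full_prior, full_posterior, reduced_prior) {
  nm <- full_prior$names
  full_posterior <- align_density(full_posterior, nm)
  reduced_prior <- align_density(reduced_prior, nm)
  P0 <- inv_sym(full_prior$cov)
  Pq <- inv_sym(full_posterior$cov)
  Pr <- inv_sym(reduced_prior$cov)
  m0 <- full_prior$mean; mq <- full_posterior$mean; mr <- reduced_prior$mean
  Pp <- symm(Pq + Pr - P0)
  ch <- tryCatch(chol(Pp), error = function(e) NULL)
  if (is.null(ch)) {
    stop_dcm("implied reduced-posterior precision is not positive definite (incompatible reduction)")
  }
  Sp <- chol2inv(ch)
  mp <- as.numeric(Sp %*% (Pq %*% mq + Pr %*% mr - P0 %*% m0))
  dF <- 0.5 * (logdet(Pr) - logdet(P0) + logdet(Pq) - logdet(Pp)) +
    0.5 * (sum(mp * (Pp %*% mp)) - sum(mq * (Pq %*% mq)) -
             sum(mr * (Pr %*% mr)) + sum(m0 * (P0 %*% m0)))
  list(posterior = gaussian_density(mp, Sp, names = nm), delta_F = dF)
}

#' Log Bayes factor and evidence label
#'
#' The log Bayes factor between two models is the difference of their log
#' evidences (here, free energies), \eqn{B_{ij} = \ln p(y|m_i) -
#' \ln p(y|m_j)}. A magnitude above 3 is conventionally strong evidence for
#' the favoured model.
#'
#' @param logev_i,logev_j Log evidences (nats) of models i and j.
#' @return List with `value` (the log Bayes factor), `label` (`"strong"` if
#'   `|value| > 3`, else `"weak"`), and `favours` (`"i"`, `"j"`, or
#'   `"neither"`).
#' @examples
#' bayes_factor(26, 0)   # strong (laminar swap scale)
#' bayes_factor(2.9, 0)  # weak: below the threshold of 3
#' @export
bayes_factor <- function(logev_i, logev_j) {
  if (!is.finite(logev_i) || !is.finite(logev_j)) stop_dcm("log evidences must be finite")
  value <- logev_i - logev_j
  list(value = value,
       label = if (abs(value) > 3) "strong" else "weak",
       favours = if (value > 0) "i" else if (value < 0) "j" else "neither")
}
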