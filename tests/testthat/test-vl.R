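test_that("the cross-spectral log-likelihood matches direct Gaussian evaluation", {
  sim <- simulate_laminar(freqs = c(10, 20, 40), seed = 2)
  pred <- predict_csd(sim$model, c(10, 20, 40))
  lambda <- 0.7
  ll <- loglik_csd(sim$data, pred, lambda)
  ## dense-covariance oracle on the stacked residual
  e <- spectraldcm:::stack_csd(sim$data) - spectraldcm:::stack_csd(pred)
  n <- length(e)
  Sigma <- diag(exp(-lambda), n)
  direct <- -n / 2 * log(2 * pi) - 0.5 * determinant(Sigma)$modulus -
    0.5 * sum(e * solve(Sigma, e))
  expect_equal(ll, as.numeric(direct), tolerance = 1e-10)
  ## zero residual leaves only the normalisation
  ll0 <- loglik_csd(sim$data, sim$data, lambda)
  expect_equal(ll0, n / 2 * (lambda - log(2 * pi)), tolerance = 1e-10)
  ## with a nonzero residual, ever-higher precision eventually hurts
  expect_lt(loglik_csd(sim$data, pred, 30), ll)
  ## frequency mismatch is an error
  pred2 <- predict_csd(sim$model, c(10, 20, 41))
  expect_error(loglik_csd(sim$data, pred2), "frequency")
})

test_that("free energy reduces to zero complexity when the posterior equals the prior", {
  m <- mass_model()
  sim <- simulate_subject(m, freqs = seq(10, 60, 10), noise_sd = 0, seed = 1)
  prior <- dcm_priors(m, free = c("a14", "a41"))
  f <- free_energy(prior, prior, sim$data, m, lambda = 0)
  ll <- loglik_csd(sim$data, predict_csd(m, sim$data$freqs), 0)
  expect_equal(f, ll, tolerance = 1e-10)
  ## tightening the prior around a mismatched value strictly lowers the
  ## attainable evidence: the fit can no longer escape the wrong region
  y <- sim$data
  fit_loose <- dcm_fit(y, m, priors = gaussian_density(c(a14 = 0.8), matrix(0.1)))
  fit_tight <- dcm_fit(y, m, priors = gaussian_density(c(a14 = 0.8), matrix(1e-3)))
  expect_lt(fit_tight$free_energy, fit_loose$free_energy)
})

test_that("variational Laplace is exact on linear-Gaussian problems", {
  for (seed in 1:5) {
    prob <- conjugate_problem(seed, n = 25 + 5 * seed, p = 2 + seed %% 4)
    fit <- vl_fit(prob$y, function(th) as.numeric(prob$A %*% th), prob$prior,
                  settings = pinned_settings(prob$lambda))
    expect_equal(fit$free_energy, prob$log_evidence, tolerance = 1e-3)
    expect_equal(unname(fit$posterior$mean), unname(prob$posterior$mean),
                 tolerance = 1e-6)
    expect_equal(fit$posterior$cov, prob$posterior$cov, tolerance = 1e-6)
    expect_monotone(fit$trajectory)
  }
})

test_that("noise-free data generated at the prior mean is a self-consistent fit", {
  m <- laminar_model()
  sim <- simulate_subject(m, freqs = seq(4, 100, 4), noise_sd = 0, seed = 1)
  fit <- dcm_fit(sim$data, m, priors = dcm_priors(m, free = c("a14", "a23")))
  expect_true(is.finite(fit$free_energy))
  expect_lt(max(abs(fit$posterior$mean)), 0.05)
  expect_monotone(fit$trajectory)
})

test_that("fits are deterministic: identical inputs give bit-identical results", {
  sim <- simulate_laminar(seed = 9, freqs = seq(10, 80, 5))
  pr <- dcm_priors(laminar_model(), free = c("a14", "a41", "alpha_u"))
  f1 <- dcm_fit(sim$data, laminar_model(), priors = pr)
  f2 <- dcm_fit(sim$data, laminar_model(), priors = pr)
  expect_identical(f1$posterior, f2$posterior)
  expect_identical(f1$free_energy, f2$free_energy)
  expect_identical(f1$trajectory, f2$trajectory)
})

test_that("posterior covariance is symmetric positive definite and methods are coherent", {
  sim <- simulate_laminar(seed = 4, freqs = seq(8, 90, 4))
  fit <- dcm_fit(sim$data, laminar_model(),
                 priors = dcm_priors(laminar_model(),
                                     free = c("a14", "a41", "a23", "alpha_u")))
  V <- vcov(fit)
  expect_equal(V, t(V), tolerance = 1e-12)
  expect_true(all(eigen(V, symmetric = TRUE, only.values = TRUE)$values > 0))
  expect_named(coef(fit), c("a14", "a41", "a23", "alpha_u"))
  expect_equal(length(residuals(fit)), spectraldcm:::n_stacked(sim$data))
  p <- predict(fit)
  expect_s3_class(p, "spectral_data")
  tab <- summary(fit)$parameters
  expect_true(all(tab$lower < tab$upper))
})

test_that("an ill-posed start reports an instability error with advice", {
  sim <- simulate_laminar(seed = 1, freqs = seq(10, 60, 10))
  m <- laminar_model()
  bad_prior <- gaussian_density(c(a14 = 6), matrix(1e-6))  # e^6-fold excitation
  expect_error(dcm_fit(sim$data, m, priors = bad_prior), class = "dcm_instability")
})

test_that("channel mismatch between data and model is rejected", {
  sim <- simulate_subject(mass_model(), freqs = c(10, 20), noise_sd = 0)
  expect_error(dcm_fit(sim$data, laminar_model()), "channel")
})
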