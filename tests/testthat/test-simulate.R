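test_that("generators are deterministic and noise-free simulation equals the prediction", {
  s1 <- simulate_subject(mass_model(), freqs = seq(10, 90, 10), seed = 5)
  s2 <- simulate_subject(mass_model(), freqs = seq(10, 90, 10), seed = 5)
  expect_identical(s1$data$csd, s2$data$csd)
  s0 <- simulate_subject(mass_model(), freqs = seq(10, 90, 10), noise_sd = 0)
  expect_equal(s0$data$csd, predict_csd(mass_model(), seq(10, 90, 10))$csd)
  l1 <- simulate_laminar(seed = 3)
  l2 <- simulate_laminar(seed = 3)
  expect_identical(l1$data$csd, l2$data$csd)
  d1 <- simulate_depth_lfp(seed = 4)
  d2 <- simulate_depth_lfp(seed = 4)
  expect_identical(d1$v, d2$v)
})

test_that("the noise level of simulated spectra matches its nominal SD", {
  m <- mass_model()
  freqs <- seq(10, 80, 10)
  pred <- predict_csd(m, freqs)
  devs <- unlist(lapply(1:200, function(i) {
    sim <- simulate_subject(m, freqs, noise_sd = 0.2, seed = i)
    spectraldcm:::stack_csd(sim$data) - spectraldcm:::stack_csd(pred)
  }))
  expect_equal(sd(devs), 0.2, tolerance = 0.1)
  ## simulated data remain Hermitian after noising
  sim <- simulate_subject(laminar_model(), freqs, noise_sd = 0.2, seed = 1)
  for (i in seq_along(freqs)) {
    S <- sim$data$csd[i, , ]
    expect_equal(S, Conj(t(S)), tolerance = 1e-12)
  }
})

test_that("cohorts follow the second-level linear model", {
  m <- laminar_model()
  ## no effects, no random variation: all subjects identical to the base
  grp0 <- simulate_group(3, re_sd = 0, model = m, freqs = c(10, 40),
                         noise_sd = 0, seed = 2)
  expect_equal(grp0$subjects[[1]]$data$csd, grp0$subjects[[3]]$data$csd)
  ## random-effect SD is reproduced across a larger cohort
  n <- 32
  X <- matrix(1, n, 1, dimnames = list(NULL, "const"))
  beta <- matrix(0.2, 1, 4, dimnames = list("const", c("a14", "a41", "a23", "a32")))
  grp <- simulate_group(n, X = X, beta = beta, re_sd = 0.15, model = m,
                        freqs = c(10, 40), noise_sd = 0, seed = 7)
  thetas <- t(sapply(grp$subjects, function(s) s$truth$theta))
  resid <- sweep(thetas, 2, c(0.2, 0.2, 0.2, 0.2))
  expect_lt(abs(sd(as.numeric(resid)) - 0.15) / 0.15, 0.25)
  expect_equal(colMeans(thetas), c(a14 = 0.2, a41 = 0.2, a23 = 0.2, a32 = 0.2),
               tolerance = 0.1)
})

test_that("the laminar generator separates superficial and deep spectra", {
  sim <- simulate_laminar(seed = 1, noise_sd = 0)
  S_sup <- Re(sim$data$csd[, 1, 1])
  S_deep <- Re(sim$data$csd[, 2, 2])
  f <- sim$data$freqs
  expect_gt(f[which.max(S_sup)], f[which.max(S_deep)])
  ## gamma-band superficial peak
  expect_gt(f[which.max(S_sup)], 30)
  ## symmetric parameters with mirrored gains give identical auto-spectra
  msym <- laminar_model(sup_params = list(kappa = 300),
                        deep_params = list(kappa = 300), cross_gain = 0)
  msym$a[c("a22", "a23", "a32", "a33")] <- msym$a[c("a11", "a14", "a41", "a44")]
  p <- predict_csd(msym, f)
  expect_equal(Re(p$csd[, 1, 1]), Re(p$csd[, 2, 2]), tolerance = 1e-10)
})

test_that("the laminar cross-spectrum is the shared-input term", {
  sim <- simulate_laminar(cross_gain = 0, noise_sd = 0, seed = 1)
  m <- sim$model
  f <- sim$data$freqs
  Tt <- transfer_mass(m, 2 * pi * f)
  gu <- one_over_f_spectrum(m$alpha_u, m$beta_u, f)
  gn <- one_over_f_spectrum(m$alpha_n, m$beta_n, f)
  expect_equal(sim$data$csd[, 1, 2], Tt[, 1] * gu * Conj(Tt[, 2]) + gn,
               tolerance = 1e-10)
})

test_that("unstable parameter draws are resampled and reported", {
  m <- laminar_model()
  ## an enormous random-effect SD cannot yield 10 stable draws
  expect_error(simulate_group(1, re_sd = 30, model = m, freqs = c(10, 20),
                              seed = 1),
               "unstable")
})
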