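test_that("kernel Fourier transform matches its closed-form limits", {
  ## total mass of the two-sided exponential kernel
  expect_equal(kernel_ft_field(1.5, 0.6, 300, 0, 0), 2 * 1.5 / 0.6 + 0i)
  ## infinite conduction speed: delay-free Lorentzian
  k <- 1.2
  expect_equal(kernel_ft_field(2, 0.8, 1e12, k, 2 * pi * 40),
               2 * 2 * 0.8 / (0.8^2 + k^2) + 0i, tolerance = 1e-6)
  expect_error(kernel_ft_field(1, -1, 300, 0, 0), "positive")
  expect_error(kernel_ft_field(1, 1, 0, 0, 0), "positive")
})

test_that("kernel Fourier transform agrees with numerical quadrature", {
  ## defining integral: alpha exp(-c|x|) with delay |x|/s against exp(-ikx)
  quad_ft <- function(alpha, cc, s, k, omega) {
    fre <- function(x) alpha * exp(-cc * abs(x)) * cos(omega * abs(x) / s + k * x)
    fim <- function(x) -alpha * exp(-cc * abs(x)) * sin(omega * abs(x) / s + k * x)
    re <- integrate(fre, -Inf, Inf, rel.tol = 1e-10, abs.tol = 1e-12)$value
    im <- integrate(fim, -Inf, Inf, rel.tol = 1e-10, abs.tol = 1e-12)$value
    complex(real = re, imaginary = im)
  }
  ks <- seq(0, 4, length.out = 5)
  oms <- 2 * pi * c(1, 12, 35, 80)
  for (k in ks) for (om in oms) {
    expect_equal(kernel_ft_field(1.3, 0.6, 300, k, om), quad_ft(1.3, 0.6, 300, k, om),
                 tolerance = 1e-6)
  }
})

test_that("a wide lead field leaves only the k = 0 mode", {
  fm <- field_model(phi = 1e4, n_modes = 8)
  p_all <- predict_csd(fm, c(10, 40))
  fm1 <- field_model(phi = 1e4, n_modes = 1)
  p_k0 <- predict_csd(fm1, c(10, 40))
  expect_equal(p_all$csd, p_k0$csd, tolerance = 1e-10)
})

test_that("at k = 0 with no delays the field transfer reduces to a matched point-source model", {
  ## field kernels that exist in the mass topology, lateral kernels off
  alpha <- c(alpha11 = 108, alpha14 = 45, alpha12 = 0.001, alpha22 = 162,
             alpha21 = 0.001, alpha23 = 45, alpha33 = 36, alpha41 = 18,
             alpha32 = 9, alpha44 = 18)
  fm <- field_model(alpha = alpha, s = 1e9, q = c(0.2, 0, 0.2, 0.6),
                    lead_gain = 1)
  mm <- mass_model(kappa = fm$kappa,
                   a = c(a11 = 108, a14 = 45, a23 = 45, a22 = 162, a32 = 9,
                         a31 = 0, a33 = 36, a34 = 0, a41 = 18, a44 = 18),
                   Lw = matrix(c(0.2, 0, 0.2, 0.6), 1, 4))
  om <- 2 * pi * c(5, 20, 60)
  Tf <- transfer_field(fm, 0, om)[, 1]
  Tm <- transfer_mass(mm, om)[, 1]
  expect_equal(Tf, Tm, tolerance = 1e-3)
})

test_that("field cross-spectra are finite and vary smoothly with frequency", {
  fm <- field_model(n_modes = 16)
  freqs <- seq(4, 100, by = 1)
  p <- predict_csd(fm, freqs)
  S <- Re(p$csd[, 1, 1])
  expect_true(all(is.finite(S)))
  expect_true(all(S > 0))
  ## no jumps: successive values change by a bounded factor on a 1 Hz grid
  expect_lt(max(abs(diff(log(S)))), 0.5)
})

test_that("field instability reports the offending wavenumber", {
  fm <- field_model(alpha = c(alpha11 = 0.001, alpha14 = 5e4, alpha12 = 0.001,
                              alpha22 = 0.001, alpha21 = 0.001, alpha23 = 0.001,
                              alpha33 = 0.001, alpha41 = 5e4, alpha32 = 0.001,
                              alpha44 = 0.001))
  err <- tryCatch(transfer_field(fm, 0, 2 * pi * 10), error = identity)
  expect_s3_class(err, "dcm_instability")
  expect_match(conditionMessage(err), "wavenumber")
})

test_that("the field model carries exactly ten intrinsic connection amplitudes", {
  fm <- field_model()
  expect_length(fm$alpha, 10)
  expect_named(fm$alpha, c("alpha11", "alpha14", "alpha12", "alpha22",
                           "alpha21", "alpha23", "alpha33", "alpha41",
                           "alpha32", "alpha44"))
})
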