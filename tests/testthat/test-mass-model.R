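test_that("centred sigmoid has the closed-form properties of the firing-rate function", {
  expect_identical(sigmoid(0, 0.54, 0), 0)
  ## derivative at the inflection equals r/4
  h <- 1e-6
  expect_equal((sigmoid(h, 0.54) - sigmoid(-h, 0.54)) / (2 * h), 0.54 / 4,
               tolerance = 1e-8)
  expect_equal(sigmoid(1e4, 0.54), 0.5, tolerance = 1e-12)
  expect_equal(sigmoid(-1e4, 0.54), -0.5, tolerance = 1e-12)
  ## strictly increasing
  v <- seq(-20, 20, 0.5)
  expect_true(all(diff(sigmoid(v, 0.54)) > 0))
  expect_error(sigmoid(0, -1), "positive")
})

test_that("the origin is a fixed point and uncoupled populations are damped oscillators", {
  m <- mass_model()
  expect_equal(drift_mass(rep(0, 8), m, 0), rep(0, 8))
  ## all gains zero, v1 = 1: acceleration is -kappa1^2
  m0 <- mass_model(a = setNames(rep(0, 10), names(m$a)))
  d <- drift_mass(c(1, rep(0, 7)), m0, 0)
  expect_equal(d[5], -m0$kappa[1]^2)
  expect_equal(d[-5], rep(0, 7))
  expect_error(drift_mass(c(NaN, rep(0, 7)), m), "blow-up")
})

test_that("drift matches centred finite differences of an ODE-integrator trajectory", {
  skip_if_not_installed("deSolve")
  m <- mass_model()
  rhs <- function(t, y, parms) list(drift_mass(y, m, U = sin(20 * t)))
  set.seed(3)
  y0 <- rnorm(8, sd = 0.1)
  times <- seq(0, 0.05, by = 1e-5)
  tr <- deSolve::lsoda(y0, times, rhs, NULL, rtol = 1e-10, atol = 1e-12)
  for (i in c(500, 2000, 4000)) {
    fd <- (tr[i + 1, -1] - tr[i - 1, -1]) / (2e-5)
    expect_equal(unname(fd),
                 unname(drift_mass(tr[i, -1], m, U = sin(20 * times[i]))),
                 tolerance = 1e-5)
  }
})

test_that("fixed_point agrees with simulated steady state and flags failure", {
  m <- mass_model()
  expect_identical(fixed_point(m, 0), rep(0, 4))
  skip_if_not_installed("deSolve")
  vstar <- fixed_point(m, U0 = 0.2)
  rhs <- function(t, y, parms) list(drift_mass(y, m, U = 0.2))
  tr <- deSolve::lsoda(rep(0, 8), c(0, 2), rhs, NULL, rtol = 1e-12, atol = 1e-14)
  expect_equal(unname(tr[2, 2:5]), vstar, tolerance = 1e-6)
  expect_equal(unname(tr[2, 6:9]), rep(0, 4), tolerance = 1e-6)
  ## exhausted iteration budget is a distinct, named failure
  expect_error(fixed_point(m, U0 = 50, max_iter = 1), "converge")
})

test_that("the Jacobian has the second-order block structure and matches finite differences", {
  m <- mass_model()
  ## decoupled case: eigenvalues -kappa_q, each twice (critically damped)
  m0 <- mass_model(a = setNames(rep(0, 10), names(m$a)))
  ev <- sort(Re(eigen(jacobian_mass(m0), only.values = TRUE)$values))
  expect_equal(ev, sort(rep(-m0$kappa, 2)), tolerance = 1e-8)
  ## closed-form coupling entry: acceleration of v1 w.r.t. v4 at the origin
  J <- jacobian_mass(m)
  expect_equal(J[5, 4], m$kappa[1] * m$a[["a14"]] * m$r / 4, tolerance = 1e-12)
  ## full finite-difference check at a generic state
  set.seed(4)
  vstar <- rnorm(4, sd = 0.2)
  Jv <- jacobian_mass(m, vstar)
  h <- 1e-6
  Jfd <- matrix(0, 8, 8)
  for (j in 1:8) {
    e <- rep(0, 8); e[j] <- h
    Jfd[, j] <- (drift_mass(c(vstar, rep(0, 4)) + e, m) -
                   drift_mass(c(vstar, rep(0, 4)) - e, m)) / (2 * h)
  }
  expect_equal(Jv, Jfd, tolerance = 1e-6)
})

test_that("transfer function reduces to the second-order low-pass closed form", {
  kap <- 120
  m1 <- mass_model(kappa = rep(kap, 4),
                   a = setNames(rep(0, 10), names(mass_model()$a)),
                   Lw = matrix(c(1, 0, 0, 0), 1, 4))
  om <- 2 * pi * c(1, 5, 20, 80)
  Tt <- transfer_mass(m1, om)[, 1]
  expect_equal(Tt, kap / (1i * om + kap)^2, tolerance = 1e-10)
  ## strictly proper: response vanishes at high frequency
  expect_lt(Mod(transfer_mass(m1, 2 * pi * 1e6)[1, 1]), 1e-8)
})

test_that("transfer function matches the Fourier-transformed impulse response", {
  ## two-population toy (only the 1-4 loop active)
  m <- mass_model(a = c(a11 = 800, a14 = 1500, a23 = 0, a22 = 0, a32 = 0,
                        a31 = 0, a33 = 0, a34 = 0, a41 = 1500, a44 = 800),
                  Lw = matrix(1000 * c(1, 0, 0, 0.5), 1, 4))
  freqs <- seq(1, 100, by = 3)
  Tm <- transfer_mass(m, 2 * pi * freqs)
  To <- transfer_oracle_mass(m, freqs)
  expect_lt(max(Mod(Tm - To) / Mod(Tm)), 1e-3)
})

test_that("instability is reported with advice instead of silent garbage", {
  m <- mass_model(a = c(a11 = 0, a14 = 5e4, a23 = 0, a22 = 0, a32 = 0,
                        a31 = 0, a33 = 0, a34 = 0, a41 = 5e4, a44 = 0))
  ## an overdriven 1-4 loop pushes the resonance past its damping
  expect_error(transfer_mass(m, 2 * pi * 10), class = "dcm_instability")
})

test_that("log-scaling parameters act multiplicatively and reject unknown names", {
  m <- mass_model()
  m2 <- apply_theta(m, c(kappa1 = log(2), a14 = log(3), alpha_u = 1))
  expect_equal(m2$kappa[1], 2 * m$kappa[1])
  expect_equal(m2$a[["a14"]], 3 * m$a[["a14"]])
  expect_equal(m2$alpha_u, m$alpha_u + 1)
  expect_error(apply_theta(m, c(bogus = 1)), "unknown")
})
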