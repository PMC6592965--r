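# Second-level tests use synthetic first-level posteriors built directly as
# Gaussian densities: the PEB machinery only ever sees (prior, posterior)
# pairs, so linear-Gaussian subjects exercise it exactly.

make_subjects <- function(theta_means, prior_var = 0.25, post_sd = 0.05) {
  pn <- colnames(theta_means)
  lapply(seq_len(nrow(theta_means)), function(i) {
    list(prior = gaussian_density(setNames(rep(0, length(pn)), pn),
                                  diag(prior_var, length(pn))),
         posterior = gaussian_density(setNames(theta_means[i, ], pn),
                                      diag(post_sd^2, length(pn))))
  })
}

test_that("a single subject with a constant design recovers its own posterior mean", {
  th <- matrix(c(0.4, -0.2, 0.1), 1, dimnames = list(NULL, c("p1", "p2", "p3")))
  subs <- make_subjects(th)
  peb <- peb_fit(subs, hierarchical_spec(matrix(1, 1, 1), params = c("p1", "p2", "p3")))
  expect_equal(unname(coef(peb)), as.numeric(th), tolerance = 0.15)
  expect_monotone(peb$trajectory)
})

test_that("identical subjects give the shared mean with shrinking uncertainty", {
  th1 <- c(p1 = 0.5, p2 = -0.3)
  sd_for <- function(n) {
    th <- matrix(rep(th1, each = n), n, dimnames = list(NULL, names(th1)))
    peb <- peb_fit(make_subjects(th), hierarchical_spec(matrix(1, n, 1),
                                                        params = names(th1)))
    expect_equal(unname(coef(peb)), unname(th1), tolerance = 0.05)
    sqrt(diag(peb$beta_posterior$cov))
  }
  expect_true(all(sd_for(16) < sd_for(4)))
})

test_that("the fit is invariant to subject ordering", {
  set.seed(11)
  n <- 8
  x <- scale(rnorm(n))[, 1]
  th <- cbind(p1 = 0.3 * x + rnorm(n, sd = 0.05),
              p2 = rnorm(n, sd = 0.05))
  X <- cbind(const = 1, x = x)
  subs <- make_subjects(th)
  spec1 <- hierarchical_spec(X, params = c("p1", "p2"))
  peb1 <- peb_fit(subs, spec1)
  perm <- sample(n)
  spec2 <- hierarchical_spec(X[perm, ], params = c("p1", "p2"))
  peb2 <- peb_fit(subs[perm], spec2)
  ## identical up to floating-point summation order
  expect_lt(max(abs(coef(peb1) - coef(peb2))), 1e-4)
  expect_lt(abs(peb1$free_energy - peb2$free_energy), 1e-4)
})

test_that("rank-deficient designs are rejected with the collinear columns named", {
  X <- cbind(const = 1, a = 1:6, b = 2 * (1:6))
  err <- tryCatch(hierarchical_spec(X, params = "p1"), error = identity)
  expect_s3_class(err, "dcm_error")
  expect_match(conditionMessage(err), "collinear")
})

test_that("Kronecker bookkeeping: constant plus three covariates over ten connections", {
  set.seed(2)
  n <- 12
  X <- cbind(const = 1, x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  pn <- names(field_model()$alpha)
  th <- matrix(rnorm(n * 10, sd = 0.1), n, dimnames = list(NULL, pn))
  peb <- peb_fit(make_subjects(th), hierarchical_spec(X, params = pn))
  expect_identical(peb$n_second_level, 40L + 0L)
  expect_identical(peb$n_group_effects, 30L + 0L)
  expect_length(peb$group_effect_names, 30)
  expect_length(peb$subject_empirical_priors, n)
})

test_that("a degenerate model space assigns probability one to its only member", {
  th <- matrix(rnorm(8, sd = 0.1), 4, 2, dimnames = list(NULL, c("p1", "p2")))
  X <- cbind(const = 1, x = scale(rnorm(4))[, 1])
  peb <- peb_fit(make_subjects(th), hierarchical_spec(X, params = c("p1", "p2")))
  ms <- search_model_space(peb, candidate_masks = list(c(TRUE, TRUE)))
  expect_equal(ms$models$posterior_prob, 1)
})

test_that("with no true effects the empty model wins; planted effects are found", {
  set.seed(21)
  n <- 20
  x <- scale(rnorm(n))[, 1]
  X <- cbind(const = 1, x = x)
  pn <- paste0("p", 1:6)
  ## null cohort
  th0 <- matrix(rnorm(n * 6, sd = 0.03), n, dimnames = list(NULL, pn))
  peb0 <- peb_fit(make_subjects(th0), hierarchical_spec(X, params = pn))
  ms0 <- search_model_space(peb0)
  empty <- paste(rep(0, 6), collapse = "")
  best <- ms0$models$mask[which.max(ms0$models$delta_F)]
  expect_identical(best, empty)
  ## two planted effects
  th1 <- th0
  th1[, "p2"] <- th1[, "p2"] + 0.5 * x
  th1[, "p5"] <- th1[, "p5"] - 0.5 * x
  peb1 <- peb_fit(make_subjects(th1), hierarchical_spec(X, params = pn))
  ms1 <- search_model_space(peb1)
  expect_gt(ms1$inclusion_prob[["x:p2"]], 0.9)
  expect_gt(ms1$inclusion_prob[["x:p5"]], 0.9)
  expect_lt(median(ms1$inclusion_prob[c("x:p1", "x:p3", "x:p4", "x:p6")]), 0.5)
  ## probabilities are proper
  expect_equal(sum(ms1$models$posterior_prob), 1, tolerance = 1e-10)
  expect_true(all(ms1$inclusion_prob >= 0 & ms1$inclusion_prob <= 1))
})

test_that("greedy pruning handles spaces larger than the exhaustive limit", {
  set.seed(31)
  n <- 16
  x <- scale(rnorm(n))[, 1]
  X <- cbind(const = 1, x = x)
  pn <- paste0("p", 1:8)
  th <- matrix(rnorm(n * 8, sd = 0.03), n, dimnames = list(NULL, pn))
  th[, "p3"] <- th[, "p3"] + 0.6 * x
  peb <- peb_fit(make_subjects(th), hierarchical_spec(X, params = pn))
  ms <- search_model_space(peb, exhaustive_limit = 4)
  expect_lte(nrow(ms$models), 2^4)
  expect_gt(ms$inclusion_prob[["x:p3"]], 0.9)
})

test_that("model averaging is moment-matched", {
  g1 <- gaussian_density(c(a = 1), matrix(0.1))
  g2 <- gaussian_density(c(a = -1), matrix(0.1))
  ## a single model passes through unchanged
  one <- bayesian_model_average(list(list(posterior = g1, prob = 1)))
  expect_equal(one$mean, g1$mean)
  expect_equal(one$cov, g1$cov)
  ## symmetric equi-probable pair: mean zero, variance inflated by the spread
  avg <- bayesian_model_average(list(list(posterior = g1, prob = 0.5),
                                    list(posterior = g2, prob = 0.5)))
  expect_equal(unname(avg$mean), 0)
  expect_equal(unname(avg$cov[1, 1]), 0.1 + 1)
})
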