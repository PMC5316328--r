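test_that("the model set is the full 3x3 factorial with unique ids", {
  specs <- enumerate_models()
  expect_length(specs, 9L)
  pairs <- vapply(specs, function(s) {
    paste(s$survival_form, s$reproduction_form)
  }, character(1))
  expect_length(unique(pairs), 9L)
  expect_identical(vapply(specs, `[[`, integer(1), "id"), 1:9)
  n_dd_surv <- sum(vapply(specs, function(s) {
    s$survival_form == "DAYS_DENSITY"
  }, logical(1)))
  expect_identical(n_dd_surv, 3L)
})

test_that("survival responds to DAYS and density exactly as parameterized", {
  p <- parameter_set(alpha0 = qlogis(0.95), alpha1 = 0.2, alpha2 = 0.5,
                     gamma0 = log(0.16), K = 60)
  null_m <- model_spec("NULL", "NULL", 1)
  days_m <- model_spec("DAYS", "NULL", 4)
  dd_m <- model_spec("DAYS_DENSITY", "NULL", 7)
  # NULL form ignores every covariate
  expect_equal(survival_rate(10, 2, p, null_m), 0.95)
  expect_equal(survival_rate(500, -3, p, null_m), 0.95)
  # DAYS form: plogis(logit(0.95) + 0.2)
  expect_equal(survival_rate(10, 1, p, days_m), plogis(qlogis(0.95) + 0.2),
               tolerance = 1e-12)
  expect_equal(survival_rate(10, 1, p, days_m), 0.958689, tolerance = 1e-5)
  # density at N/K = 1: plogis(logit(0.95) - 0.5)
  expect_equal(survival_rate(60, 0, p, dd_m), plogis(qlogis(0.95) - 0.5),
               tolerance = 1e-12)
  expect_equal(survival_rate(60, 0, p, dd_m), 0.920154, tolerance = 1e-5)
  expect_error(survival_rate(-1, 0, p, null_m), "non-negative")
})

test_that("reproduction responds to DAYS and density exactly as parameterized", {
  p <- parameter_set(alpha0 = qlogis(0.95), gamma0 = log(0.16),
                     gamma1 = 0.3, gamma2 = 0.3, K = 60)
  null_m <- model_spec("NULL", "NULL", 1)
  days_m <- model_spec("NULL", "DAYS", 2)
  dd_m <- model_spec("NULL", "DAYS_DENSITY", 3)
  expect_equal(reproduction_rate(10, 5, p, null_m), 0.16)
  # cold springs suppress reproduction toward zero
  expect_lt(reproduction_rate(10, -30, p, days_m), 1e-3)
  expect_equal(reproduction_rate(60, 0, p, dd_m), 0.16 * exp(-0.3),
               tolerance = 1e-12)
  expect_equal(reproduction_rate(60, 0, p, dd_m), 0.118531, tolerance = 1e-4)
  expect_error(reproduction_rate(-0.1, 0, p, null_m), "non-negative")
})

test_that("rates decline with abundance whenever density terms are active", {
  p <- parameter_set(alpha0 = qlogis(0.95), alpha2 = 0.4,
                     gamma0 = log(0.16), gamma2 = 0.4, K = 60)
  dd <- model_spec("DAYS_DENSITY", "DAYS_DENSITY", 9)
  grid <- seq(0, 150, by = 5)
  expect_true(all(diff(survival_rate(grid, 0, p, dd)) < 0))
  expect_true(all(diff(reproduction_rate(grid, 0, p, dd)) < 0))
})

test_that("the transition applies recruitment, truncated harvest, then survival", {
  # near-certain survival isolates the removal accounting
  p1 <- parameter_set(alpha0 = 30, gamma0 = -Inf)
  null_m <- model_spec("NULL", "NULL", 1)
  expect_equal(transition(80, 10, 0, p1, null_m), 70, tolerance = 1e-10)
  # worked value: N (1 + r) s - h s with r = 0.1684, s = 0.95
  p2 <- parameter_set(alpha0 = qlogis(0.95), gamma0 = log(0.1684))
  expect_equal(transition(81.6, 11.3, 0, p2, null_m),
               (81.6 * 1.1684 - 11.3) * 0.95, tolerance = 1e-12)
  expect_equal(transition(81.6, 11.3, 0, p2, null_m), 79.839368,
               tolerance = 1e-6)
  # harvest beyond the post-breeding population floors at zero
  expect_equal(transition(10, 1e4, 0, p2, null_m), 0)
  expect_error(transition(5, -1, 0, p2, null_m), "non-negative")
})

test_that("stochastic transitions are seeded and mean-match the deterministic core", {
  p <- parameter_set(alpha0 = qlogis(0.95), gamma0 = log(0.17),
                     process_sd = 0.1)
  null_m <- model_spec("NULL", "NULL", 1)
  a <- transition(rep(80, 5), 10, 0, p, null_m, stochastic = TRUE, seed = 99)
  b <- transition(rep(80, 5), 10, 0, p, null_m, stochastic = TRUE, seed = 99)
  expect_identical(a, b)
  # with process_sd = 0 the stochastic flag is a no-op
  p0 <- parameter_set(alpha0 = qlogis(0.95), gamma0 = log(0.17))
  expect_identical(transition(80, 10, 0, p0, null_m, stochastic = TRUE),
                   transition(80, 10, 0, p0, null_m))
  # lognormal noise is mean-corrected: MC mean matches the deterministic core
  det <- transition(80, 10, 0, p, null_m)
  draws <- transition(rep(80, 10000), 10, 0, p, null_m, stochastic = TRUE,
                      seed = 1)
  mc_se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - det), 3 * mc_se)
})

test_that("coefficients excluded by the structural form have no effect", {
  base <- parameter_set(alpha0 = qlogis(0.95), alpha1 = 0.3, alpha2 = 0.4,
                        gamma0 = log(0.16), gamma1 = 0.3, gamma2 = 0.4)
  zeroed <- parameter_set(alpha0 = qlogis(0.95), alpha1 = 0, alpha2 = 0,
                          gamma0 = log(0.16), gamma1 = 0, gamma2 = 0)
  null_m <- model_spec("NULL", "NULL", 1)
  for (N in c(5, 60, 120)) {
    expect_identical(transition(N, 5, 1.3, base, null_m),
                     transition(N, 5, 1.3, zeroed, null_m))
  }
  # DAYS-only forms must ignore the density coefficients
  days_m <- model_spec("DAYS", "DAYS", 5)
  no_density <- parameter_set(alpha0 = qlogis(0.95), alpha1 = 0.3, alpha2 = 0,
                              gamma0 = log(0.16), gamma1 = 0.3, gamma2 = 0)
  expect_identical(transition(90, 5, 0.7, base, days_m),
                   transition(90, 5, 0.7, no_density, days_m))
})

test_that("the adult/young split is exact and sums to the total", {
  expect_equal(derive_age_split(60, 0), list(A = 60, Y = 0))
  expect_equal(derive_age_split(60, 0.2), list(A = 50, Y = 10))
  set.seed(4)
  for (i in 1:20) {
    N <- runif(1, 0, 150); r <- runif(1, 0, 0.5)
    sp <- derive_age_split(N, r)
    expect_equal(sp$A + sp$Y, N, tolerance = 1e-12)
  }
})

test_that("climatology support is a proper non-negative distribution", {
  cl <- climatology(10, 4)
  expect_true(all(cl$support >= 0))
  expect_equal(sum(cl$probs), 1, tolerance = 1e-9)
  cl2 <- climatology(support = c(5, 10, 15), probs = c(0.25, 0.5, 0.25))
  expect_equal(days_z(10, cl2), 0)
})
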