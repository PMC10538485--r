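test_that("transition density: atom weight, no-recombination limit, domain errors", {
  expect_equal(smc_transition_density(0.5, s = 1, rho = 0.0006)$atom_weight,
               exp(-0.0006), tolerance = 1e-12)
  z <- smc_transition_density(c(0.3, 2), s = 1.7, rho = 0)
  expect_equal(z$atom_weight, 1)
  expect_equal(z$density, c(0, 0))
  expect_error(smc_transition_density(-1, 1, 0.1), "must be > 0")
  expect_error(smc_transition_density(1, 0, 0.1), "must be > 0")
})

test_that("transition density: mass conservation and Exp(1) near-stationarity", {
  for (cfg in list(c(0.4, 0.002), c(1, 0.0006), c(3, 0.05))) {
    s <- cfg[1]
    rho <- cfg[2]
    tz <- smc_transition_density(1, s, rho)
    cont <- integrate(function(t) smc_transition_density(t, s, rho)$density,
                      1e-12, s + 60, rel.tol = 1e-11)$value
    expect_equal(tz$atom_weight + cont, 1, tolerance = 1e-9)
  }
  # integrating the kernel against the Exp(1) prior returns Exp(1) up to
  # O(rho^2) (the continuum-limit stationarity of the coalescent prior)
  rho <- 0.0006
  for (t in c(0.1, 1, 3)) {
    marg <- integrate(function(s) {
      vapply(s, function(si) {
        smc_transition_density(t, si, rho)$density * exp(-si)
      }, numeric(1))
    }, 1e-12, 60, rel.tol = 1e-11)$value +
      exp(-rho * t) * exp(-t)  # atom contribution at s = t
    expect_equal(marg, exp(-t), tolerance = 1e-6)
  }
})

test_that("compound moments: closed forms match the quadrature oracle", {
  # rho = 0 reduces to the input gamma
  m0 <- compound_moments(gamma_state(3.2, 5), rho = 0)
  expect_equal(m0$mean, 3.2 / 5, tolerance = 1e-14)
  expect_equal(m0$variance, 3.2 / 25, tolerance = 1e-14)
  # prior is stationary to first order in rho (exact only as rho -> 0)
  mp <- compound_moments(gamma_state(1, 1), rho = 0.0006)
  expect_equal(mp$mean, 1, tolerance = 1e-6)
  expect_equal(mp$variance, 1, tolerance = 1e-5)
  # oracle check away from the fixed point
  st <- gamma_state(4, 2)
  mom <- compound_moments(st, rho = 0.01)
  m1 <- compound_oracle_moment(4, 2, 0.01, k = 1)
  m2 <- compound_oracle_moment(4, 2, 0.01, k = 2)
  expect_equal(mom$mean, m1, tolerance = 1e-6)
  expect_equal(mom$variance, m2 - m1^2, tolerance = 1e-6)
})

test_that("gamma projection: identity at rho = 0, stationary prior, variance growth", {
  for (method in c("moment", "kl")) {
    pr <- gamma_project(gamma_state(2.5, 4), rho = 0, method = method)
    expect_equal(pr$alpha, 2.5, tolerance = 1e-10)
    expect_equal(pr$beta, 4, tolerance = 1e-10)
    st <- gamma_project(gamma_state(1, 1), rho = 0.0006, method = method)
    expect_equal(st$alpha, 1, tolerance = 1e-6)
    expect_equal(st$beta, 1, tolerance = 1e-6)
  }
  # a concentrated state gains variance under recombination
  pr <- gamma_project(gamma_state(50, 100), rho = 0.0006)
  expect_lt(pr$alpha, 50)
  v_quad <- compound_oracle_moment(50, 100, 0.0006, 2) -
    compound_oracle_moment(50, 100, 0.0006, 1)^2
  expect_gt(v_quad, 50 / 100^2)
})

test_that("KL projection matches E[T] and E[log T] of the compound", {
  st <- gamma_state(4, 2)
  rho <- 0.01
  pr <- gamma_project(st, rho, method = "kl")
  m1 <- compound_oracle_moment(4, 2, rho, 1)
  expect_equal(pr$alpha / pr$beta, m1, tolerance = 1e-6)
  elog <- compound_oracle_expect(4, 2, rho, g = log)
  expect_equal(compound_log_mean(st, rho), elog, tolerance = 1e-7)
  expect_equal(digamma(pr$alpha) - log(pr$beta), elog, tolerance = 1e-6)
})

test_that("emission update is exact Poisson-gamma conjugacy", {
  up <- emission_update(gamma_state(1, 1), y = 1, theta = 0.00075)
  expect_equal(up$alpha, 2)
  expect_equal(up$beta, 1.00075)
  up <- emission_update(gamma_state(2.5, 3), y = 0, theta = 0.5)
  expect_equal(up$alpha, 2.5)
  expect_equal(up$beta, 3.5)
  # iterated conjugacy over a random observation sequence
  obs <- random_obs(200, p_het = 0.3, seed = 42)
  st <- gamma_state(1, 1)
  for (y in obs) st <- emission_update(st, y, theta = 0.002)
  expect_equal(st$alpha, 1 + sum(obs), tolerance = 1e-12)
  expect_equal(st$beta, 1 + 200 * 0.002, tolerance = 1e-12)
  expect_error(emission_update(gamma_state(1, 1), NA, 0.1), "missing")
  expect_error(emission_update(gamma_state(1, 1), 2, 0.1), "y must be")
})

test_that("forward/backward combination: formula, commutativity, identity", {
  co <- combine_forward_backward(gamma_state(2, 3), gamma_state(4, 5))
  expect_equal(co$alpha, 5)
  expect_equal(co$beta, 7)
  expect_equal(combine_forward_backward(gamma_state(1, 1), gamma_state(1, 1)),
               gamma_state(1, 1))
  a <- gamma_state(2.3, 1.7)
  b <- gamma_state(0.9, 4.4)
  expect_equal(combine_forward_backward(a, b), combine_forward_backward(b, a))
  expect_equal(combine_forward_backward(a, gamma_state(1, 1)), a)
  expect_error(combine_forward_backward(gamma_state(0.3, 1), gamma_state(0.5, 1),
                                        position = 123),
               "123")
})

test_that("unit conversion to generations and years", {
  p <- model_params(theta = 0.00075, rho = 0.0006, Ne = 15000)
  cv <- to_generations(gamma_state(1, 1), p)
  expect_equal(cv$generations, 30000)
  expect_equal(cv$years, 900000)
  expect_equal(to_generations(gamma_state(2, 4), p)$generations, 15000)
  expect_equal(to_generations(gamma_state(2, 40), p)$generations, 1500)
  p2 <- model_params(theta = 1e-3, rho = 0)
  expect_error(to_generations(gamma_state(1, 1), p2), "Ne")
})

test_that("model parameters: scaled-rate definitions and validation", {
  p <- model_params(mu_rate = 1.25e-8, r_rate = 1e-8, Ne = 15000)
  expect_equal(p$theta, 0.00075)
  expect_equal(p$rho, 0.0006)
  p2 <- model_params(theta = 0.00075, rho_over_theta = 0.8)
  expect_equal(p2$rho, 0.0006)
  expect_error(model_params(theta = 0.001, rho = 0.1, mu_rate = 1e-8, Ne = 1e4),
               "inconsistent")
  expect_error(model_params(rho = 0.1), "theta")
})

test_that("gamma state log-coordinate round trip is the identity", {
  set.seed(3)
  a <- 10^runif(50, -1, 4)
  b <- 10^runif(50, -3, 6)
  lg <- state_to_log(gamma_state(a, b))
  back <- log_to_state(lg$l_mu, lg$l_cv)
  expect_equal(back$alpha, a, tolerance = 1e-12)
  expect_equal(back$beta, b, tolerance = 1e-12)
  expect_equal(state_cv(gamma_state(4, 9)), 0.5)
  expect_error(gamma_state(-1, 2), "alpha")
})
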