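test_that("flow field at rho = 0 maps every node to itself", {
  ff <- ff_zero()
  nodes <- expand.grid(l_mu = ff$l_mu_axis, l_cv = ff$l_cv_axis)
  expect_equal(as.vector(ff$mu_img), nodes$l_mu, tolerance = 1e-9)
  expect_equal(as.vector(ff$cv_img), nodes$l_cv, tolerance = 1e-9)
})

test_that("stationary prior is (approximately) a fixed point of the flow field", {
  ff <- ff_std()
  out <- apply_flow(ff, gamma_state(1, 1))
  lg <- state_to_log(out)
  expect_lt(abs(lg$l_mu), 1e-4)
  expect_lt(abs(lg$l_cv), 1e-4)
})

test_that("apply_flow: node lookup, bilinear midpoint identity, boundary clip", {
  ff <- ff_std()
  i <- 20L
  j <- 30L
  st <- log_to_state(ff$l_mu_axis[i], ff$l_cv_axis[j])
  out <- state_to_log(apply_flow(ff, st))
  expect_equal(out$l_mu, ff$mu_img[i, j], tolerance = 1e-12)
  expect_equal(out$l_cv, ff$cv_img[i, j], tolerance = 1e-12)
  # cell-centre value is the mean of the four corner images
  mid <- log_to_state(mean(ff$l_mu_axis[i:(i + 1)]), mean(ff$l_cv_axis[j:(j + 1)]))
  out_mid <- state_to_log(apply_flow(ff, mid))
  expect_equal(out_mid$l_mu, mean(ff$mu_img[i:(i + 1), j:(j + 1)]),
               tolerance = 1e-12)
  expect_equal(out_mid$l_cv, mean(ff$cv_img[i:(i + 1), j:(j + 1)]),
               tolerance = 1e-12)
  # l_mu = 3 is clipped back to the grid edge l_mu = 2
  over <- log_to_state(3, -0.5)
  edge <- log_to_state(2, -0.5)
  expect_equal(apply_flow(ff, over), apply_flow(ff, edge))
  bad <- gamma_state(1, 1)
  bad$alpha <- NaN
  expect_error(apply_flow(ff, bad), "non-finite")
})

test_that("unclipped skip cache equals sequential flow + emission stepping", {
  ff <- ff_std()
  ca <- cache_noclip()
  theta <- ca$theta
  # node trajectories equal sequential stepping (exact up to the float
  # round trip between (alpha, beta) and log coordinates)
  set.seed(9)
  for (rep in 1:20) {
    i <- sample(length(ff$l_mu_axis), 1)
    j <- sample(length(ff$l_cv_axis), 1)
    n <- sample(c(1L, 37L, 137L, 300L), 1)
    st <- log_to_state(ff$l_mu_axis[i], ff$l_cv_axis[j])
    for (k in seq_len(n)) st <- emission_update(apply_flow(ff, st), 0L, theta)
    cached <- skip_run(ca, log_to_state(ff$l_mu_axis[i], ff$l_cv_axis[j]),
                       n_missing = 0, n_hom = n)
    expect_equal(cached$alpha, st$alpha, tolerance = 1e-12)
    expect_equal(cached$beta, st$beta, tolerance = 1e-12)
  }
  # off-node states: cached lookup within interpolation tolerance of
  # stepping (nearby node trajectories diverge over ~100 steps, so the
  # worst-case interpolation error grows above the single-step level)
  set.seed(11)
  for (rep in 1:10) {
    lg0 <- c(runif(1, -2, 1), runif(1, -1.5, -0.1))
    n <- sample(50:250, 1)
    st <- log_to_state(lg0[1], lg0[2])
    for (k in seq_len(n)) st <- emission_update(apply_flow(ff, st), 0L, theta)
    cached <- state_to_log(skip_run(ca, log_to_state(lg0[1], lg0[2]), 0, n))
    stepped <- state_to_log(st)
    expect_lt(abs(cached$l_mu - stepped$l_mu), 2e-3)
    expect_lt(abs(cached$l_cv - stepped$l_cv), 3e-2)
  }
})

test_that("skip cache: one-step hom entry, missing table independent of theta", {
  ff <- ff_std()
  ca <- cache_noclip()
  node_state <- log_to_state(ff$l_mu_axis[7], ff$l_cv_axis[40])
  one <- emission_update(apply_flow(ff, node_state), 0L, ca$theta)
  cached <- skip_run(ca, node_state, 0, 1)
  expect_equal(cached, one, tolerance = 1e-12)
  ca2 <- build_skip_cache(ff, theta = 0.01, max_len = 50L, clip = "none")
  expect_identical(ca2$mis_mu[, 1:50], cache_noclip()$mis_mu[, 1:50])
  expect_identical(ca2$mis_cv[, 1:50], cache_noclip()$mis_cv[, 1:50])
  expect_false(identical(ca2$hom_mu[, 2], cache_noclip()$hom_mu[, 2]))
})

test_that("skip_run: zero-length runs, chunked long runs, input validation", {
  ca <- cache_noclip()
  st <- gamma_state(2.2, 3.1)
  expect_identical(skip_run(ca, st, 0, 0), st)
  # chaining two half-length chunks ~ one long lookup (off a node)
  st0 <- log_to_state(-0.63, -0.48)
  whole <- state_to_log(skip_run(ca, st0, 0, 300))
  halves <- state_to_log(skip_run(ca, skip_run(ca, st0, 0, 150), 0, 150))
  expect_lt(abs(whole$l_mu - halves$l_mu), 2e-3)
  expect_lt(abs(whole$l_cv - halves$l_cv), 5e-3)
  # a run longer than max_len is processed in max_len chunks
  long <- skip_run(ca, st0, 0, 750)   # max_len = 300
  manual <- skip_run(ca, skip_run(ca, skip_run(ca, st0, 0, 300), 0, 300), 0, 150)
  expect_equal(long, manual, tolerance = 1e-12)
  expect_error(skip_run(ca, st, -1, 0), ">= 0")
  expect_error(build_skip_cache(ff_std(), theta = 0.00075, max_len = 1e6,
                                max_bytes = 1e6), "cap")
})

test_that("long missing runs relax towards the stationary prior", {
  ca <- cache_std()
  # recombination happens at rate rho * t per bp, so relaxation from
  # moderate states completes within ~10 kb while deep small-TMRCA states
  # (short branches) are legitimately long-lived: those only move closer.
  for (start in list(c(-1.5, -1), c(-1, -0.5), c(0.5, -0.3), c(1, -1))) {
    out <- state_to_log(skip_run(ca, log_to_state(start[1], start[2]),
                                 n_missing = 10000, n_hom = 0))
    expect_lt(abs(out$l_mu), 0.06)
    expect_lt(abs(out$l_cv), 0.06)
  }
  deep <- state_to_log(skip_run(ca, log_to_state(-4, -1.8), 10000, 0))
  expect_gt(deep$l_mu, -4)      # strictly closer to the prior
  expect_lt(deep$l_mu, -0.5)    # but far from equilibrated: e-folding 1/(rho mu)
})

test_that("family clip: hom trajectories track small means instead of ratcheting up", {
  ca <- cache_std()
  # from the prior, a very long hom run should keep the mean near the
  # conjugate closed form 1/(1 + n theta), not equilibrate near rho/theta
  out <- skip_run(ca, gamma_state(1, 1), 0, 10000)
  mean_clip <- state_mean(out)
  conj <- 1 / (1 + 10000 * ca$theta)
  expect_lt(mean_clip, 5 * conj)
  # the unclipped cache ratchets to a spurious equilibrium well above that
  ca_none <- build_skip_cache(ff_std(), theta = 0.00075, max_len = 300L,
                              clip = "none")
  st <- gamma_state(1, 1)
  for (k in 1:33) st <- skip_run(ca_none, st, 0, 300)
  expect_gt(state_mean(st), 3 * mean_clip)
})

test_that("flow cache sidecar round-trips and validates its key", {
  ff <- ff_std()
  ca <- cache_noclip()
  path <- tempfile(fileext = ".gsc")
  write_flow_cache(ff, ca, path)
  back <- read_flow_cache(path, rho = 0.0006, theta = 0.00075, max_len = 300)
  expect_identical(back$cache$hom_mu, ca$hom_mu)
  expect_identical(back$grid$mu_img, ff$mu_img)
  expect_error(read_flow_cache(path, theta = 0.001), "mismatch")
})
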