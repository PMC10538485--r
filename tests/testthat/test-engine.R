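test_that("segmentation cuts at hets, targets, caps, and conserves counts", {
  segs <- segment_observations(c(0L, 0L, 1L, 0L, 0L), max_len = 10L)
  expect_equal(segs$end, c(3L, 5L))
  expect_equal(segs$terminal_type, c("het", "chrom-end"))
  expect_equal(segs$terminal_y, c(1L, NA_integer_))
  expect_equal(segs$n_hom, c(2L, 2L))
  # 25 kb of hom with a 10 kb cap -> 10000 / 10000 / 5000
  segs <- segment_observations(rep(0L, 25000), max_len = 10000L)
  expect_equal(segs$end - segs$start + 1L, c(10000L, 10000L, 5000L))
  expect_equal(segs$terminal_type, c("length-cap", "length-cap", "chrom-end"))
  expect_equal(sum(segs$n_hom), 25000L)
  # masked bases are counted as missing, the rest as hom
  obs <- rep(0L, 100)
  obs[21:40] <- NA_integer_
  obs[70] <- 1L
  segs <- segment_observations(obs, targets = 90L, max_len = 1000L)
  expect_equal(segs$end, c(70L, 90L, 100L))
  expect_equal(segs$n_missing, c(20L, 0L, 0L))
  expect_equal(segs$n_hom, c(49L, 19L, 10L))
  expect_true(all(segs$n_missing + segs$n_hom +
                    !is.na(segs$terminal_y) == segs$end - segs$start + 1L))
  expect_error(segment_observations(obs, targets = c(50L, 10L)), "sorted")
  expect_error(segment_observations(obs, targets = 1000L), "outside")
})

test_that("compact and per-bp segmentations agree when data are complete", {
  obs <- random_obs(5000, p_het = 0.01, seed = 5)
  targets <- c(100L, 2500L, 4999L)
  a <- segment_observations(obs, targets, max_len = 700L)
  b <- segment_observations(list(length = 5000L, het = which(obs == 1L)),
                            targets, max_len = 700L)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("decoder reproduces Poisson-gamma closed forms exactly at rho = 0", {
  ff <- ff_zero()
  ca <- cache_zero()
  p <- model_params(theta = 0.001, rho = 0, Ne = 15000)
  for (seed in 1:3) {
    obs <- random_obs(2000, p_het = 0.05, seed = seed)
    targets <- c(17L, 900L, 2000L)
    tr <- decode_pair(obs, targets, p, ca, ff)
    k_upto <- cumsum(obs)[targets]
    n_all <- length(obs)
    k_all <- sum(obs)
    # forward: observations up to and including the target
    expect_equal(tr$fwd_alpha, 1 + k_upto, tolerance = 1e-9)
    expect_equal(tr$fwd_beta, 1 + targets * 0.001, tolerance = 1e-9)
    # backward: strictly downstream observations
    expect_equal(tr$bwd_alpha, 1 + k_all - k_upto, tolerance = 1e-9)
    expect_equal(tr$bwd_beta, 1 + (n_all - targets) * 0.001, tolerance = 1e-9)
    # combined: all observations, independent of the target position
    expect_equal(tr$alpha, rep(1 + k_all, 3), tolerance = 1e-9)
    expect_equal(tr$beta, rep(1 + n_all * 0.001, 3), tolerance = 1e-9)
  }
})

test_that("an uninformative (all-missing) sequence returns the prior", {
  ff <- ff_zero()
  ca <- cache_zero()
  p <- model_params(theta = 0.001, rho = 0, Ne = 15000)
  obs <- rep(NA_integer_, 400)
  tr <- decode_pair(obs, targets = c(50L, 350L), p, ca, ff)
  expect_equal(tr$alpha, c(1, 1), tolerance = 1e-9)
  expect_equal(tr$beta, c(1, 1), tolerance = 1e-9)
})

test_that("backward pass equals the reversed forward pass plus one transition", {
  ff <- ff_std()
  ca <- cache_std()
  theta <- ca$theta
  half <- random_obs(600, p_het = 0.03, seed = 13)
  obs <- c(half, 0L, rev(half))          # palindrome, centre at 601
  centre <- 601L
  bw <- backward_pass(obs, centre, ca, ff, theta, max_len = ca$max_len)
  # by symmetry: the state on the first half (excluding the centre),
  # pushed through one flow transition
  segs <- segment_observations(half, integer(0), max_len = ca$max_len)
  fw_half <- forward_pass(segs, ca, ff, theta)$final
  expected <- apply_flow(ff, fw_half)
  expect_equal(bw$states$alpha, expected$alpha, tolerance = 1e-9)
  expect_equal(bw$states$beta, expected$beta, tolerance = 1e-9)
})

test_that("posterior reacts to data in the expected directions", {
  ff <- ff_std()
  ca <- cache_std()
  p <- params_std()
  # lone het at the target: TMRCA pushed above the prior mean
  obs <- c(rep(0L, 10), 1L, rep(0L, 10))
  tr <- decode_pair(obs, 11L, p, ca, ff)
  expect_gt(tr$post_mean, 1)
  # long hom stretch: TMRCA pushed below the prior mean
  tr2 <- decode_pair(rep(0L, 20000), 10000L, p, ca, ff)
  expect_lt(tr2$post_mean, 1)
  # decoding is deterministic
  obs3 <- random_obs(3000, p_het = 0.02, seed = 77)
  t1 <- decode_pair(obs3, c(10L, 1500L), p, ca, ff)
  t2 <- decode_pair(obs3, c(10L, 1500L), p, ca, ff)
  expect_identical(t1, t2)
})

test_that("cached decoding matches fully sequential per-bp decoding", {
  ff <- ff_std()
  ca <- cache_noclip()
  theta <- ca$theta
  sim <- simulate_smc_pair(5e4, seed = 21)
  obs <- pair_observations(sim, compact = FALSE)
  targets <- seq(5000L, 5e4L, by = 5000L)
  segs <- segment_observations(obs, targets, max_len = ca$max_len)
  fw <- forward_pass(segs, ca, ff, theta)
  # sequential reference: per-bp flow + emission
  st <- gamma_state(1, 1)
  seq_states <- vector("list", length(targets))
  ti <- 1L
  for (i in seq_along(obs)) {
    st <- emission_update(apply_flow(ff, st), obs[i], theta)
    if (ti <= length(targets) && i == targets[ti]) {
      seq_states[[ti]] <- st
      ti <- ti + 1L
    }
  }
  for (k in seq_along(targets)) {
    a <- state_to_log(fw$states)
    b <- state_to_log(seq_states[[k]])
    expect_lt(abs(a$l_mu[k] - b$l_mu), 5e-3)
    expect_lt(abs(a$l_cv[k] - b$l_cv), 5e-2)
  }
})

test_that("decoder recovers simulated TMRCA paths and shows shrinkage to the mean", {
  ff <- ff_std()
  ca <- cache_std()
  p <- params_std()
  tt <- c()
  pm <- c()
  for (s in 1:3) {
    sim <- simulate_smc_pair(3e6, seed = 200 + s)
    tg <- seq(1000L, 3e6L, by = 1000L)
    tr <- decode_pair(pair_observations(sim), tg, p, ca, ff)
    tt <- c(tt, true_tmrca_at(sim, tg))
    pm <- c(pm, tr$post_mean)
  }
  expect_gt(cor(tt, pm)^2, 0.4)
  # posterior-mean estimators regress to the mean: overestimate small
  # TMRCAs, underestimate large ones
  qs <- cut(tt, quantile(tt, 0:4 / 4), include.lowest = TRUE)
  bias <- tapply(pm - tt, qs, mean)
  expect_gt(bias[[1]], -0.05)
  expect_lt(bias[[4]], -0.2)
  expect_gt(bias[[1]], bias[[4]])
})

test_that("central 50% credible intervals are roughly calibrated", {
  ff <- ff_std()
  ca <- cache_std()
  p <- params_std()
  sim <- simulate_smc_pair(5e6, seed = 31)
  tg <- seq(500L, 5e6L, by = 500L)
  tr <- decode_pair(pair_observations(sim), tg, p, ca, ff)
  tv <- true_tmrca_at(sim, tg)
  lo <- qgamma(0.25, tr$alpha, tr$beta)
  hi <- qgamma(0.75, tr$alpha, tr$beta)
  cover <- mean(tv >= lo & tv <= hi)
  # approximate posterior: the gamma family plus the family clip leaves the
  # intervals somewhat over-confident, but far from degenerate
  expect_gt(cover, 0.35)
  expect_lt(cover, 0.65)
})

test_that("scale misspecification: 100x-smaller truth still strongly rank-correlated", {
  ff <- ff_std()
  ca <- cache_std()
  p <- params_std()
  sim <- simulate_misspecified(3e6, factor = 100, seed = 8)
  expect_lt(mean(sim$segments$tmrca), 0.05)
  tg <- seq(1000L, 3e6L, by = 1000L)
  tr <- decode_pair(pair_observations(sim), tg, p, ca, ff)
  tv <- true_tmrca_at(sim, tg)
  expect_gt(cor(tv, tr$post_mean, method = "spearman"), 0.3)
  # the continuous state space actually reaches those small values
  expect_lt(median(tr$post_mean), 0.1)
})
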