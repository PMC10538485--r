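# Shared fixtures, memoised per session (grids and caches are deterministic,
# so they are built once and reused across test files via tempdir()).

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, build) {
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  path <- file.path(tempdir(), paste0("gammasmc-fixture-", key, ".rds"))
  val <- if (file.exists(path)) readRDS(path) else {
    v <- build()
    saveRDS(v, path)
    v
  }
  assign(key, val, envir = .fixture_env)
  val
}

# standard flow field at the human-like rho, moment projection
ff_std <- function() fixture("ff_std", function() build_flow_field(rho = 0.0006))

# rho = 0 grid + cache (exact conjugate path)
ff_zero <- function() fixture("ff_zero", function() build_flow_field(rho = 0))
cache_zero <- function() fixture("cache_zero", function() {
  build_skip_cache(ff_zero(), theta = 0.001, max_len = 500L)
})

# full-length default cache used by decoding-accuracy tests
cache_std <- function() fixture("cache_std", function() {
  build_skip_cache(ff_std(), theta = 0.00075, max_len = 10000L)
})

# small unclipped cache for cache-vs-sequential equivalence checks
cache_noclip <- function() fixture("cache_noclip", function() {
  build_skip_cache(ff_std(), theta = 0.00075, max_len = 300L, clip = "none")
})

params_std <- function() model_params(theta = 0.00075, rho = 0.0006, Ne = 15000)

# quadrature oracle for the compound distribution: E[g(t)] by nested adaptive
# integration of the exact mixture density (independent of the closed-form
# moment identities used by the implementation).
# p(t) = (beta/(beta+rho))^alpha f_{alpha,beta+rho}(t) + e^{-t} I(t),
# I(t) = E_s[(1 - e^{-rho s})(e^{min(s,t)} - 1)/s] under Gamma(alpha, beta).
compound_density_oracle <- function(alpha, beta, rho) {
  s_lo <- qgamma(1e-14, alpha, beta)
  s_hi <- qgamma(1e-14, alpha, beta, lower.tail = FALSE)
  I_of_t <- function(ti) {
    f <- function(s) {
      (1 - exp(-rho * s)) * (exp(pmin(s, ti) - ti) - exp(-ti)) / s *
        dgamma(s, alpha, beta)
    }
    # split at the kink s = t
    if (ti > s_lo && ti < s_hi) {
      stats::integrate(f, s_lo, ti, rel.tol = 1e-11, subdivisions = 800L,
                       stop.on.error = FALSE)$value +
        stats::integrate(f, ti, s_hi, rel.tol = 1e-11, subdivisions = 800L,
                         stop.on.error = FALSE)$value
    } else {
      stats::integrate(f, s_lo, s_hi, rel.tol = 1e-11, subdivisions = 800L,
                       stop.on.error = FALSE)$value
    }
  }
  cc <- exp(-alpha * log1p(rho / beta))
  function(t) {
    cc * dgamma(t, alpha, beta + rho) + vapply(t, I_of_t, numeric(1))
  }
}

compound_oracle_expect <- function(alpha, beta, rho, g = identity) {
  dens <- compound_density_oracle(alpha, beta, rho)
  # integration nodes covering both the state scale and the prior scale
  cuts <- sort(unique(c(0, qgamma(c(1e-12, 0.5), alpha, beta + rho),
                        qgamma(1e-12, alpha, beta + rho, lower.tail = FALSE),
                        1, 60)))
  tot <- function(f) {
    sum(vapply(seq_len(length(cuts) - 1), function(i) {
      stats::integrate(f, cuts[i], cuts[i + 1], rel.tol = 1e-10,
                       subdivisions = 400L, stop.on.error = FALSE)$value
    }, numeric(1)))
  }
  tot(function(t) g(t) * dens(t)) / tot(dens)
}

compound_oracle_moment <- function(alpha, beta, rho, k = 1) {
  compound_oracle_expect(alpha, beta, rho, function(t) t^k)
}

# random observation vector with given het density
random_obs <- function(n, p_het = 0.2, seed = 1) {
  withr::with_seed(seed, sample(c(0L, 1L), n, replace = TRUE,
                                prob = c(1 - p_het, p_het)))
}
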