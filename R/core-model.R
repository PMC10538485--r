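#' SMC transition density between coalescence times at adjacent sites
#'
#' Under the sequentially Markovian coalescent with per-bp scaled
#' recombination rate \eqn{\rho}, the TMRCA at the next base equals the
#' current TMRCA \eqn{s} with probability \eqn{e^{-\rho s}} (no
#' recombination); otherwise the recombination point is uniform on
#' \eqn{(0, s)} and the detached lineage re-coalesces at rate 1 (coalescent
#' units), giving the continuous part
#' \deqn{p(t | s) = (1 - e^{-\rho s}) \frac{1}{s} (e^{\min(s,t)} - 1) e^{-t}.}
#' The atom and continuous part together integrate to one; the Exp(1)
#' coalescent prior is stationary in the small-\eqn{\rho} (continuum) limit.
#'
#' @param t candidate new coalescence time(s), > 0 (coalescent units).
#' @param s current coalescence time, > 0.
#' @param rho scaled recombination rate per bp, >= 0.
#' @return A list: `density` -- the continuous-part density evaluated at `t`;
#'   `atom_weight` -- the point mass \eqn{e^{-\rho s}} at \eqn{t = s}.
#' @examples
#' smc_transition_density(0.5, s = 1, rho = 0.0006)$atom_weight # exp(-0.0006)
#' @export
smc_transition_density <- function(t, s, rho) {
  if (any(s <= 0) || any(t <= 0)) stop("s and t must be > 0")
  if (rho < 0) stop("rho must be >= 0")
  atom <- exp(-rho * s)
  # expm1 keeps precision for small min(s, t); exp(min - t) avoids overflow
  m <- pmin(s, t)
  dens <- (1 - atom) * (exp(m - t) - exp(-t)) / s
  list(density = dens, atom_weight = atom)
}

#' Moments of the one-step compound (predictive) distribution
#'
#' Given a gamma forward density \eqn{\Gamma(\alpha, \beta)} at one site, the
#' TMRCA at the next site follows the compound distribution
#' \eqn{p_{\alpha,\beta}(t) = \int p(t|s) f_{\alpha,\beta}(s) ds}. Its first
#' two moments follow from the conditional moments
#' \eqn{E[t|s] = e^{-\rho s} s + (1-e^{-\rho s})(s/2 + 1)} and
#' \eqn{E[t^2|s] = e^{-\rho s} s^2 + (1-e^{-\rho s})(s^2/3 + s + 2)},
#' integrated against \eqn{f_{\alpha,\beta}} using the tilt identity
#' \eqn{e^{-\rho s} f_{\alpha,\beta}(s) = (\beta/(\beta+\rho))^\alpha
#' f_{\alpha,\beta+\rho}(s)}. The tilt constant is computed in log space so
#' extreme \eqn{\alpha, \beta} (grid corners) do not overflow.
#'
#' @param state a \code{gamma_state}; fields may be equal-length vectors.
#' @param rho scaled recombination rate per bp, >= 0.
#' @return A list with numeric fields `mean` and `variance`.
#' @examples
#' compound_moments(gamma_state(1, 1), rho = 0)    # mean 1, variance 1
#' @export
compound_moments <- function(state, rho) {
  if (rho < 0) stop("rho must be >= 0")
  a <- state$alpha
  b <- state$beta
  m  <- a / b                    # E[s]
  g2 <- a * (a + 1) / b^2        # E[s^2]
  lc <- -a * log1p(rho / b)      # log (beta/(beta+rho))^alpha
  cc <- exp(lc)
  one_cc <- -expm1(lc)           # 1 - cc, accurate for small rho
  mp  <- a / (b + rho)           # E_tilt[s]
  g2p <- a * (a + 1) / (b + rho)^2
  # grouped so the O(1) terms cancel analytically as rho -> 0 (otherwise the
  # tiny variance of concentrated small-mean states is lost to roundoff)
  M1 <- (m + cc * mp) / 2 + one_cc
  M2 <- (g2 + 2 * cc * g2p) / 3 + m * (one_cc + cc * rho / (b + rho)) +
    2 * one_cc
  list(mean = M1, variance = M2 - M1^2)
}

#' Log-mean of the one-step compound distribution
#'
#' \eqn{E[\log T]} under \eqn{p_{\alpha,\beta}}, needed by the KL gamma
#' projection. The no-recombination part is closed form
#' (\eqn{(\beta/(\beta+\rho))^\alpha (\psi(\alpha) - \log(\beta+\rho))});
#' the recombination part uses \eqn{E[\log(u + w)] = \log u + e^u E_1(u)}
#' for \eqn{u \sim U(0, s)}, \eqn{w \sim Exp(1)}, with the log-singularity
#' at \eqn{u = 0} integrated out analytically, and fixed Gauss-Legendre
#' quadrature in probability space for the mixing over \eqn{s} (smooth and
#' bounded, so low-order rules are accurate to ~1e-10).
#'
#' @inheritParams compound_moments
#' @param n_s,n_u quadrature orders for the outer (over s) and inner (over
#'   the recombination point) integrals.
#' @return Numeric vector of \eqn{E[\log T]} values.
#' @export
compound_log_mean <- function(state, rho, n_s = 64L, n_u = 48L) {
  a <- state$alpha
  b <- state$beta
  cc <- exp(-a * log1p(rho / b))
  part1 <- cc * (digamma(a) - log(b + rho))
  if (rho == 0) return(part1)
  gl_s0 <- pracma::gaussLegendre(n_s, 0, 1)
  # substitute p = 1 - (1-u)^3: clusters nodes near the gamma tail, where
  # qgamma'(p) diverges and plain Gauss-Legendre converges slowly
  gl_s <- list(x = 1 - (1 - gl_s0$x)^3, w = gl_s0$w * 3 * (1 - gl_s0$x)^2)
  gl_u <- pracma::gaussLegendre(n_u, 0, 1)
  N <- length(a)
  S <- matrix(stats::qgamma(rep(gl_s$x, each = N), rep(a, n_s), rep(b, n_s)),
              N, n_s)
  # g(s) = E[log t | s, recombination] = -gamma_E + (1/s) int_0^s r(u) du,
  # r(u) = e^u E1(u) + gamma_E + log(u) (smooth, r(0) = 0)
  gamma_e <- 0.5772156649015329
  G <- matrix(-gamma_e, N, n_s)
  for (k in seq_len(n_u)) {
    U <- S * gl_u$x[k]
    G <- G + gl_u$w[k] * (.e1_scaled(U) + gamma_e + log(U))
  }
  W <- 1 - exp(-rho * S)
  part1 + as.vector((W * G) %*% gl_s$w)
}

# exponentially scaled exponential integral: e^u E1(u), vectorised.
# Power series below 1, continued fraction (fixed-depth backward
# evaluation) above; both accurate to ~1e-15 in double precision.
.e1_scaled <- function(u) {
  out <- u
  sm <- u <= 1
  if (any(sm)) {
    us <- u[sm]
    acc <- 0
    term <- rep(1, length(us))
    for (n in 1:30) {
      term <- term * (-us) / n
      acc <- acc - term / n
    }
    out[sm] <- exp(us) * (-0.5772156649015329 - log(us) + acc)
  }
  if (any(!sm)) {
    ul <- u[!sm]
    v <- ul
    for (k in 120:1) v <- ul + k / (1 + k / v)
    out[!sm] <- 1 / v
  }
  out
}

#' Project the compound distribution back onto the gamma family
#'
#' One transition step of the decoder: the compound distribution
#' \eqn{p_{\alpha,\beta}} is generally not gamma, so it is approximated by
#' \eqn{\Gamma(\alpha', \beta')}. The default criterion (`"moment"`) matches
#' mean and variance in closed form (\eqn{\alpha' = M_1^2/V},
#' \eqn{\beta' = M_1/V}). `"kl"` instead minimises the KL divergence
#' \eqn{KL(p_{\alpha,\beta} \| \Gamma)} by matching the gamma family's
#' sufficient statistics \eqn{E[T]} and \eqn{E[\log T]}, solving
#' \eqn{\log\alpha' - \psi(\alpha') = \log E[T] - E[\log T]} by Newton
#' iteration; it is less sensitive to the recombination tail for
#' concentrated states and is exposed for sensitivity checks. Both leave
#' \eqn{\Gamma(1,1)} fixed (the stationary prior) and reduce to the
#' identity at \eqn{\rho = 0}.
#'
#' @inheritParams compound_moments
#' @param method `"moment"` (default) or `"kl"`.
#' @return A \code{gamma_state} (vectorised).
#' @examples
#' gamma_project(gamma_state(1, 1), rho = 0.0006)  # ~ Gamma(1, 1): stationary
#' @export
gamma_project <- function(state, rho, method = c("moment", "kl")) {
  method <- match.arg(method)
  M1 <- compound_moments(state, rho)$mean
  if (method == "moment") {
    v <- compound_moments(state, rho)$variance
    if (any(v <= 0)) {
      warning("degenerate compound variance clamped to machine-epsilon floor")
      v <- pmax(v, .Machine$double.eps * M1^2)
    }
    return(gamma_state(alpha = M1^2 / v, beta = M1 / v))
  }
  d <- log(M1) - compound_log_mean(state, rho)
  if (any(d <= 0)) stop("invalid moments for KL projection (E[log T] >= log E[T])")
  # generalised-method-of-moments initialisation, then Newton on
  # f(a) = log(a) - digamma(a) - d
  a <- (3 - d + sqrt((d - 3)^2 + 24 * d)) / (12 * d)
  for (i in 1:60) {
    f <- log(a) - digamma(a) - d
    a_new <- a - f / (1 / a - trigamma(a))
    bad <- a_new <= 0
    a_new[bad] <- a[bad] / 2
    if (all(abs(a_new - a) <= 1e-13 * a)) {
      a <- a_new
      break
    }
    a <- a_new
  }
  gamma_state(alpha = a, beta = a / M1)
}

# E[g(T)] under the compound distribution, by two-level adaptive quadrature
# over the exact mixture (atom part + uniform-recombination part).
# Test-grade numerics, not used in the decoding hot path.
compound_expect <- function(state, rho, g, rel.tol = 1e-9) {
  a <- state$alpha
  b <- state$beta
  lo <- stats::qgamma(1e-14, a, b)
  hi <- stats::qgamma(1e-14, a, b, lower.tail = FALSE)
  # no-recombination component: t = s, s ~ tilted gamma, weight cc
  cc <- exp(-a * log1p(rho / b))
  lo_t <- stats::qgamma(1e-14, a, b + rho)
  hi_t <- stats::qgamma(1e-14, a, b + rho, lower.tail = FALSE)
  part_atom <- cc * stats::integrate(function(s) {
    g(s) * stats::dgamma(s, a, b + rho)
  }, lo_t, hi_t, rel.tol = rel.tol)$value
  # recombination component: s ~ Gamma(a,b), u | s ~ U(0,s), t = u + Exp(1)
  inner <- function(s) {
    vapply(s, function(si) {
      w <- 1 - exp(-rho * si)
      if (w == 0) return(0)
      val <- stats::integrate(function(t) {
        g(t) * (exp(pmin(si, t) - t) - exp(-t)) / si
      }, 0, si + 60, rel.tol = rel.tol)$value
      w * val * stats::dgamma(si, a, b)
    }, numeric(1))
  }
  part_rec <- stats::integrate(inner, lo, hi, rel.tol = rel.tol)$value
  part_atom + part_rec
}

#' Emission update: absorb one observed site
#'
#' The per-site emission is Poisson-like with rate \eqn{\theta t} linearised
#' to the kernel \eqn{t^y e^{-\theta t}} for observation
#' \eqn{y \in \{0 = hom, 1 = het\}}. By Poisson-gamma conjugacy the update of
#' the forward density is exact: \eqn{\Gamma(\alpha, \beta) \to
#' \Gamma(\alpha + y, \beta + \theta)}. Missing sites carry no emission and
#' must not be passed through this function.
#'
#' @param state a \code{gamma_state}.
#' @param y observation: 0 (hom) or 1 (het). `NA` is an error.
#' @param theta scaled mutation rate per bp, > 0.
#' @return The updated \code{gamma_state}.
#' @examples
#' emission_update(gamma_state(1, 1), y = 1, theta = 0.00075)
#' @export
emission_update <- function(state, y, theta) {
  if (any(is.na(y))) stop("missing observations must not be passed to emission_update")
  if (!all(y %in% c(0, 1))) stop("y must be 0 (hom) or 1 (het)")
  if (theta <= 0) stop("theta must be > 0")
  gamma_state(alpha = state$alpha + y, beta = state$beta + theta)
}

#' Combine forward and backward densities into the posterior
#'
#' If \eqn{\Gamma(\alpha, \beta)} approximates the forward density at a
#' position and \eqn{\Gamma(\alpha', \beta')} the backward density, the
#' combined posterior is \eqn{\Gamma(\alpha + \alpha' - 1, \beta + \beta' - 1)}
#' (the product of the two densities divided once by the Exp(1) prior both
#' passes start from). The operation is commutative with identity
#' \eqn{\Gamma(1, 1)}.
#'
#' @param fwd,bwd \code{gamma_state}s (vectorised).
#' @param position optional positions used in the error message when the
#'   combined parameters leave the valid domain.
#' @return The combined \code{gamma_state}.
#' @examples
#' combine_forward_backward(gamma_state(2, 3), gamma_state(4, 5)) # Gamma(5, 7)
#' @export
combine_forward_backward <- function(fwd, bwd, position = NULL) {
  a <- fwd$alpha + bwd$alpha - 1
  b <- fwd$beta + bwd$beta - 1
  bad <- which(a <= 0 | b <= 0)
  if (length(bad)) {
    where <- if (!is.null(position)) {
      paste(" at position(s)", paste(utils::head(position[bad], 5), collapse = ", "))
    } else {
      paste(" at index(es)", paste(utils::head(bad, 5), collapse = ", "))
    }
    stop("combined gamma parameters are nonpositive", where)
  }
  gamma_state(alpha = a, beta = b)
}
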