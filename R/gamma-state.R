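#' Gamma-distributed coalescence-time state
#'
#' The forward, backward and combined posterior densities of the pairwise
#' TMRCA are all constrained to the gamma family \eqn{\Gamma(\alpha, \beta)}
#' (shape/rate). A state can equivalently be addressed by its mean
#' \eqn{\mu = \alpha/\beta} (in coalescent units of \eqn{2 N_e} generations)
#' and coefficient of variation \eqn{CV = 1/\sqrt{\alpha}}, or by their
#' base-10 logarithms \code{l_mu}, \code{l_cv} -- the coordinates of the
#' flow-field grid.
#'
#' @param alpha shape parameter, > 0.
#' @param beta rate parameter, > 0 (per coalescent time unit).
#' @return An object of class \code{"gamma_state"}: a list with fields
#'   \code{alpha} and \code{beta}.
#' @seealso [state_to_log()], [log_to_state()], [gamma_project()]
#' @examples
#' s <- gamma_state(1, 1)   # the Exp(1) coalescent prior
#' state_mean(s)            # 1 coalescent unit = 2 Ne generations
#' @export
gamma_state <- function(alpha, beta) {
  if (!is.numeric(alpha) || !is.numeric(beta) ||
      any(!is.finite(alpha)) || any(!is.finite(beta)) ||
      any(alpha <= 0) || any(beta <= 0)) {
    stop("gamma_state requires finite alpha > 0 and beta > 0")
  }
  structure(list(alpha = alpha, beta = beta), class = "gamma_state")
}

#' @export
print.gamma_state <- function(x, ...) {
  cat(sprintf("Gamma(alpha = %.6g, beta = %.6g): mean = %.6g, CV = %.6g\n",
              x$alpha, x$beta, x$alpha / x$beta, 1 / sqrt(x$alpha)))
  invisible(x)
}

#' @rdname gamma_state
#' @param state a \code{gamma_state}.
#' @export
state_mean <- function(state) state$alpha / state$beta

#' @rdname gamma_state
#' @export
state_cv <- function(state) 1 / sqrt(state$alpha)

#' Convert between (alpha, beta) and log grid coordinates
#'
#' `state_to_log()` maps a state to \code{(l_mu, l_cv)} =
#' \code{(log10(alpha/beta), log10(1/sqrt(alpha)))}; `log_to_state()` is the
#' inverse. Both are vectorised and are exact inverses to floating precision.
#'
#' @param state a \code{gamma_state} (fields may be vectors).
#' @return `state_to_log()`: a list with numeric fields `l_mu`, `l_cv`.
#' @export
state_to_log <- function(state) {
  list(l_mu = log10(state$alpha / state$beta),
       l_cv = -0.5 * log10(state$alpha))
}

#' @rdname state_to_log
#' @param l_mu base-10 log of the mean (coalescent units).
#' @param l_cv base-10 log of the coefficient of variation.
#' @export
log_to_state <- function(l_mu, l_cv) {
  alpha <- 10^(-2 * l_cv)
  gamma_state(alpha = alpha, beta = alpha / 10^l_mu)
}

#' Population-genetic model parameters and unit conversions
#'
#' Holds the scaled mutation rate \eqn{\theta = 4 N_e \mu} and scaled
#' recombination rate \eqn{\rho = 4 N_e r} (both per base pair), together
#' with the unscaled rates, the diploid effective population size and the
#' generation time used to convert coalescent units to generations and years.
#' Scaled rates may be given directly, or derived from \code{mu_rate},
#' \code{r_rate} and \code{Ne}; \code{rho} may also be given as
#' \code{rho_over_theta * theta}.
#'
#' @param theta scaled mutation rate per bp (optional if `mu_rate` and `Ne`
#'   given).
#' @param rho scaled recombination rate per bp (optional if `r_rate` and `Ne`
#'   given, or if `rho_over_theta` given).
#' @param mu_rate unscaled mutation rate, mutations/bp/generation.
#' @param r_rate unscaled recombination rate, recombinations/bp/generation.
#' @param Ne diploid effective population size.
#' @param generation_time years per generation (default 30).
#' @param rho_over_theta ratio \eqn{\rho/\theta}, an alternative way to set
#'   `rho`.
#' @return An object of class \code{"model_params"}.
#' @examples
#' model_params(mu_rate = 1.25e-8, r_rate = 1e-8, Ne = 15000)
#' model_params(theta = 0.00075, rho_over_theta = 0.8)
#' @export
model_params <- function(theta = NULL, rho = NULL, mu_rate = NULL,
                         r_rate = NULL, Ne = NULL, generation_time = 30,
                         rho_over_theta = NULL) {
  if (is.null(theta)) {
    if (is.null(mu_rate) || is.null(Ne)) {
      stop("theta must be given, or derivable from mu_rate and Ne")
    }
    theta <- 4 * Ne * mu_rate
  }
  if (is.null(rho)) {
    if (!is.null(rho_over_theta)) {
      rho <- rho_over_theta * theta
    } else if (!is.null(r_rate) && !is.null(Ne)) {
      rho <- 4 * Ne * r_rate
    } else {
      stop("rho must be given, or derivable from rho_over_theta, ",
           "or from r_rate and Ne")
    }
  }
  if (theta <= 0) stop("theta must be > 0")
  if (rho < 0) stop("rho must be >= 0")
  if (!is.null(mu_rate) && !is.null(Ne) &&
      abs(theta - 4 * Ne * mu_rate) > 1e-12 * theta) {
    stop("theta is inconsistent with 4 * Ne * mu_rate")
  }
  if (!is.null(r_rate) && !is.null(Ne) && is.null(rho_over_theta) &&
      abs(rho - 4 * Ne * r_rate) > 1e-12 * max(rho, 1e-300)) {
    stop("rho is inconsistent with 4 * Ne * r_rate")
  }
  structure(list(theta = theta, rho = rho, mu_rate = mu_rate,
                 r_rate = r_rate, Ne = Ne,
                 generation_time = generation_time),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Model parameters:\n")
  cat(sprintf("  theta (4 Ne mu) = %g per bp\n", x$theta))
  cat(sprintf("  rho   (4 Ne r)  = %g per bp\n", x$rho))
  if (!is.null(x$Ne)) cat(sprintf("  Ne = %g diploids\n", x$Ne))
  cat(sprintf("  generation time = %g yr\n", x$generation_time))
  invisible(x)
}

#' Posterior mean coalescence time in generations and years
#'
#' Converts the mean of a gamma state from coalescent units (1 unit =
#' \eqn{2 N_e} generations) to generations and years.
#'
#' @param state a \code{gamma_state} (vectorised over its fields).
#' @param params a \code{model_params} with \code{Ne} set.
#' @return A list with fields `generations` and `years`.
#' @examples
#' p <- model_params(theta = 0.00075, rho = 0.0006, Ne = 15000)
#' to_generations(gamma_state(1, 1), p)  # 30,000 generations, 900,000 yr
#' @export
to_generations <- function(state, params) {
  if (is.null(params$Ne)) stop("Ne must be set in model_params to convert to generations")
  gens <- (state$alpha / state$beta) * 2 * params$Ne
  list(generations = gens, years = gens * params$generation_time)
}
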