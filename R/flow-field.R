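#' Precompute the flow field on the log-mean / log-CV grid
#'
#' One SMC transition step maps a gamma forward density \eqn{\Gamma(\alpha,
#' \beta)} to its gamma projection \eqn{\Gamma(\alpha', \beta')}; viewed over
#' all states this mapping \eqn{F} is a two-dimensional flow field. It is
#' evaluated once, on a grid of \code{l_mu = log10(mean)} (default 51 values
#' equally spaced on \eqn{[-5, 2]}) by \code{l_cv = log10(CV)} (default 50
#' values on \eqn{[-2, 0]}; CV > 1 is excluded since the gamma density then
#' diverges at 0). Off-grid states are clipped to the grid ranges and
#' bilinearly interpolated. The build depends only on \code{rho}, never on
#' \code{theta} or the data, and can be serialised and reused.
#'
#' @param rho scaled recombination rate per bp, >= 0.
#' @param n_mu,mu_range,n_cv,cv_range grid layout (defaults: 51 on \[-5, 2\],
#'   50 on \[-2, 0\]).
#' @param projection gamma projection criterion, see [gamma_project()].
#' @return An object of class \code{"flow_field"}: the axes, the image
#'   matrices `mu_img`, `cv_img` (node \eqn{(i, j)} holds the \code{(l_mu',
#'   l_cv')} image of grid state \eqn{(l\_mu_i, l\_cv_j)}), and `rho`.
#' @examples
#' ff <- build_flow_field(rho = 0.0006)
#' apply_flow(ff, gamma_state(1, 1))   # ~ unchanged: stationary prior
#' @export
build_flow_field <- function(rho, n_mu = 51L, mu_range = c(-5, 2),
                             n_cv = 50L, cv_range = c(-2, 0),
                             projection = c("moment", "kl")) {
  if (rho < 0) stop("rho must be >= 0")
  projection <- match.arg(projection)
  l_mu_axis <- seq(mu_range[1], mu_range[2], length.out = n_mu)
  l_cv_axis <- seq(cv_range[1], cv_range[2], length.out = n_cv)
  nodes <- expand.grid(l_mu = l_mu_axis, l_cv = l_cv_axis)  # mu fastest
  st <- log_to_state(nodes$l_mu, nodes$l_cv)
  img <- gamma_project(st, rho, method = projection)
  if (any(!is.finite(img$alpha)) || any(!is.finite(img$beta))) {
    bad <- which(!is.finite(img$alpha) | !is.finite(img$beta))[1]
    stop(sprintf("flow-field projection failed at node (l_mu = %g, l_cv = %g)",
                 nodes$l_mu[bad], nodes$l_cv[bad]))
  }
  lg <- state_to_log(img)
  structure(list(
    l_mu_axis = l_mu_axis, l_cv_axis = l_cv_axis,
    mu_img = matrix(lg$l_mu, n_mu, n_cv),
    cv_img = matrix(lg$l_cv, n_mu, n_cv),
    rho = rho,
    projection = projection,
    version = 1L
  ), class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("SMC flow field: %d x %d grid, l_mu in [%g, %g], l_cv in [%g, %g], rho = %g\n",
              length(x$l_mu_axis), length(x$l_cv_axis),
              min(x$l_mu_axis), max(x$l_mu_axis),
              min(x$l_cv_axis), max(x$l_cv_axis), x$rho))
  invisible(x)
}

# Clip (x, y) into the grid ranges and return bilinear weights/indices.
# Axes are uniform; vectorised over x, y.
.bilinear_ix <- function(grid, x, y) {
  nx <- length(grid$l_mu_axis)
  ny <- length(grid$l_cv_axis)
  x0 <- grid$l_mu_axis[1]
  y0 <- grid$l_cv_axis[1]
  hx <- (grid$l_mu_axis[nx] - x0) / (nx - 1)
  hy <- (grid$l_cv_axis[ny] - y0) / (ny - 1)
  x <- pmin(pmax(x, x0), grid$l_mu_axis[nx])
  y <- pmin(pmax(y, y0), grid$l_cv_axis[ny])
  u <- (x - x0) / hx
  v <- (y - y0) / hy
  i0 <- pmin(floor(u), nx - 2)  # 0-based cell index
  j0 <- pmin(floor(v), ny - 2)
  fx <- u - i0
  fy <- v - j0
  base <- i0 + 1 + j0 * nx      # vector index of node (i0+1, j0+1), column-major
  list(i00 = base, i10 = base + 1, i01 = base + nx, i11 = base + nx + 1,
       w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy),
       w01 = (1 - fx) * fy, w11 = fx * fy,
       x = x, y = y)
}

# Interpolate one value table (stored column-major over nodes) at prepared
# bilinear indices.
.bilinear_val <- function(tab, ix) {
  ix$w00 * tab[ix$i00] + ix$w10 * tab[ix$i10] +
    ix$w01 * tab[ix$i01] + ix$w11 * tab[ix$i11]
}

# One flow step in (l_mu, l_cv) coordinates; vectorised. Used by both
# apply_flow and the cache builder.
.flow_log <- function(grid, l_mu, l_cv) {
  ix <- .bilinear_ix(grid, l_mu, l_cv)
  list(l_mu = .bilinear_val(grid$mu_img, ix),
       l_cv = .bilinear_val(grid$cv_img, ix))
}

# differential entropy of Gamma(alpha, beta)
.gamma_entropy <- function(alpha, beta) {
  alpha - log(beta) + lgamma(alpha) + (1 - alpha) * digamma(alpha)
}

#' Apply one flow-field transition step to a state
#'
#' Converts the state to \code{(l_mu, l_cv)}, clips each coordinate into the
#' grid range, bilinearly interpolates the precomputed images of the four
#' nearest grid nodes, and converts back to \eqn{(\alpha, \beta)}. An
#' optional entropy guard (off by default) rejects an interpolated image
#' whose differential entropy exceeds the pre-transition entropy by more than
#' `entropy_slack`, keeping the (clipped) input state instead.
#'
#' @param grid a \code{flow_field}.
#' @param state a \code{gamma_state} (vectorised).
#' @param entropy_guard logical; enable the entropy clip (default `FALSE`).
#' @param entropy_slack allowed entropy increase in nats when the guard is on.
#' @return The transitioned \code{gamma_state}.
#' @export
apply_flow <- function(grid, state, entropy_guard = FALSE, entropy_slack = 0.05) {
  lg <- state_to_log(state)
  if (any(!is.finite(lg$l_mu)) || any(!is.finite(lg$l_cv))) {
    stop("non-finite state passed to apply_flow")
  }
  ix <- .bilinear_ix(grid, lg$l_mu, lg$l_cv)
  out_mu <- .bilinear_val(grid$mu_img, ix)
  out_cv <- .bilinear_val(grid$cv_img, ix)
  if (entropy_guard) {
    before <- log_to_state(ix$x, ix$y)
    after <- log_to_state(out_mu, out_cv)
    h0 <- .gamma_entropy(before$alpha, before$beta)
    h1 <- .gamma_entropy(after$alpha, after$beta)
    rej <- h1 > h0 + entropy_slack
    out_mu[rej] <- ix$x[rej]
    out_cv[rej] <- ix$y[rej]
  }
  log_to_state(out_mu, out_cv)
}

#' Build run-length skip caches for homozygous and missing stretches
#'
#' Starting a trajectory at every grid node, repeatedly applies one flow step
#' followed by a hom emission (`hom` table) or one flow step only (`missing`
#' table, independent of `theta`), recording the \code{(l_mu, l_cv)} state
#' after each of \code{1..max_len} steps. A run of n identical observations
#' can then be replayed in O(1) by interpolating the cached n-step images at
#' the current off-grid state -- "locus skipping". Cached node trajectories
#' are bit-identical to n sequential [apply_flow()] / [emission_update()]
#' calls, by construction.
#'
#' @param grid a \code{flow_field} built for the run's `rho`.
#' @param theta scaled mutation rate per bp (baked into the hom table).
#' @param max_len maximal cached run length in bp (default 10000); longer
#'   runs are chained in `max_len` chunks by [skip_run()].
#' @param max_bytes abort if the estimated table memory exceeds this cap
#'   (default 4 GiB).
#' @param clip transition-clip rule for hom-trajectory steps:
#'   \describe{
#'     \item{`"family"` (default)}{one SMC transition mixes the current state
#'       with recombination weight \eqn{w = 1-(\beta/(\beta+\rho))^\alpha} of
#'       prior-resampled mass; when the state mean is far below the prior
#'       mean this makes the exact compound bimodal, with a coefficient of
#'       variation above 1 -- outside the representable gamma family (the
#'       grid excludes CV > 1). Absorbing that tail into a clipped CV = 1
#'       gamma permanently inflates the mean (homozygous data can no longer
#'       suppress the tail, whose kill rate is \eqn{\theta\,var} and
#'       \eqn{var} has been truncated), so the state ratchets to a spurious
#'       equilibrium near \eqn{\rho/\theta} instead of tracking small
#'       coalescence times. The rule: a hom-run transition whose exact
#'       compound has CV > 1 (moment-matched \eqn{\alpha' < 1}) is deferred
#'       (state kept; the emission still applies) until the next informative
#'       site. Within the family the projection is applied unchanged.}
#'     \item{`"entropy"`}{reject images whose differential entropy exceeds
#'       the honest mixture bound \eqn{H + h(w) + w (H_{prior}-H)^+}.}
#'     \item{`"none"`}{iterate flow + emission unconditionally; with this
#'       setting cached node trajectories are bit-identical to sequential
#'       [apply_flow()] / [emission_update()] calls.}
#'   }
#'   Missing-run trajectories are never clipped: with no data, diffusion
#'   towards the prior is honest.
#' @return An object of class \code{"skip_cache"} holding per-node, per-length
#'   image tables and the `(theta, rho)` they were built for.
#' @export
build_skip_cache <- function(grid, theta, max_len = 10000L,
                             max_bytes = 4 * 1024^3,
                             clip = c("family", "entropy", "none")) {
  clip <- match.arg(clip)
  if (max_len < 1) stop("max_len must be >= 1")
  if (theta <= 0) stop("theta must be > 0")
  n_nodes <- length(grid$l_mu_axis) * length(grid$l_cv_axis)
  need <- 4 * 8 * n_nodes * as.numeric(max_len)
  if (need > max_bytes) {
    stop(sprintf(paste0("skip cache would need ~%.1f GiB > cap; ",
                        "reduce max_len or raise max_bytes"), need / 1024^3))
  }
  nodes <- expand.grid(l_mu = grid$l_mu_axis, l_cv = grid$l_cv_axis)
  hom_mu <- matrix(NA_real_, n_nodes, max_len)
  hom_cv <- matrix(NA_real_, n_nodes, max_len)
  mis_mu <- matrix(NA_real_, n_nodes, max_len)
  mis_cv <- matrix(NA_real_, n_nodes, max_len)
  # hom trajectory: flow then hom emission (alpha unchanged, beta += theta)
  hm <- nodes$l_mu
  hc <- nodes$l_cv
  # missing trajectory: flow only
  mm <- nodes$l_mu
  mc <- nodes$l_cv
  for (n in seq_len(max_len)) {
    st <- .flow_log(grid, hm, hc)
    if (clip != "none") {
      a0 <- 10^(-2 * hc)
      b0 <- a0 / 10^hm
      if (clip == "family") {
        mom <- compound_moments(gamma_state(a0, b0), grid$rho)
        rej <- mom$mean^2 < mom$variance        # compound CV > 1
      } else {
        w <- -expm1(-a0 * log1p(grid$rho / b0))
        h_bin <- ifelse(w > 0 & w < 1, -w * log(w) - (1 - w) * log1p(-w), 0)
        H0 <- .gamma_entropy(a0, b0)
        bound <- H0 + h_bin + w * pmax(1 - H0, 0)   # H(Exp(1)) = 1 nat
        a1 <- 10^(-2 * st$l_cv)
        H1 <- .gamma_entropy(a1, a1 / 10^st$l_mu)
        rej <- H1 > bound + 1e-12
      }
      st$l_mu[rej] <- hm[rej]
      st$l_cv[rej] <- hc[rej]
    }
    alpha <- 10^(-2 * st$l_cv)
    beta <- alpha / 10^st$l_mu
    hm <- log10(alpha / (beta + theta))
    hc <- st$l_cv
    hom_mu[, n] <- hm
    hom_cv[, n] <- hc
    st <- .flow_log(grid, mm, mc)
    mm <- st$l_mu
    mc <- st$l_cv
    mis_mu[, n] <- mm
    mis_cv[, n] <- mc
  }
  structure(list(
    hom_mu = hom_mu, hom_cv = hom_cv,
    mis_mu = mis_mu, mis_cv = mis_cv,
    theta = theta, rho = grid$rho, max_len = as.integer(max_len),
    clip = clip,
    l_mu_axis = grid$l_mu_axis, l_cv_axis = grid$l_cv_axis,
    version = 1L
  ), class = "skip_cache")
}

#' @export
print.skip_cache <- function(x, ...) {
  cat(sprintf("Skip cache: max run %d bp, theta = %g, rho = %g, %d grid nodes\n",
              x$max_len, x$theta, x$rho, nrow(x$hom_mu)))
  invisible(x)
}

# Interpolated lookup of the n-step image for one table pair at (possibly
# off-grid) log coordinates. Scalar state, scalar n.
.cache_lookup <- function(cache, tab_mu, tab_cv, l_mu, l_cv, n) {
  ix <- .bilinear_ix(cache, l_mu, l_cv)
  list(l_mu = ix$w00 * tab_mu[ix$i00, n] + ix$w10 * tab_mu[ix$i10, n] +
         ix$w01 * tab_mu[ix$i01, n] + ix$w11 * tab_mu[ix$i11, n],
       l_cv = ix$w00 * tab_cv[ix$i00, n] + ix$w10 * tab_cv[ix$i10, n] +
         ix$w01 * tab_cv[ix$i01, n] + ix$w11 * tab_cv[ix$i11, n])
}

# skip in log coordinates (hot path); chains runs longer than max_len.
# With rho = 0 the transition is the identity map, so the whole run reduces
# to exact Poisson-gamma accumulation (alpha unchanged, beta += n * theta):
# no lookup, no interpolation error, no grid clipping.
.skip_log <- function(cache, l_mu, l_cv, n_missing, n_hom) {
  if (cache$rho == 0) {
    if (n_hom > 0) {
      alpha <- 10^(-2 * l_cv)
      beta <- alpha / 10^l_mu + n_hom * cache$theta
      l_mu <- log10(alpha / beta)
    }
    return(list(l_mu = l_mu, l_cv = l_cv))
  }
  ml <- cache$max_len
  n <- n_missing
  while (n > 0) {
    k <- if (n > ml) ml else n
    st <- .cache_lookup(cache, cache$mis_mu, cache$mis_cv, l_mu, l_cv, k)
    l_mu <- st$l_mu
    l_cv <- st$l_cv
    n <- n - k
  }
  n <- n_hom
  while (n > 0) {
    k <- if (n > ml) ml else n
    st <- .cache_lookup(cache, cache$hom_mu, cache$hom_cv, l_mu, l_cv, k)
    l_mu <- st$l_mu
    l_cv <- st$l_cv
    n <- n - k
  }
  list(l_mu = l_mu, l_cv = l_cv)
}

#' Skip a run of missing and homozygous observations in one step
#'
#' Applies the cached image of `n_missing` transition-only steps followed by
#' the cached image of `n_hom` transition-plus-hom-emission steps, each via
#' clipped bilinear interpolation at the state's off-grid coordinates. Runs
#' longer than the cache's `max_len` are chained in `max_len` chunks.
#'
#' @param cache a \code{skip_cache}.
#' @param state a \code{gamma_state} (scalar).
#' @param n_missing,n_hom run lengths in bp, >= 0.
#' @return The \code{gamma_state} after the run.
#' @export
skip_run <- function(cache, state, n_missing, n_hom) {
  if (n_missing < 0 || n_hom < 0) stop("run lengths must be >= 0")
  if (n_missing == 0 && n_hom == 0) return(state)
  lg <- state_to_log(state)
  out <- .skip_log(cache, lg$l_mu, lg$l_cv, n_missing, n_hom)
  log_to_state(out$l_mu, out$l_cv)
}

#' Serialise / restore a flow field and skip cache sidecar
#'
#' The sidecar is a versioned binary file keyed by `(rho, theta, grid layout,
#' max_len)`; [read_flow_cache()] refuses mismatched keys when expectations
#' are supplied.
#'
#' @param grid a \code{flow_field}.
#' @param cache a \code{skip_cache} built from `grid`.
#' @param path output file path.
#' @return `write_flow_cache()`: the path, invisibly. `read_flow_cache()`: a
#'   list with elements `grid` and `cache`.
#' @export
write_flow_cache <- function(grid, cache, path) {
  stopifnot(inherits(grid, "flow_field"), inherits(cache, "skip_cache"))
  if (!identical(grid$rho, cache$rho)) stop("grid and cache rho mismatch")
  tmp <- paste0(path, ".tmp")
  saveRDS(list(format = "gammasmc-cache", version = 1L,
               grid = grid, cache = cache), tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname write_flow_cache
#' @param rho,theta,max_len expected key values (optional; checked if given).
#' @export
read_flow_cache <- function(path, rho = NULL, theta = NULL, max_len = NULL) {
  obj <- readRDS(path)
  if (!identical(obj$format, "gammasmc-cache")) stop("not a flow-cache sidecar file")
  chk <- function(want, have, what) {
    if (!is.null(want) && abs(want - have) > 1e-15 * max(abs(want), 1)) {
      stop(sprintf("cache %s mismatch: file has %g, expected %g", what, have, want))
    }
  }
  chk(rho, obj$cache$rho, "rho")
  chk(theta, obj$cache$theta, "theta")
  chk(max_len, obj$cache$max_len, "max_len")
  obj[c("grid", "cache")]
}
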