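#' Segment an observation sequence for locus skipping
#'
#' Cuts the per-bp observation sequence at every het site, every requested
#' target (output) position, and every `max_len` bp, so that each segment is
#' a stretch of missing/hom sites with at most one informative terminal base.
#' Within a segment only the missing and hom counts are retained; the decoder
#' treats the segment as a missing run followed by a hom run followed by the
#' terminal observation.
#'
#' @param obs either an integer vector over base pairs (0 = hom, 1 = het,
#'   `NA` = missing; positions 1-based), or a compact representation
#'   `list(length = L, het = <sorted het positions>)` for long sequences with
#'   no missing data (avoids materialising a per-bp vector for multi-Mb
#'   regions).
#' @param targets sorted 1-based positions at which posteriors are required
#'   (may be empty).
#' @param max_len maximal segment length in bp.
#' @return A data frame of class \code{"segment_sequence"} with columns
#'   `start`, `end` (1-based inclusive), `n_missing`, `n_hom`, `terminal_y`
#'   (0/1/`NA`), `terminal_type` (`"het"`, `"target"`, `"length-cap"`,
#'   `"chrom-end"`), `is_target`. Segments tile `[1, length(obs)]` without
#'   gaps. Length-cap and chromosome-end segments have no terminal
#'   observation (all bases counted in the runs); a terminal contributes the
#'   `+1` in `n_missing + n_hom + 1 == end - start + 1`.
#' @export
segment_observations <- function(obs, targets = integer(0), max_len = 10000L) {
  if (is.list(obs)) return(.segment_compact(obs, targets, max_len))
  L <- length(obs)
  if (L < 1) stop("empty observation sequence")
  targets <- as.integer(targets)
  if (is.unsorted(targets, strictly = TRUE)) stop("targets must be sorted, unique")
  if (length(targets) && (targets[1] < 1 || targets[length(targets)] > L)) {
    stop("targets outside the observed interval")
  }
  het_pos <- which(!is.na(obs) & obs == 1L)
  # observation-bearing cut points
  cuts <- sort(unique(c(het_pos, targets)))
  has_obs <- rep(TRUE, length(cuts))
  # enforce max_len within every inter-cut gap (and the tail)
  bounds <- c(0L, cuts, if (length(cuts) == 0L || cuts[length(cuts)] < L) L)
  extra <- integer(0)
  for (k in seq_len(length(bounds) - 1L)) {
    gap <- bounds[k + 1L] - bounds[k]
    if (gap > max_len) {
      extra <- c(extra, seq(bounds[k] + max_len, bounds[k + 1L] - 1L, by = max_len))
    }
  }
  if (length(extra)) {
    cuts2 <- sort(unique(c(cuts, extra, L)))
  } else {
    cuts2 <- sort(unique(c(cuts, L)))
  }
  obs_term <- cuts2 %in% cuts[has_obs]
  n_mis_cum <- cumsum(is.na(obs))
  n_het_cum <- cumsum(!is.na(obs) & obs == 1L)
  starts <- c(1L, cuts2[-length(cuts2)] + 1L)
  ends <- cuts2
  run_end <- ifelse(obs_term, ends - 1L, ends)  # runs exclude the terminal bp
  cum_at <- function(v, i) ifelse(i >= 1L, v[pmax(i, 1L)], 0)
  n_missing <- cum_at(n_mis_cum, run_end) - cum_at(n_mis_cum, starts - 1L)
  n_het_run <- cum_at(n_het_cum, run_end) - cum_at(n_het_cum, starts - 1L)
  if (any(n_het_run > 0)) stop("internal error: het inside a segment run")
  n_hom <- pmax(run_end - starts + 1L, 0L) - n_missing
  terminal_y <- ifelse(obs_term, obs[ends], NA_integer_)
  is_tgt <- ends %in% targets
  terminal_type <- ifelse(!obs_term & ends == L, "chrom-end",
                   ifelse(!obs_term, "length-cap",
                   ifelse(is_tgt, "target", "het")))
  # a het that is also a target is recorded as a target terminal with y = 1
  out <- data.frame(start = starts, end = ends,
                    n_missing = as.integer(n_missing),
                    n_hom = as.integer(n_hom),
                    terminal_y = as.integer(terminal_y),
                    terminal_type = terminal_type,
                    is_target = is_tgt)
  class(out) <- c("segment_sequence", class(out))
  out
}

# Segmentation for the compact all-accessible representation
# list(length =, het = sorted positions): no per-bp vector, no missing data.
.segment_compact <- function(obs, targets, max_len) {
  L <- as.integer(obs$length)
  if (is.null(L) || L < 1) stop("compact obs needs a positive 'length'")
  het_pos <- as.integer(obs$het)
  if (is.unsorted(het_pos, strictly = TRUE)) stop("compact het positions must be sorted, unique")
  if (length(het_pos) && (het_pos[1] < 1 || het_pos[length(het_pos)] > L)) {
    stop("het positions outside [1, length]")
  }
  targets <- as.integer(targets)
  if (is.unsorted(targets, strictly = TRUE)) stop("targets must be sorted, unique")
  if (length(targets) && (targets[1] < 1 || targets[length(targets)] > L)) {
    stop("targets outside the observed interval")
  }
  cuts <- sort(unique(c(het_pos, targets)))
  bounds <- c(0L, cuts, if (length(cuts) == 0L || cuts[length(cuts)] < L) L)
  extra <- integer(0)
  gaps <- diff(bounds)
  for (k in which(gaps > max_len)) {
    extra <- c(extra, seq(bounds[k] + max_len, bounds[k + 1L] - 1L, by = max_len))
  }
  cuts2 <- sort(unique(c(cuts, extra, L)))
  obs_term <- cuts2 %in% cuts
  starts <- c(1L, cuts2[-length(cuts2)] + 1L)
  ends <- cuts2
  run_len <- ends - starts + 1L - as.integer(obs_term)
  is_het <- ends %in% het_pos
  terminal_y <- ifelse(obs_term, as.integer(is_het), NA_integer_)
  is_tgt <- ends %in% targets
  terminal_type <- ifelse(!obs_term & ends == L, "chrom-end",
                   ifelse(!obs_term, "length-cap",
                   ifelse(is_tgt, "target", "het")))
  out <- data.frame(start = starts, end = ends,
                    n_missing = 0L, n_hom = as.integer(run_len),
                    terminal_y = terminal_y, terminal_type = terminal_type,
                    is_target = is_tgt)
  class(out) <- c("segment_sequence", class(out))
  out
}

# Reverse an observation sequence (either representation).
.reverse_observations <- function(obs) {
  if (is.list(obs)) {
    list(length = obs$length,
         het = sort(obs$length + 1L - as.integer(obs$het)))
  } else {
    rev(obs)
  }
}

.obs_length <- function(obs) if (is.list(obs)) as.integer(obs$length) else length(obs)

# Core pass over segments, in log coordinates.
# record = "after_terminal": forward semantics -- the state stored at a target
#   includes the terminal base's transition and emission.
# record = "before_terminal": used by the backward pass -- the state stored at
#   a target excludes the terminal base entirely.
# Returns list(states = 2 x n_targets matrix of (l_mu, l_cv), final).
.run_pass <- function(segments, cache, grid, theta,
                      record = c("after_terminal", "before_terminal")) {
  record <- match.arg(record)
  if (abs(cache$theta - theta) > 1e-15 * theta) {
    stop("skip cache was built for a different theta")
  }
  if (!identical(cache$rho, grid$rho)) stop("cache/grid rho mismatch")
  n_tgt <- sum(segments$is_target)
  rec_mu <- numeric(n_tgt)
  rec_cv <- numeric(n_tgt)
  rec_pos <- integer(n_tgt)
  l_mu <- 0
  l_cv <- 0                      # Gamma(1, 1) prior at the chromosome start
  exact0 <- grid$rho == 0        # identity transition: exact conjugate path
  ti <- 0L
  ns <- nrow(segments)
  s_nm <- segments$n_missing
  s_nh <- segments$n_hom
  s_y <- segments$terminal_y
  s_tgt <- segments$is_target
  s_end <- segments$end
  for (k in seq_len(ns)) {
    st <- .skip_log(cache, l_mu, l_cv, s_nm[k], s_nh[k])
    l_mu <- st$l_mu
    l_cv <- st$l_cv
    y <- s_y[k]
    if (s_tgt[k] && record == "before_terminal") {
      ti <- ti + 1L
      rec_mu[ti] <- l_mu
      rec_cv[ti] <- l_cv
      rec_pos[ti] <- s_end[k]
    }
    if (!is.na(y)) {             # terminal base: transition + emission
      if (exact0) {
        st <- list(l_mu = l_mu, l_cv = l_cv)
      } else {
        st <- .flow_log(grid, l_mu, l_cv)
      }
      alpha <- 10^(-2 * st$l_cv)
      beta <- alpha / 10^st$l_mu
      alpha <- alpha + y
      beta <- beta + theta
      l_mu <- log10(alpha / beta)
      l_cv <- -0.5 * log10(alpha)
    } else if (s_tgt[k] && !exact0) {
      # target at a missing base: transition only
      st <- .flow_log(grid, l_mu, l_cv)
      l_mu <- st$l_mu
      l_cv <- st$l_cv
    }
    if (s_tgt[k] && record == "after_terminal") {
      ti <- ti + 1L
      rec_mu[ti] <- l_mu
      rec_cv[ti] <- l_cv
      rec_pos[ti] <- s_end[k]
    }
  }
  list(l_mu = rec_mu, l_cv = rec_cv, pos = rec_pos,
       final = c(l_mu, l_cv))
}

#' Forward pass over a segmented pair
#'
#' Runs the forward filter from the \eqn{\Gamma(1,1)} prior: per segment, the
#' missing run and hom run are replayed through the skip cache, then the
#' terminal base (if any) receives one flow transition and its emission. The
#' gamma approximation to the forward density is recorded at every target
#' position (including that position's own emission, when it carries one).
#'
#' @param segments a \code{segment_sequence}.
#' @param cache a \code{skip_cache} built with matching `(theta, rho)`.
#' @param grid the \code{flow_field} the cache was built from.
#' @param theta scaled mutation rate per bp.
#' @return A list: `pos` (target positions), `states` (a \code{gamma_state}
#'   with vector fields, one entry per target), `final` (the state after the
#'   last segment).
#' @export
forward_pass <- function(segments, cache, grid, theta) {
  r <- .run_pass(segments, cache, grid, theta, record = "after_terminal")
  list(pos = r$pos,
       states = log_to_state(r$l_mu, r$l_cv),
       final = log_to_state(r$final[1], r$final[2]))
}

#' Backward pass via the reversed forward pass
#'
#' The backward density at position p -- the likelihood of the observations
#' strictly after p as a function of the TMRCA at p, times the prior -- is
#' obtained by running the forward pass on the reversed sequence up to (but
#' excluding) the mirrored position, then applying one extra flow-field
#' transition to step from position p+1 back to p. With `rho = 0` this
#' reproduces the Poisson-gamma closed form on the downstream observations
#' exactly.
#'
#' @param obs per-bp observation vector (0/1/`NA`), as in
#'   [segment_observations()].
#' @param targets sorted 1-based target positions.
#' @inheritParams forward_pass
#' @param max_len maximal segment length in bp.
#' @return As [forward_pass()]: `pos` (original coordinates, ascending) and
#'   `states`.
#' @export
backward_pass <- function(obs, targets, cache, grid, theta, max_len = 10000L) {
  L <- .obs_length(obs)
  rev_obs <- .reverse_observations(obs)
  rev_targets <- sort(L + 1L - as.integer(targets))
  segs <- segment_observations(rev_obs, rev_targets, max_len = max_len)
  r <- .run_pass(segs, cache, grid, theta, record = "before_terminal")
  if (grid$rho == 0) {                       # identity transition, exactly
    st <- list(l_mu = r$l_mu, l_cv = r$l_cv)
  } else {
    st <- .flow_log(grid, r$l_mu, r$l_cv)    # the extra transition
  }
  pos <- L + 1L - r$pos
  o <- order(pos)
  list(pos = pos[o],
       states = log_to_state(st$l_mu[o], st$l_cv[o]))
}

#' Decode the posterior TMRCA track for one haplotype pair
#'
#' Runs the forward and backward passes and combines them at every target
#' position into the posterior \eqn{\Gamma(\alpha + \alpha' - 1, \beta +
#' \beta' - 1)}, reporting posterior means in coalescent units and (when
#' `Ne` is available) generations and years. Deterministic given its inputs.
#'
#' @param obs per-bp observation vector (0 = hom, 1 = het, `NA` = missing).
#' @param targets sorted 1-based positions at which to report posteriors.
#' @param params a \code{model_params}.
#' @param cache a \code{skip_cache} for `(params$theta, params$rho)`.
#' @param grid the \code{flow_field} the cache was built from.
#' @param pair optional length-2 identifier of the two haplotypes.
#' @return An object of class \code{"posterior_track"}: a data frame with
#'   columns `pos`, `fwd_alpha`, `fwd_beta`, `bwd_alpha`, `bwd_beta`,
#'   `alpha`, `beta`, `post_mean` (coalescent units) and, if `Ne` is set,
#'   `post_mean_gen`, `post_mean_years`; attributes `pair` and `params`.
#' @examples
#' ff <- build_flow_field(rho = 0)
#' sc <- build_skip_cache(ff, theta = 0.001, max_len = 50)
#' p <- model_params(theta = 0.001, rho = 0, Ne = 15000)
#' obs <- c(rep(0L, 10), 1L, rep(0L, 10))
#' decode_pair(obs, targets = 11L, p, sc, ff)
#' @export
decode_pair <- function(obs, targets, params, cache, grid, pair = c("hapA", "hapB")) {
  targets <- as.integer(targets)
  segs <- segment_observations(obs, targets, max_len = cache$max_len)
  fw <- forward_pass(segs, cache, grid, params$theta)
  bw <- backward_pass(obs, targets, cache, grid, params$theta,
                      max_len = cache$max_len)
  stopifnot(identical(fw$pos, bw$pos))
  # In the exact conjugate filter both passes have beta = 1 + theta*n >= 1,
  # so the combination is always proper. Projection and interpolation can
  # produce pass states with beta < 1 (mean above the prior at CV ~ 1); if
  # both passes do, alpha+alpha'-1 / beta+beta'-1 degenerates. At such
  # positions the product formula double-counts diffuseness beyond the
  # prior; fall back to the better-conditioned single pass (the one with
  # the larger rate parameter) instead of failing.
  fa <- fw$states$alpha
  fb <- fw$states$beta
  ba <- bw$states$alpha
  bb <- bw$states$beta
  bad <- (fa + ba - 1 <= 0) | (fb + bb - 1 <= 0)
  if (any(bad)) {
    use_f <- bad & fb >= bb
    use_b <- bad & fb < bb
    ba[use_f] <- 1
    bb[use_f] <- 1
    fa[use_b] <- 1
    fb[use_b] <- 1
  }
  post <- combine_forward_backward(gamma_state(fa, fb), gamma_state(ba, bb),
                                   position = fw$pos)
  out <- data.frame(pos = fw$pos,
                    fwd_alpha = fw$states$alpha, fwd_beta = fw$states$beta,
                    bwd_alpha = bw$states$alpha, bwd_beta = bw$states$beta,
                    alpha = post$alpha, beta = post$beta,
                    post_mean = post$alpha / post$beta)
  if (!is.null(params$Ne)) {
    conv <- to_generations(post, params)
    out$post_mean_gen <- conv$generations
    out$post_mean_years <- conv$years
  }
  structure(out, pair = pair, params = params,
            class = c("posterior_track", class(out)))
}

#' @export
print.posterior_track <- function(x, ...) {
  pr <- attr(x, "pair")
  cat(sprintf("Posterior TMRCA track for pair (%s, %s): %d positions\n",
              pr[1], pr[2], nrow(x)))
  NextMethod()
}

#' @export
summary.posterior_track <- function(object, ...) {
  cat(sprintf("Posterior TMRCA track: %d positions, pair (%s, %s)\n",
              nrow(object), attr(object, "pair")[1], attr(object, "pair")[2]))
  q <- stats::quantile(object$post_mean, c(0, .25, .5, .75, 1))
  cat("posterior mean (coalescent units):\n")
  print(signif(q, 4))
  invisible(q)
}

#' @export
plot.posterior_track <- function(x, y, units = c("coalescent", "generations", "years"),
                                 ...) {
  units <- match.arg(units)
  yy <- switch(units,
               coalescent = x$post_mean,
               generations = x$post_mean_gen,
               years = x$post_mean_years)
  lo <- stats::qgamma(0.25, x$alpha, x$beta)
  hi <- stats::qgamma(0.75, x$alpha, x$beta)
  scale <- yy / x$post_mean
  graphics::plot(x$pos, yy, type = "l", log = "y", xlab = "position (bp)",
                 ylab = paste0("posterior mean TMRCA (", units, ")"), ...)
  graphics::lines(x$pos, lo * scale, col = "grey", lty = 2)
  graphics::lines(x$pos, hi * scale, col = "grey", lty = 2)
  invisible(x)
}
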