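#' Matrix of posterior mean TMRCAs (generations) across pairs
#'
#' @param tracks list of \code{posterior_track}s decoded at common positions
#'   with `Ne` set.
#' @return A pairs x positions numeric matrix with `positions` attribute.
#' @export
track_matrix <- function(tracks) {
  if (!length(tracks)) stop("no pairs: empty track list")
  pos <- tracks[[1]]$pos
  m <- t(vapply(tracks, function(tr) {
    if (!identical(tr$pos, pos)) stop("tracks decoded at differing positions")
    if (is.null(tr$post_mean_gen)) stop("tracks lack generation-scale means (Ne unset)")
    tr$post_mean_gen
  }, numeric(length(pos))))
  attr(m, "positions") <- pos
  m
}

#' Fraction of pairs with recent coalescence
#'
#' The sweep-scan statistic: the proportion of haplotype pairs whose
#' posterior-mean TMRCA at a position is below a threshold of `T_gen`
#' generations. Recent positive selection inflates this fraction near the
#' selected site. Monotone non-decreasing in `T_gen`.
#'
#' @param tracks list of \code{posterior_track}s, or a matrix from
#'   [track_matrix()].
#' @param T_gen threshold in generations.
#' @param position one position (bp) to evaluate at, or `NULL` for all
#'   decoded positions.
#' @return A fraction in \[0, 1\] (vector if `position` is `NULL`, named by
#'   position).
#' @examples
#' # means 10k, 40k, 60k generations at one position, T = 50k -> 2/3
#' @export
recent_fraction <- function(tracks, T_gen, position = NULL) {
  m <- if (is.matrix(tracks)) tracks else track_matrix(tracks)
  pos <- attr(m, "positions")
  frac <- colMeans(m < T_gen)
  names(frac) <- pos
  if (is.null(position)) return(frac)
  k <- match(position, pos)
  if (any(is.na(k))) stop("position not among the decoded output positions")
  unname(frac[k])
}

#' Average the scan statistic over a window
#'
#' Mean of per-position fractions within `[focal - W/2, focal + W/2]`;
#' `W = 0` returns the focal value (the nearest decoded position must be the
#' focal position itself).
#'
#' @param fractions named vector from [recent_fraction()] (names are
#'   positions), or an unnamed vector with `positions` supplied.
#' @param W window size in bp (0 for no window).
#' @param focal focal position in bp.
#' @param positions positions of `fractions` (defaults to their names).
#' @return The averaged statistic.
#' @export
windowed_statistic <- function(fractions, W, focal, positions = NULL) {
  if (is.null(positions)) positions <- as.numeric(names(fractions))
  if (W < 0) stop("W must be >= 0")
  if (W == 0) {
    k <- which(positions == focal)
    if (!length(k)) stop("focal position not among decoded positions (empty window)")
    return(unname(fractions[k]))
  }
  sel <- positions >= focal - W / 2 & positions <= focal + W / 2
  if (!any(sel)) stop("empty window around the focal position")
  mean(fractions[sel])
}

#' ROC evaluation of a selection statistic
#'
#' Standard threshold-sweep ROC over scores of selected versus neutral
#' replicates, with trapezoidal AUC (via pROC).
#'
#' @param selected,neutral numeric score vectors (higher = more
#'   selection-like); each must be non-empty.
#' @return A list: `tpr`, `fpr` (threshold sweep, ascending FPR), `auc`.
#' @examples
#' evaluate_detection(c(0.9, 0.8), c(0.4, 0.1))$auc  # 1
#' @export
evaluate_detection <- function(selected, neutral) {
  if (!length(selected) || !length(neutral)) {
    stop("need at least one score in each class (selected and neutral)")
  }
  r <- pROC::roc(response = c(rep(1L, length(selected)), rep(0L, length(neutral))),
                 predictor = c(selected, neutral),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  o <- order(1 - r$specificities, r$sensitivities)
  list(tpr = r$sensitivities[o], fpr = (1 - r$specificities)[o],
       auc = as.numeric(pROC::auc(r)))
}

#' Genome-wide sweep scan from decoded posteriors
#'
#' Computes the recent-coalescence fraction at every decoded position for a
#' threshold given in years (converted via the generation time), averages it
#' in windows, and reports windows above an empirical quantile cutoff --
#' candidate sweep regions.
#'
#' @param tracks list of \code{posterior_track}s or a [track_matrix()].
#' @param params a \code{model_params} (for the years-to-generations
#'   conversion).
#' @param threshold_years recency threshold in years (default 4500).
#' @param window window size in bp (default 1e5).
#' @param top_quantile report windows above this empirical quantile of the
#'   windowed statistic (default 0.999).
#' @param chrom chromosome label for the output.
#' @return A list: `table` (data frame `pos`, `stat`, `candidate`),
#'   `regions` (BED-style data frame of merged candidate windows),
#'   `threshold_gen`.
#' @export
scan_regions <- function(tracks, params, threshold_years = 4500,
                         window = 1e5, top_quantile = 0.999, chrom = "chr1") {
  T_gen <- threshold_years / params$generation_time
  m <- if (is.matrix(tracks)) tracks else track_matrix(tracks)
  pos <- attr(m, "positions")
  frac <- recent_fraction(m, T_gen)
  stat <- if (window > 0) {
    vapply(pos, function(p) windowed_statistic(frac, window, p, positions = pos),
           numeric(1))
  } else {
    unname(frac)
  }
  cut <- stats::quantile(stat, top_quantile, names = FALSE)
  cand <- stat >= cut & stat > 0
  regions <- NULL
  if (any(cand)) {
    r <- rle(cand)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1
    keep <- which(r$values)
    regions <- data.frame(
      chrom = chrom,
      start = pmax(pos[starts_i[keep]] - window / 2, 0),
      end = pos[ends_i[keep]] + window / 2,
      stat = vapply(keep, function(k) max(stat[starts_i[k]:ends_i[k]]), numeric(1)))
  }
  list(table = data.frame(pos = pos, stat = stat, candidate = cand),
       regions = regions, threshold_gen = T_gen)
}
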