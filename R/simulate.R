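#' Simulate one haplotype pair under the SMC with known truth
#'
#' Generates a Markov TMRCA path along the genome and matching observations,
#' in run-length form. The initial TMRCA is drawn from the Exp(1) coalescent
#' prior (times scale-multiplied); along the genome, a base carries a
#' recombination breakpoint with probability \eqn{1 - e^{-\rho t}} given the
#' current TMRCA \eqn{t}, after which the new TMRCA is drawn from the SMC
#' kernel (recombination point uniform on \eqn{(0, t)}, re-coalescence at
#' rate 1, in pre-scale units, then multiplied by `scale`). A base is
#' heterozygous with probability \eqn{1 - e^{-\theta t}}. Both the
#' recombination and emission probabilities are evaluated on the output-scale
#' TMRCA, so `scale < 1` depresses breakpoint and het rates together, exactly
#' as a smaller effective population size does.
#'
#' @param length sequence length in bp, >= 1.
#' @param theta,rho scaled mutation/recombination rates per bp.
#' @param scale multiplier applied to all true TMRCAs (1 = well-specified).
#' @param seed integer seed (required: fixtures are reproducible).
#' @return An object of class \code{"simulated_pair"}: list with `length`,
#'   `segments` (data frame `start`, `end`, `tmrca` -- coalescent units,
#'   post-scale), `het` (sorted positions), `theta`, `rho`, `scale`, `seed`.
#' @examples
#' sim <- simulate_smc_pair(1e5, theta = 0.00075, rho = 0.0006, seed = 1)
#' head(sim$segments)
#' @export
simulate_smc_pair <- function(length, theta = 0.00075, rho = 0.0006,
                              scale = 1, seed) {
  L <- as.numeric(length)
  if (L < 1) stop("length must be >= 1")
  if (missing(seed)) stop("seed must be given")
  set.seed(seed)
  starts <- numeric(0)
  tmrcas <- numeric(0)
  pos <- 1
  t <- stats::rexp(1) * scale
  while (pos <= L) {
    q <- 1 - exp(-rho * t)
    n <- if (q <= 0) L - pos + 1 else stats::rgeom(1, q) + 1
    n <- min(n, L - pos + 1)
    starts <- c(starts, pos)
    tmrcas <- c(tmrcas, t)
    pos <- pos + n
    if (pos <= L) {
      s <- t / scale
      t <- (stats::runif(1, 0, s) + stats::rexp(1)) * scale
    }
  }
  ends <- c(starts[-1] - 1, L)
  # emissions per run: Binomial(run length, 1 - e^{-theta t}), positions uniform
  p_het <- 1 - exp(-theta * tmrcas)
  het <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    len_k <- ends[k] - starts[k] + 1
    nh <- stats::rbinom(1, len_k, p_het[k])
    if (nh > 0) {
      het[[k]] <- starts[k] - 1 + sample.int(len_k, nh)
    }
  }
  structure(list(length = as.integer(L),
                 segments = data.frame(start = starts, end = ends,
                                       tmrca = tmrcas),
                 het = sort(unlist(het)),
                 theta = theta, rho = rho, scale = scale, seed = seed),
            class = "simulated_pair")
}

#' @export
print.simulated_pair <- function(x, ...) {
  cat(sprintf(paste0("Simulated SMC pair: %d bp, %d TMRCA segments, %d het sites",
                     " (theta = %g, rho = %g, scale = %g)\n"),
              x$length, nrow(x$segments), length(x$het), x$theta, x$rho, x$scale))
  invisible(x)
}

#' Simulate a scale-misspecified pair
#'
#' True TMRCAs are `factor` times smaller than the unit-scale coalescent
#' prior while decoding will typically use unscaled parameters -- the
#' misspecification scenario in which a discretised decoder loses all
#' resolution but a continuous-state one does not.
#'
#' @inheritParams simulate_smc_pair
#' @param factor the misspecification factor (> 0); `factor = 100` emulates
#'   simulating at Ne/100.
#' @return A \code{simulated_pair} (identical to [simulate_smc_pair()] with
#'   `scale = 1/factor`).
#' @export
simulate_misspecified <- function(length, theta = 0.00075, rho = 0.0006,
                                  factor = 100, seed) {
  if (factor <= 0) stop("factor must be > 0")
  simulate_smc_pair(length, theta, rho, scale = 1 / factor, seed = seed)
}

#' True TMRCA of a simulated pair at given positions
#'
#' @param sim a \code{simulated_pair} (or any object with a `segments`
#'   run-length data frame).
#' @param positions 1-based positions.
#' @return Numeric vector of true TMRCAs (coalescent units).
#' @export
true_tmrca_at <- function(sim, positions) {
  seg <- sim$segments
  idx <- findInterval(positions, seg$start)
  if (any(idx < 1 | positions > sim$length)) stop("positions outside the simulated interval")
  seg$tmrca[idx]
}

#' Observations of a simulated pair in decoder form
#'
#' @param sim a \code{simulated_pair}.
#' @param compact return the compact list form (default; recommended for
#'   multi-Mb sequences) or a per-bp integer vector.
#' @return See [segment_observations()].
#' @export
pair_observations <- function(sim, compact = TRUE) {
  if (compact) return(list(length = sim$length, het = sim$het))
  obs <- integer(sim$length)
  obs[sim$het] <- 1L
  obs
}

# ---- star-genealogy sweep panel ------------------------------------------

# Kingman coalescent (optionally with a forced star clade) as a branch list.
# Returns list(branches = list of list(tips, len), pair_tmrca = n x n matrix).
# Swept tips form a star clade merging at exactly sweep_tmrca; below that
# they coalesce with nothing, and other lineages coalesce only among
# themselves. All times in coalescent units.
.sim_block_tree <- function(n, swept = integer(0), sweep_tmrca = NULL) {
  branches_tips <- vector("list", 3 * n)
  branches_len <- numeric(3 * n)
  nbr <- 0
  pair_t <- matrix(NA_real_, n, n)
  tips <- as.list(seq_len(n))   # tip set of each active lineage
  born <- rep(0, n)             # height at which each lineage formed
  h <- 0
  merge_pair <- function(i, j, at) {  # i < j are positions in `tips`
    nbr <<- nbr + 1
    branches_tips[[nbr]] <<- tips[[i]]
    branches_len[nbr] <<- at - born[i]
    nbr <<- nbr + 1
    branches_tips[[nbr]] <<- tips[[j]]
    branches_len[nbr] <<- at - born[j]
    pair_t[tips[[i]], tips[[j]]] <<- at
    pair_t[tips[[j]], tips[[i]]] <<- at
    tips[[i]] <<- c(tips[[i]], tips[[j]])
    born[i] <<- at
    tips[[j]] <<- NULL
    born <<- born[-j]
  }
  if (length(swept) >= 2) {
    repeat {
      fr <- which(!vapply(tips, function(tp) any(tp %in% swept), logical(1)))
      k <- length(fr)
      if (k < 2) break
      w <- stats::rexp(1, k * (k - 1) / 2)
      if (h + w >= sweep_tmrca) break
      h <- h + w
      pick <- sort(fr[sample.int(k, 2)])
      merge_pair(pick[1], pick[2], h)
    }
    h <- sweep_tmrca
    sw <- which(vapply(tips, function(tp) any(tp %in% swept), logical(1)))
    all_tips <- integer(0)
    for (p in sw) {
      nbr <- nbr + 1
      branches_tips[[nbr]] <- tips[[p]]
      branches_len[nbr] <- h - born[p]
      if (length(all_tips)) {
        pair_t[all_tips, tips[[p]]] <- h
        pair_t[tips[[p]], all_tips] <- h
      }
      all_tips <- c(all_tips, tips[[p]])
    }
    tips[sw] <- NULL
    born <- born[-sw]
    tips[[length(tips) + 1]] <- all_tips
    born <- c(born, h)
  }
  while (length(tips) > 1) {
    k <- length(tips)
    h <- h + stats::rexp(1, k * (k - 1) / 2)
    pick <- sort(sample.int(k, 2))
    merge_pair(pick[1], pick[2], h)
  }
  list(branches = Map(function(tp, ln) list(tips = tp, len = ln),
                      branches_tips[seq_len(nbr)], branches_len[seq_len(nbr)]),
       pair_tmrca = pair_t)
}

#' Simulate a haplotype panel with a star-like selective sweep
#'
#' A simplified sweep fixture: the genome is split into recombination blocks
#' of Exp(1/rho)-distributed length, each carrying an independent Kingman
#' coalescent genealogy (a renewal approximation across blocks). Mutations
#' are dropped on branches at rate \eqn{\theta/2} per bp per coalescent
#' unit, giving a phased 0/1 haplotype panel with consistent pairwise
#' heterozygosity. Around `sweep_pos`, carrier haplotypes form a star clade
#' that coalesces at exactly `sweep_tmrca`: carrier i stays linked to the
#' sweep out to an Exp(`sweep_halfwidth`)-distributed escape distance on
#' each side, so the swept clade shrinks with distance from the focal site.
#' With `carrier_fraction = 0` the panel is exactly the neutral panel for
#' the same seed.
#'
#' @param n_haplotypes panel size (even, so diploid VCF output is possible).
#' @param length genome length in bp.
#' @param sweep_pos focal position (default centre).
#' @param carrier_fraction fraction of haplotypes carrying the sweep, in
#'   \[0, 1\].
#' @param sweep_tmrca forced carrier coalescence time (coalescent units, < 1).
#' @param theta,rho scaled rates per bp.
#' @param sweep_halfwidth mean escape distance from the sweep centre in bp.
#' @param seed integer seed.
#' @return An object of class \code{"sweep_panel"}: list with `haplotypes`
#'   (sites x haplotypes 0/1 matrix), `site_pos`, `blocks` (data frame
#'   `start`, `end`), `truth` (blocks x pairs matrix of true TMRCAs),
#'   `pairs` (2-column index matrix), `carriers`, and the parameters.
#' @export
simulate_sweep_panel <- function(n_haplotypes, length, sweep_pos = NULL,
                                 carrier_fraction = 0, sweep_tmrca = 0.05,
                                 theta = 0.00075, rho = 0.0006,
                                 sweep_halfwidth = 2e5, seed) {
  n <- as.integer(n_haplotypes)
  L <- as.numeric(length)
  if (n < 2) stop("need at least 2 haplotypes")
  if (carrier_fraction < 0 || carrier_fraction > 1) {
    stop("carrier_fraction must be in [0, 1]")
  }
  if (!is.null(sweep_tmrca) && sweep_tmrca >= 1) {
    stop("sweep_tmrca must be < 1 (coalescent units)")
  }
  if (is.null(sweep_pos)) sweep_pos <- round(L / 2)
  set.seed(seed)
  carriers <- seq_len(round(carrier_fraction * n))
  if (length(carriers) >= 2) {
    esc_left <- stats::rexp(length(carriers), 1 / sweep_halfwidth)
    esc_right <- stats::rexp(length(carriers), 1 / sweep_halfwidth)
  }
  # recombination blocks
  brk <- cumsum(stats::rexp(ceiling(3 * L * rho) + 10, rho))
  brk <- brk[brk < L]
  starts <- c(1, floor(brk) + 1)
  starts <- unique(starts)
  ends <- c(starts[-1] - 1, L)
  nb <- length(starts)
  pair_idx <- utils::combn(n, 2)
  truth <- matrix(NA_real_, nb, ncol(pair_idx))
  sites <- list()
  genos <- list()
  for (b in seq_len(nb)) {
    centre <- (starts[b] + ends[b]) / 2
    swept <- integer(0)
    if (length(carriers) >= 2) {
      d <- centre - sweep_pos
      ok <- if (d >= 0) esc_right > d else esc_left > -d
      if (starts[b] <= sweep_pos && ends[b] >= sweep_pos) ok <- rep(TRUE, length(carriers))
      swept <- carriers[ok]
      if (length(swept) < 2) swept <- integer(0)
    }
    tree <- .sim_block_tree(n, swept, sweep_tmrca)
    truth[b, ] <- tree$pair_tmrca[cbind(pair_idx[1, ], pair_idx[2, ])]
    blen <- ends[b] - starts[b] + 1
    for (br in tree$branches) {
      nm <- stats::rpois(1, blen * (theta / 2) * br$len)
      if (nm > 0) {
        pos <- starts[b] - 1 + sample.int(blen, nm, replace = TRUE)
        for (p in pos) {
          g <- integer(n)
          g[br$tips] <- 1L
          sites[[length(sites) + 1]] <- p
          genos[[length(genos) + 1]] <- g
        }
      }
    }
  }
  site_pos <- unlist(sites)
  if (is.null(site_pos)) site_pos <- numeric(0)
  hap <- if (length(site_pos)) do.call(rbind, genos) else matrix(0L, 0, n)
  o <- order(site_pos)
  structure(list(haplotypes = hap[o, , drop = FALSE],
                 site_pos = as.integer(site_pos[o]),
                 blocks = data.frame(start = starts, end = ends),
                 truth = truth, pairs = t(pair_idx), carriers = carriers,
                 sweep_pos = sweep_pos, sweep_tmrca = sweep_tmrca,
                 theta = theta, rho = rho, length = as.integer(L),
                 seed = seed),
            class = "sweep_panel")
}

#' Pairwise observations from a sweep panel
#'
#' @param panel a \code{sweep_panel}.
#' @param i,j haplotype indices.
#' @return Compact observation list (see [segment_observations()]).
#' @export
panel_pair_observations <- function(panel, i, j) {
  diff_sites <- panel$site_pos[panel$haplotypes[, i] != panel$haplotypes[, j]]
  list(length = panel$length, het = sort(unique(diff_sites)))
}

#' Write a sweep panel as a phased VCF (plus truth TSV)
#'
#' Haplotypes 2k-1, 2k become diploid sample k with phased genotypes.
#'
#' @param panel a \code{sweep_panel}.
#' @param path output VCF path (plain text).
#' @param truth_path optional path for the per-block pairwise truth table.
#' @param chrom chromosome name.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path, truth_path = NULL, chrom = "chr1") {
  n <- ncol(panel$haplotypes)
  if (n %% 2 != 0) stop("need an even number of haplotypes for diploid VCF output")
  ns <- n / 2
  snames <- sprintf("ind%03d", seq_len(ns))
  con <- file(path, "w")
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", chrom, panel$length),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", snames), collapse = "\t")), con)
  if (length(panel$site_pos)) {
    gt <- vapply(seq_len(ns), function(k) {
      paste0(panel$haplotypes[, 2 * k - 1], "|", panel$haplotypes[, 2 * k])
    }, character(length(panel$site_pos)))
    gt <- matrix(gt, ncol = ns)
    rows <- paste(chrom, panel$site_pos, ".", "A", "T", ".", "PASS", ".", "GT",
                  apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(rows, con)
  }
  close(con)
  if (!is.null(truth_path)) {
    tt <- data.frame(start = panel$blocks$start, end = panel$blocks$end)
    cn <- apply(panel$pairs, 1, paste, collapse = "_")
    tr <- as.data.frame(panel$truth)
    names(tr) <- paste0("tmrca_", cn)
    utils::write.table(cbind(tt, tr), truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

# ---- msprime adapter ------------------------------------------------------

#' Simulate a diploid with msprime (external Python) and return truth + hets
#'
#' Runs the bundled Python script (msprime/tskit must be available on the
#' calling `python`) to simulate a two-haplotype sample under either a
#' constant-size coalescent or the three-population out-of-Africa model
#' (Gutenkunst et al. 2009 parameterisation), with mutations, and returns
#' the true TMRCA path (in generations) and heterozygous-site positions.
#' Used as the independent simulation oracle for decoder benchmarking.
#'
#' @param length sequence length in bp.
#' @param Ne effective population size (constant model only).
#' @param mu,recomb unscaled per-bp per-generation rates.
#' @param model `"constant"` or `"ooa_ceu"` (one CEU diploid).
#' @param seed integer seed passed to msprime.
#' @param python python executable (default `"python"`).
#' @return A list: `length`, `segments` (data frame `start`, `end`,
#'   `tmrca_gen` in generations), `het` (sorted 1-based positions), plus the
#'   call parameters.
#' @export
simulate_msprime_pair <- function(length, Ne = 15000, mu = 1.25e-8,
                                  recomb = 1e-8,
                                  model = c("constant", "ooa_ceu"),
                                  seed, python = "python") {
  model <- match.arg(model)
  if (missing(seed)) stop("seed must be given")
  script <- system.file("python", "coalsim.py", package = "gammasmc")
  if (script == "") stop("bundled python script not found")
  out_prefix <- tempfile("coalsim_")
  status <- system2(python,
                    c(shQuote(script), "--model", model,
                      "--length", format(length, scientific = FALSE),
                      "--ne", format(Ne, scientific = FALSE),
                      "--mu", format(mu), "--recomb", format(recomb),
                      "--seed", format(seed, scientific = FALSE),
                      "--out-prefix", shQuote(out_prefix)),
                    stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status"))) {
    stop("msprime simulation failed:\n", paste(status, collapse = "\n"))
  }
  truth <- utils::read.table(paste0(out_prefix, "_truth.tsv"), header = TRUE,
                             sep = "\t")
  hets_file <- paste0(out_prefix, "_hets.txt")
  het <- if (file.size(hets_file) > 0) {
    sort(unique(as.integer(readLines(hets_file))))
  } else {
    integer(0)
  }
  unlink(paste0(out_prefix, c("_truth.tsv", "_hets.txt")))
  list(length = as.integer(length),
       segments = data.frame(start = truth$start, end = truth$end,
                             tmrca_gen = truth$tmrca_gen),
       het = het, model = model, Ne = Ne, mu = mu, recomb = recomb,
       seed = seed)
}
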