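#' Read a BED accessibility mask
#'
#' BED intervals are 0-based half-open; internally masks are kept as 1-based
#' inclusive integer intervals. Alleles outside the mask are treated as
#' missing for the sample the mask belongs to.
#'
#' @param path BED file (3+ columns, optionally with track/browser lines).
#' @param chrom optional chromosome to filter on (column 1).
#' @return A two-column integer matrix `cbind(start, end)`, 1-based inclusive.
#' @export
read_mask_bed <- function(path, chrom = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (!length(lines)) return(cbind(start = integer(0), end = integer(0)))
  f <- strsplit(lines, "\t| +")
  ch <- vapply(f, `[[`, "", 1L)
  s <- as.integer(vapply(f, `[[`, "", 2L))
  e <- as.integer(vapply(f, `[[`, "", 3L))
  if (!is.null(chrom)) {
    keep <- ch == chrom
    s <- s[keep]
    e <- e[keep]
  }
  cbind(start = s + 1L, end = e)
}

# logical accessibility vector of length L from a 1-based inclusive mask
.mask_to_logical <- function(mask, L) {
  acc <- logical(L)
  if (is.null(mask)) return(rep(TRUE, L))
  for (k in seq_len(nrow(mask))) {
    a <- max(mask[k, 1], 1L)
    b <- min(mask[k, 2], L)
    if (a <= b) acc[a:b] <- TRUE
  }
  acc
}

#' Build the per-bp observation sequence for one haplotype pair
#'
#' Compares two phased haplotypes from a VCF over a region: a base is
#' missing outside the intersection of the two haplotypes' accessibility
#' masks (or where a genotype is missing), heterozygous where the two
#' alleles differ at a biallelic SNP, and homozygous elsewhere (non-variant
#' accessible positions are hom). Multiallelic records and indels are
#' treated as missing, as are records whose FILTER is not PASS/"." (by
#' default). Cross-individual pairs require phased genotypes.
#'
#' @param vcf a \code{vcfR} object or path to a VCF file.
#' @param region_length length L of the analysed interval in bp; VCF
#'   positions must lie in `[1, L]`.
#' @param hapA,hapB haplotype identifiers `"sample|1"` or `"sample|2"`
#'   naming a VCF sample column and which phased allele to take.
#' @param maskA,maskB optional masks from [read_mask_bed()] (either may be a
#'   shared global mask).
#' @param require_pass treat non-PASS records as missing sites (default
#'   `TRUE`).
#' @return Integer vector of length `region_length`: 0 hom, 1 het, `NA`
#'   missing. A VCF record at 1-based position p maps to index p.
#' @export
read_pair_observations <- function(vcf, region_length, hapA, hapB,
                                   maskA = NULL, maskB = NULL,
                                   require_pass = TRUE) {
  if (is.character(vcf)) vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  L <- as.integer(region_length)
  acc <- .mask_to_logical(maskA, L) & .mask_to_logical(maskB, L)
  obs <- ifelse(acc, 0L, NA_integer_)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) {      # single-record VCFs come back as a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  gt <- vcfR::extract.gt(vcf)
  if (is.null(dim(gt))) {
    gt <- matrix(gt, nrow = nrow(fix), dimnames = list(NULL, names(gt)))
  }
  parse_hap <- function(h) {
    m <- regmatches(h, regexec("^(.*)\\|([12])$", h))[[1]]
    if (length(m) != 3) stop("haplotype id must look like 'sample|1' or 'sample|2'")
    list(sample = m[2], allele = as.integer(m[3]))
  }
  ha <- parse_hap(hapA)
  hb <- parse_hap(hapB)
  cross <- ha$sample != hb$sample
  pos <- as.integer(fix[, "POS"])
  if (any(pos < 1 | pos > L)) stop("VCF positions outside [1, region_length]")
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  filt <- fix[, "FILTER"]
  biallelic_snp <- nchar(ref) == 1 & nchar(alt) == 1 & !grepl(",", alt) &
    ref != "." & alt != "."
  pass <- if (require_pass) (is.na(filt) | filt %in% c("PASS", ".")) else TRUE
  allele_of <- function(sample, which_allele) {
    g <- gt[, sample]
    sep <- substr(g, 2, 2)
    if (cross && any(sep == "/" & !is.na(g))) {
      stop("unphased genotypes: cross-individual pairs require phased data")
    }
    as.integer(substr(g, if (which_allele == 1) 1 else 3,
                      if (which_allele == 1) 1 else 3))
  }
  aA <- suppressWarnings(allele_of(ha$sample, ha$allele))
  aB <- suppressWarnings(allele_of(hb$sample, hb$allele))
  usable <- biallelic_snp & pass & !is.na(aA) & !is.na(aB)
  # unusable records: site becomes missing
  obs[pos[!usable]] <- NA_integer_
  ok <- usable & !is.na(obs[pos])
  obs[pos[ok]] <- as.integer(aA[ok] != aB[ok])
  obs
}

#' Enumerate haplotype pairs
#'
#' @param samples character vector of sample names.
#' @param mode `"all"` for all unordered pairs of the `2n` haplotypes,
#'   `"within-diploid"` for the n within-individual pairs only.
#' @return A two-column character matrix of haplotype ids (`"sample|1"`
#'   etc.); `2n` haplotypes give `n(2n-1)` ... i.e. `choose(2n, 2)` rows in
#'   `"all"` mode (300 haplotypes -> 44850 pairs).
#' @export
haplotype_pairs <- function(samples, mode = c("all", "within-diploid")) {
  mode <- match.arg(mode)
  haps <- as.vector(t(outer(samples, 1:2, function(s, a) paste0(s, "|", a))))
  if (mode == "within-diploid") {
    return(cbind(paste0(samples, "|1"), paste0(samples, "|2")))
  }
  idx <- utils::combn(length(haps), 2)
  cbind(haps[idx[1, ]], haps[idx[2, ]])
}

#' Estimate the scaled mutation rate from average heterozygosity
#'
#' When `theta` is not supplied it is estimated as the mean over pairs of
#' (het count / unmasked length) -- pairwise heterozygosity per accessible
#' base pair.
#'
#' @param obs_list list of per-bp observation vectors (0/1/`NA`), one per
#'   pair.
#' @return The estimate of `theta` (per bp).
#' @examples
#' estimate_theta(list(c(rep(0L, 997), 1L, 1L, 1L)))  # 0.003
#' @export
estimate_theta <- function(obs_list) {
  rates <- vapply(obs_list, function(o) {
    n <- sum(!is.na(o))
    if (n == 0) return(NA_real_)
    sum(o, na.rm = TRUE) / n
  }, numeric(1))
  if (all(is.na(rates))) stop("no pair has unmasked bases; cannot estimate theta")
  mean(rates, na.rm = TRUE)
}

#' Write and read posterior tracks
#'
#' Two sinks: a TSV with one row per (pair, position) and a binary matrix of
#' `(alpha, beta)` values preceded by a JSON header (positions, pair list,
#' parameters, format version). The binary round trip is lossless. Writes go
#' through a temp file renamed into place.
#'
#' @param tracks list of \code{posterior_track}s (may be empty).
#' @param path output path (`.tsv` for the text sink).
#' @param format `"binary"` or `"tsv"`.
#' @param chrom chromosome label for the TSV.
#' @return The path, invisibly.
#' @export
write_posteriors <- function(tracks, path, format = c("binary", "tsv"),
                             chrom = "chr1") {
  format <- match.arg(format)
  tmp <- paste0(path, ".tmp")
  if (format == "tsv") {
    rows <- lapply(tracks, function(tr) {
      pr <- attr(tr, "pair")
      data.frame(chrom = chrom, pos = tr$pos, hapA = pr[1], hapB = pr[2],
                 alpha = tr$alpha, beta = tr$beta,
                 post_mean_generations = if (!is.null(tr$post_mean_gen))
                   tr$post_mean_gen else NA_real_,
                 post_mean_years = if (!is.null(tr$post_mean_years))
                   tr$post_mean_years else NA_real_)
    })
    tab <- do.call(rbind, c(rows, make.row.names = FALSE))
    if (is.null(tab)) {
      tab <- data.frame(chrom = character(0), pos = integer(0),
                        hapA = character(0), hapB = character(0),
                        alpha = numeric(0), beta = numeric(0),
                        post_mean_generations = numeric(0),
                        post_mean_years = numeric(0))
    } else {
      tab <- tab[order(tab$hapA, tab$hapB, tab$pos), , drop = FALSE]
    }
    utils::write.table(tab, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    file.rename(tmp, path)
    return(invisible(path))
  }
  pairs <- lapply(tracks, attr, "pair")
  positions <- if (length(tracks)) tracks[[1]]$pos else integer(0)
  params <- if (length(tracks)) attr(tracks[[1]], "params") else NULL
  header <- jsonlite::toJSON(list(
    format = "gammasmc-posteriors", version = 1L,
    n_pairs = length(tracks), n_positions = length(positions),
    positions = positions,
    pairs = pairs,
    theta = params$theta, rho = params$rho, Ne = params$Ne,
    generation_time = params$generation_time
  ), auto_unbox = TRUE, digits = NA)
  con <- file(tmp, "wb")
  hb <- charToRaw(as.character(header))
  writeBin(length(hb), con, size = 8L, endian = "little")
  writeBin(hb, con)
  for (tr in tracks) {
    writeBin(as.numeric(rbind(tr$alpha, tr$beta)), con, size = 8L,
             endian = "little")
  }
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname write_posteriors
#' @export
read_posteriors <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  n <- readBin(con, "integer", size = 8L, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n)))
  if (!identical(header$format, "gammasmc-posteriors")) {
    stop("not a gammasmc posterior file")
  }
  npos <- header$n_positions
  tracks <- vector("list", header$n_pairs)
  for (k in seq_len(header$n_pairs)) {
    v <- readBin(con, "numeric", 2 * npos, size = 8L, endian = "little")
    m <- matrix(v, nrow = 2)
    tr <- data.frame(pos = header$positions, alpha = m[1, ], beta = m[2, ],
                     post_mean = m[1, ] / m[2, ])
    pair <- if (is.matrix(header$pairs)) header$pairs[k, ] else header$pairs[[k]]
    attr(tr, "pair") <- pair
    class(tr) <- c("posterior_track", class(tr))
    tracks[[k]] <- tr
  }
  list(header = header, tracks = tracks)
}

#' Decode every requested haplotype pair of a VCF
#'
#' High-level driver: reads the VCF (and optional masks), enumerates pairs,
#' estimates `theta` from average pairwise heterozygosity if absent, builds
#' or reuses the flow field and skip cache, and decodes each pair at het
#' sites and/or an even grid of output positions.
#'
#' @param vcf path to a VCF or a \code{vcfR} object.
#' @param region_length analysed interval length in bp.
#' @param params a \code{model_params}; if its theta is `NA`/missing use
#'   `theta = NULL` and it is estimated from the data.
#' @param theta,rho,rho_over_theta,Ne,generation_time convenience scalars
#'   used when `params` is `NULL`.
#' @param pair_mode `"all"` or `"within-diploid"`.
#' @param output `"grid"`, `"het"`, or `"both"`.
#' @param grid_spacing spacing of the even output grid in bp (default 1000).
#' @param masks optional: a single mask matrix applied to all samples, or a
#'   named list of per-sample masks from [read_mask_bed()].
#' @param max_len segment/cache cap in bp (default 10000).
#' @param cache optionally a prebuilt \code{skip_cache}; `grid` its
#'   \code{flow_field}.
#' @param grid prebuilt \code{flow_field} (optional).
#' @return An object of class \code{"gamma_smc_fit"}: list with `tracks`
#'   (one \code{posterior_track} per pair), `params`, `pairs`.
#' @export
decode_vcf <- function(vcf, region_length, params = NULL, theta = NULL,
                       rho = NULL, rho_over_theta = NULL, Ne = 15000,
                       generation_time = 30,
                       pair_mode = c("all", "within-diploid"),
                       output = c("grid", "het", "both"),
                       grid_spacing = 1000L, masks = NULL, max_len = 10000L,
                       cache = NULL, grid = NULL) {
  pair_mode <- match.arg(pair_mode)
  output <- match.arg(output)
  if (grid_spacing < 1) stop("grid_spacing must be >= 1")
  if (is.character(vcf)) vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  pairs <- haplotype_pairs(samples, pair_mode)
  mask_of <- function(hap) {
    if (is.null(masks)) return(NULL)
    if (is.matrix(masks)) return(masks)
    masks[[sub("\\|[12]$", "", hap)]]
  }
  obs_list <- lapply(seq_len(nrow(pairs)), function(k) {
    read_pair_observations(vcf, region_length, pairs[k, 1], pairs[k, 2],
                           maskA = mask_of(pairs[k, 1]),
                           maskB = mask_of(pairs[k, 2]))
  })
  if (is.null(params)) {
    if (is.null(theta)) theta <- estimate_theta(obs_list)
    params <- model_params(theta = theta, rho = rho,
                           rho_over_theta = rho_over_theta, Ne = Ne,
                           generation_time = generation_time)
  }
  if (is.null(grid)) grid <- build_flow_field(params$rho)
  if (is.null(cache)) {
    cache <- build_skip_cache(grid, params$theta, max_len = max_len)
  }
  grid_targets <- seq(grid_spacing, region_length, by = grid_spacing)
  tracks <- lapply(seq_len(nrow(pairs)), function(k) {
    obs <- obs_list[[k]]
    targets <- switch(output,
      grid = grid_targets,
      het = which(!is.na(obs) & obs == 1L),
      both = sort(unique(c(grid_targets, which(!is.na(obs) & obs == 1L)))))
    decode_pair(obs, targets, params, cache, grid, pair = pairs[k, ])
  })
  structure(list(tracks = tracks, params = params, pairs = pairs),
            class = "gamma_smc_fit")
}

#' @export
print.gamma_smc_fit <- function(x, ...) {
  cat(sprintf("Gamma-SMC decoding of %d haplotype pair(s)\n", length(x$tracks)))
  print(x$params)
  invisible(x)
}
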