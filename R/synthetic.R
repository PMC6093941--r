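#' Simulate a Hi-C-like contact matrix with planted domains
#'
#' Generates the statistical structure the caller exploits, and nothing
#' more: independent Poisson counts for each bin pair, with a power-law
#' distance decay `(1 + |i - j|)^-decay`, a multiplicative enrichment for
#' pairs inside the same planted domain (compounded for pairs inside the
#' same sub-domain when a second level is planted), symmetrized by
#' construction.  Reproducible given a seed.
#'
#' @param n_bins number of bins.
#' @param boundaries integer vector of 0-based domain start bins; must begin
#'   at 0 and increase; domains tile `[0, n_bins)`.
#' @param background base Poisson rate at distance 0 (counts per pair).
#' @param decay power-law decay exponent (> 0).
#' @param enrichment intra-domain rate multiplier (>= 1).
#' @param sub_boundaries optional second level: 0-based start bins of
#'   sub-domains, refining `boundaries` (every domain start must reappear).
#' @param sub_enrichment extra multiplier for intra-sub-domain pairs.
#' @param max_distance optional band width: pairs farther apart than this
#'   many bins get zero rate (keeps large matrices sparse).
#' @param binsize,chrom genomic metadata for the resulting matrix.
#' @param seed RNG seed (`NULL` = use the current RNG state).
#' @return list with `matrix` (a [contact_matrix]), `truth` (a [domain_set]
#'   of the planted domains) and, with a second level, `truth_sub`.
#' @examples
#' sim <- simulate_hic(30, c(0, 10, 20), background = 20, seed = 1)
#' sim$truth$domains
#' @export
simulate_hic <- function(n_bins, boundaries, background = 20, decay = 1,
                         enrichment = 6, sub_boundaries = NULL,
                         sub_enrichment = enrichment, max_distance = NULL,
                         binsize = 40000L, chrom = "chrS", seed = NULL) {
  n_bins <- as.integer(n_bins)
  boundaries <- sort(as.integer(boundaries))
  if (!length(boundaries) || boundaries[1] != 0L || any(boundaries >= n_bins) ||
      anyDuplicated(boundaries))
    stop("'boundaries' must be increasing 0-based starts beginning at 0, < n_bins",
         call. = FALSE)
  if (background <= 0 || decay <= 0 || enrichment < 1)
    stop("need background > 0, decay > 0, enrichment >= 1", call. = FALSE)
  dom_of <- function(bins0, starts) findInterval(bins0, starts)
  if (!is.null(sub_boundaries)) {
    sub_boundaries <- sort(as.integer(sub_boundaries))
    if (!all(boundaries %in% sub_boundaries))
      stop("'sub_boundaries' must refine 'boundaries'", call. = FALSE)
  }
  maxd <- if (is.null(max_distance)) n_bins else as.integer(max_distance)
  # pairs i <= j within the band, built diagonal by diagonal
  i <- j <- integer(0)
  for (d in 0:min(maxd, n_bins - 1L)) {
    i <- c(i, seq_len(n_bins - d))
    j <- c(j, seq_len(n_bins - d) + d)
  }
  rate <- background * (1 + (j - i))^(-decay)
  di <- dom_of(i - 1L, boundaries); dj <- dom_of(j - 1L, boundaries)
  fold <- ifelse(di == dj, enrichment, 1)
  if (!is.null(sub_boundaries)) {
    si <- dom_of(i - 1L, sub_boundaries); sj <- dom_of(j - 1L, sub_boundaries)
    fold <- fold * ifelse(si == sj, sub_enrichment, 1)
  }
  counts <- with_seed(seed, rpois(length(rate), rate * fold))
  nz <- counts > 0
  mat <- Matrix::sparseMatrix(i = i[nz], j = j[nz], x = as.numeric(counts[nz]),
                              dims = c(n_bins, n_bins))
  cm <- contact_matrix(mat, chrom = chrom, binsize = binsize)
  ends <- c(boundaries[-1] - 1L, n_bins - 1L)
  truth <- domain_set(data.frame(start_bin = boundaries, end_bin = ends),
                      chrom = chrom, binsize = binsize, mode = "truth")
  out <- list(matrix = cm, truth = truth)
  if (!is.null(sub_boundaries)) {
    sends <- c(sub_boundaries[-1] - 1L, n_bins - 1L)
    out$truth_sub <- domain_set(
      data.frame(start_bin = sub_boundaries, end_bin = sends),
      chrom = chrom, binsize = binsize, mode = "truth")
  }
  out
}

#' Convert a contact matrix to contact-pair records
#'
#' Expands matrix entries into `chrom pos1 pos2 count` records at bin
#' midpoints (1-based), the input format of the binsize scanner.  Re-binning
#' the result at the original binsize recovers the matrix.
#'
#' @param cm a [contact_matrix].
#' @return a data.frame with columns `chrom`, `pos1`, `pos2`, `count`.
#' @export
matrix_to_pairs <- function(cm) {
  stopifnot(inherits(cm, "contact_matrix"))
  tri <- as(Matrix::triu(cm$mat), "TsparseMatrix")
  mid <- function(b0) b0 * cm$binsize + cm$binsize %/% 2 + 1L
  data.frame(chrom = cm$chrom, pos1 = mid(tri@i), pos2 = mid(tri@j),
             count = tri@x)
}

#' Binomial thinning of a contact matrix
#'
#' Keeps each contact unit independently with the given probability,
#' emulating random read down-sampling.  Requires integer counts.
#'
#' @param cm a [contact_matrix] with integer weights.
#' @param fraction retention probability in `(0, 1]`.
#' @param seed RNG seed (`NULL` = current RNG state).
#' @return a [contact_matrix] with thinned counts.
#' @export
downsample_matrix <- function(cm, fraction, seed = NULL) {
  stopifnot(inherits(cm, "contact_matrix"))
  if (fraction <= 0 || fraction > 1)
    stop("'fraction' must be in (0, 1]", call. = FALSE)
  tri <- as(Matrix::triu(cm$mat), "TsparseMatrix")
  if (any(tri@x != floor(tri@x)))
    stop("thinning requires integer counts", call. = FALSE)
  if (fraction == 1) return(cm)
  kept <- with_seed(seed, rbinom(length(tri@x), size = as.integer(tri@x),
                                 prob = fraction))
  nz <- kept > 0
  mat <- Matrix::sparseMatrix(i = tri@i[nz] + 1L, j = tri@j[nz] + 1L,
                              x = as.numeric(kept[nz]),
                              dims = dim(cm$mat))
  contact_matrix(mat, chrom = cm$chrom, binsize = cm$binsize)
}
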