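#' Contact matrices
#'
#' A `contact_matrix` is a symmetric, non-negative bin-by-bin matrix of Hi-C
#' contact counts for one chromosome, together with its genomic metadata
#' (chromosome name, binsize in bp, number of bins).  Bin indices are 0-based
#' internally.  No normalization is ever applied: downstream entropy
#' computations operate on raw counts by design.
#'
#' @param mat a square numeric matrix or `Matrix` sparse matrix of
#'   non-negative weights; it is symmetrized by taking entry-wise maxima of
#'   the two triangles, so either triangular or full storage is accepted.
#' @param chrom chromosome name.
#' @param binsize bin width in base pairs (positive integer).
#' @return an object of class `contact_matrix` with fields `mat` (a
#'   `dgCMatrix`), `chrom`, `binsize`, `n_bins`.
#' @examples
#' m <- contact_matrix(matrix(c(0, 4, 4, 0), 2), "chrT", 40000L)
#' m$n_bins
#' @export
contact_matrix <- function(mat, chrom = "chr1", binsize = 1L) {
  if (!is(mat, "Matrix")) mat <- as(as.matrix(mat), "CsparseMatrix")
  mat <- as(mat, "generalMatrix")
  if (nrow(mat) != ncol(mat))
    stop("contact matrix must be square", call. = FALSE)
  if (length(mat@x) && min(mat@x) < 0)
    stop("contact matrix has negative weights", call. = FALSE)
  if (length(mat@x) && any(!is.finite(mat@x)))
    stop("contact matrix has non-finite weights", call. = FALSE)
  binsize <- as.integer(binsize)
  if (is.na(binsize) || binsize <= 0)
    stop("'binsize' must be a positive integer", call. = FALSE)
  # symmetrize: mirror whichever triangle carries each entry
  mat <- pmax(mat, Matrix::t(mat))
  mat <- as(Matrix::drop0(mat), "CsparseMatrix")
  mat <- as(mat, "generalMatrix")
  structure(
    list(mat = mat, chrom = as.character(chrom), binsize = binsize,
         n_bins = nrow(mat)),
    class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %s, %d bins @ %d bp, total weight %.6g\n",
              x$chrom, x$n_bins, x$binsize, total_weight(x)))
  invisible(x)
}

#' Total weight of a contact matrix
#'
#' Sum of all distinct contacts: each off-diagonal pair counted once plus the
#' diagonal.
#' @param cm a `contact_matrix`.
#' @return a number.
#' @export
total_weight <- function(cm) {
  stopifnot(inherits(cm, "contact_matrix"))
  m <- cm$mat
  (sum(m) + sum(Matrix::diag(m))) / 2
}

#' Read a Hi-C contact matrix from text
#'
#' Supports the two plain-text dialects in common circulation: sparse triplet
#' lines `i j weight` (0-based bin indices, triangular or full storage) and
#' header-free dense whitespace-delimited square matrices.  The result is
#' always symmetrized, so reading is idempotent.
#'
#' @param path file path.
#' @param dialect `"triplet"` or `"dense"`.
#' @param binsize bin width in bp.
#' @param chrom chromosome name to attach.
#' @param n_bins optional; forces the bin count (triplet dialect only), e.g.
#'   when trailing bins have no contacts.
#' @param skip_label_col dense dialect: drop a leading row-label column.
#' @return a [contact_matrix].
#' @export
read_contact_matrix <- function(path, dialect = c("triplet", "dense"),
                                binsize = 1L, chrom = "chr1",
                                n_bins = NULL, skip_label_col = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (dialect == "triplet") {
    lines <- readLines(path)
    keep <- nzchar(trimws(lines))
    toks <- strsplit(trimws(lines[keep]), "[ \t]+")
    lineno <- which(keep)
    i <- j <- w <- numeric(length(toks))
    for (k in seq_along(toks)) {
      t <- toks[[k]]
      if (length(t) != 3L)
        stop_parse(path, lineno[k], sprintf("expected 3 fields, got %d", length(t)))
      v <- suppressWarnings(as.numeric(t))
      if (any(is.na(v)))
        stop_parse(path, lineno[k], sprintf("non-numeric token '%s'", t[which(is.na(v))[1]]))
      if (v[1] < 0 || v[2] < 0 || v[1] != floor(v[1]) || v[2] != floor(v[2]))
        stop_parse(path, lineno[k], "bin indices must be non-negative integers")
      if (v[3] < 0)
        stop_parse(path, lineno[k], sprintf("negative weight %g", v[3]))
      i[k] <- v[1]; j[k] <- v[2]; w[k] <- v[3]
    }
    n <- if (is.null(n_bins)) (if (length(i)) max(i, j) + 1 else 0L) else as.integer(n_bins)
    mat <- Matrix::sparseMatrix(i = i + 1, j = j + 1, x = w, dims = c(n, n))
  } else {
    dat <- tryCatch(read.table(path, header = FALSE),
                    error = function(e) stop(sprintf("%s: %s", path, conditionMessage(e)),
                                             call. = FALSE))
    if (skip_label_col) dat <- dat[, -1, drop = FALSE]
    if (!all(vapply(dat, is.numeric, logical(1))))
      stop(sprintf("%s: dense matrix contains non-numeric entries", path), call. = FALSE)
    if (nrow(dat) != ncol(dat))
      stop(sprintf("%s: dense matrix is not square (%d x %d)", path,
                   nrow(dat), ncol(dat)), call. = FALSE)
    mat <- as.matrix(dat)
    dimnames(mat) <- NULL
  }
  contact_matrix(mat, chrom = chrom, binsize = binsize)
}

#' Read contact pairs from text
#'
#' Parses raw contact-pair records `chrom pos1 pos2 [count]` (1-based genomic
#' coordinates) into a data frame suitable for [bin_contact_pairs()].
#'
#' @param path file path.
#' @return a data.frame with columns `chrom`, `pos1`, `pos2`, `count`.
#' @export
read_contact_pairs <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  dat <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(dat) == 3L) dat$V4 <- 1L
  if (ncol(dat) != 4L)
    stop(sprintf("%s: expected 3 or 4 columns", path), call. = FALSE)
  names(dat) <- c("chrom", "pos1", "pos2", "count")
  if (any(dat$pos1 < 1 | dat$pos2 < 1))
    stop(sprintf("%s: positions must be >= 1", path), call. = FALSE)
  if (any(dat$count < 1 | dat$count != floor(dat$count)))
    stop(sprintf("%s: counts must be positive integers", path), call. = FALSE)
  dat
}

#' Bin raw contact pairs into a contact matrix
#'
#' Positions are 1-based; bin index of a position is
#' `floor((pos - 1) / binsize)`.  Counts accumulate symmetrically, so the
#' total weight of the result equals the total input count exactly.
#'
#' @param pairs a data.frame with columns `pos1`, `pos2` and optionally
#'   `count` (default 1) and `chrom` (must be a single chromosome).
#' @param binsize bin width in bp.
#' @param chrom_length chromosome length in bp; `n_bins = ceiling(length / binsize)`.
#' @param chrom chromosome name (defaults to the pairs' chromosome).
#' @return a [contact_matrix].
#' @export
bin_contact_pairs <- function(pairs, binsize, chrom_length, chrom = NULL) {
  binsize <- as.integer(binsize)
  if (is.na(binsize) || binsize <= 0) stop("'binsize' must be positive", call. = FALSE)
  if (!is.null(pairs$chrom)) {
    u <- unique(pairs$chrom)
    if (length(u) > 1)
      stop("pairs span multiple chromosomes; bin one chromosome at a time", call. = FALSE)
    if (is.null(chrom) && length(u)) chrom <- u
  }
  if (is.null(chrom)) chrom <- "chr1"
  if (is.null(pairs$count)) pairs$count <- 1L
  if (nrow(pairs) && any(pairs$pos1 < 1 | pairs$pos2 < 1))
    stop("positions must be >= 1", call. = FALSE)
  if (nrow(pairs) && any(pairs$pos1 > chrom_length | pairs$pos2 > chrom_length))
    stop("position exceeds chromosome length", call. = FALSE)
  n <- as.integer(ceiling(chrom_length / binsize))
  if (n < 1) stop("chromosome shorter than one bin", call. = FALSE)
  if (!nrow(pairs)) {
    mat <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n))
    return(contact_matrix(mat, chrom = chrom, binsize = binsize))
  }
  bi <- (pairs$pos1 - 1) %/% binsize
  bj <- (pairs$pos2 - 1) %/% binsize
  lo <- pmin(bi, bj); hi <- pmax(bi, bj)
  mat <- Matrix::sparseMatrix(i = lo + 1, j = hi + 1, x = as.numeric(pairs$count),
                              dims = c(n, n))
  contact_matrix(mat, chrom = chrom, binsize = binsize)
}
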