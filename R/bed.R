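#' Write domain calls as BED3
#'
#' Domains are written 0-based half-open: `start = start_bin * binsize`,
#' `end = (end_bin + 1) * binsize`, optionally clipped to the chromosome
#' length.  Domains must be sorted and non-overlapping (enforced by
#' [domain_set()]).
#'
#' @param domains a [domain_set].
#' @param path output file.
#' @param chrom_length optional chromosome length in bp for clipping the
#'   last domain.
#' @return `path`, invisibly.
#' @export
write_domains_bed <- function(domains, path, chrom_length = NULL) {
  stopifnot(inherits(domains, "domain_set"))
  d <- domains$domains
  if (!nrow(d)) {
    file.create(path)
    return(invisible(path))
  }
  start <- d$start_bp
  end <- d$end_bp
  if (!is.null(chrom_length)) end <- pmin(end, chrom_length)
  writeLines(sprintf("%s\t%.0f\t%.0f", domains$chrom, start, end), path)
  invisible(path)
}

#' Read a BED3 file back into a domain set
#'
#' Inverse of [write_domains_bed()] for unclipped output: bin indices are
#' recovered as `start / binsize` and `end / binsize - 1` (the end rounded
#' up to a bin edge first, so clipped last domains load too).
#'
#' @param path BED3 file.
#' @param binsize bin width in bp.
#' @param mode provenance label for the resulting [domain_set].
#' @return a [domain_set].
#' @export
read_domains_bed <- function(path, binsize, mode = "bed") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (file.size(path) == 0)
    return(domain_set(data.frame(start_bin = integer(0), end_bin = integer(0)),
                      binsize = binsize, mode = mode))
  dat <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(dat) < 3) stop(sprintf("%s: not BED3", path), call. = FALSE)
  chrom <- unique(dat[[1]])
  if (length(chrom) > 1)
    stop(sprintf("%s: multiple chromosomes in one domain set", path), call. = FALSE)
  start_bin <- dat[[2]] %/% binsize
  end_bin <- (dat[[3]] + binsize - 1L) %/% binsize - 1L
  domain_set(data.frame(start_bin = start_bin, end_bin = end_bin),
             chrom = chrom, binsize = binsize, mode = mode)
}
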