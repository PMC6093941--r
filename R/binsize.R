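#' Normalized structural entropies of a contact matrix
#'
#' `nse1` is the one-dimensional structural entropy divided by its maximum
#' `log2(n_bins)`; `nse2` is the minimized height-2 entropy (as approximated
#' by the greedy caller) divided by the one-dimensional entropy.  Both are
#' normalizations that make entropies comparable across binsizes with
#' different bin counts; both lie in `(0, 1]`.
#'
#' @param cm a [contact_matrix] with at least two bins and positive total
#'   weight.
#' @param contiguity forwarded to [dedoc2()] (`nse2` only).
#' @return a value in `(0, 1]`.
#' @export
nse1 <- function(cm) {
  stopifnot(inherits(cm, "contact_matrix"))
  if (cm$n_bins < 2) stop("need at least 2 bins", call. = FALSE)
  one_dim_entropy(hic_graph(cm)) / log2(cm$n_bins)
}

#' @rdname nse1
#' @export
nse2 <- function(cm, contiguity = c("free", "adjacent")) {
  contiguity <- match.arg(contiguity)
  stopifnot(inherits(cm, "contact_matrix"))
  if (cm$n_bins < 2) stop("need at least 2 bins", call. = FALSE)
  g <- hic_graph(cm)
  h1 <- one_dim_entropy(g)
  if (h1 == 0) stop("one-dimensional entropy is zero", call. = FALSE)
  dedoc2(g, contiguity = contiguity)$entropy / h1
}

#' Stable local minima of a normalized-entropy sequence
#'
#' A binsize is *stable* when its normalized entropy is a strict local
#' minimum: strictly below both neighbors.  Endpoints can never be stable.
#'
#' @param nse numeric vector of normalized entropies along increasing
#'   binsizes.
#' @return logical vector of the same length.
#' @export
stable_binsizes <- function(nse) {
  k <- length(nse)
  stable <- rep(FALSE, k)
  if (k >= 3) for (i in 2:(k - 1))
    stable[i] <- nse[i - 1] > nse[i] && nse[i + 1] > nse[i]
  stable
}

#' Select the stable binsize with minimal normalized entropy
#'
#' Applies the stable-binsize rule to a scanned sequence: among all strict
#' interior local minima, pick the one with the smallest normalized entropy.
#' Appending binsizes whose values exceed the current selection cannot
#' change it.
#'
#' @param binsizes increasing binsizes (bp).
#' @param nse normalized entropies at those binsizes.
#' @return the selected binsize, or `NA` when no stable binsize exists.
#' @examples
#' select_stable_binsize(seq(10e3, 60e3, 10e3),
#'                       c(0.9, 0.8, 0.85, 0.7, 0.75, 0.72))  # 40000
#' @export
select_stable_binsize <- function(binsizes, nse) {
  stopifnot(length(binsizes) == length(nse))
  stable <- stable_binsizes(nse)
  if (!any(stable)) return(NA_integer_)
  cand <- which(stable)
  binsizes[cand[which.min(nse[cand])]]
}

#' Scan binsizes by normalized structural entropy
#'
#' Bins the contact pairs at each candidate binsize, computes the requested
#' normalized entropy, flags stable binsizes (strict interior local minima)
#' and selects the stable binsize with the smallest value — or none, when no
#' local minimum exists (as happens on some chromosomes).
#'
#' @param pairs contact pairs as from [read_contact_pairs()].
#' @param binsizes strictly increasing vector of at least 3 binsizes (bp).
#' @param chrom_length chromosome length in bp.
#' @param metric `"1d"` (default; much faster) or `"2d"`, or both.
#' @param contiguity forwarded to the 2D metric.
#' @return an object of class `binsize_scan`: a table with columns
#'   `binsize`, `n_bins`, `H1`, `nse1` (and `H2`, `nse2` when requested),
#'   stability flags, and `selected1`/`selected2` (chosen binsize or `NA`).
#' @export
scan_binsizes <- function(pairs, binsizes, chrom_length,
                          metric = c("1d", "2d"),
                          contiguity = c("free", "adjacent")) {
  metric <- match.arg(metric, several.ok = TRUE)
  contiguity <- match.arg(contiguity)
  binsizes <- as.integer(binsizes)
  if (length(binsizes) < 3) stop("need at least 3 binsizes", call. = FALSE)
  if (any(diff(binsizes) <= 0))
    stop("binsizes must be strictly increasing", call. = FALSE)
  tab <- data.frame(binsize = binsizes, n_bins = NA_integer_,
                    H1 = NA_real_, nse1 = NA_real_)
  want2 <- "2d" %in% metric
  if (want2) { tab$H2 <- NA_real_; tab$nse2 <- NA_real_ }
  for (i in seq_along(binsizes)) {
    cm <- bin_contact_pairs(pairs, binsizes[i], chrom_length)
    g <- hic_graph(cm)
    tab$n_bins[i] <- cm$n_bins
    tab$H1[i] <- one_dim_entropy(g)
    tab$nse1[i] <- tab$H1[i] / log2(cm$n_bins)
    if (want2) {
      tab$H2[i] <- dedoc2(g, contiguity = contiguity)$entropy
      tab$nse2[i] <- tab$H2[i] / tab$H1[i]
    }
  }
  tab$stable1 <- stable_binsizes(tab$nse1)
  selected1 <- select_stable_binsize(binsizes, tab$nse1)
  selected2 <- NA_integer_
  if (want2) {
    tab$stable2 <- stable_binsizes(tab$nse2)
    selected2 <- select_stable_binsize(binsizes, tab$nse2)
  }
  structure(list(table = tab, selected1 = selected1, selected2 = selected2,
                 metric = metric),
            class = "binsize_scan")
}

#' @export
print.binsize_scan <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("selected (1D-nSE): %s\n",
              ifelse(is.na(x$selected1), "none", x$selected1)))
  if ("2d" %in% x$metric)
    cat(sprintf("selected (2D-nSE): %s\n",
                ifelse(is.na(x$selected2), "none", x$selected2)))
  invisible(x)
}
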