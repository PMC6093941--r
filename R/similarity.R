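#' Similarity of two genomic intervals
#'
#' Overlap similarity `|X intersect Y| / sqrt(|X| * |Y|)`, with sizes and
#' intersections measured in bp on half-open intervals.  1 exactly when the
#' intervals coincide, 0 when they are disjoint.
#'
#' @param x,y numeric length-2 vectors `c(start, end)`, half-open, in bp.
#' @return a value in `[0, 1]`.
#' @examples
#' pair_similarity(c(0, 4), c(0, 8))   # 4 / sqrt(32)
#' @export
pair_similarity <- function(x, y) {
  if (x[2] <= x[1] || y[2] <= y[1]) stop("empty interval", call. = FALSE)
  ov <- max(0, min(x[2], y[2]) - max(x[1], y[1]))
  ov / sqrt((x[2] - x[1]) * (y[2] - y[1]))
}

as_interval_df <- function(x) {
  d <- if (inherits(x, "domain_set")) x$domains else as.data.frame(x)
  if (!all(c("start_bp", "end_bp") %in% names(d))) {
    if (all(c("start", "end") %in% names(d)))
      d <- data.frame(start_bp = d$start, end_bp = d$end)
    else stop("need columns start_bp/end_bp (or start/end)", call. = FALSE)
  }
  d <- d[order(d$start_bp), c("start_bp", "end_bp"), drop = FALSE]
  if (nrow(d) && any(d$end_bp <= d$start_bp)) stop("empty interval", call. = FALSE)
  if (nrow(d) > 1 && any(d$start_bp[-1] < d$end_bp[-nrow(d)]))
    stop("intervals overlap", call. = FALSE)
  d
}

#' Weighted similarity (WS) of two domain partitions
#'
#' For every reference domain the best-matching query domain is found under
#' [pair_similarity()], and the scores are averaged weighted by reference
#' domain length: `ws = sum(|X_j| S(j)) / sum(|X_j|)` with
#' `S(j) = max_i |X_j intersect Y_i| / sqrt(|X_j| |Y_i|)`.  The measure is
#' asymmetric; compute both directions when a symmetric picture is wanted.
#' Partitions called at different binsizes compare directly because
#' everything is measured on the bp axis.
#'
#' @param P reference partition: a [domain_set] or data.frame with
#'   `start_bp`, `end_bp` (sorted, non-overlapping; need not tile the
#'   chromosome).
#' @param Q query partition, same form.
#' @return `ws` of `Q` to `P`, in `[0, 1]`; `ws(P, P) == 1`.
#' @export
weighted_similarity <- function(P, Q) {
  p <- as_interval_df(P)
  q <- as_interval_df(Q)
  if (!nrow(p)) stop("reference partition is empty", call. = FALSE)
  if (!nrow(q)) return(0)
  lenp <- p$end_bp - p$start_bp
  lenq <- q$end_bp - q$start_bp
  # sweep: for each reference interval, only query intervals overlapping it
  # can score; find the overlapping run by binary search on sorted starts
  S <- numeric(nrow(p))
  for (j in seq_len(nrow(p))) {
    first <- findInterval(p$start_bp[j], q$end_bp) + 1L  # first q with end > p.start
    best <- 0
    i <- first
    while (i <= nrow(q) && q$start_bp[i] < p$end_bp[j]) {
      ov <- min(p$end_bp[j], q$end_bp[i]) - max(p$start_bp[j], q$start_bp[i])
      if (ov > 0) best <- max(best, ov / sqrt(lenp[j] * lenq[i]))
      i <- i + 1L
    }
    S[j] <- best
  }
  sum(lenp * S) / sum(lenp)
}
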