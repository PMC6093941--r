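#' Greedy two-level structural-entropy minimization
#'
#' The deDoc(2) core: starting from the all-singleton partition under the
#' root, repeatedly applies the sister merge with the largest positive
#' entropy gain until no merge reduces the structural entropy.  Candidates
#' are module pairs connected by at least one edge (merging a disconnected
#' pair can never gain); in `adjacent` mode only genomically neighboring
#' modules may merge, so every module is a contiguous bin run by
#' construction.  Ties in the gain are broken deterministically towards the
#' pair with the lowest leading bin.
#'
#' @param graph a `hic_graph` (or a [contact_matrix], coerced with defaults).
#' @param contiguity `"free"` (any connected pair) or `"adjacent"`.
#' @return a list with `partition` (list of 1-based vertex vectors, ordered
#'   by first bin), `membership` (module id per vertex), `entropy` (final
#'   height-2 tree entropy, bits), `deltas` (entropy gain of each accepted
#'   merge, all positive), `n_merges`.
#' @export
dedoc2 <- function(graph, contiguity = c("free", "adjacent")) {
  contiguity <- match.arg(contiguity)
  graph <- as_hic_graph(graph)
  if (graph$w <= 0) stop("empty graph: total weight is zero", call. = FALSE)
  tri <- as(Matrix::triu(graph$adj, k = 1L), "TsparseMatrix")
  g0 <- graph$degree - 2 * graph$selfloop
  res <- .greedy_merge_cpp(graph$n, graph$degree, g0, graph$w,
                           tri@i, tri@j, tri@x, contiguity == "adjacent")
  part <- split(seq_len(graph$n), res$membership)
  ord <- order(vapply(part, min, numeric(1)))
  part <- unname(part[ord])
  membership <- integer(graph$n)
  for (k in seq_along(part)) membership[part[[k]]] <- k
  list(partition = part, membership = membership, entropy = res$entropy,
       deltas = res$deltas, n_merges = res$n_merges)
}

#' Height-2 entropy of an explicit partition
#'
#' Structural entropy of the two-level coding tree whose modules are the
#' given partition, computed directly from the graph (no greedy search).
#'
#' @param graph a `hic_graph` (or coercible).
#' @param membership integer module label per vertex (any labels), or a list
#'   of vertex vectors.
#' @return entropy in bits.
#' @export
partition_entropy <- function(graph, membership) {
  graph <- as_hic_graph(graph)
  if (is.list(membership)) {
    mem <- integer(graph$n)
    for (k in seq_along(membership)) mem[membership[[k]]] <- k
    membership <- mem
  }
  mem <- as.integer(factor(membership))
  k <- max(mem)
  ind <- Matrix::sparseMatrix(i = mem, j = seq_len(graph$n), x = 1,
                              dims = c(k, graph$n))
  V <- as.numeric(ind %*% graph$degree)
  intra <- Matrix::diag(ind %*% graph$adj %*% Matrix::t(ind))
  loop <- as.numeric(ind %*% graph$selfloop)
  g <- V - 2 * loop - intra
  two_w <- 2 * graph$w
  mod_terms <- mapply(se_term, g, V, MoreArgs = list(Vp = two_w, w = graph$w))
  d <- graph$degree
  Vm <- V[mem]
  ok <- d > 0 & Vm > 0
  leaf <- -sum(xlog2(d[ok] / two_w, d[ok] / Vm[ok]))
  sum(mod_terms) + leaf
}

#' Domain sets
#'
#' Ordered, non-overlapping contiguous bin intervals on one chromosome: the
#' output of the TAD callers.  `dropped_bins` records bins that belonged to
#' non-contiguous modules removed in `free` mode; `zero_bins` records bins
#' with no contacts at all (retained as vertices, never called as domains).
#'
#' @param domains data.frame with 0-based inclusive `start_bin`, `end_bin`.
#' @param chrom,binsize genomic metadata.
#' @param mode `"E"`, `"M"` or other provenance label.
#' @param entropy final height-2 tree entropy (bits).
#' @param entropy_depth3 for mode `"M"`: entropy of the 3-level tree whose
#'   middle layer is the deDoc(E) partition; `NA` otherwise.
#' @param dropped_bins,zero_bins 0-based bin indices.
#' @return an object of class `domain_set`.
#' @export
domain_set <- function(domains, chrom = "chr1", binsize = 1L, mode = "E",
                       entropy = NA_real_, entropy_depth3 = NA_real_,
                       dropped_bins = integer(0), zero_bins = integer(0)) {
  domains <- as.data.frame(domains)
  stopifnot(all(c("start_bin", "end_bin") %in% names(domains)))
  domains <- domains[order(domains$start_bin), , drop = FALSE]
  rownames(domains) <- NULL
  if (nrow(domains)) {
    if (any(domains$start_bin > domains$end_bin))
      stop("domain with start_bin > end_bin", call. = FALSE)
    if (nrow(domains) > 1 &&
        any(domains$start_bin[-1] <= domains$end_bin[-nrow(domains)]))
      stop("overlapping domains", call. = FALSE)
  }
  binsize <- as.integer(binsize)
  domains$start_bp <- domains$start_bin * binsize
  domains$end_bp <- (domains$end_bin + 1) * binsize
  structure(list(domains = domains, chrom = as.character(chrom),
                 binsize = binsize, mode = mode, entropy = entropy,
                 entropy_depth3 = entropy_depth3,
                 dropped_bins = as.integer(dropped_bins),
                 zero_bins = as.integer(zero_bins)),
            class = "domain_set")
}

#' @export
print.domain_set <- function(x, ...) {
  cat(sprintf("domain_set [deDoc(%s)]: %s, %d domains @ %d bp bins\n",
              x$mode, x$chrom, nrow(x$domains), x$binsize))
  cat(sprintf("  entropy %.6g bits; %d dropped bins; %d contact-free bins\n",
              x$entropy, length(x$dropped_bins), length(x$zero_bins)))
  invisible(x)
}

is_contiguous <- function(v) length(v) == max(v) - min(v) + 1L

# split modules into domains / dropped / zero-degree classes
modules_to_domains <- function(part, graph) {
  keep <- list(); dropped <- integer(0); zero <- integer(0)
  for (mod in part) {
    if (all(graph$degree[mod] == 0)) {
      zero <- c(zero, mod - 1L)
    } else if (is_contiguous(mod)) {
      keep[[length(keep) + 1L]] <- mod
    } else {
      dropped <- c(dropped, mod - 1L)
    }
  }
  list(keep = keep, dropped = dropped, zero = zero)
}

#' Call TADs with deDoc(E)
#'
#' Runs the greedy height-2 structural-entropy minimization on the whole
#' chromosome and converts the resulting modules into domains.  In `free`
#' mode (the production default) modules whose bins are not consecutive are
#' removed after the fact and their bins reported in `dropped_bins`; in
#' `adjacent` mode only neighboring modules ever merge, so every module is
#' contiguous by construction.
#'
#' @param cm a [contact_matrix].
#' @param contiguity `"free"` or `"adjacent"`.
#' @param keep_diagonal forwarded to [hic_graph()].
#' @return a [domain_set] with `mode = "E"`.
#' @export
call_domains_E <- function(cm, contiguity = c("free", "adjacent"),
                           keep_diagonal = FALSE) {
  contiguity <- match.arg(contiguity)
  stopifnot(inherits(cm, "contact_matrix"))
  if (cm$n_bins == 1L)   # degenerate: nothing to partition
    return(domain_set(data.frame(start_bin = 0L, end_bin = 0L),
                      chrom = cm$chrom, binsize = cm$binsize, mode = "E",
                      entropy = 0))
  graph <- hic_graph(cm, keep_diagonal = keep_diagonal)
  fit <- dedoc2(graph, contiguity = contiguity)
  cls <- modules_to_domains(fit$partition, graph)
  dom <- data.frame(
    start_bin = vapply(cls$keep, function(v) min(v) - 1L, integer(1)),
    end_bin = vapply(cls$keep, function(v) max(v) - 1L, integer(1)))
  domain_set(dom, chrom = cm$chrom, binsize = cm$binsize, mode = "E",
             entropy = fit$entropy, dropped_bins = cls$dropped,
             zero_bins = cls$zero)
}

#' Call TADs with deDoc(M)
#'
#' deDoc(M) reapplies deDoc(2) inside each deDoc(E) domain: the induced
#' intra-domain subgraph is re-partitioned, yielding smaller domains nested
#' within the E-level ones.  Domains of two bins or fewer pass through
#' unrefined.  Two entropies are reported: `entropy` is the height-2 entropy
#' of the refined (flat) partition on the full graph, and `entropy_depth3`
#' is the entropy of the 3-level tree that keeps the E-domains as the middle
#' layer.
#'
#' @inheritParams call_domains_E
#' @return a [domain_set] with `mode = "M"`.
#' @export
call_domains_M <- function(cm, contiguity = c("free", "adjacent"),
                           keep_diagonal = FALSE) {
  contiguity <- match.arg(contiguity)
  stopifnot(inherits(cm, "contact_matrix"))
  graph <- hic_graph(cm, keep_diagonal = keep_diagonal)
  e_set <- call_domains_E(cm, contiguity = contiguity,
                          keep_diagonal = keep_diagonal)
  dropped <- e_set$dropped_bins
  refined <- list()     # list of global 1-based bin vectors
  e_parent <- integer(0)
  for (d in seq_len(nrow(e_set$domains))) {
    bins <- (e_set$domains$start_bin[d]:e_set$domains$end_bin[d]) + 1L
    if (length(bins) <= 2L) {
      refined[[length(refined) + 1L]] <- bins
      e_parent <- c(e_parent, d)
      next
    }
    sub_adj <- graph$adj[bins, bins, drop = FALSE]
    sub_loop <- graph$selfloop[bins]
    sub_g <- structure(list(
      n = length(bins),
      degree = as.numeric(Matrix::rowSums(sub_adj)) + 2 * sub_loop,
      w = sum(sub_adj) / 2 + sum(sub_loop),
      adj = as(sub_adj, "generalMatrix"), selfloop = sub_loop),
      class = "hic_graph")
    if (sub_g$w <= 0) {            # no intra-domain contacts left
      refined[[length(refined) + 1L]] <- bins
      e_parent <- c(e_parent, d)
      next
    }
    sub_fit <- dedoc2(sub_g, contiguity = contiguity)
    for (mod in sub_fit$partition) {
      gl <- bins[mod]
      if (contiguity == "free" && !is_contiguous(gl)) {
        dropped <- c(dropped, gl - 1L)
      } else {
        refined[[length(refined) + 1L]] <- gl
        e_parent <- c(e_parent, d)
      }
    }
  }
  ord <- order(vapply(refined, min, numeric(1)))
  refined <- refined[ord]; e_parent <- e_parent[ord]
  dom <- data.frame(
    start_bin = vapply(refined, function(v) min(v) - 1L, integer(1)),
    end_bin = vapply(refined, function(v) max(v) - 1L, integer(1)))
  # flat height-2 entropy of the refined partition (dropped/zero bins as
  # singletons), plus the 3-level entropy keeping E-domains as middle layer
  all_mods <- c(refined, as.list(setdiff(seq_len(graph$n), unlist(refined))))
  H_flat <- partition_entropy(graph, all_mods)
  H3 <- depth3_entropy(graph, e_set, refined, e_parent)
  domain_set(dom, chrom = cm$chrom, binsize = cm$binsize, mode = "M",
             entropy = H_flat, entropy_depth3 = H3,
             dropped_bins = sort(unique(dropped)), zero_bins = e_set$zero_bins)
}

# entropy of the 3-level tree: root -> E-domains -> M-subdomains -> leaves;
# bins outside any E-domain hang under the root as singleton modules
depth3_entropy <- function(graph, e_set, refined, e_parent) {
  two_w <- 2 * graph$w
  H <- 0
  for (d in seq_len(nrow(e_set$domains))) {
    bins <- (e_set$domains$start_bin[d]:e_set$domains$end_bin[d]) + 1L
    gE <- cut_weight(graph, bins); VE <- volume_of(graph, bins)
    H <- H + se_term(gE, VE, two_w, graph$w)
    for (k in which(e_parent == d)) {
      mod <- refined[[k]]
      gM <- cut_weight(graph, mod); VM <- volume_of(graph, mod)
      H <- H + se_term(gM, VM, VE, graph$w)
      dle <- graph$degree[mod]
      ok <- dle > 0 & VM > 0
      H <- H - sum(xlog2(dle[ok] / two_w, dle[ok] / VM))
    }
  }
  outside <- setdiff(seq_len(graph$n) - 1L,
                     unlist(lapply(seq_len(nrow(e_set$domains)), function(d)
                       e_set$domains$start_bin[d]:e_set$domains$end_bin[d]))) + 1L
  for (v in outside) {
    dv <- graph$degree[v]
    if (dv > 0) H <- H + se_term(cut_weight(graph, v), dv, two_w, graph$w)
  }
  H
}

#' Fraction of reference boundaries recovered by a call
#'
#' A reference boundary (start or end of a reference domain, in bp) counts
#' as recovered when the called set has a boundary within `tol_bp`.  Only
#' internal boundaries are scored: the chromosome ends are excluded.
#'
#' @param truth,called [domain_set]s (or data.frames with `start_bp`,
#'   `end_bp`).
#' @param tol_bp matching tolerance in bp (e.g. one bin width).
#' @return fraction in `[0, 1]`; `NA` if the reference has no internal
#'   boundaries.
#' @export
boundary_recovery <- function(truth, called, tol_bp = 0) {
  bp <- function(x) {
    d <- if (inherits(x, "domain_set")) x$domains else as.data.frame(x)
    sort(unique(c(d$start_bp, d$end_bp)))
  }
  tb <- bp(truth); cb <- bp(called)
  tb <- tb[tb > min(tb) & tb < max(tb)]   # internal boundaries only
  if (!length(tb)) return(NA_real_)
  if (!length(cb)) return(0)
  hit <- vapply(tb, function(b) any(abs(cb - b) <= tol_bp), logical(1))
  mean(hit)
}
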