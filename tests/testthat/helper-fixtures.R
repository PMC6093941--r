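# Small graph fixtures and independent brute-force oracles used across the
# suite.  The oracles recompute everything from the dense adjacency by the
# definitions (double loops, no caches, no incremental updates) so that the
# production path can be checked against them.

clique_pair_matrix <- function(s) {
  A <- matrix(0, 2 * s, 2 * s)
  A[1:s, 1:s] <- 1
  A[(s + 1):(2 * s), (s + 1):(2 * s)] <- 1
  diag(A) <- 0
  contact_matrix(A)
}

cycle_matrix <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    A[i, j] <- 1; A[j, i] <- 1
  }
  contact_matrix(A)
}

star_matrix <- function(n) {
  A <- matrix(0, n, n)
  A[1, 2:n] <- 1; A[2:n, 1] <- 1
  contact_matrix(A)
}

# connected Erdos-Renyi-style random graph as a contact matrix
er_matrix <- function(n, p = 0.5, weighted = FALSE, max_tries = 200) {
  for (t in seq_len(max_tries)) {
    A <- matrix(0, n, n)
    up <- upper.tri(A)
    edge <- runif(sum(up)) < p
    wts <- if (weighted) sample(1:5, sum(up), replace = TRUE) else 1
    A[up] <- edge * wts
    A <- A + t(A)
    # connectivity by reachability
    reach <- logical(n); reach[1] <- TRUE
    repeat {
      nxt <- reach | (colSums(A[reach, , drop = FALSE]) > 0)
      if (all(nxt == reach)) break
      reach <- nxt
    }
    if (all(reach)) return(contact_matrix(A))
  }
  stop("could not draw a connected graph")
}

# --- oracles -------------------------------------------------------------

# height-2 structural entropy of a membership vector, straight from the
# definitions on a dense adjacency (diagonal assumed empty)
naive_partition_entropy <- function(A, mem) {
  d <- rowSums(A)
  w <- sum(A) / 2
  H <- 0
  for (mod in unique(mem)) {
    in_mod <- mem == mod
    V <- sum(d[in_mod])
    g <- sum(A[in_mod, !in_mod, drop = FALSE])
    if (g > 0 && V > 0 && V < 2 * w) H <- H - (g / (2 * w)) * log2(V / (2 * w))
    for (i in which(in_mod))
      if (d[i] > 0 && d[i] < V) H <- H - (d[i] / (2 * w)) * log2(d[i] / V)
  }
  H
}

# all set partitions of 1..n as membership vectors (restricted growth
# strings), cached per n
.setparts_cache <- new.env(parent = emptyenv())
setparts_of <- function(n) {
  key <- as.character(n)
  if (!is.null(.setparts_cache[[key]])) return(.setparts_cache[[key]])
  parts <- list()
  rec <- function(prefix, kmax) {
    i <- length(prefix) + 1L
    if (i > n) {
      parts[[length(parts) + 1L]] <<- prefix
      return()
    }
    for (v in seq_len(kmax + 1L)) rec(c(prefix, v), max(kmax, v))
  }
  rec(integer(0), 0L)
  .setparts_cache[[key]] <- parts
  parts
}

# exhaustive minimum height-2 entropy over every set partition
exhaustive_min_entropy <- function(A) {
  best <- Inf
  for (mem in setparts_of(nrow(A)))
    best <- min(best, naive_partition_entropy(A, mem))
  best
}

# structural entropy of a coding tree recomputed from scratch off the
# markers (ignores all cached g/V)
naive_tree_entropy <- function(tree) {
  A <- as.matrix(tree$graph$adj)
  d <- tree$graph$degree
  w <- tree$graph$w
  H <- 0
  for (id in seq_along(tree$nodes)) {
    nd <- tree$nodes[[id]]
    if (is.null(nd) || id == tree$root) next
    set <- nd$vertices
    V <- sum(d[set])
    g <- sum(A[set, setdiff(seq_len(tree$graph$n), set), drop = FALSE])
    Vp <- sum(d[tree$nodes[[nd$parent]]$vertices])
    if (g > 0 && V > 0 && V < Vp) H <- H - (g / (2 * w)) * log2(V / Vp)
  }
  H
}

# random partition of 1..n into contiguous-or-not blocks
random_partition <- function(n, k = sample(2:max(2, n %/% 2), 1)) {
  mem <- sample(rep_len(seq_len(k), n))
  unname(split(seq_len(n), mem))
}

# a random coding tree: random height-2 partition, deepened by a few random
# combines (unbounded height)
random_coding_tree <- function(graph, n_combines = 2) {
  tr <- coding_tree(graph, random_partition(graph$n))
  for (i in seq_len(n_combines)) {
    kids <- tr$nodes[[tr$root]]$children
    if (length(kids) < 2) break
    ab <- sample(kids, 2)
    tr <- combine_nodes(tr, ab[1], ab[2])
  }
  tr
}

# sister pairs available in a tree (pairs of children of any live node)
sister_pairs <- function(tree) {
  out <- list()
  for (id in seq_along(tree$nodes)) {
    nd <- tree$nodes[[id]]
    if (is.null(nd) || length(nd$children) < 2) next
    cmb <- utils::combn(nd$children, 2)
    for (k in seq_len(ncol(cmb)))
      out[[length(out) + 1L]] <- cmb[, k]
  }
  out
}

# WS by the literal double loop over all reference/query pairs
naive_weighted_similarity <- function(P, Q) {
  p <- if (inherits(P, "domain_set")) P$domains else P
  q <- if (inherits(Q, "domain_set")) Q$domains else Q
  S <- numeric(nrow(p)); len <- p$end_bp - p$start_bp
  for (j in seq_len(nrow(p))) {
    best <- 0
    for (i in seq_len(nrow(q))) {
      ov <- max(0, min(p$end_bp[j], q$end_bp[i]) - max(p$start_bp[j], q$start_bp[i]))
      sim <- ov / sqrt((p$end_bp[j] - p$start_bp[j]) * (q$end_bp[i] - q$start_bp[i]))
      best <- max(best, sim)
    }
    S[j] <- best
  }
  sum(len * S) / sum(len)
}

# internal-boundary recovery used by the planted-domain tests
planted_sim <- function(seed, n_bins = 30, starts = c(0, 10, 20), B = 20,
                        decay = 1, eps = 6, ...) {
  simulate_hic(n_bins, starts, background = B, decay = decay,
               enrichment = eps, seed = seed, ...)
}
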