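#' Weighted-graph view of a contact matrix
#'
#' Interprets a contact matrix as a weighted undirected graph: bins are
#' vertices and contact counts are edge weights.  Diagonal (self) contacts
#' are excluded by default; with `keep_diagonal = TRUE` a self-contact of
#' weight `m` is treated as a self-loop contributing `2 m` to its vertex's
#' degree and `m` to the total weight, so the handshake identity
#' `sum(degree) == 2 w` always holds.  Self-loops never cross a cut, so they
#' affect volumes only.
#'
#' @param cm a [contact_matrix], or a square (sparse) matrix.
#' @param keep_diagonal keep self-contacts as self-loops?
#' @return an object of class `hic_graph` with fields `n`, `degree`, `w`,
#'   `adj` (off-diagonal symmetric `dgCMatrix`), `selfloop` (per-vertex
#'   self-loop weight).
#' @export
hic_graph <- function(cm, keep_diagonal = FALSE) {
  mat <- if (inherits(cm, "contact_matrix")) cm$mat else
    contact_matrix(cm)$mat
  n <- nrow(mat)
  dg <- Matrix::diag(mat)
  adj <- mat
  if (any(dg != 0)) Matrix::diag(adj) <- 0
  adj <- Matrix::drop0(adj)
  degree <- Matrix::rowSums(adj)
  selfloop <- numeric(n)
  if (keep_diagonal) {
    selfloop <- dg
    degree <- degree + 2 * dg
  }
  w <- sum(adj) / 2 + sum(selfloop)
  structure(list(n = n, degree = as.numeric(degree), w = w,
                 adj = as(adj, "generalMatrix"), selfloop = selfloop),
            class = "hic_graph")
}

#' @export
print.hic_graph <- function(x, ...) {
  cat(sprintf("hic_graph: %d vertices, total weight %.6g, %d nonzero edges\n",
              x$n, x$w, length(x$adj@x) / 2))
  invisible(x)
}

#' One-dimensional structural entropy
#'
#' The structural entropy of the trivial (height-1) encoding of a weighted
#' graph: the Shannon entropy of the stationary distribution of a random
#' walk, `H1 = -sum_i (d_i / 2w) log2(d_i / 2w)`.  Zero-degree vertices
#' contribute nothing (`0 log 0 := 0`).
#'
#' @param graph a `hic_graph` (or an object coercible via [hic_graph()]).
#' @return entropy in bits.
#' @examples
#' g <- hic_graph(contact_matrix(matrix(c(0, 1, 1, 0), 2)))
#' one_dim_entropy(g)  # 1 bit: uniform over two vertices
#' @export
one_dim_entropy <- function(graph) {
  graph <- as_hic_graph(graph)
  if (graph$w <= 0) stop("empty graph: total weight is zero", call. = FALSE)
  p <- graph$degree / (2 * graph$w)
  -sum(xlog2(p, p))
}

as_hic_graph <- function(x) {
  if (inherits(x, "hic_graph")) x else hic_graph(x)
}

# total weight of edges between two disjoint vertex sets (1-based indices)
cut_between <- function(graph, a, b) {
  if (!length(a) || !length(b)) return(0)
  sum(graph$adj[a, b, drop = FALSE])
}

# cut weight between `set` and its complement
cut_weight <- function(graph, set) {
  if (!length(set) || length(set) == graph$n) return(0)
  sum(graph$degree[set]) - 2 * sum(graph$selfloop[set]) -
    sum(graph$adj[set, set, drop = FALSE])
}

# volume: sum of weighted degrees over `set`
volume_of <- function(graph, set) sum(graph$degree[set])
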