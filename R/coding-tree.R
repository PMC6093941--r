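#' Coding trees
#'
#' A coding tree of a graph is a rooted tree whose root carries the whole
#' vertex set, whose internal nodes' children partition their parent's
#' vertex set (the node's *marker*), and whose leaves carry single vertices.
#' Each node caches its cut weight `g` (total weight of edges leaving its
#' marker) and its volume `V` (sum of weighted degrees inside the marker).
#' The structural entropy of the graph given the tree is the sum of per-node
#' terms `-(g / 2w) log2(V / V_parent)` over all non-root nodes.
#'
#' `coding_tree()` builds a two-level tree from a partition of the vertices
#' (default: every vertex its own module, the starting point of the greedy
#' caller).  Every module node carries explicit singleton leaves, including
#' single-vertex modules, so module nodes are never themselves leaves.
#'
#' @param graph a `hic_graph` (or coercible).
#' @param partition a list of integer vectors (1-based vertex indices)
#'   forming a disjoint cover of the vertices, or `NULL` for all singletons.
#' @return an object of class `coding_tree`: fields `graph`, `nodes` (list;
#'   each node has `parent`, `children`, `vertices`, `g`, `V`), `root`.
#' @export
coding_tree <- function(graph, partition = NULL) {
  graph <- as_hic_graph(graph)
  n <- graph$n
  if (is.null(partition)) partition <- as.list(seq_len(n))
  partition <- lapply(partition, function(v) sort(as.integer(v)))
  verts <- unlist(partition)
  if (length(verts) != n || anyDuplicated(verts) || !setequal(verts, seq_len(n)))
    stop("partition must be a disjoint cover of the vertices", call. = FALSE)
  nodes <- vector("list", 1L)
  nodes[[1L]] <- list(parent = NA_integer_, children = integer(0),
                      vertices = seq_len(n), g = 0, V = 2 * graph$w)
  next_id <- 2L
  for (mod in partition) {
    mid <- next_id; next_id <- next_id + 1L
    kids <- seq.int(next_id, length.out = length(mod))
    next_id <- next_id + length(mod)
    nodes[[mid]] <- list(parent = 1L, children = kids, vertices = mod,
                         g = cut_weight(graph, mod), V = volume_of(graph, mod))
    for (k in seq_along(kids))
      nodes[[kids[k]]] <- list(parent = mid, children = integer(0),
                               vertices = mod[k],
                               g = cut_weight(graph, mod[k]),
                               V = graph$degree[mod[k]])
    nodes[[1L]]$children <- c(nodes[[1L]]$children, mid)
  }
  structure(list(graph = graph, nodes = nodes, root = 1L), class = "coding_tree")
}

#' @export
print.coding_tree <- function(x, ...) {
  live <- !vapply(x$nodes, is.null, logical(1))
  cat(sprintf("coding_tree: %d nodes, height %d, entropy %.6g bits\n",
              sum(live), tree_height(x), tree_entropy(x)))
  invisible(x)
}

# one structural-entropy term; conventions: g = 0, V = 0 or V = Vp give 0
se_term <- function(g, V, Vp, w) {
  if (g == 0 || V == 0 || V == Vp) return(0)
  -(g / (2 * w)) * log2(V / Vp)
}

#' Structural entropy of one tree node
#'
#' `-(g_a / 2w) log2(V_a / V_parent)` for a non-root node; zero when the
#' node's cut or volume is zero or its volume equals the parent's.
#'
#' @param tree a [coding_tree].
#' @param id node index.
#' @return entropy contribution in bits.
#' @export
node_entropy <- function(tree, id) {
  nd <- tree$nodes[[id]]
  if (is.null(nd)) stop("node does not exist", call. = FALSE)
  if (id == tree$root) stop("the root has no entropy term", call. = FALSE)
  se_term(nd$g, nd$V, tree$nodes[[nd$parent]]$V, tree$graph$w)
}

#' Structural entropy of a graph given a coding tree
#'
#' Sum of [node_entropy()] over every non-root node.  With the trivial
#' one-module tree this equals [one_dim_entropy()].
#'
#' @param tree a [coding_tree].
#' @return entropy in bits.
#' @export
tree_entropy <- function(tree) {
  if (!setequal(tree$nodes[[tree$root]]$vertices, seq_len(tree$graph$n)))
    stop("root marker does not cover the vertex set", call. = FALSE)
  ids <- which(!vapply(tree$nodes, is.null, logical(1)))
  sum(vapply(setdiff(ids, tree$root), function(i) node_entropy(tree, i),
             numeric(1)))
}

#' Tree height
#' @param tree a [coding_tree].
#' @return maximal leaf depth (root has depth 0).
#' @export
tree_height <- function(tree) {
  depth <- function(id, d) {
    kids <- tree$nodes[[id]]$children
    if (!length(kids)) return(d)
    max(vapply(kids, depth, numeric(1), d = d + 1))
  }
  depth(tree$root, 0)
}

check_sisters <- function(tree, a, b) {
  na <- tree$nodes[[a]]; nb <- tree$nodes[[b]]
  if (is.null(na) || is.null(nb)) stop("node does not exist", call. = FALSE)
  if (a == tree$root || b == tree$root)
    stop("cannot operate on the root", call. = FALSE)
  if (a == b) stop("nodes must be distinct", call. = FALSE)
  if (na$parent != nb$parent)
    stop("nodes are not sisters (different parents)", call. = FALSE)
  list(a = na, b = nb)
}

# children of `id`, materializing a singleton leaf when `id` is itself a leaf
# (the merged node must keep singleton leaves below it)
child_records <- function(tree, id) {
  nd <- tree$nodes[[id]]
  if (length(nd$children))
    return(lapply(nd$children, function(c) c(tree$nodes[[c]], list(id = c))))
  v <- nd$vertices
  list(list(parent = id, children = integer(0), vertices = v,
            g = cut_weight(tree$graph, v), V = tree$graph$degree[v], id = NA))
}

#' Merging operator
#'
#' Merges two sister nodes: the first node's marker becomes the union of the
#' two markers, the second node is deleted, and its children (or implicit
#' singleton leaves) are re-homed under the first.  Cached cuts and volumes
#' are updated incrementally.
#'
#' @param tree a [coding_tree].
#' @param a,b indices of sister nodes (neither the root).
#' @return the modified tree.
#' @export
merge_nodes <- function(tree, a, b) {
  p <- check_sisters(tree, a, b)
  g <- tree$graph
  w_ab <- cut_between(g, p$a$vertices, p$b$vertices)
  merged_verts <- sort(c(p$a$vertices, p$b$vertices))
  # re-home existing children; a side that was itself a leaf contributes its
  # vertex as a new explicit singleton leaf
  nodes <- tree$nodes
  newkids <- integer(0)
  for (side in c(a, b)) {
    nd <- nodes[[side]]
    if (length(nd$children)) {
      newkids <- c(newkids, nd$children)
    } else {
      for (v in nd$vertices) {
        nid <- length(nodes) + 1L
        nodes[[nid]] <- list(parent = a, children = integer(0), vertices = v,
                             g = cut_weight(g, v), V = g$degree[v])
        newkids <- c(newkids, nid)
      }
    }
  }
  nodes[[a]]$vertices <- merged_verts
  nodes[[a]]$g <- p$a$g + p$b$g - 2 * w_ab
  nodes[[a]]$V <- p$a$V + p$b$V
  nodes[[a]]$children <- newkids
  for (c in newkids) nodes[[c]]$parent <- a
  par <- p$a$parent
  nodes[[par]]$children <- setdiff(nodes[[par]]$children, b)
  nodes[b] <- list(NULL)
  tree$nodes <- nodes
  tree
}

#' Entropy change of a merge
#'
#' Returns `H_before - H_after` for [merge_nodes()], computed incrementally
#' from the affected nodes only (the two sisters and their children);
#' positive means the merge reduces the structural entropy.
#'
#' @inheritParams merge_nodes
#' @return entropy difference in bits.
#' @export
merge_delta <- function(tree, a, b) {
  p <- check_sisters(tree, a, b)
  g <- tree$graph
  w <- g$w
  Vp <- tree$nodes[[p$a$parent]]$V
  w_ab <- cut_between(g, p$a$vertices, p$b$vertices)
  g_new <- p$a$g + p$b$g - 2 * w_ab
  V_new <- p$a$V + p$b$V
  kids <- c(child_records(tree, a), child_records(tree, b))
  before <- se_term(p$a$g, p$a$V, Vp, w) + se_term(p$b$g, p$b$V, Vp, w)
  after <- se_term(g_new, V_new, Vp, w)
  # explicit children had a term against their parent's old volume; a sister
  # that was itself a leaf had its term counted above and reappears as a
  # materialized singleton leaf under the merged node
  for (k in kids) {
    if (!is.na(k$id)) before <- before + se_term(k$g, k$V, tree$nodes[[k$parent]]$V, w)
    after <- after + se_term(k$g, k$V, V_new, w)
  }
  before - after
}

#' Combining operator
#'
#' Inserts a new node between two sisters and their parent: the new node's
#' marker is the union of the two markers and the sisters become its
#' children.  Refuses (with an error of class `dedocr_height_refusal`) when
#' a height bound is given and the result would exceed it.
#'
#' @inheritParams merge_nodes
#' @param max_height optional height bound `k`; the combine is refused if the
#'   resulting tree would be taller.
#' @return the modified tree (new node appended last).
#' @export
combine_nodes <- function(tree, a, b, max_height = NULL) {
  p <- check_sisters(tree, a, b)
  g <- tree$graph
  if (!is.null(max_height)) {
    sub_h <- function(id) {
      kids <- tree$nodes[[id]]$children
      if (!length(kids)) return(if (length(tree$nodes[[id]]$vertices) > 1L) 1L else 0L)
      1L + max(vapply(kids, sub_h, integer(1)))
    }
    # depth of new node = depth of a; its subtree height grows by 1
    depth_of <- function(id) {
      d <- 0L
      while (!is.na(tree$nodes[[id]]$parent)) { id <- tree$nodes[[id]]$parent; d <- d + 1L }
      d
    }
    new_height <- depth_of(a) + 1L + max(sub_h(a), sub_h(b))
    if (new_height > max_height) {
      cond <- structure(class = c("dedocr_height_refusal", "error", "condition"),
                        list(message = sprintf(
                          "combine refused: resulting height %d exceeds bound %d",
                          new_height, max_height), call = NULL))
      stop(cond)
    }
  }
  w_ab <- cut_between(g, p$a$vertices, p$b$vertices)
  nodes <- tree$nodes
  nid <- length(nodes) + 1L
  par <- p$a$parent
  nodes[[nid]] <- list(parent = par,
                       children = c(a, b),
                       vertices = sort(c(p$a$vertices, p$b$vertices)),
                       g = p$a$g + p$b$g - 2 * w_ab,
                       V = p$a$V + p$b$V)
  nodes[[par]]$children <- c(setdiff(nodes[[par]]$children, c(a, b)), nid)
  nodes[[a]]$parent <- nid
  nodes[[b]]$parent <- nid
  tree$nodes <- nodes
  tree
}

#' Entropy change of a combine
#'
#' `H_before - H_after` for [combine_nodes()], incremental: only the two
#' sisters' terms change (they become relative to the new node's volume) and
#' the new node contributes one term.
#'
#' @inheritParams combine_nodes
#' @return entropy difference in bits.
#' @export
combine_delta <- function(tree, a, b) {
  p <- check_sisters(tree, a, b)
  w <- tree$graph$w
  Vp <- tree$nodes[[p$a$parent]]$V
  w_ab <- cut_between(tree$graph, p$a$vertices, p$b$vertices)
  g_xi <- p$a$g + p$b$g - 2 * w_ab
  V_xi <- p$a$V + p$b$V
  before <- se_term(p$a$g, p$a$V, Vp, w) + se_term(p$b$g, p$b$V, Vp, w)
  after <- se_term(g_xi, V_xi, Vp, w) +
    se_term(p$a$g, p$a$V, V_xi, w) + se_term(p$b$g, p$b$V, V_xi, w)
  before - after
}

#' Extract the depth-1 partition of a coding tree
#' @param tree a [coding_tree].
#' @return list of integer vectors: the markers of the root's children.
#' @export
tree_partition <- function(tree) {
  lapply(tree$nodes[[tree$root]]$children, function(i) tree$nodes[[i]]$vertices)
}

#' Validate coding-tree invariants
#'
#' Checks that children partition their parents' markers, leaves are
#' singletons, the root covers the vertex set with zero cut, and cached cuts
#' and volumes agree with recomputation from the graph.
#'
#' @param tree a [coding_tree].
#' @param tol numeric tolerance for the cache checks.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_coding_tree <- function(tree, tol = 1e-9) {
  g <- tree$graph
  ids <- which(!vapply(tree$nodes, is.null, logical(1)))
  root <- tree$nodes[[tree$root]]
  stopifnot(setequal(root$vertices, seq_len(g$n)), root$g == 0,
            abs(root$V - 2 * g$w) <= tol * max(1, 2 * g$w))
  for (i in ids) {
    nd <- tree$nodes[[i]]
    if (length(nd$children)) {
      kid_verts <- unlist(lapply(nd$children, function(c) tree$nodes[[c]]$vertices))
      if (anyDuplicated(kid_verts) || !setequal(kid_verts, nd$vertices))
        stop(sprintf("node %d: children do not partition the marker", i), call. = FALSE)
      for (c in nd$children)
        if (tree$nodes[[c]]$parent != i)
          stop(sprintf("node %d: child %d has wrong parent", i, c), call. = FALSE)
    }
    g_ref <- cut_weight(g, nd$vertices)
    V_ref <- volume_of(g, nd$vertices)
    if (abs(nd$g - g_ref) > tol * max(1, g_ref) ||
        abs(nd$V - V_ref) > tol * max(1, V_ref))
      stop(sprintf("node %d: stale cached g/V", i), call. = FALSE)
  }
  invisible(TRUE)
}
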