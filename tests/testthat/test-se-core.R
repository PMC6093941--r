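test_that("degrees and total weight satisfy the handshake identity", {
  set.seed(3)
  for (rep in 1:10) {
    cm <- er_matrix(sample(3:10, 1), 0.5, weighted = TRUE)
    for (keep in c(FALSE, TRUE)) {
      g <- hic_graph(cm, keep_diagonal = keep)
      expect_equal(sum(g$degree), 2 * g$w, tolerance = 1e-9)
    }
  }
})

test_that("one-dimensional entropy matches hand-computed values", {
  expect_equal(one_dim_entropy(hic_graph(cycle_matrix(4))), 2)
  expect_equal(one_dim_entropy(hic_graph(contact_matrix(matrix(c(0, 1, 1, 0), 2)))), 1)
  # star on 4 vertices: degree distribution (1/2, 1/6, 1/6, 1/6)
  h_star <- -(1 / 2) * log2(1 / 2) - 3 * (1 / 6) * log2(1 / 6)
  expect_equal(one_dim_entropy(hic_graph(star_matrix(4))), h_star, tolerance = 1e-9)
  expect_equal(round(h_star, 5), 1.79248)
})

test_that("regular graphs saturate the one-dimensional entropy at log2 n", {
  for (n in c(2, 4, 8, 16))
    expect_equal(one_dim_entropy(hic_graph(cycle_matrix(n))), log2(n),
                 tolerance = 1e-12)
})

test_that("the one-module tree reproduces the one-dimensional entropy", {
  set.seed(7)
  for (rep in 1:50) {
    cm <- er_matrix(sample(3:12, 1), 0.5, weighted = TRUE)
    g <- hic_graph(cm)
    tr <- coding_tree(g, list(seq_len(g$n)))
    expect_equal(tree_entropy(tr), one_dim_entropy(g), tolerance = 1e-9)
  }
})

test_that("two disjoint cliques partitioned by clique score log2 s", {
  for (s in 2:6) {
    g <- hic_graph(clique_pair_matrix(s))
    tr <- coding_tree(g, list(1:s, (s + 1):(2 * s)))
    expect_equal(tree_entropy(tr), log2(s), tolerance = 1e-9)
    # cross-check against the scratch oracle
    expect_equal(naive_tree_entropy(tr), log2(s), tolerance = 1e-9)
  }
})

test_that("all-singleton modules on a 4-cycle give 2 bits", {
  g <- hic_graph(cycle_matrix(4))
  expect_equal(tree_entropy(coding_tree(g)), 2)
})

test_that("node entropy follows the per-node term with its conventions", {
  g <- hic_graph(contact_matrix(matrix(c(0, 1, 1, 0), 2)))
  tr <- coding_tree(g)                      # two singleton modules
  mods <- tr$nodes[[tr$root]]$children
  expect_equal(node_entropy(tr, mods[1]), 0.5)
  expect_error(node_entropy(tr, tr$root), "root")

  # an isolated clique as its own module has zero cut, hence zero term
  gq <- hic_graph(clique_pair_matrix(3))
  trq <- coding_tree(gq, list(1:3, 4:6))
  expect_equal(node_entropy(trq, trq$nodes[[trq$root]]$children[1]), 0)

  # a module whose volume equals the parent volume contributes nothing
  tr1 <- coding_tree(g, list(1:2))
  leafV <- tr1$nodes[[tr1$root]]$children[1]
  expect_equal(tr1$nodes[[leafV]]$V, tr1$nodes[[tr1$root]]$V)
  expect_equal(node_entropy(tr1, leafV), 0)
})

test_that("merging the two singleton modules of K2 leaves the entropy at 1 bit", {
  g <- hic_graph(contact_matrix(matrix(c(0, 1, 1, 0), 2)))
  tr <- coding_tree(g)
  mods <- tr$nodes[[tr$root]]$children
  expect_equal(merge_delta(tr, mods[1], mods[2]), 0)
  tr2 <- merge_nodes(tr, mods[1], mods[2])
  expect_equal(tree_entropy(tr), 1)
  expect_equal(tree_entropy(tr2), 1)
  validate_coding_tree(tr2)
})

test_that("merging clique modules raises the entropy to the 1D value", {
  g <- hic_graph(clique_pair_matrix(3))
  tr <- coding_tree(g, list(1:3, 4:6))
  mods <- tr$nodes[[tr$root]]$children
  tr2 <- merge_nodes(tr, mods[1], mods[2])
  expect_equal(tree_entropy(tr), log2(3), tolerance = 1e-9)
  expect_equal(tree_entropy(tr2), one_dim_entropy(g), tolerance = 1e-9)
  validate_coding_tree(tr2)
})

test_that("operators refuse non-sisters and the root", {
  g <- hic_graph(cycle_matrix(4))
  tr <- coding_tree(g, list(1:2, 3:4))
  mod1 <- tr$nodes[[tr$root]]$children[1]
  leaf_in_mod2 <- tr$nodes[[tr$nodes[[tr$root]]$children[2]]]$children[1]
  expect_error(merge_nodes(tr, mod1, leaf_in_mod2), "not sisters")
  expect_error(merge_nodes(tr, tr$root, mod1), "root")
  expect_error(combine_nodes(tr, mod1, mod1), "distinct")
})

test_that("incremental deltas equal scratch recomputation on random trees", {
  set.seed(19)
  for (rep in 1:60) {
    cm <- er_matrix(sample(4:12, 1), 0.5, weighted = TRUE)
    g <- hic_graph(cm)
    tr <- random_coding_tree(g, n_combines = sample(0:2, 1))
    sp <- sister_pairs(tr)
    ab <- sp[[sample(length(sp), 1)]]

    tr_m <- merge_nodes(tr, ab[1], ab[2])
    expect_equal(merge_delta(tr, ab[1], ab[2]),
                 naive_tree_entropy(tr) - naive_tree_entropy(tr_m),
                 tolerance = 1e-9)
    validate_coding_tree(tr_m)

    tr_c <- combine_nodes(tr, ab[1], ab[2])
    expect_equal(combine_delta(tr, ab[1], ab[2]),
                 naive_tree_entropy(tr) - naive_tree_entropy(tr_c),
                 tolerance = 1e-9)
    validate_coding_tree(tr_c)
  }
})

test_that("combining the two clique modules under the root changes nothing", {
  g <- hic_graph(clique_pair_matrix(3))
  tr <- coding_tree(g, list(1:3, 4:6))
  mods <- tr$nodes[[tr$root]]$children
  expect_equal(combine_delta(tr, mods[1], mods[2]), 0, tolerance = 1e-12)
  tr2 <- combine_nodes(tr, mods[1], mods[2])
  xi <- tr2$nodes[[length(tr2$nodes)]]
  expect_equal(xi$g, 0)
  expect_equal(xi$V, 2 * g$w)
  expect_equal(tree_entropy(tr2), tree_entropy(tr), tolerance = 1e-12)
})

test_that("combining depth-1 modules is refused under a height bound of 2", {
  g <- hic_graph(clique_pair_matrix(3))
  tr <- coding_tree(g)    # all singleton modules (height 2 with leaves)
  mods <- tr$nodes[[tr$root]]$children
  expect_error(combine_nodes(tr, mods[1], mods[2], max_height = 2),
               class = "dedocr_height_refusal")
  # without the bound the same combine succeeds
  expect_silent(validate_coding_tree(combine_nodes(tr, mods[1], mods[2])))
})

test_that("zero-degree vertices contribute nothing and stay indexed", {
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- 2
  g <- hic_graph(contact_matrix(A))
  expect_equal(g$degree[3:4], c(0, 0))
  expect_equal(one_dim_entropy(g), 1)
  tr <- coding_tree(g, list(1:2, 3L, 4L))
  # the connected pair's module has volume 2w (term 0); its two leaves carry
  # half a bit each; the zero-degree singletons contribute nothing
  expect_equal(tree_entropy(tr), 1)
  validate_coding_tree(tr)
})

test_that("self-contacts enter degrees as self-loops only when requested", {
  A <- matrix(c(3, 1, 1, 0), 2)
  cm <- contact_matrix(A)
  g0 <- hic_graph(cm)
  expect_equal(g0$degree, c(1, 1))
  g1 <- hic_graph(cm, keep_diagonal = TRUE)
  expect_equal(g1$degree, c(7, 1))
  expect_equal(sum(g1$degree), 2 * g1$w)
  # self-loops never cross a cut
  expect_equal(cut_weight(g1, 1L), 1)
})
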