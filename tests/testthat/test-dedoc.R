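test_that("the greedy caller separates two disjoint cliques exactly", {
  cm <- clique_pair_matrix(3)
  fit <- dedoc2(hic_graph(cm))
  expect_equal(fit$partition, list(1:3, 4:6))
  expect_equal(fit$entropy, log2(3), tolerance = 1e-9)
  # the greedy result here is the global height-2 optimum
  expect_equal(fit$entropy, exhaustive_min_entropy(as.matrix(cm$mat)),
               tolerance = 1e-9)
})

test_that("strictly positive gains are required: K2 stays all-singleton", {
  fit <- dedoc2(hic_graph(contact_matrix(matrix(c(0, 1, 1, 0), 2))))
  expect_equal(length(fit$partition), 2L)
  expect_equal(fit$n_merges, 0L)
  expect_equal(fit$entropy, 1)
})

test_that("accepted merges all gain and the trajectory is consistent", {
  set.seed(23)
  for (rep in 1:5) {
    cm <- er_matrix(10, 0.4, weighted = TRUE)
    g <- hic_graph(cm)
    fit <- dedoc2(g)
    if (length(fit$deltas)) expect_true(all(fit$deltas > 0))
    expect_equal(one_dim_entropy(g) - sum(fit$deltas), fit$entropy,
                 tolerance = 1e-9)
    # cached final entropy agrees with a from-scratch partition entropy
    expect_equal(partition_entropy(g, fit$partition), fit$entropy,
                 tolerance = 1e-9)
  }
})

test_that("the caller is deterministic on a fixed matrix", {
  sim <- planted_sim(1)
  a <- call_domains_E(sim$matrix)
  b <- call_domains_E(sim$matrix)
  expect_identical(a$domains, b$domains)
  expect_identical(a$entropy, b$entropy)
})

test_that("planted domains are recovered exactly at moderate domain size", {
  sim <- simulate_hic(21, c(0, 7, 14), background = 20, decay = 1,
                      enrichment = 6, seed = 1)
  ds <- call_domains_E(sim$matrix)
  expect_equal(ds$domains$start_bin, c(0L, 7L, 14L))
  expect_equal(ds$domains$end_bin, c(6L, 13L, 20L))
  dsA <- call_domains_E(sim$matrix, contiguity = "adjacent")
  expect_equal(dsA$domains, ds$domains)
})

test_that("free-mode calls on planted matrices drop no bins", {
  for (s in 1:5) {
    sim <- simulate_hic(16, c(0, 8), background = 20, decay = 1,
                        enrichment = 6, seed = s)
    ds <- call_domains_E(sim$matrix)
    expect_length(ds$dropped_bins, 0)
  }
})

test_that("adjacent mode always yields contiguous, tiling domains", {
  for (s in 1:5) {
    sim <- planted_sim(s)
    ds <- call_domains_E(sim$matrix, contiguity = "adjacent")
    d <- ds$domains
    expect_true(all(d$start_bin[-1] == d$end_bin[-nrow(d)] + 1))
    expect_equal(d$start_bin[1], 0L)
    expect_equal(d$end_bin[nrow(d)], sim$matrix$n_bins - 1L)
  }
})

test_that("a single-bin matrix yields a single one-bin domain", {
  ds <- call_domains_E(contact_matrix(matrix(5, 1, 1), binsize = 1000))
  expect_equal(nrow(ds$domains), 1L)
  expect_equal(ds$domains$start_bin, 0L)
  expect_equal(ds$domains$end_bin, 0L)
})

test_that("deDoc(M) refines a planted two-level hierarchy into nested domains", {
  sim <- simulate_hic(8, c(0, 4), background = 50, decay = 1, enrichment = 6,
                      sub_boundaries = c(0, 2, 4, 6), sub_enrichment = 1.3,
                      seed = 2)
  E <- call_domains_E(sim$matrix)
  M <- call_domains_M(sim$matrix)
  expect_equal(E$domains$start_bin, c(0L, 4L))
  expect_equal(M$domains$start_bin, c(0L, 2L, 4L, 6L))
  # nesting: every M-domain inside exactly one E-domain
  for (k in seq_len(nrow(M$domains))) {
    inside <- M$domains$start_bin[k] >= E$domains$start_bin &
      M$domains$end_bin[k] <= E$domains$end_bin
    expect_equal(sum(inside), 1L)
  }
  # E boundaries are a subset of M boundaries; WS is well-behaved
  expect_true(all(E$domains$start_bp %in% M$domains$start_bp))
  expect_lte(weighted_similarity(E, M), 1)
  expect_lte(weighted_similarity(M, E), 1)
  # both reported entropies are finite and positive (the flat height-2
  # entropy of the refinement may exceed the E partition's, since the
  # refinement optimizes within each domain's subgraph, not globally)
  expect_true(is.finite(M$entropy) && M$entropy > 0)
  expect_true(is.finite(M$entropy_depth3) && M$entropy_depth3 > 0)
})

test_that("indivisible two-bin domains pass through deDoc(M) unchanged", {
  sim <- simulate_hic(8, c(0, 2, 4, 6), background = 50, decay = 1,
                      enrichment = 8, seed = 1)
  E <- call_domains_E(sim$matrix)
  M <- call_domains_M(sim$matrix)
  expect_equal(M$domains[, c("start_bin", "end_bin")],
               E$domains[, c("start_bin", "end_bin")])
})

test_that("zero-contact bins are reported separately, never as domains", {
  A <- matrix(0, 6, 6)
  A[1:2, 1:2] <- 5; A[5:6, 5:6] <- 5; diag(A) <- 0
  A[2, 5] <- A[5, 2] <- 1   # connect the blocks so merges can fire
  cm <- contact_matrix(A)
  ds <- call_domains_E(cm)
  expect_setequal(ds$zero_bins, c(2L, 3L))
  called <- unlist(lapply(seq_len(nrow(ds$domains)), function(k)
    ds$domains$start_bin[k]:ds$domains$end_bin[k]))
  expect_false(any(c(2L, 3L) %in% called))
})
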