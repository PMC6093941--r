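test_that("the generator is reproducible and validates its configuration", {
  a <- simulate_hic(20, c(0, 10), background = 10, seed = 9)
  b <- simulate_hic(20, c(0, 10), background = 10, seed = 9)
  expect_identical(as.matrix(a$matrix$mat), as.matrix(b$matrix$mat))
  c <- simulate_hic(20, c(0, 10), background = 10, seed = 10)
  expect_false(identical(as.matrix(a$matrix$mat), as.matrix(c$matrix$mat)))

  expect_error(simulate_hic(20, c(5, 10), seed = 1), "beginning at 0")
  expect_error(simulate_hic(20, c(0, 25), seed = 1), "beginning at 0")
  expect_error(simulate_hic(20, c(0, 10), enrichment = 0.5, seed = 1),
               "enrichment")
  expect_error(simulate_hic(20, c(0, 5), sub_boundaries = c(0, 3), seed = 1),
               "refine")
})

test_that("without enrichment the expected count depends only on distance", {
  sim <- simulate_hic(60, c(0, 20, 40), background = 50, decay = 1,
                      enrichment = 1, seed = 13)
  M <- as.matrix(sim$matrix$mat)
  for (d in 0:3) {
    vals <- M[cbind(seq_len(60 - d), seq_len(60 - d) + d)]
    mu <- 50 * (1 + d)^-1
    # Poisson mean check within 4 standard errors
    expect_lt(abs(mean(vals) - mu), 4 * sqrt(mu / length(vals)))
  }
})

test_that("the planted truth tiles the matrix and matches the boundaries", {
  sim <- simulate_hic(30, c(0, 10, 20), seed = 2)
  d <- sim$truth$domains
  expect_equal(d$start_bin, c(0L, 10L, 20L))
  expect_equal(d$end_bin, c(9L, 19L, 29L))
  sim2 <- simulate_hic(12, c(0, 6), sub_boundaries = c(0, 3, 6, 9), seed = 2)
  expect_equal(sim2$truth_sub$domains$start_bin, c(0L, 3L, 6L, 9L))
})

test_that("binomial thinning preserves identity at 1 and the binomial law", {
  sim <- planted_sim(5, B = 50)
  cm <- sim$matrix
  expect_identical(downsample_matrix(cm, 1), cm)

  total <- total_weight(cm)
  thin <- downsample_matrix(cm, 0.1, seed = 77)
  sd_expect <- sqrt(total * 0.1 * 0.9)
  expect_lt(abs(total_weight(thin) - 0.1 * total), 4 * sd_expect)

  expect_error(downsample_matrix(cm, 0), "fraction")
  frac <- contact_matrix(matrix(c(0, 0.5, 0.5, 0), 2))
  expect_error(downsample_matrix(frac, 0.5), "integer counts")
})

test_that("thinning composes multiplicatively in distribution", {
  sim <- planted_sim(6, B = 200)
  cm <- sim$matrix
  tot <- total_weight(cm)
  two_step <- replicate(8, total_weight(
    downsample_matrix(downsample_matrix(cm, 0.4), 0.5)))
  one_step <- replicate(8, total_weight(downsample_matrix(cm, 0.2)))
  sd_tot <- sqrt(tot * 0.2 * 0.8)
  expect_lt(abs(mean(two_step) - mean(one_step)), 4 * sd_tot / sqrt(8) * 2)
  expect_lt(abs(mean(two_step) - 0.2 * tot), 4 * sd_tot / sqrt(8))
})

test_that("boundary recovery declines in expectation as data thin", {
  recs <- sapply(1:8, function(s) {
    sim <- planted_sim(s, B = 20)
    sapply(c(1, 0.2, 0.05), function(f) {
      thin <- downsample_matrix(sim$matrix, f, seed = s + 100)
      boundary_recovery(sim$truth, call_domains_E(thin),
                        tol_bp = sim$matrix$binsize)
    })
  })
  m <- rowMeans(recs)
  expect_gte(m[1] + 1e-9, m[3])
  expect_gte(m[1], 0.95)
})

test_that("matrix-to-pairs round-trips through binning", {
  sim <- planted_sim(8)
  pairs <- matrix_to_pairs(sim$matrix)
  cm2 <- bin_contact_pairs(pairs, sim$matrix$binsize,
                           sim$matrix$n_bins * sim$matrix$binsize)
  expect_equal(as.matrix(cm2$mat), as.matrix(sim$matrix$mat))
})
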