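test_that("score updates equal brute-force per-row/column averages", {
  expect_equal(unname(gene_scores(matrix(1:3, 1), c(1, 3))), 2)

  set.seed(4)
  x <- matrix(rnorm(25), 5, 5)
  s <- c(2L, 4L)
  f <- gene_scores(x, s)
  f_loop <- vapply(1:5, function(g) {
    tot <- 0
    for (j in s) tot <- tot + x[g, j]
    tot / length(s)
  }, numeric(1))
  expect_equal(unname(f), f_loop)

  x2 <- matrix(rnorm(24), 6, 4)
  g <- c(1L, 3L, 5L)
  h <- sample_scores(x2, g)
  h_loop <- vapply(1:4, function(s) mean(x2[g, s]), numeric(1))
  expect_equal(unname(h), h_loop)

  # a single gene's scores are that gene's row
  expect_equal(sample_scores(x2, 1L), x2[1L, ])
  expect_error(gene_scores(x, integer(0)), "empty")
  expect_error(sample_scores(x, integer(0)), "empty")
})

test_that("threshold selection applies the centred strict-inequality rule", {
  f <- c(10, 0, 0, 0, 0)
  # centred scores (8, -2, -2, -2, -2); cut 1/1 with |S| = 1
  expect_equal(select_genes(f, theta_g = 1, s_size = 1), 1L)
  expect_equal(select_genes(f, theta_g = 1, s_size = 1, denominator = "linear"), 1L)
  # all-equal scores: nothing exceeds a positive threshold
  expect_length(select_genes(rep(2, 6), 0.5, s_size = 4), 0)
  # vanishing threshold: everything strictly above the mean
  f2 <- c(1, 2, 3, 4)
  expect_equal(select_genes(f2, 1e-12, s_size = 100), 3:4)
  # mirrored rule for under-expression
  expect_equal(select_genes(-f, 1, 1, mode = "under"), 1L)
  expect_equal(select_samples(-f, 1, 1, mode = "under"), 1L)
})

test_that("a noiseless planted block is the fixed point reached from its columns", {
  x <- block_matrix(value = 3)
  b <- boa(x, init = 1:5, theta_g = 2, theta_s = 2, check = "none")
  expect_true(b$converged)
  expect_equal(b$genes, 1:10)
  expect_equal(b$samples, 1:5)
  # hand evaluation of one iteration from the fixed point reproduces it
  step <- one_iteration(x, b)
  expect_equal(step$genes, b$genes)
  expect_equal(step$samples, b$samples)

  # sign-flipped block found by the under-expression variant
  bu <- boa(-x, init = 1:5, theta_g = 2, theta_s = 2, mode = "under",
            check = "none")
  expect_true(bu$converged)
  expect_equal(bu$genes, 1:10)
  expect_equal(bu$samples, 1:5)
})

test_that("iteration collapse on pure noise returns an empty, non-converged fit", {
  set.seed(5)
  x <- matrix(rnorm(600), 30, 20)
  b <- boa(x, init = 11:14, theta_g = 50, theta_s = 50, check = "none")
  expect_false(b$converged)
  expect_equal(b$status, "empty")
  expect_length(b$genes, 0)
  expect_length(b$samples, 0)
})

test_that("the fit is deterministic and sign-symmetric", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(1200), 60, 20)
    x[1:12, 1:6] <- x[1:12, 1:6] + 2.5
    b1 <- boa(x, init = 1:6, theta_g = 2.5, theta_s = 2, check = "none")
    b2 <- boa(x, init = 1:6, theta_g = 2.5, theta_s = 2, check = "none")
    expect_equal(b1$genes, b2$genes)
    expect_equal(b1$samples, b2$samples)
    bu <- boa(-x, init = 1:6, theta_g = 2.5, theta_s = 2, mode = "under",
              check = "none")
    expect_equal(bu$genes, b1$genes)
    expect_equal(bu$samples, b1$samples)
    expect_equal(bu$converged, b1$converged)
  }
})

test_that("every converged fit is self-consistent under one extra iteration", {
  sim <- generate_matrix(small_design(), seed = 6)
  inits <- random_initializations(60, 20, 0.2, seed = 6)
  for (s0 in inits) {
    b <- boa(sim$x, s0, theta_g = 2.8, theta_s = 2, check = "none")
    if (!b$converged) next
    step <- one_iteration(sim$x, b)
    expect_equal(step$genes, b$genes)
    expect_equal(step$samples, b$samples)
  }
})

test_that("raw unnormalized input is flagged", {
  set.seed(7)
  x <- matrix(rnorm(600, mean = 8, sd = 4), 30, 20)
  expect_warning(boa(x, 1:4, 3, 2), "normalize")
  expect_error(boa(x, 1:4, 3, 2, check = "error"), "normalize")
  expect_silent(boa(normalize_matrix(x), 1:4, 3, 2))
})

test_that("random initializations honour the inclusion probability and seed", {
  inits <- random_initializations(124, 1000, 0.2, seed = 9)
  expect_length(inits, 1000)
  expect_true(all(lengths(inits) > 0))
  sizes <- lengths(inits)
  expect_gt(mean(sizes), 22)   # binomial mean 24.8
  expect_lt(mean(sizes), 28)
  expect_lte(min(sizes), 17)   # observed spread comparable to 14..41
  expect_gte(max(sizes), 33)
  expect_identical(inits, random_initializations(124, 1000, 0.2, seed = 9))

  # near-certain inclusion: subsets are the full sample set
  full <- random_initializations(5, 20, 1 - 1e-12, seed = 1)
  expect_true(all(vapply(full, identical, logical(1), 1:5)))
})
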