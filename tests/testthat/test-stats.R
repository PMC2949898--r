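test_that("hypergeometric tail matches enumeration and the library tail", {
  expect_equal(hypergeometric_tail(0, 3, 2, 10), 1)
  expect_equal(hypergeometric_tail(2, 2, 2, 4), 1 / 6)
  expect_equal(hypergeometric_tail(4, 5, 4, 10), 5 / 210)
  # small-case enumeration oracle
  expect_equal(hypergeometric_tail(2, 3, 4, 8), enum_tail(2, 3, 4, 8))
  expect_equal(hypergeometric_tail(3, 6, 5, 11), enum_tail(3, 6, 5, 11))
  # random cross-check against the distribution implementation
  set.seed(14)
  for (i in 1:50) {
    n <- sample(5:200, 1)
    m <- sample(0:n, 1)
    s <- sample(1:n, 1)
    k <- sample(0:min(m, s), 1)
    expect_equal(hypergeometric_tail(k, m, s, n),
                 phyper(k - 1, m, n - m, s, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(hypergeometric_tail(3, 2, 2, 4), "outside")
  expect_error(hypergeometric_tail(1, 5, 2, 4), "exceed")
})

test_that("log-space accumulation survives extreme enrichment", {
  p <- hypergeometric_tail(250, 515, 515, 7383)
  expect_gt(p, 0)
  expect_equal(log(p), phyper(249, 515, 7383 - 515, 515,
                              lower.tail = FALSE, log.p = TRUE),
               tolerance = 1e-9)
})

test_that("saturation scan finds the winning class subset", {
  ann <- sample_annotation(paste0("s", 1:10),
                           rep(c("a", "b", "c"), c(4, 3, 3)))
  # bicluster holding exactly all members of one class
  b_ids <- paste0("s", 1:4)
  scs <- scs_pvalue(b_ids, ann)
  expect_equal(scs$class_subset, "a")
  expect_equal(scs$p_value, hypergeometric_tail(4, 4, 4, 10))
  # degenerate full subset has p = 1 and never wins
  mcs <- mcs_pvalue(b_ids, ann)
  expect_lt(length(mcs$class_subset), 3)
  expect_equal(hypergeometric_tail(4, 10, 4, 10), 1)
})

test_that("MCS equals an independent brute-force subset scan", {
  set.seed(15)
  for (i in 1:25) {
    q <- sample(2:4, 1)
    n <- sample(8:30, 1)
    classes <- letters[1:q]
    lab <- sample(classes, n, replace = TRUE)
    lab[1:q] <- classes  # every class nonempty
    ids <- paste0("s", 1:n)
    ann <- sample_annotation(ids, lab)
    in_b <- sample(ids, sample(2:(n - 1), 1))

    # brute force over all nonempty subsets with the library tail
    best_p <- Inf
    best_sub <- NULL
    for (msk in 1:(2^q - 1)) {
      sub <- classes[bitwAnd(msk, 2^(seq_len(q) - 1)) > 0]
      m <- sum(lab %in% sub)
      k <- sum(lab[ids %in% in_b] %in% sub)
      p <- phyper(k - 1, m, n - m, length(in_b), lower.tail = FALSE)
      if (p < best_p) {
        best_p <- p
        best_sub <- sub
      }
    }
    got <- mcs_pvalue(in_b, ann)
    expect_equal(got$p_value, best_p, tolerance = 1e-12)
    expect_setequal(got$class_subset, best_sub)
    # SCS can never beat MCS: minimum over a superset of subsets
    expect_gte(scs_pvalue(in_b, ann)$p_value, got$p_value)
  }
})

test_that("unannotated samples are excluded from the saturation universe", {
  ann <- sample_annotation(paste0("s", 1:6), c("a", "a", "b", "b", NA, NA))
  res <- mcs_pvalue(paste0("s", c(1, 2, 5)), ann)  # s5 unannotated
  expect_equal(res$N, 4L)
  expect_equal(res$s_size, 2L)
  expect_equal(res$class_subset, "a")
})

test_that("concordant pair counting follows the strict-inequality definition", {
  # two classes of 2, perfectly concordant: all 4 cross pairs count
  expect_equal(jonckheere_U(c(1, 2, 10, 20), c(1, 1, 2, 2)), 4)
  expect_equal(jonckheere_U(c(10, 20, 1, 2), c(1, 1, 2, 2)), 0)
  expect_equal(jonckheere_U(c(3, 1, 4, 1), rep(1, 4)), 0)

  set.seed(16)
  for (i in 1:30) {
    n <- sample(3:50, 1)
    h <- rnorm(n)
    y <- sample(1:4, n, replace = TRUE)
    u_loop <- 0L
    for (a in 1:n) for (b in 1:n) {
      if (h[a] < h[b] && y[a] < y[b]) u_loop <- u_loop + 1L
    }
    expect_equal(jonckheere_U(h, y), u_loop)
  }
})

test_that("tie-free orderings split the cross pairs between both directions", {
  set.seed(17)
  h <- rnorm(12)
  y <- rep(1:3, each = 4)
  total_cross <- sum(outer(y, y, "<"))
  expect_equal(jonckheere_U(h, y) + jonckheere_U(-h, y), total_cross)
})

test_that("null moments match the closed forms", {
  tr <- jonckheere_test(c(2, 1), c(1, 2))
  expect_equal(tr$mu0, 0.5)
  expect_equal(tr$var0, (4 * 7 - 2 * 5) / 72)  # = 0.25

  # U equal to its null mean gives z = 0 and one-sided p = 1/2
  tr2 <- jonckheere_test(c(2, 1, 3), c(1, 2, 2))
  expect_equal(tr2$U, 1)
  expect_equal(tr2$mu0, 1)
  expect_equal(tr2$z, 0)
  expect_equal(tr2$p_value, 0.5)

  # permutation check of Eqs for a small partition
  set.seed(18)
  y <- rep(1:3, c(3, 3, 4))
  u_perm <- replicate(4000, jonckheere_U(sample(rnorm(10)), y))
  ref <- jonckheere_test(rnorm(10), y)
  se_mean <- sd(u_perm) / sqrt(length(u_perm))
  expect_lt(abs(mean(u_perm) - ref$mu0), 3 * se_mean)
  se_var <- sqrt((mean((u_perm - mean(u_perm))^4) - var(u_perm)^2) / length(u_perm))
  expect_lt(abs(var(u_perm) - ref$var0), 3 * se_var)
})

test_that("direction, sign and tie handling are reported", {
  y <- rep(1:3, each = 5)
  h_up <- seq_len(15) + rnorm(15, sd = 0.01)
  up <- jonckheere_test(h_up, y)
  expect_equal(up$direction, 1L)
  expect_equal(up$signed_p, up$p_value)
  down <- jonckheere_test(rev(h_up), y)
  expect_equal(down$direction, -1L)
  expect_lt(down$signed_p, 0)
  expect_false(up$ties)

  tied <- jonckheere_test(rep(c(1, 2, 3), each = 5), y, n_perm = 200, seed = 1)
  expect_true(tied$ties)
  expect_gt(tied$p_perm, 0)
  # seeded permutation p is reproducible
  expect_equal(tied$p_perm,
               jonckheere_test(rep(c(1, 2, 3), each = 5), y,
                               n_perm = 200, seed = 1)$p_perm)

  expect_error(jonckheere_test(rnorm(5), rep(1, 5)), "two classes")
})
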