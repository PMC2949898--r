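test_that("vanishing noise leaves exactly the planted shifts", {
  des <- planted_design(n_genes = 40, n_samples = 20,
                        class_sizes = c(A = 10L, B = 10L),
                        blocks = list(list(genes = 1:5, samples = 1:4,
                                           shift = 2, sign = 1L)),
                        noise_sd = 1e-12)
  sim <- generate_matrix(des, seed = 20)
  expect_equal(sim$x[1:5, 1:4], matrix(2, 5, 4, dimnames = dimnames(sim$x[1:5, 1:4])),
               tolerance = 1e-9)
  expect_equal(max(abs(sim$x[6:40, ])), 0, tolerance = 1e-9)
})

test_that("identical design and seed give a bitwise-identical matrix", {
  des <- small_design()
  a <- generate_matrix(des, seed = 21)
  b <- generate_matrix(des, seed = 21)
  expect_identical(a$x, b$x)
  expect_false(identical(a$x, generate_matrix(des, seed = 22)$x))
  # the caller's RNG stream is not consumed
  set.seed(1)
  before <- rnorm(1)
  set.seed(1)
  invisible(generate_matrix(des, seed = 21))
  expect_identical(rnorm(1), before)
})

test_that("class layout, ordinal map and annotation match the design", {
  des <- planted_design()
  sim <- generate_matrix(des, seed = 23)
  ann <- sim$annotation
  expect_equal(dim(sim$x), c(1500, 124))
  expect_equal(table(ann$class)[c("normal", "CG", "IM", "DGC", "IGC", "MGC")],
               table(rep(c("normal", "CG", "IM", "DGC", "IGC", "MGC"),
                         c(10, 26, 22, 35, 22, 7)))[
                 c("normal", "CG", "IM", "DGC", "IGC", "MGC")])
  expect_equal(sum(is.na(ann$class)), 2)  # unannotated singletons
  expect_equal(unique(ann$score[which(ann$class == "normal")]), 1)
  expect_equal(unique(ann$score[which(ann$class %in% c("DGC", "IGC", "MGC"))]), 4)
  # default blocks sit inside their target class groups
  b1 <- des$blocks[[1]]
  expect_true(all(ann$class[b1$samples] %in% c("normal", "CG")))
})

test_that("overlapping blocks add their shifts", {
  des <- planted_design(n_genes = 10, n_samples = 6,
                        class_sizes = c(A = 6L),
                        blocks = list(
                          list(genes = 1:4, samples = 1:3, shift = 1, sign = 1L),
                          list(genes = 3:6, samples = 2:4, shift = 2, sign = -1L)),
                        noise_sd = 1e-12)
  sim <- generate_matrix(des, seed = 24)
  expect_equal(sim$x[3, 2], 1 - 2, tolerance = 1e-9)
  expect_equal(sim$x[1, 1], 1, tolerance = 1e-9)
  expect_equal(sim$x[5, 3], -2, tolerance = 1e-9)
})

test_that("recovery scores are plain Jaccard overlaps", {
  sim <- generate_matrix(small_design(), seed = 25)
  truth <- sim$truth[[1]]
  b <- boa(sim$x, truth$samples, 2.8, 2, check = "none")
  exact <- biorder:::new_bicluster(
    genes = truth$genes, samples = truth$samples, gene_scores = NULL,
    sample_scores = NULL, theta_g = 1, theta_s = 1, mode = "over",
    denominator = "sqrt", variant = "threshold", iterations = 1L,
    converged = TRUE, status = "converged", init = truth$samples, init_id = 1L)
  expect_equal(unname(recovery_score(exact, truth)), c(1, 1))
  disjoint <- biorder:::new_bicluster(
    genes = 200:210, samples = 50:55, gene_scores = NULL, sample_scores = NULL,
    theta_g = 1, theta_s = 1, mode = "over", denominator = "sqrt",
    variant = "threshold", iterations = 1L, converged = TRUE,
    status = "converged", init = 50:55, init_id = 1L)
  expect_equal(unname(recovery_score(disjoint, truth)), c(0, 0))
  half <- biorder:::new_bicluster(
    genes = c(1, 2, 3), samples = truth$samples, gene_scores = NULL,
    sample_scores = NULL, theta_g = 1, theta_s = 1, mode = "over",
    denominator = "sqrt", variant = "threshold", iterations = 1L,
    converged = TRUE, status = "converged", init = truth$samples, init_id = 1L)
  half$genes <- c(truth$genes[1:15], 101:115)
  expect_equal(recovery_score(half, truth)[["gene_jaccard"]], 15 / 45)
  # the full fit recovers the planted block here
  expect_gte(recovery_score(b, truth)[["gene_jaccard"]], 0.9)
})

test_that("recovery improves with the planted shift", {
  rates <- vapply(c(1, 2, 3), function(shift) {
    sim <- generate_matrix(small_design(shift = shift), seed = 26)
    inits <- random_initializations(60, 15, 0.2, seed = 26)
    mean(vapply(inits, function(s0) {
      b <- boa(sim$x, s0, 2.8, 2, check = "none")
      if (!b$converged) return(0)
      recovery_score(b, sim$truth[[1]])[["gene_jaccard"]]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rates) >= -0.02))   # non-decreasing up to noise
  expect_gt(rates[3], rates[1])
})
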