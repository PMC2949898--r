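# Fixture builders shared across test files.  Everything is generated in
# code; sizes are kept small so the default run stays fast.

# noiseless matrix with a single constant block; selection rules keep the
# block exactly at the thresholds used in the tests
block_matrix <- function(n_g = 30L, n_s = 20L, block_g = 1:10, block_s = 1:5,
                         value = 3) {
  x <- matrix(0, n_g, n_s,
              dimnames = list(paste0("g", seq_len(n_g)),
                              paste0("s", seq_len(n_s))))
  x[block_g, block_s] <- value
  x
}

# small planted design on the standardized scale (unit noise background)
small_design <- function(shift = 3, n_genes = 300L, n_samples = 60L,
                         block_genes = 1:30, block_samples = 15L) {
  planted_design(
    n_genes = n_genes, n_samples = n_samples,
    class_sizes = c(A = 20L, B = 20L, C = 20L),
    blocks = list(list(genes = block_genes, n_samples = block_samples,
                       classes = "A", shift = shift, sign = 1L))
  )
}

# one extra hand-evaluated BOA iteration from a converged state
one_iteration <- function(x, b) {
  f <- gene_scores(x, b$samples)
  g <- select_genes(f, b$theta_g, length(b$samples), b$denominator, b$mode)
  h <- sample_scores(x, g)
  s <- select_samples(h, b$theta_s, length(g), b$denominator, b$mode)
  list(genes = g, samples = s)
}

# independent hypergeometric upper tail via full enumeration of draws:
# population 1..n with 1..m marked, all size-s subsets equally likely
enum_tail <- function(k, m, s, n) {
  draws <- utils::combn(n, s)
  counts <- colSums(draws <= m)
  mean(counts >= k)
}
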