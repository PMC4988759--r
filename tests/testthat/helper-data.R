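# small builders used across test files

toy_counts <- function(mat = matrix(c(10L, 0L, 7L, 20L, 5L, 7L), nrow = 3),
                       genes = paste0("g", seq_len(nrow(mat))),
                       samples = paste0("s", seq_len(ncol(mat))),
                       labels = NULL) {
  dimnames(mat) <- list(genes, samples)
  if (is.null(labels))
    labels <- stats::setNames(rep(c("A", "B"), length.out = ncol(mat)),
                              samples)
  count_matrix(mat, labels)
}

# lognorm container straight from a value matrix (bypasses counts) for
# variance-curve tests that need exact Gaussian noise
lognorm_from_values <- function(values, labels) {
  structure(list(values = values, class_labels = labels,
                 pseudocount = 0, scale = "common",
                 lib_sizes = rep(1, ncol(values))),
            class = "lognorm_matrix")
}

gaussian_lognorm <- function(n_genes, m_per_class, sd = 0.5, seed = 1,
                             a_center = stats::runif(n_genes, -15, -5)) {
  set.seed(seed)
  m <- m_per_class
  vals <- matrix(rep(a_center, 2 * m), ncol = 2 * m) +
    matrix(stats::rnorm(n_genes * 2 * m, sd = sd), ncol = 2 * m)
  samples <- c(paste0("X_", seq_len(m)), paste0("Y_", seq_len(m)))
  dimnames(vals) <- list(sprintf("g%04d", seq_len(n_genes)), samples)
  lognorm_from_values(vals, stats::setNames(rep(c("X", "Y"), each = m),
                                            samples))
}
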