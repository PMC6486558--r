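# Shared fixtures and independent oracles for the test suite.

# Brute-force mutual information between binary type membership and binary
# gene status from the full joint distribution: I(T;G) = H(T)+H(G)-H(T,G).
# Independent of the conditional-entropy decomposition the package uses.
oracle_mutual_information <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  joint <- c(n11, n10, n01, n00) / n
  h <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  h_t <- h(c(n11 + n10, n01 + n00) / n)
  h_g <- h(c(n11 + n01, n10 + n00) / n)
  h_t + h_g - h(joint)
}

# A tiny dense expression fixture written to disk: 3 genes x 2 cells.
write_tiny_dense <- function(path) {
  writeLines(c("gene\tc1\tc2", "A\t0\t2", "B\t5\t0", "C\t1\t1"), path)
  path
}

# Small, quickly separable synthetic configuration used where the full
# default sizes would be wasteful.
small_synth <- function(seed, n_types = 4L, cells_per_type = 100L) {
  synthetic_config(n_types = n_types, markers_per_type = 20L,
                   n_background_genes = 300L, cells_per_type = cells_per_type,
                   seed = seed)
}

# Fast training settings matched to the small fixture sizes: small batches
# and a higher learning rate compensate for the few updates per epoch.
fast_train <- function(seed, max_epochs = 15L, batch_size = 64L,
                       learning_rate = 0.05) {
  train_config(batch_size = batch_size, max_epochs = max_epochs,
               patience = 5L, learning_rate = learning_rate, seed = seed)
}

# Random sparse count matrix (genes x cells) for round-trip tests.
random_count_matrix <- function(seed, n_genes = 30L, n_cells = 12L,
                                density = 0.2) {
  withr::with_seed(seed, {
    m <- matrix(0, n_genes, n_cells)
    nz <- sample(length(m), round(length(m) * density))
    m[nz] <- sample(1:20, length(nz), replace = TRUE)
    dimnames(m) <- list(sprintf("G%03d", seq_len(n_genes)),
                        sprintf("CELL%02d", seq_len(n_cells)))
    m
  })
}
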