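# shared small fixtures; everything is generated in code at test time

small_spec <- function(seed = 1L, ...) {
  synthetic_spec(chrom_length = 8e6, resolution = 4e4, seed = seed, ...)
}

balanced_small <- function(seed = 1L, ...) {
  sim <- generate_hic(small_spec(seed = seed, ...))
  list(bal = ice_balance(mask_low_coverage(sim$matrix)), truth = sim$truth,
       raw = sim$matrix)
}

# Rand index between two partitions (pair-counting)
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# dense contact matrix from a hand-written symmetric matrix
cm_from_dense <- function(m, resolution = 1e4, state = "raw") {
  n <- nrow(m)
  idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  bt <- bin_table("chrT", n * resolution, resolution)
  contact_matrix(bt, idx[, 1] - 1L, idx[, 2] - 1L, m[idx], state = state)
}
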