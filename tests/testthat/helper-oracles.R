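# Independent brute-force oracles used to check the analytical machinery.
# Each is written from the definition, not from the implementation path
# it verifies.

# Signed-rank tail by exhaustive enumeration of every sign assignment.
oracle_signed_rank <- function(d, alternative = "two.sided") {
  d <- d[is.finite(d) & d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  lower <- mean(w_all <= w_obs + 1e-9)
  upper <- mean(w_all >= w_obs - 1e-9)
  switch(alternative,
         greater = upper,
         less = lower,
         two.sided = min(1, 2 * min(lower, upper)))
}

# Hypergeometric tail from the combinatorial definition.
oracle_hyper <- function(N, m, n, k, tail) {
  pmf <- function(j) choose(m, j) * choose(N - m, n - j) / choose(N, n)
  ks <- if (tail == "upper") k:min(m, n) else 0:k
  sum(vapply(ks, pmf, numeric(1)))
}

# Naive O(n^3) UPGMA agglomeration returning the cophenetic matrix and
# the sorted merge heights.
oracle_upgma <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  members <- lapply(seq_len(n), identity)
  active <- rep(TRUE, n + (n - 1))
  dmat <- matrix(NA_real_, n + (n - 1), n + (n - 1))
  dmat[1:n, 1:n] <- d
  coph <- matrix(0, n, n)
  heights <- numeric(n - 1)
  members <- c(members, vector("list", n - 1))
  active[(n + 1):(2 * n - 1)] <- FALSE
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    best <- c(NA, NA); bestd <- Inf
    for (ii in seq_along(idx)) for (jj in seq_along(idx)) {
      if (jj <= ii) next
      a <- idx[ii]; b <- idx[jj]
      if (dmat[a, b] < bestd) { bestd <- dmat[a, b]; best <- c(a, b) }
    }
    a <- best[1]; b <- best[2]
    new <- n + step
    members[[new]] <- c(members[[a]], members[[b]])
    heights[step] <- bestd
    for (x in members[[a]]) for (y in members[[b]]) {
      coph[x, y] <- coph[y, x] <- bestd
    }
    active[c(a, b)] <- FALSE
    active[new] <- TRUE
    for (o in which(active)) {
      if (o == new) next
      # unweighted average of original pairwise distances
      pairs <- expand.grid(members[[new]], members[[o]])
      dmat[new, o] <- dmat[o, new] <- mean(d[cbind(pairs[[1]], pairs[[2]])])
    }
  }
  list(cophenetic = coph, heights = sort(heights))
}

# Small fast synthetic spec shared across tests.
tiny_spec <- function(seed = 42, noise = 0.35, n_genes = 80,
                      block_size = 6, shared_size = 8, n_null = 4) {
  synthetic_spec(
    n_genes = n_genes, probes_per_gene = 11,
    planted_blocks = default_planted_blocks(block_size = block_size,
                                            shared_size = shared_size),
    noise_sd_log2 = noise,
    categories = default_categories(size = 12, fraction = 0.5, n_null = n_null),
    seed = seed)
}

# Write a small gene-level matrix + sheet pair to temp files.
write_fixture_matrix <- function(values, samples, probe_index = NULL,
                                 feature_ids = rownames(values)) {
  mat <- expr_matrix(values, feature_ids, samples, probe_index = probe_index)
  paths <- c(tempfile(fileext = ".tsv"), tempfile(fileext = ".tsv"))
  write_expression_matrix(mat, paths[1], paths[2])
  paths
}

sheet_4x3 <- function(conditions = c("G9", "S9", "G22", "S22"), reps = 3) {
  data.frame(
    sample_id = as.vector(t(outer(conditions, seq_len(reps), paste, sep = "_r"))),
    condition = rep(conditions, each = reps),
    replicate = rep(seq_len(reps), length(conditions)),
    stringsAsFactors = FALSE)
}
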