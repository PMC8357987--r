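# Independent brute-force oracles used to cross-check the implementation.

# Greedy pruning reference: at every step re-derives the most significant
# remaining marker and the removal set from the full correlation matrix.
prune_reference <- function(stats, mat, r_cutoff, use_abs = TRUE) {
  id_col <- if ("cpg_id" %in% names(stats)) "cpg_id" else "snp_id"
  ids <- as.character(stats[[id_col]])
  cm <- stats::cor(unclass(mat)[, ids, drop = FALSE])
  if (use_abs) cm <- abs(cm)
  active <- seq_len(nrow(stats))
  kept <- integer()
  while (length(active)) {
    o <- active[order(stats$p[active], ids[active])]
    pick <- o[1]
    kept <- c(kept, pick)
    active <- setdiff(active, pick)
    if (length(active)) {
      drop <- active[cm[ids[active], ids[pick]] >= r_cutoff]
      active <- setdiff(active, drop)
    }
  }
  stats[kept, , drop = FALSE]
}

# Naive per-sample accumulation of a weighted marker sum.
weighted_sum_reference <- function(weights, ids, mat) {
  v <- unclass(mat)
  out <- numeric(nrow(v))
  for (s in seq_len(nrow(v))) {
    tot <- 0
    for (j in seq_along(ids)) tot <- tot + weights[j] * v[s, ids[j]]
    out[s] <- tot
  }
  stats::setNames(out, rownames(v))
}

# Random marker statistics + matching beta matrix for pruning tests.
random_prune_instance <- function(n_markers, n_samples = 40) {
  ids <- sprintf("cg%03d", sample.int(999, n_markers))
  # latent factor structure induces a mix of strong and weak correlations
  k <- sample(2:4, 1)
  L <- matrix(rnorm(n_markers * k), n_markers)
  z <- matrix(rnorm(n_samples * k), n_samples) %*% t(L) +
    matrix(rnorm(n_samples * n_markers), n_samples)
  b <- stats::plogis(scale(z))
  colnames(b) <- ids
  rownames(b) <- sprintf("S%03d", seq_len(n_samples))
  list(stats = data.frame(cpg_id = ids, effect = rnorm(n_markers),
                          se = runif(n_markers, 0.1, 1),
                          p = runif(n_markers), stringsAsFactors = FALSE),
       beta = omics_matrix(b, "beta"))
}

# Small default cohort shared by several tests.
tiny_cohort <- function(seed = 11, ...) {
  simulate_cohort(sim_config(n_pairs = 150, n_cpgs = 60, n_snps = 60,
                             n_causal_cpgs = 10, n_causal_snps = 10,
                             seed = seed, ...))
}
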