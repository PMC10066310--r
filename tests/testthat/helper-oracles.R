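# Independent oracles used to validate the package implementations.
# Everything here is deliberately naive (dense, double-loop, direct
# formulas) and shares no code path with the package internals.

# Needleman-Wunsch global alignment score, linear gap cost, plain DP.
nw_score_oracle <- function(a, b, mat = blosum45_matrix(), gap = 10) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  H[, 1] <- -gap * (0:n)
  H[1, ] <- -gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      H[i + 1, j + 1] <- max(H[i, j] + mat[A[i], B[j]],
                             H[i, j + 1] - gap,
                             H[i + 1, j] - gap)
    }
  }
  H[n + 1, m + 1]
}

# Dense direct evaluation of ln D(q, lambda): no chunking, no log-sum-exp.
oracle_ln_diversity <- function(freqs, dmat, q, lambda) {
  zp <- if (is.infinite(lambda)) {
    freqs
  } else {
    as.vector(exp(-lambda * dmat) %*% freqs)
  }
  if (is.infinite(q)) {
    log(1 / max(zp))
  } else if (q == 1) {
    -sum(freqs * log(zp))
  } else {
    log(sum(freqs * zp^(q - 1))) / (1 - q)
  }
}

oracle_grid <- function(freqs, dmat, grid = parameter_grid()) {
  lambdas <- c(grid$lambda, if (grid$include_identity) Inf)
  vapply(lambdas, function(l) {
    vapply(grid$q, function(q) oracle_ln_diversity(freqs, dmat, q, l),
           numeric(1))
  }, numeric(length(grid$q)))
}

# Frequency-weighted mean pairwise distance sum_ij p_i p_j d_ij.
oracle_dbar <- function(freqs, dmat) {
  as.numeric(t(freqs) %*% dmat %*% freqs)
}

# O(n^3) complete-linkage agglomeration; returns the merge heights in order.
complete_linkage_heights_oracle <- function(D) {
  D <- as.matrix(D)
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- max(D[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, j, i)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# Random canonical peptides (plain sampling; independent of the package's
# motif-based generator).
rand_peptides <- function(n, len = c(6, 14)) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  lens <- len[1]:len[2]
  vapply(seq_len(n), function(i) {
    paste(sample(aa, lens[sample.int(length(lens), 1)], replace = TRUE),
          collapse = "")
  }, character(1))
}

# Random positive frequency vector.
rand_freqs <- function(S) {
  u <- runif(S, 0.05, 1)
  u / sum(u)
}

# A small sequence repertoire with heterogeneous frequencies, for oracle
# comparisons; uses the package generator for sequences only.
make_test_repertoire <- function(seed, S = 40) {
  ct <- make_mock_repertoire(
    mock_spec(S = S, size_law = "dirichlet", conc = 0.7,
              n_motifs = 3, mutations_per_step = 2),
    sample_id = sprintf("test_%d", seed), seed = seed)
  as_tcr_repertoire(ct)
}
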