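# Independent oracles used to cross-check the implementation. These are
# deliberately naive (loops, full enumeration) and share no code with the
# package internals they verify.

# Textbook UPGMA: cluster dissimilarity = mean over all cross-cluster pairs
# of the ORIGINAL dissimilarity, merging the closest pair each step.
naive_upgma_heights <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d) {
          best_d <- dd
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Triple-loop topological overlap.
naive_tom <- function(a) {
  n <- nrow(a)
  out <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l_ij <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l_ij <- l_ij + a[i, u] * a[u, j]
      }
      k_i <- sum(a[i, -i])
      k_j <- sum(a[j, -j])
      denom <- min(k_i, k_j) + 1 - a[i, j]
      out[i, j] <- if (denom == 0) 0 else (l_ij + a[i, j]) / denom
    }
  }
  dimnames(out) <- dimnames(a)
  out
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled values to the two groups; two-sided tail by symmetry of U around
# n1*n2/2 (valid for tie-free inputs).
enumerate_mw_p <- function(x, y) {
  n1 <- length(x)
  pool <- c(x, y)
  n <- length(pool)
  u_obs <- sum(rank(pool)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  u_null <- apply(combos, 2, function(idx) {
    sum(rank(pool)[idx]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * (n - n1) / 2
  mean(abs(u_null - mu) >= abs(u_obs - mu))
}

# Direct hypergeometric upper-tail sum P(X >= k).
hyper_upper <- function(k, term_size, bg_size, module_size) {
  ks <- k:min(term_size, module_size)
  if (k > min(term_size, module_size)) return(0)
  sum(choose(term_size, ks) * choose(bg_size - term_size, module_size - ks)) /
    choose(bg_size, module_size)
}

# Random valid adjacency matrix: symmetric, unit diagonal, entries in [0,1].
random_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  a
}

# Small study built from an explicit matrix.
make_study <- function(values, n_cancer, name = "test") {
  n <- ncol(values)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(n))
  }
  grp <- stats::setNames(
    rep(c("cancer", "normal"), c(n_cancer, n - n_cancer)), colnames(values))
  expression_study(values, grp, name = name)
}

# Config for the degradation harness: small, moderately noisy modules in
# two correlated meta-branches, where rewiring has measurable effect on
# eigengene preservation.
degradation_config <- function(seed = 1L) {
  sim_config(
    n_genes = 100, module_sizes = rep(10L, 8), factor_loading = 0.6,
    branches = rep(1:2, each = 4), branch_cor = 0.8, seed = seed
  )
}
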