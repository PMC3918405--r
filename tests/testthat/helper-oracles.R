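# Fixtures and independent brute-force oracles used across tests.

random_traits <- function(n, p, seed, mu = 50, sd = 10) {
  set.seed(seed)
  trait_matrix(matrix(rnorm(n * p, mu, sd), n, p))
}

# Brute-force LDSS: recompute the full distance matrix of the survivors
# from scratch at every step and take the global minimum pair
# (lexicographic tie-break), mirroring the definition rather than the
# package's incremental implementation. The coin flips are replayed from
# the recorded trace (kept vs removed), so only the pair choice and its
# distance are independently derived.
brute_force_ldss_check <- function(matrix, result) {
  z <- standardize(matrix)
  metric <- result$metric
  alive <- accessions(matrix)
  for (step in seq_len(nrow(result$trace))) {
    D <- as.matrix(trait_distance(z[alive, , drop = FALSE], metric,
                                  reference = z))
    diag(D) <- Inf
    best <- Inf; best_pair <- NULL
    for (i in seq_len(nrow(D) - 1L)) {
      for (j in seq.int(i + 1L, nrow(D))) {
        if (D[i, j] < best) { best <- D[i, j]; best_pair <- c(i, j) }
      }
    }
    pair_ids <- alive[best_pair]
    tr <- result$trace[step, ]
    if (!setequal(c(tr$removed, tr$kept), pair_ids)) return(FALSE)
    if (abs(tr$distance - best) > 1e-9) return(FALSE)
    alive <- setdiff(alive, tr$removed)
  }
  setequal(alive, result$selected)
}

# Brute-force compact-letter count: all maximal cliques of the
# non-significance graph (isolated vertices count as their own clique).
brute_force_cld_count <- function(sig) {
  k <- nrow(sig)
  nonsig <- !sig
  diag(nonsig) <- TRUE
  subsets <- lapply(seq_len(2^k - 1L), function(m) which(bitwAnd(m, 2^(seq_len(k) - 1L)) > 0))
  is_clique <- vapply(subsets, function(s) all(nonsig[s, s]), logical(1))
  cliques <- subsets[is_clique]
  maximal <- vapply(seq_along(cliques), function(i) {
    !any(vapply(seq_along(cliques), function(j) {
      i != j && all(cliques[[i]] %in% cliques[[j]])
    }, logical(1)))
  }, logical(1))
  sum(maximal)
}

# Tukey-Kramer significance matrix computed independently (direct
# formula), for feeding the brute-force CLD.
tukey_sig_matrix <- function(values, groups, alpha = 0.05) {
  lev <- unique(groups)
  k <- length(lev)
  ni <- vapply(lev, function(g) sum(groups == g), 1L)
  mi <- vapply(lev, function(g) mean(values[groups == g]), numeric(1))
  df <- length(values) - k
  mse <- sum((values - mi[match(groups, lev)])^2) / df
  sig <- matrix(FALSE, k, k)
  for (a in seq_len(k - 1)) {
    for (b in seq.int(a + 1, k)) {
      q <- abs(mi[a] - mi[b]) / sqrt((mse / 2) * (1 / ni[a] + 1 / ni[b]))
      p <- stats::ptukey(q, k, df, lower.tail = FALSE)
      sig[a, b] <- sig[b, a] <- p < alpha
    }
  }
  list(sig = sig, means = mi, levels = lev)
}
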