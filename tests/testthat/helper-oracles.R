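# Independent brute-force oracles used to validate the package's
# implementations. These deliberately re-derive each quantity from its
# definition rather than calling the code under test.

# Trimmed mean of M-values, step by step from its published definition:
# reference = sample whose upper-quartile CPM is closest to the mean;
# per-sample factor = inverse-variance weighted mean of M values after
# trimming the extremes of M and of average abundance; factors rescaled to
# geometric mean 1.
tmm_oracle <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, function(x) quantile(x / sum(x), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(s) {
    obs <- counts[, s] / lib[s]
    refv <- counts[, ref] / lib[ref]
    keep <- obs > 0 & refv > 0
    M <- log2(obs[keep] / refv[keep])
    A <- (log2(obs[keep]) + log2(refv[keep])) / 2
    if (max(abs(M)) < 1e-6) return(1)
    v <- (lib[s] - counts[keep, s]) / (lib[s] * counts[keep, s]) +
      (lib[ref] - counts[keep, ref]) / (lib[ref] * counts[keep, ref])
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * sum_trim) + 1; hiA <- n + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep2] / v[keep2]) / sum(1 / v[keep2]))
  }, 1.0)
  f / exp(mean(log(f)))
}

# BDeu family marginal likelihood by the sequential predictive product:
# P(x_1..x_n) = prod_s P(x_s | x_1..x_{s-1}) with Dirichlet-multinomial
# posterior predictive probabilities. An algebraically different route to
# the same quantity as the closed-form gamma expression.
bdeu_sequential_oracle <- function(states_node, states_parents, r, q_states,
                                   ess) {
  q <- if (length(q_states)) prod(q_states) else 1
  a_jk <- ess / (q * r)
  a_j <- ess / q
  n_jk <- matrix(0, nrow = q, ncol = r)
  logp <- 0
  n <- length(states_node)
  for (s in seq_len(n)) {
    j <- 1
    if (length(q_states)) {
      stride <- 1
      for (p in seq_along(q_states)) {
        j <- j + states_parents[[p]][s] * stride
        stride <- stride * q_states[p]
      }
    }
    k <- states_node[s] + 1
    logp <- logp + log((a_jk + n_jk[j, k]) / (a_j + sum(n_jk[j, ])))
    n_jk[j, k] <- n_jk[j, k] + 1
  }
  logp
}

# Bounded-depth reachability by repeated adjacency-matrix multiplication.
bfs_oracle <- function(adj, node, max_path) {
  nodes <- rownames(adj)
  reach <- setNames(rep(FALSE, length(nodes)), nodes)
  frontier <- adj[node, ] > 0
  steps <- 0
  while (any(frontier) && steps < max_path) {
    reach <- reach | frontier
    steps <- steps + 1
    if (steps >= max_path) break
    frontier <- (colSums(adj[frontier, , drop = FALSE]) > 0) & !reach
  }
  setdiff(nodes[reach], node)
}

# Benjamini-Hochberg by the textbook step-up definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  q
}

# Hypergeometric upper tail by direct summation of point masses.
hyper_tail_oracle <- function(overlap, n_fg, n_cat, n_universe) {
  ks <- overlap:min(n_fg, n_cat)
  sum(dhyper(ks, n_cat, n_universe - n_cat, n_fg))
}

# Small deterministic count fixture.
toy_counts <- function(n_genes = 20, n_samples = 6, seed = 42,
                       lambda = 100) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda), nrow = n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%d", seq_len(n_samples))))
  m
}

# A small cached default cohort + preprocessing shared across test files.
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- simulate_cohort(seed = 101L)
      norm <- suppressWarnings(preprocess_counts(co$counts, co$batches))
      cache <<- list(cohort = co, norm = norm)
    }
    cache
  }
})
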