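# Independent oracles used across the suite. These re-derive expected values
# by brute force or closed form and stay independent of the package's own
# code paths.

# Full Bron-Kerbosch maximal-clique enumeration (with pivoting).
bk_maximal_cliques <- function(g) {
  labs <- igraph::V(g)$name
  n <- igraph::vcount(g)
  adj <- lapply(seq_len(n), function(i) as.integer(igraph::neighbors(g, i)))
  out <- list()
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      out[[length(out) + 1L]] <<- sort(R)
      return(invisible(NULL))
    }
    pool <- c(P, X)
    u <- pool[which.max(vapply(pool, function(v) sum(P %in% adj[[v]]),
                               integer(1)))]
    for (v in setdiff(P, adj[[u]])) {
      bk(c(R, v), intersect(P, adj[[v]]), intersect(X, adj[[v]]))
      P <- setdiff(P, v)
      X <- union(X, v)
    }
    invisible(NULL)
  }
  bk(integer(0), seq_len(n), integer(0))
  lapply(out, function(i) sort(labs[i]))
}

# Exhaustive hypergeometric upper tail by enumerating every draw of n items
# from an urn of N with K marked (small N only).
hyper_tail_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  overlaps <- apply(draws, 2L, function(d) sum(d %in% marked))
  mean(overlaps >= k)
}

# Hypergeometric upper tail by log-gamma summation.
hyper_tail_lgamma <- function(N, K, n, k) {
  ks <- k:min(n, K)
  ks <- ks[ks >= max(0L, n + K - N)]
  if (!length(ks)) return(0)
  lt <- lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)
  m <- max(lt)
  exp(m) * sum(exp(lt - m))
}

# Benjamini-Hochberg step-up arithmetic, written out directly.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Jonckheere-Terpstra W computed directly from its definition (double loop).
jt_W_direct <- function(x, g) {
  g <- as.integer(factor(g, levels = sort(unique(g))))
  W <- 0
  n <- length(x)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (g[a] < g[b]) {
        W <- W + (x[a] < x[b]) + 0.5 * (x[a] == x[b])
      }
    }
  }
  W
}

# Mean local clustering coefficient by direct triangle counting.
clustering_direct <- function(g) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  vals <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    d <- length(nb)
    if (d < 2L) return(0)
    sum(A[nb, nb]) / 2 / choose(d, 2)
  }, numeric(1))
  mean(vals)
}
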