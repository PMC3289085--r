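# Independent oracles, sharing no helpers with the package internals:
# - a naive matrix-based re-implementation of the greedy expansion policy;
# - Floyd-Warshall induced diameters;
# - exhaustive subset enumeration for the hypergeometric tail.

# Adjacency (0/1) and weight matrices from an edge table.
oracle_matrices <- function(edges) {
  ids <- sort(unique(c(edges$u, edges$v)))
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  for (r in seq_len(nrow(edges))) {
    u <- edges$u[r]; v <- edges$v[r]
    A[u, v] <- A[v, u] <- 1
    W[u, v] <- W[v, u] <- edges$total[r]
  }
  list(ids = ids, A = A, W = W)
}

# Floyd-Warshall diameter of the subgraph induced by `members`.
oracle_diameter <- function(members, A) {
  k <- length(members)
  if (k == 1L) return(0)
  D <- matrix(Inf, k, k)
  diag(D) <- 0
  sub <- A[members, members, drop = FALSE]
  D[sub == 1] <- 1
  for (m in seq_len(k)) {
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (D[i, m] + D[m, j] < D[i, j]) D[i, j] <- D[i, m] + D[m, j]
      }
    }
  }
  max(D)
}

# Naive greedy expansion: at every step recompute, from scratch, every
# external adjacent vertex's E = sum(W[v, K]) / (internal weight of K),
# rank by (-E, -e, id), and admit the first candidate with E >= t_in whose
# admission keeps the full induced diameter <= d.
oracle_extend <- function(seed, edges, t_in, d) {
  mats <- oracle_matrices(edges)
  A <- mats$A; W <- mats$W; ids <- mats$ids
  K <- seed
  nb <- ids[A[seed, ] == 1]
  if (length(nb) == 0L) return(K)
  wts <- W[seed, nb]
  first <- nb[order(-wts, nb)][1L]
  K <- c(K, first)
  repeat {
    outside <- setdiff(ids, K)
    adjacent <- outside[vapply(outside, function(v) any(A[v, K] == 1), TRUE)]
    if (length(adjacent) == 0L) break
    w_k <- sum(W[K, K]) / 2
    e <- vapply(adjacent, function(v) sum(W[v, K]), 0)
    E <- e / w_k
    ord <- order(-E, -e, adjacent)
    pick <- NA_character_
    for (i in ord) {
      if (!isTRUE(E[[i]] >= t_in)) next
      if (oracle_diameter(c(K, adjacent[i]), A) <= d) {
        pick <- adjacent[i]
        break
      }
    }
    if (is.na(pick)) break
    K <- c(K, pick)
  }
  K
}

# Exhaustive hypergeometric upper tail: enumerate every cluster_size-subset
# of 1..n and count those with at least k members in the group {1..f}.
enum_hyper_tail <- function(n, f, cs, k) {
  subsets <- utils::combn(n, cs)
  mean(colSums(subsets <= f) >= k)
}
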