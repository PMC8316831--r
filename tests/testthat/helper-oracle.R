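# Independent brute-force reference implementations of the network panel,
# kept deliberately naive (Floyd-Warshall, direct neighbor-pair
# enumeration) and separate from the package's BFS / sparse-matrix code
# paths.  Only usable for small N.

oracle_adjacency <- function(net) {
  a <- matrix(FALSE, net$N, net$N)
  for (e in seq_len(net$M)) {
    a[net$edges$i[e], net$edges$j[e]] <- TRUE
    a[net$edges$j[e], net$edges$i[e]] <- TRUE
  }
  a
}

oracle_distances <- function(net) {
  n <- net$N
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[oracle_adjacency(net)] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_L_reachable <- function(net) {
  d <- oracle_distances(net)
  v <- d[upper.tri(d)]
  mean(v[is.finite(v)])
}

oracle_clustering <- function(net) {
  a <- oracle_adjacency(net)
  n <- net$N
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ])
    k <- length(nb)
    if (k < 2) next
    e <- 0
    for (x in seq_len(k - 1))
      for (y in seq(x + 1, k))
        if (a[nb[x], nb[y]]) e <- e + 1
    ci[i] <- 2 * e / (k * (k - 1))
  }
  mean(ci)
}

oracle_degrees <- function(net) {
  rowSums(oracle_adjacency(net))
}

oracle_density <- function(net) {
  net$M / choose(net$N, 2)
}

oracle_centralization <- function(net) {
  n <- net$N
  (n / (n - 1)) * (max(oracle_degrees(net)) / (n - 1) - oracle_density(net))
}
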