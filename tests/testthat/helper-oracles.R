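# Independent brute-force oracles for graph statistics, used to validate
# the package's implementations. All of these deliberately use naive
# algorithms (triangle enumeration, Floyd-Warshall, exhaustive simple-path
# enumeration) and never call igraph or package internals.

oracle_clustering <- function(A) {
  n <- nrow(A)
  per <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ])
    k <- length(nb)
    if (k < 2) { per[i] <- 0; next }
    tri <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (A[nb[a], nb[b]]) tri <- tri + 1
    per[i] <- 2 * tri / (k * (k - 1))
  }
  list(per_node = per, mean = mean(per))
}

oracle_distances <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[A] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_charpath <- function(A) {
  d <- oracle_distances(A)
  d <- d[upper.tri(d)]
  if (!any(is.finite(d) & d > 0) && all(!is.finite(d)))
    return(list(L = NA_real_, n_unreachable_pairs = length(d)))
  list(L = mean(d[is.finite(d)]), n_unreachable_pairs = sum(!is.finite(d)))
}

# all simple paths i -> j by depth-first enumeration; keep shortest ones
oracle_geodesics <- function(A, i, j) {
  n <- nrow(A)
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == j) { paths[[length(paths) + 1]] <<- path; return() }
    for (w in which(A[v, ])) if (!(w %in% path)) walk(c(path, w))
  }
  walk(i)
  if (!length(paths)) return(list())
  len <- vapply(paths, length, integer(1))
  paths[len == min(len)]
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  btw <- numeric(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    geo <- oracle_geodesics(A, i, j)
    if (!length(geo)) next
    for (v in seq_len(n)) {
      if (v == i || v == j) next
      through <- sum(vapply(geo, function(p) v %in% p, logical(1)))
      btw[v] <- btw[v] + through / length(geo)
    }
  }
  btw / ((n - 1) * (n - 2) / 2)
}

random_adjacency <- function(n, p = 0.3) {
  A <- matrix(FALSE, n, n)
  A[upper.tri(A)] <- runif(n * (n - 1) / 2) < p
  A | t(A)
}

# exhaustive rank-sum enumeration, independent of the package's ranksum()
oracle_ranksum_p <- function(a, b) {
  r <- rank(c(a, b))
  na <- length(a); N <- length(r)
  W <- sum(r[seq_len(na)])
  Ws <- utils::combn(N, na, function(ix) sum(r[ix]))
  min(1, 2 * min(mean(Ws <= W + 1e-9), mean(Ws >= W - 1e-9)))
}

# tiny deterministic two-region config used across tests
tiny_config <- function(duration = 10, seed = 42, m_per_region = 2, ...) {
  synth_config(n_channels_per_region = m_per_region, duration = duration,
               seed = seed, ...)
}
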