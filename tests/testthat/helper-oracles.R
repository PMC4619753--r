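# Independent brute-force oracles for graph metrics and signal processing.
# These deliberately use different algorithms from the package (Floyd-
# Warshall instead of BFS/Dijkstra, explicit path enumeration instead of
# Brandes, restricted-growth partition enumeration instead of incremental
# search) so agreement is evidence, not tautology.

# All-pairs shortest path lengths by Floyd-Warshall. Binary graphs use hop
# counts; weighted graphs use 1/w edge lengths.
oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && a[i, j] > 0) d[i, j] <- if (all(a %in% c(0, 1))) 1 else 1 / a[i, j]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_lp <- function(a) {
  d <- oracle_distances(a)
  off <- d[row(d) != col(d)]
  list(lp = mean(off[is.finite(off)]), disc = mean(!is.finite(off)))
}

oracle_eglob <- function(a) {
  d <- oracle_distances(a)
  inv <- 1 / d
  diag(inv) <- 0
  n <- nrow(a)
  list(eglob = sum(inv) / (n * (n - 1)), nodal = rowSums(inv) / (n - 1))
}

oracle_eloc <- function(a) {
  n <- nrow(a)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_eglob(a[nb, nb, drop = FALSE])$eglob
  }, 0)
  mean(vals)
}

# Per-node clustering by explicit triangle counting.
oracle_clustering <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (x in seq_len(k - 1)) for (y in (x + 1):k)
      if (a[nb[x], nb[y]] > 0) tri <- tri + 1
    2 * tri / (k * (k - 1))
  }, 0)
}

# Betweenness by enumerating every shortest path (DFS bounded by the known
# shortest distance), with fractional counting over multiple shortest paths.
oracle_betweenness <- function(a) {
  n <- nrow(a)
  d <- oracle_distances(a)
  bt <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(d[s, t])) next
    paths <- list()
    walk <- function(v, trail) {
      if (length(trail) - 1 > d[s, t]) return(invisible())
      if (v == t) {
        if (length(trail) - 1 == d[s, t]) paths[[length(paths) + 1]] <<- trail
        return(invisible())
      }
      for (w in which(a[v, ] > 0)) if (!(w %in% trail)) walk(w, c(trail, w))
    }
    walk(s, s)
    if (length(paths) == 0) next
    interior <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
    if (length(interior) > 0)
      for (v in interior) bt[v] <- bt[v] + 1 / length(paths)
  }
  bt
}

# All set partitions of n elements as restricted-growth membership vectors.
oracle_partitions <- function(n) {
  out <- list()
  grow <- function(mem) {
    i <- length(mem) + 1
    if (i > n) { out[[length(out) + 1]] <<- mem; return(invisible()) }
    for (g in seq_len(max(mem, 0) + 1)) grow(c(mem, g))
  }
  grow(integer(0))
  out
}

# Newman modularity of a membership vector, by the direct formula.
oracle_q <- function(a, mem) {
  m2 <- sum(a)
  k <- rowSums(a)
  b <- a - outer(k, k) / m2
  sum(b[outer(mem, mem, `==`)]) / m2
}

# Best Q over all partitions (exhaustive).
oracle_modularity <- function(a) {
  parts <- oracle_partitions(nrow(a))
  qs <- vapply(parts, function(p) oracle_q(a, p), 0)
  best <- which.max(qs)
  list(q = qs[best], membership = parts[[best]])
}

# Erdos-Renyi random graph (symmetric, zero diagonal).
random_graph <- function(n, p) {
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- as.numeric(stats::runif(n * (n - 1) / 2) < p)
  a + t(a)
}

# Amplitude of a sinusoid at frequency f in a series, by least squares over
# the central 60% (edge transients excluded).
fit_amplitude <- function(y, f, fs) {
  n <- length(y)
  i <- seq(round(n * 0.2), round(n * 0.8))
  tv <- (i - 1) / fs
  X <- cbind(sin(2 * pi * f * tv), cos(2 * pi * f * tv))
  sqrt(sum(qr.solve(X, y[i])^2))
}

# Closed-form squared Butterworth magnitude response (zero-phase = squared)
# of the band-pass cascade: HP order 5 at f1, LP order 3 at f2.
analytic_bandpass_gain <- function(f, f1 = 0.01, f2 = 0.1) {
  (1 / (1 + (f1 / f)^10)) * (1 / (1 + (f / f2)^6))
}

# Adjacency matrix from an edge list on n nodes.
graph_from_edges <- function(n, edges) {
  a <- matrix(0, n, n)
  for (e in edges) { a[e[1], e[2]] <- 1; a[e[2], e[1]] <- 1 }
  a
}
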