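#' Threshold a correlation matrix into an adjacency matrix
#'
#' Sparsity mode keeps the `ceiling(s * N(N-1)/2)` strongest positive
#' correlations; cutoff mode keeps entries above an r cutoff. Negative
#' correlations are excluded by default (`use_abs = FALSE`); with
#' `use_abs = TRUE` the magnitude is thresholded instead. The diagonal is
#' forced to zero before any thresholding.
#'
#' @param fc Symmetric correlation matrix (or an `fc_result` in whole-brain
#'   mode).
#' @param sparsity Fraction of strongest connections to keep, in (0, 1).
#' @param cutoff Alternative absolute r cutoff (entries > cutoff kept).
#' @param mode "binary" (edges become 1) or "weighted" (edges keep r).
#' @param use_abs Threshold |r| instead of r.
#' @return An `adjacency_matrix`: list with `weights` (N x N, zero diagonal),
#'   `mode`, `threshold_spec`, `actual_sparsity`.
#' @export
threshold_matrix <- function(fc, sparsity = NULL, cutoff = NULL,
                             mode = c("binary", "weighted"), use_abs = FALSE) {
  mode <- match.arg(mode)
  w <- if (inherits(fc, "fc_result")) fc$values else as.matrix(fc)
  if (nrow(w) != ncol(w)) stop("correlation matrix must be square")
  if (max(abs(w - t(w)), na.rm = TRUE) > 1e-9) stop("correlation matrix must be symmetric")
  diag(w) <- 0
  score <- if (use_abs) abs(w) else w
  n <- nrow(w)
  ut <- upper.tri(w)
  if (!is.null(sparsity)) {
    if (sparsity <= 0 || sparsity >= 1) stop("sparsity must be in (0, 1)")
    k <- ceiling(sparsity * n * (n - 1) / 2)
    vals <- score[ut]
    pos <- which(vals > 0 & !is.na(vals))
    if (length(pos) < k) {
      warning("only ", length(pos), " positive entries available for ", k,
              " requested edges; actual sparsity will be lower")
      keep <- pos
    } else {
      keep <- pos[order(vals[pos], decreasing = TRUE)[seq_len(k)]]
    }
    sel <- matrix(FALSE, n, n)
    sel[ut][keep] <- TRUE
    sel <- sel | t(sel)
    spec <- list(type = "sparsity", value = sparsity)
  } else if (!is.null(cutoff)) {
    sel <- score > cutoff & !is.na(score)
    diag(sel) <- FALSE
    spec <- list(type = "cutoff", value = cutoff)
  } else stop("give either sparsity or cutoff")
  adj <- matrix(0, n, n)
  adj[sel] <- if (mode == "binary") 1 else (if (use_abs) abs(w[sel]) else w[sel])
  structure(list(weights = adj, mode = mode, threshold_spec = spec,
                 actual_sparsity = sum(adj[ut] > 0) / (n * (n - 1) / 2),
                 use_abs = use_abs),
            class = "adjacency_matrix")
}

.adj_weights <- function(adj) {
  if (inherits(adj, "adjacency_matrix")) adj$weights else {
    w <- as.matrix(adj); diag(w) <- 0; w
  }
}

.adj_graph <- function(w) {
  igraph::graph_from_adjacency_matrix(w, mode = "undirected", weighted = TRUE,
                                      diag = FALSE)
}

# All-pairs shortest path lengths: hop counts for binary graphs, 1/w edge
# lengths for weighted ones. Inf marks disconnected pairs.
.adj_distances <- function(w) {
  binary <- all(w %in% c(0, 1))
  g <- .adj_graph(w)
  if (binary) {
    igraph::distances(g, weights = NA)
  } else {
    ew <- igraph::E(g)$weight
    igraph::distances(g, weights = 1 / ew)
  }
}

#' Clustering coefficient
#'
#' Binary graphs: node-wise fraction of closed triangles,
#' c_i = 2 T(i) / (k_i (k_i - 1)), zero for degree < 2; Cp is the mean over
#' all nodes. Weighted graphs use the geometric-mean triangle formulation
#' (weights normalized by the matrix maximum, cube root per triangle edge).
#'
#' @param adj An `adjacency_matrix` or square weight matrix (zero diagonal).
#' @return List with `cp` (global mean) and `nodal` (per-node values).
#' @export
clustering_coefficient <- function(adj) {
  w <- .adj_weights(adj)
  n <- nrow(w)
  a <- (w > 0) + 0
  k <- rowSums(a)
  if (all(w %in% c(0, 1))) {
    tri <- diag(a %*% a %*% a) / 2
  } else {
    wn <- (w / max(w))^(1 / 3)
    tri <- diag(wn %*% wn %*% wn) / 2
  }
  nodal <- ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0)
  list(cp = mean(nodal), nodal = nodal)
}

#' Characteristic path length
#'
#' Mean shortest-path length over connected ordered node pairs (hop counts
#' for binary graphs, 1/w edge lengths for weighted graphs); the fraction of
#' disconnected pairs is reported alongside. A graph with no connected pair
#' yields `lp = NA`.
#'
#' @param adj An `adjacency_matrix` or square weight matrix.
#' @return List with `lp` and `disconnected_fraction`.
#' @export
characteristic_path_length <- function(adj) {
  w <- .adj_weights(adj)
  d <- .adj_distances(w)
  off <- d[row(d) != col(d)]
  conn <- is.finite(off)
  list(lp = if (any(conn)) mean(off[conn]) else NA_real_,
       disconnected_fraction = mean(!conn))
}

#' Global, local, and nodal efficiency
#'
#' Global efficiency is the mean over ordered pairs of 1/d(i, j) with
#' 1/Inf = 0 for disconnected pairs; nodal efficiency is the same mean per
#' node; local efficiency is the mean over nodes of the global efficiency of
#' each node's neighborhood subgraph (0 for degree < 2).
#'
#' @param adj An `adjacency_matrix` or square weight matrix.
#' @return List with `eglob`, `eloc`, `nodal` (per-node efficiency).
#' @export
efficiencies <- function(adj) {
  w <- .adj_weights(adj)
  n <- nrow(w)
  d <- .adj_distances(w)
  inv <- 1 / d
  diag(inv) <- 0
  nodal <- rowSums(inv) / (n - 1)
  eglob <- mean(nodal)
  eloc_i <- vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2L) return(0)
    sub <- w[nb, nb, drop = FALSE]
    ds <- .adj_distances(sub)
    invs <- 1 / ds; diag(invs) <- 0
    sum(invs) / (length(nb) * (length(nb) - 1))
  }, 0)
  list(eglob = eglob, eloc = mean(eloc_i), nodal = nodal, eloc_nodal = eloc_i)
}

#' Nodal betweenness centrality
#'
#' Shortest-path betweenness with fractional counting over multiple shortest
#' paths (Brandes), unnormalized, endpoints excluded.
#'
#' @param adj An `adjacency_matrix` or square weight matrix.
#' @return Numeric vector of per-node betweenness values.
#' @export
betweenness_centrality <- function(adj) {
  w <- .adj_weights(adj)
  g <- .adj_graph(w)
  if (all(w %in% c(0, 1))) {
    igraph::betweenness(g, directed = FALSE, weights = NA)
  } else {
    igraph::betweenness(g, directed = FALSE, weights = 1 / igraph::E(g)$weight)
  }
}

# Newman modularity of a membership vector on weight matrix w.
.modularity_q <- function(w, membership) {
  m2 <- sum(w)                       # = 2m
  if (m2 == 0) return(NA_real_)
  k <- rowSums(w)
  b <- w - outer(k, k) / m2
  s <- outer(membership, membership, `==`)
  sum(b[s]) / m2
}

# Exhaustive best-partition search by recursive assignment with incremental
# Q accumulation; affordable up to ~10 nodes (Bell(10) ~ 1.2e5 partitions).
.modularity_exact <- function(w) {
  n <- nrow(w)
  m2 <- sum(w)
  k <- rowSums(w)
  b <- w - outer(k, k) / m2
  best_q <- -Inf; best_mem <- rep(1L, n)
  mem <- integer(n)
  recurse <- function(i, ngroups, qacc) {
    if (i > n) {
      if (qacc > best_q) { best_q <<- qacc; best_mem <<- mem[1:n] }
      return(invisible())
    }
    for (g in seq_len(ngroups + 1L)) {
      mem[i] <<- g
      members <- which(mem[seq_len(i - 1L)] == g)
      dq <- b[i, i] + 2 * sum(b[i, members])
      recurse(i + 1L, max(ngroups, g), qacc + dq)
    }
  }
  recurse(1L, 0L, 0)
  list(q = best_q / m2, membership = best_mem)
}

#' Modularity of the best community partition
#'
#' Newman modularity Q. For graphs of up to `exact_max` nodes the optimal
#' partition is found by exhaustive search over all set partitions; larger
#' graphs use greedy agglomeration (fast-greedy), with Q always rescored by
#' the package's own formula.
#'
#' @param adj An `adjacency_matrix` or square weight matrix.
#' @param seed RNG seed (kept for interface stability; both search paths are
#'   deterministic).
#' @param exact_max Largest node count for exhaustive search (default 10).
#' @return List with `q`, `membership`, and `method` ("exact"/"greedy").
#'   An edgeless graph yields `q = NA`.
#' @export
network_modularity <- function(adj, seed = 1L, exact_max = 10L) {
  w <- .adj_weights(adj)
  if (sum(w) == 0) return(list(q = NA_real_, membership = rep(1L, nrow(w)),
                               method = "none"))
  if (nrow(w) <= exact_max) {
    res <- .modularity_exact(w)
    list(q = res$q, membership = res$membership, method = "exact")
  } else {
    g <- .adj_graph(w)
    cl <- withr::with_seed(seed, igraph::cluster_fast_greedy(g))
    mem <- igraph::membership(cl)
    list(q = .modularity_q(w, as.integer(mem)), membership = as.integer(mem),
         method = "greedy")
  }
}

#' Hierarchy exponent
#'
#' Least-squares fit of log c_i = const - beta * log k_i over nodes with
#' degree >= 2 and positive clustering; beta > 0 means high-degree hubs have
#' low clustering (a hierarchical organization).
#'
#' @param adj An `adjacency_matrix` or square weight matrix.
#' @return List with `beta` (NA when fewer than 3 eligible nodes or no degree
#'   spread) and `n_eligible`.
#' @export
hierarchy_beta <- function(adj) {
  w <- .adj_weights(adj)
  k <- rowSums((w > 0) + 0)
  cc <- clustering_coefficient(w)$nodal
  ok <- k >= 2 & cc > 0
  if (sum(ok) < 3L) return(list(beta = NA_real_, n_eligible = sum(ok)))
  lk <- log(k[ok]); lc <- log(cc[ok])
  if (stats::sd(lk) == 0) return(list(beta = NA_real_, n_eligible = sum(ok)))
  fit <- stats::lm.fit(cbind(1, lk), lc)
  list(beta = -fit$coefficients[[2L]], n_eligible = sum(ok))
}

#' Degree-preserving random rewiring
#'
#' Maslov-Sneppen edge swaps on a binary graph: repeatedly pick two edges
#' (a-b, c-d) and swap to (a-d, c-b) when that creates neither self-loops nor
#' multi-edges. The degree sequence is preserved exactly. Deterministic given
#' the seed.
#'
#' @param adj An `adjacency_matrix` or binary weight matrix.
#' @param n_swap_per_edge Attempted swaps per edge (default 10).
#' @param seed RNG seed.
#' @return A binary adjacency matrix (plain matrix) with the same degree
#'   sequence; a warning is emitted when no swap was possible.
#' @export
random_rewire <- function(adj, n_swap_per_edge = 10, seed = 1L) {
  w <- .adj_weights(adj)
  if (!all(w %in% c(0, 1))) stop("rewiring requires a binary graph")
  edges <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  ne <- nrow(edges)
  if (ne < 2L) {
    warning("fewer than 2 edges: nothing to rewire")
    return(w)
  }
  withr::with_seed(seed, {
    a <- w
    swapped <- 0L
    attempts <- ceiling(n_swap_per_edge * ne)
    for (it in seq_len(attempts)) {
      ij <- sample.int(ne, 2L)
      e1 <- edges[ij[1L], ]; e2 <- edges[ij[2L], ]
      p <- e1[1L]; q <- e1[2L]; r <- e2[1L]; s <- e2[2L]
      # orient the second edge randomly so both swap patterns are reachable
      if (stats::runif(1) < 0.5) { tmp <- r; r <- s; s <- tmp }
      if (length(unique(c(p, q, r, s))) < 4L) next
      if (a[p, s] == 1 || a[r, q] == 1) next
      a[p, q] <- 0; a[q, p] <- 0; a[r, s] <- 0; a[s, r] <- 0
      a[p, s] <- 1; a[s, p] <- 1; a[r, q] <- 1; a[q, r] <- 1
      edges[ij[1L], ] <- sort(c(p, s)); edges[ij[2L], ] <- sort(c(r, q))
      swapped <- swapped + 1L
    }
    if (swapped == 0L) warning("no valid swap found; returning input graph")
    a
  })
}

#' Small-world coefficients against degree-preserving nulls
#'
#' gamma = Cp / mean(Cp of rewired nulls), lambda = Lp / mean(Lp of nulls),
#' sigma = gamma / lambda. A small-world network has gamma clearly above 1
#' with lambda near 1. Null networks come from [random_rewire()] with seeds
#' derived from `seed`.
#'
#' @param adj An `adjacency_matrix` or binary weight matrix.
#' @param n_random Number of null networks (default 100).
#' @param seed RNG seed.
#' @param n_swap_per_edge Attempted swaps per edge in each null.
#' @return List with `cp`, `lp`, `cp_random`, `lp_random` (null means),
#'   `gamma`, `lambda`, `sigma`.
#' @export
small_world <- function(adj, n_random = 100, seed = 1L, n_swap_per_edge = 10) {
  w <- .adj_weights(adj)
  cp <- clustering_coefficient(w)$cp
  lp <- characteristic_path_length(w)$lp
  cps <- numeric(n_random); lps <- numeric(n_random)
  for (i in seq_len(n_random)) {
    rw <- suppressWarnings(random_rewire(w, n_swap_per_edge, seed = seed + i))
    cps[i] <- clustering_coefficient(rw)$cp
    lps[i] <- characteristic_path_length(rw)$lp
  }
  gamma <- cp / mean(cps)
  lambda <- lp / mean(lps)
  list(cp = cp, lp = lp, cp_random = mean(cps), lp_random = mean(lps),
       gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

#' All graph metrics for one adjacency matrix
#'
#' Convenience wrapper computing the global metrics (Cp, Lp, Eglob, Eloc, Q,
#' hierarchy beta, and optionally gamma/lambda/sigma against nulls) and the
#' nodal metrics (degree, efficiency, betweenness).
#'
#' @param adj An `adjacency_matrix` or square weight matrix.
#' @param n_random Null networks for normalized metrics; 0 skips them.
#' @param seed RNG seed for nulls and modularity.
#' @return A `graph_metrics` object (list of global scalars plus nodal
#'   vectors).
#' @export
graph_metrics <- function(adj, n_random = 0L, seed = 1L) {
  w <- .adj_weights(adj)
  cc <- clustering_coefficient(w)
  pl <- characteristic_path_length(w)
  ef <- efficiencies(w)
  mod <- network_modularity(w, seed = seed)
  hb <- hierarchy_beta(w)
  out <- list(cp = cc$cp, lp = pl$lp,
              disconnected_fraction = pl$disconnected_fraction,
              eglob = ef$eglob, eloc = ef$eloc, q = mod$q, beta = hb$beta,
              gamma = NA_real_, lambda = NA_real_, sigma = NA_real_,
              nodal_degree = rowSums((w > 0) + 0),
              nodal_clustering = cc$nodal,
              nodal_efficiency = ef$nodal,
              nodal_betweenness = betweenness_centrality(w),
              n_random = n_random, seed = seed)
  if (n_random > 0L && all(w %in% c(0, 1))) {
    sw <- small_world(w, n_random = n_random, seed = seed)
    out$gamma <- sw$gamma; out$lambda <- sw$lambda; out$sigma <- sw$sigma
  }
  structure(out, class = "graph_metrics")
}

#' @export
print.graph_metrics <- function(x, ...) {
  cat(sprintf("graph metrics (n = %d nodes):\n", length(x$nodal_degree)))
  cat(sprintf("  Cp = %.4f  Lp = %.4f  Eglob = %.4f  Eloc = %.4f\n",
              x$cp, x$lp, x$eglob, x$eloc))
  cat(sprintf("  Q = %.4f  beta = %.4f  gamma = %.3f  lambda = %.3f  sigma = %.3f\n",
              x$q, x$beta, x$gamma, x$lambda, x$sigma))
  invisible(x)
}

#' Metrics across a sparsity sweep, batched over subjects
#'
#' Thresholds each subject's FC matrix at every sparsity in `s_values` and
#' computes the selected graph metrics. Per-subject failures are recorded
#' and the batch continues. Results are identical for any `n_jobs` because
#' every (subject, sparsity) cell uses a seed derived from `seed` before
#' dispatch.
#'
#' @param fc_list Named list of symmetric FC matrices (or `fc_result`s).
#' @param s_values Sparsity values in (0, 1).
#' @param mode "binary" or "weighted".
#' @param n_random Null networks per cell for normalized metrics (0 = skip).
#' @param seed Base RNG seed.
#' @param n_jobs Worker processes (forked; values > 1 need a Unix-alike).
#' @return Tidy data frame: one row per subject x sparsity with the global
#'   metrics, plus a `status` column.
#' @export
sparsity_sweep <- function(fc_list, s_values, mode = c("binary", "weighted"),
                           n_random = 0L, seed = 1L, n_jobs = 1L) {
  mode <- match.arg(mode)
  if (is.null(names(fc_list)))
    names(fc_list) <- sprintf("subject%02d", seq_along(fc_list))
  stopifnot(all(s_values > 0 & s_values < 1))
  grid <- expand.grid(subject = names(fc_list), sparsity = s_values,
                      stringsAsFactors = FALSE)
  grid$cell_seed <- seed + seq_len(nrow(grid))
  run_cell <- function(i) {
    row <- grid[i, ]
    tryCatch({
      adj <- suppressWarnings(threshold_matrix(fc_list[[row$subject]],
                                               sparsity = row$sparsity,
                                               mode = mode))
      gm <- graph_metrics(adj, n_random = n_random, seed = row$cell_seed)
      data.frame(subject = row$subject, sparsity = row$sparsity,
                 cp = gm$cp, lp = gm$lp, eglob = gm$eglob, eloc = gm$eloc,
                 q = gm$q, beta = gm$beta, gamma = gm$gamma,
                 lambda = gm$lambda, sigma = gm$sigma,
                 status = "ok", message = "")
    }, error = function(e)
      data.frame(subject = row$subject, sparsity = row$sparsity,
                 cp = NA_real_, lp = NA_real_, eglob = NA_real_,
                 eloc = NA_real_, q = NA_real_, beta = NA_real_,
                 gamma = NA_real_, lambda = NA_real_, sigma = NA_real_,
                 status = "failed", message = conditionMessage(e)))
  }
  rows <- if (n_jobs > 1L) {
    parallel::mclapply(seq_len(nrow(grid)), run_cell, mc.cores = n_jobs)
  } else {
    lapply(seq_len(nrow(grid)), run_cell)
  }
  out <- do.call(rbind, rows)
  out[order(out$subject, out$sparsity), , drop = FALSE]
}

#' Ring lattice and Watts-Strogatz-style small-world graph
#'
#' `ring_lattice` connects each of `n` nodes to its `k` nearest neighbors
#' (`k` even). `sample_small_world` rewires each lattice edge with
#' probability `p` to a uniformly chosen new endpoint (no self-loops or
#' multi-edges), the classic small-world construction used to exercise the
#' normalized metrics.
#'
#' @param n Number of nodes.
#' @param k Neighbors per node (even).
#' @return Binary adjacency matrix.
#' @export
ring_lattice <- function(n, k) {
  stopifnot(k %% 2 == 0, k < n)
  a <- matrix(0, n, n)
  for (d in seq_len(k / 2)) {
    i <- seq_len(n)
    j <- ((i - 1 + d) %% n) + 1
    a[cbind(i, j)] <- 1; a[cbind(j, i)] <- 1
  }
  a
}

#' @rdname ring_lattice
#' @param p Rewiring probability.
#' @param seed RNG seed.
#' @export
sample_small_world <- function(n, k, p, seed = 1L) {
  a <- ring_lattice(n, k)
  withr::with_seed(seed, {
    edges <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
    for (e in seq_len(nrow(edges))) {
      if (stats::runif(1) >= p) next
      i <- edges[e, 1L]; j <- edges[e, 2L]
      cand <- which(a[i, ] == 0 & seq_len(n) != i)
      if (length(cand) == 0L) next
      newj <- cand[sample.int(length(cand), 1L)]
      a[i, j] <- 0; a[j, i] <- 0
      a[i, newj] <- 1; a[newj, i] <- 1
    }
    a
  })
}
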