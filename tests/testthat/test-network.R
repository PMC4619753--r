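# Worked small graphs used throughout: K4 minus one edge, the 6-cycle, the
# 4-leaf star, two triangles joined by a bridge, two disconnected triangles.
k4_minus_edge <- function() graph_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4),
                                                     c(2, 3), c(2, 4)))
six_cycle <- function() graph_from_edges(6, list(c(1, 2), c(2, 3), c(3, 4),
                                                 c(4, 5), c(5, 6), c(6, 1)))
star4 <- function() graph_from_edges(5, list(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
two_triangles_bridge <- function()
  graph_from_edges(6, list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6),
                           c(5, 6), c(3, 4)))
two_triangles <- function()
  graph_from_edges(6, list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6)))

test_that("worked small-graph metric values are exact", {
  # K4 minus one edge: cp = (2/3 + 2/3 + 1 + 1)/4 = 5/6
  expect_equal(clustering_coefficient(k4_minus_edge())$cp, 5 / 6,
               tolerance = 1e-12)
  # triangle and star limits
  expect_equal(clustering_coefficient(graph_from_edges(3, list(c(1, 2), c(1, 3),
                                                               c(2, 3))))$cp, 1)
  expect_equal(clustering_coefficient(star4())$cp, 0)
  # 6-cycle: per-node distances 1,1,2,2,3 -> lp = 1.8; eglob = (2 + 1 + 1/3)/5
  cyc <- characteristic_path_length(six_cycle())
  expect_equal(cyc$lp, 1.8, tolerance = 1e-12)
  expect_equal(cyc$disconnected_fraction, 0)
  expect_equal(efficiencies(six_cycle())$eglob, (1 + 1 + 1 / 2 + 1 / 2 + 1 / 3) / 5,
               tolerance = 1e-12)
  # complete graph: lp = 1, eglob = 1; empty graph: eglob = 0
  k5 <- 1 - diag(5)
  expect_equal(characteristic_path_length(k5)$lp, 1)
  expect_equal(efficiencies(k5)$eglob, 1)
  expect_equal(efficiencies(matrix(0, 4, 4))$eglob, 0)
  # two isolated edges: lp = 1 over connected pairs, 2/3 of pairs disconnected
  iso <- graph_from_edges(4, list(c(1, 2), c(3, 4)))
  pl <- characteristic_path_length(iso)
  expect_equal(pl$lp, 1)
  expect_equal(pl$disconnected_fraction, 2 / 3)
  # betweenness: path center 1, star center C(4,2) = 6, complete graph all 0
  expect_equal(betweenness_centrality(graph_from_edges(3, list(c(1, 2), c(2, 3)))),
               c(0, 1, 0))
  expect_equal(betweenness_centrality(star4()), c(6, 0, 0, 0, 0))
  expect_equal(betweenness_centrality(k5), rep(0, 5))
  # modularity: two-triangle bridge Q = 5/14 with the triangles as communities
  mod <- network_modularity(two_triangles_bridge())
  expect_equal(mod$q, 5 / 14, tolerance = 1e-12)
  expect_equal(length(unique(mod$membership)), 2)
  expect_equal(mod$membership[1:3], rep(mod$membership[1], 3))
  # two disconnected triangles: Q = 1/2; complete graph: Q = 0
  expect_equal(network_modularity(two_triangles())$q, 0.5, tolerance = 1e-12)
  expect_equal(network_modularity(k5)$q, 0, tolerance = 1e-12)
  expect_true(is.na(network_modularity(matrix(0, 3, 3))$q))
})

test_that("graph metrics equal brute-force enumeration on random graphs", {
  withr::with_seed(101, {
    for (rep in 1:40) {
      n <- sample(4:8, 1)
      a <- random_graph(n, stats::runif(1, 0.25, 0.6))
      expect_equal(clustering_coefficient(a)$nodal, oracle_clustering(a),
                   tolerance = 1e-12)
      pl <- characteristic_path_length(a)
      ol <- oracle_lp(a)
      if (is.na(pl$lp)) expect_true(is.nan(ol$lp)) else
        expect_equal(pl$lp, ol$lp, tolerance = 1e-12)
      ef <- efficiencies(a)
      oe <- oracle_eglob(a)
      expect_equal(ef$eglob, oe$eglob, tolerance = 1e-12)
      expect_equal(ef$nodal, oe$nodal, tolerance = 1e-12)
      expect_equal(ef$eloc, oracle_eloc(a), tolerance = 1e-12)
      expect_equal(as.numeric(betweenness_centrality(a)), oracle_betweenness(a),
                   tolerance = 1e-12)
      if (sum(a) > 0)
        expect_equal(network_modularity(a)$q, oracle_modularity(a)$q,
                     tolerance = 1e-12)
    }
  })
})

test_that("thresholding keeps the strongest positive correlations", {
  # 4-node matrix with a known ordering of the 6 upper-triangle entries
  vals <- c(0.9, 0.7, 0.5, 0.3, 0.2, 0.1)
  fc <- matrix(0, 4, 4)
  fc[upper.tri(fc)] <- vals
  fc <- fc + t(fc); diag(fc) <- 1
  adj <- threshold_matrix(fc, sparsity = 0.5)
  expect_equal(sum(adj$weights[upper.tri(adj$weights)]), 3)  # top-3 edges
  expect_true(all(adj$weights[fc < 0.5 & row(fc) != col(fc)] == 0))
  expect_equal(diag(adj$weights), rep(0, 4))
  # weighted mode retains r values
  adjw <- threshold_matrix(fc, sparsity = 0.5, mode = "weighted")
  expect_equal(sort(adjw$weights[adjw$weights > 0]), rep(c(0.5, 0.7, 0.9), each = 2))
  # sparsity 1 is rejected; all-equal matrix at s close to 1 -> complete graph
  expect_error(threshold_matrix(fc, sparsity = 1), "sparsity")
  eq <- matrix(0.5, 4, 4); diag(eq) <- 1
  expect_equal(threshold_matrix(eq, sparsity = 0.999)$actual_sparsity, 1)
  # negative-only matrix -> empty graph with warning
  neg <- -eq; diag(neg) <- 1
  expect_warning(e <- threshold_matrix(neg, sparsity = 0.3), "positive")
  expect_equal(sum(e$weights), 0)
  # r cutoff mode
  adj2 <- threshold_matrix(fc, cutoff = 0.45)
  expect_equal(sum(adj2$weights) / 2, 3)
})

test_that("eglob is monotone under sparsity increase and edge addition", {
  withr::with_seed(103, {
    fc <- cor(matrix(rnorm(40 * 12), 40, 12))
    es <- vapply(seq(0.1, 0.9, 0.1), function(s)
      efficiencies(suppressWarnings(
        threshold_matrix(fc, sparsity = s))$weights)$eglob, 0)
    expect_true(all(diff(es) >= -1e-12))
  })
})

test_that("hierarchy fit recovers constructed exponents", {
  # c_i = k_i^(-0.5) exactly -> beta = 0.5 (synthetic regression input,
  # bypassing the topology)
  k <- c(2, 3, 4, 6, 8)
  cc <- k^(-0.5)
  fit <- stats::lm.fit(cbind(1, log(k)), log(cc))
  expect_equal(-fit$coefficients[[2]], 0.5, tolerance = 1e-12)
  # identical clustering across degrees -> beta = 0: a graph where every node
  # has c_i equal; the 6-cycle with chords is messy, so use two triangles
  # (all c_i = 1, all k_i = 2 -> no degree spread -> undefined marker)
  expect_true(is.na(hierarchy_beta(two_triangles())$beta))
  # K4-minus-edge has degree spread (2, 3) with clustering (1, 2/3): beta from
  # the package must match a direct lm on (log k, log c)
  hb <- hierarchy_beta(k4_minus_edge())
  ref <- stats::lm(y ~ x, data = list(x = log(c(3, 3, 2, 2)),
                                      y = log(c(2/3, 2/3, 1, 1))))
  expect_equal(hb$beta, -stats::coef(ref)[[2]], tolerance = 1e-12)
  expect_equal(hb$n_eligible, 4)
  # too few eligible nodes -> marker
  expect_true(is.na(hierarchy_beta(star4())$beta))
})

test_that("rewiring preserves degrees, is seeded, and destroys clustering", {
  latt <- ring_lattice(60, 6)
  r1 <- random_rewire(latt, seed = 7)
  r2 <- random_rewire(latt, seed = 7)
  r3 <- random_rewire(latt, seed = 8)
  expect_identical(r1, r2)
  expect_false(identical(r1, r3))
  expect_equal(rowSums(r1), rowSums(latt))
  expect_equal(sort(colSums(r3)), sort(colSums(latt)))
  expect_true(all(diag(r1) == 0))
  expect_true(all(r1 %in% c(0, 1)))
  # randomization drives clustering down from the lattice value
  expect_lt(clustering_coefficient(r1)$cp, clustering_coefficient(latt)$cp)
  expect_warning(random_rewire(graph_from_edges(3, list(c(1, 2))), seed = 1),
                 "fewer than 2 edges")
})

test_that("small-world normalization behaves at its fixed points", {
  # complete graph: nulls are identical -> gamma = lambda = sigma = 1
  k6 <- 1 - diag(6)
  sw <- suppressWarnings(small_world(k6, n_random = 5, seed = 1))
  expect_equal(sw$gamma, 1, tolerance = 1e-12)
  expect_equal(sw$lambda, 1, tolerance = 1e-12)
  # a random graph against its own nulls: both ratios near 1
  withr::with_seed(105, a <- random_graph(40, 0.25))
  swr <- small_world(a, n_random = 20, seed = 2)
  expect_lt(abs(swr$gamma - 1), 0.35)
  expect_lt(abs(swr$lambda - 1), 0.1)
})

test_that("sparsity sweep is deterministic across parallelism and isolates failures", {
  withr::with_seed(107, {
    fcs <- lapply(1:2, function(i) cor(matrix(rnorm(60 * 10), 60, 10)))
  })
  names(fcs) <- c("s1", "s2")
  s_values <- seq(0.1, 0.5, 0.1)
  t1 <- sparsity_sweep(fcs, s_values, n_jobs = 1)
  expect_equal(nrow(t1), 10)
  t4 <- sparsity_sweep(fcs, s_values, n_jobs = 4)
  expect_identical(t1, t4)
  # a defective subject fails alone
  fcs$bad <- matrix("not numeric", 2, 2)
  t5 <- suppressWarnings(sparsity_sweep(fcs, c(0.2)))
  expect_equal(sum(t5$status == "failed"), 1)
  expect_equal(sum(t5$status == "ok"), 2)
})
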