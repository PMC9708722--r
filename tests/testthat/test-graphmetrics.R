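test_that("weight-to-distance conversion follows the reciprocal convention", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[2, 3] <- w[3, 2] <- 0.5
  d <- to_distance(weighted_network(w, "binary"))
  expect_equal(d[1, 2], 1)
  expect_equal(d[2, 3], 2)
  expect_equal(d[1, 3], Inf)
  expect_equal(diag(d), rep(0, 3))
  expect_error(weighted_network(matrix(c(0, -1, -1, 0), 2, 2)), "negative")
})

test_that("hand-enumerated metrics on K4 and the 3-node path are exact", {
  k4 <- weighted_network(matrix(1, 4, 4) - diag(4), "binary")
  m <- network_metrics(k4)
  expect_equal(m$Eg, 1)
  expect_equal(m$Lp, 1)
  expect_equal(m$Cp, 1)
  expect_equal(m$Eloc, 1)

  p3 <- weighted_network(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)), "binary")
  m3 <- network_metrics(p3)
  expect_equal(m3$Eg, 5 / 6)
  expect_equal(m3$Lp, 4 / 3)
  expect_equal(m3$Cp, 0)
  expect_equal(m3$Eloc, 0)
})

test_that("Dijkstra distances agree with a Floyd-Warshall oracle", {
  set.seed(77)
  for (i in 1:50) {
    w <- matrix(0, 30, 30)
    ut <- upper.tri(w)
    vals <- ifelse(stats::runif(sum(ut)) < 0.2, stats::runif(sum(ut), 0.1, 3), 0)
    w[ut] <- vals; w <- w + t(w)
    net <- weighted_network(w, "fiber_number")
    d_impl <- glymphnet:::shortest_distances(net)
    expect_lt(max(abs(d_impl - floyd_warshall(to_distance(net))), na.rm = TRUE), 1e-12)
  }
})

test_that("metrics are invariant to node relabeling and monotone in edges", {
  set.seed(5)
  w <- matrix(0, 12, 12)
  ut <- upper.tri(w)
  w[ut] <- ifelse(stats::runif(sum(ut)) < 0.3, stats::runif(sum(ut), 0.5, 2), 0)
  w <- w + t(w)
  net <- weighted_network(w, "fiber_number")
  m <- network_metrics(net)
  perm <- sample(12)
  m2 <- network_metrics(weighted_network(w[perm, perm], "fiber_number"))
  for (nm in c("Eg", "Eloc", "Lp", "Cp"))
    expect_equal(m2[[nm]], m[[nm]], tolerance = 1e-12)

  # adding an edge to a binary network never decreases Eg
  b <- (w > 0) * 1
  netb <- weighted_network(b, "binary")
  zero <- which(b == 0 & upper.tri(b), arr.ind = TRUE)
  pick <- zero[sample(nrow(zero), 5), , drop = FALSE]
  for (k in seq_len(nrow(pick))) {
    b2 <- b
    b2[pick[k, 1], pick[k, 2]] <- b2[pick[k, 2], pick[k, 1]] <- 1
    expect_gte(network_metrics(weighted_network(b2, "binary"))$Eg,
               network_metrics(netb)$Eg)
  }
})

test_that("rewired nulls preserve degrees and weights, and destroy clustering", {
  rl <- igraph::sample_smallworld(1, 100, 2, 0)   # ring lattice, k = 4
  w <- adj_of(rl)
  net <- weighted_network(w, "binary")
  nl <- rewire_null(net, seed = 3)
  expect_equal(rowSums(nl$w > 0), rowSums(net$w > 0))
  expect_equal(sort(nl$w[upper.tri(nl$w)]), sort(net$w[upper.tri(net$w)]))

  # weights travel with edges
  set.seed(8)
  ww <- w * matrix(stats::runif(10000, 1, 5), 100, 100)
  ww[lower.tri(ww)] <- t(ww)[lower.tri(ww)]
  netw <- weighted_network(ww, "fiber_number")
  nlw <- rewire_null(netw, seed = 4)
  expect_equal(sort(nlw$w[nlw$w > 0]), sort(netw$w[netw$w > 0]))
  expect_equal(rowSums(nlw$w > 0), rowSums(netw$w > 0))

  cin <- glymphnet:::clustering_onnela(net)
  lower <- vapply(1:100, function(s)
    glymphnet:::clustering_onnela(rewire_null(net, seed = s)) < cin, logical(1))
  expect_gte(sum(lower), 95)

  # complete graphs admit no legal swap
  k5 <- weighted_network(matrix(1, 5, 5) - diag(5), "binary")
  same <- rewire_null(k5, seed = 1)
  expect_true(attr(same, "unchanged"))
  expect_equal(same$w, k5$w)
})

test_that("small-worldness is 1 on complete graphs and calibrated on random/lattice graphs", {
  k6 <- weighted_network(matrix(1, 6, 6) - diag(6), "binary")
  sw <- small_worldness(k6, n_null = 10, seed = 2)
  expect_equal(sw$sigma, 1)

  set.seed(42)
  er <- weighted_network(adj_of(igraph::sample_gnp(100, 0.3)), "binary")
  sig_er <- small_worldness(er, n_null = 20, seed = 5)$sigma
  expect_gt(sig_er, 0.9); expect_lt(sig_er, 1.1)

  set.seed(43)
  ws <- weighted_network(adj_of(igraph::sample_smallworld(1, 100, 3, 0.05)), "binary")
  sig_ws <- small_worldness(ws, n_null = 30, seed = 6)$sigma
  expect_gt(sig_ws, 1.5)

  # fixed seed reproduces sigma to the last bit
  expect_identical(small_worldness(ws, n_null = 5, seed = 9)$sigma,
                   small_worldness(ws, n_null = 5, seed = 9)$sigma)
})
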