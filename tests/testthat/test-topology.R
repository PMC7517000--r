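# Topology suite: distribution curves, exponent fits, clustering, distances.

test_that("degree curves match hand-computed small cases", {
  cur <- degree_curves(star_edges(5))
  expect_equal(cur$cdf[cur$k == 1], 1)
  expect_equal(cur$cdf[cur$k == 4], 0.2)
  expect_equal(sum(cur$pdf), 1)

  cyc <- degree_curves(cycle_edges(4))
  expect_equal(cyc$k, 2L)
  expect_equal(cyc$pdf, 1)
  expect_equal(cyc$cdf, 1)

  net <- fpa_network(2000, m = 1, f = 0.4, seed = 3)
  cur2 <- degree_curves(net)
  expect_true(all(diff(cur2$cdf) < 0))          # strictly fewer at-or-above
  expect_equal(cur2$cdf[1], 1)
  expect_gte(min(cur2$cdf), 1 / net$n)
  expect_equal(sum(cur2$pdf), 1)
})

test_that("knn curve reproduces hand cases and matches igraph", {
  st <- knn_curve(star_edges(5))$by_degree
  expect_equal(st$knn[st$k == 4], 1)
  expect_equal(st$knn[st$k == 1], 4)

  p3 <- knn_curve(path_edges(3))$by_degree
  expect_equal(p3$knn[p3$k == 1], 2)
  expect_equal(p3$knn[p3$k == 2], 1)

  cy <- knn_curve(cycle_edges(6))$by_degree   # 2-regular
  expect_equal(cy$knn, 2)

  net <- fpa_network(3000, m = 2, f = 0.5, seed = 13)
  mine <- knn_curve(net)$by_degree
  ig <- igraph::knn(as.igraph(net))$knnk      # independent route
  ig_k <- which(!is.nan(ig))
  expect_equal(mine$knn, unname(ig[mine$k]), tolerance = 1e-12)
  expect_setequal(mine$k, ig_k)
})

test_that("exponent fits are exact on noiseless power laws", {
  cur <- data.frame(k = 1:100, cdf = 0.7 * (1:100)^-2)
  fit <- fit_ccdf_exponent(cur)
  expect_equal(fit$exponent, 2, tolerance = 1e-10)
  expect_equal(fit$amplitude, 0.7, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  kc <- data.frame(k = 1:50, knn = 100 * (1:50)^-1)
  afit <- fit_alpha(kc)
  expect_equal(afit$exponent, -1, tolerance = 1e-10)
  expect_equal(afit$amplitude, 100, tolerance = 1e-6)

  up <- data.frame(k = 2:40, knn = 3 * (2:40)^0.5)
  expect_equal(fit_alpha(up)$exponent, 0.5, tolerance = 1e-10)

  expect_error(fit_ccdf_exponent(data.frame(k = 1:2, cdf = c(1, 0.5))),
               "3 points")
})

test_that("clustering matches brute-force triangle counting", {
  tri <- rbind(c(1, 2), c(2, 3), c(3, 1))
  expect_equal(clustering_coeff(tri)$average, 1)

  net <- fpa_network(4000, m = 1, f = 0.7, seed = 8)
  expect_identical(clustering_coeff(net)$average, 0)   # trees: exactly zero

  pend <- rbind(tri, c(1, 4))   # triangle plus pendant on vertex 1
  cc <- clustering_coeff(pend)
  expect_equal(cc$local[1], 1 / 3)
  expect_equal(cc$average, (1 + 1 + 1 / 3 + 0) / 4)

  set.seed(41)
  for (i in 1:10) {
    n <- sample(5:9, 1)
    e <- random_connected_edges(n, extra = 3L)
    expect_equal(clustering_coeff(e)$local,
                 oracle_local_clustering(e, n), tolerance = 1e-12)
  }
})

test_that("diameter: hand cases, and double-BFS equals brute force on trees", {
  expect_equal(net_diameter(path_edges(6))$value, 5)
  expect_equal(net_diameter(star_edges(7))$value, 2)
  set.seed(23)
  for (i in 1:100) {
    e <- random_tree_edges(sample(4:200, 1))
    got <- net_diameter(e)
    expect_true(got$exact)
    expect_equal(got$value, oracle_apsp(e)$diameter)
  }
})

test_that("average path length: hand cases, tree identity, sampling", {
  expect_equal(avg_path_length(path_edges(3))$value, 4 / 3)
  st <- avg_path_length(star_edges(30))
  expect_equal(st$value, oracle_apsp(star_edges(30))$avg_path)
  expect_true(st$exact)
  set.seed(29)
  for (i in 1:100) {
    e <- random_tree_edges(sample(4:200, 1))
    expect_equal(avg_path_length(e)$value, oracle_apsp(e)$avg_path,
                 tolerance = 1e-12)
  }
  # non-tree exact route (all sources sampled) agrees with the oracle
  e <- random_connected_edges(40, extra = 10L)
  expect_equal(avg_path_length(e, n_samples = 40)$value,
               oracle_apsp(e)$avg_path, tolerance = 1e-12)
  # sampled estimate is close on a mid-size graph
  set.seed(5)
  net <- fpa_network(3000, m = 2, f = 0.8, seed = 55)
  full <- avg_path_length(net, n_samples = 3000)$value
  est <- avg_path_length(net, n_samples = 400)
  expect_false(est$exact)
  expect_lt(abs(est$value - full) / full, 0.05)
})

test_that("disconnected input is rejected with the component count", {
  two <- rbind(c(1, 2), c(3, 4))
  expect_error(net_diameter(two), "2 components")
  expect_error(avg_path_length(two), "disconnected")
})

test_that("ultra-small-world reference behaves at and away from its domain edge", {
  expect_equal(round(ultra_small_reference(1e5), 2), 4.71)
  expect_equal(round(ultra_small_reference(1e5), 1), 4.7)
  expect_equal(ultra_small_reference(1e6), log(1e6) / log(log(1e6)))
  expect_error(ultra_small_reference(10), "16")
})

test_that("m = 1 summaries satisfy the tree identities", {
  net <- fpa_network(5000, m = 1, f = 0.3, seed = 19)
  s <- topology_summary(net)
  expect_identical(s$rho, 0)
  expect_equal(s$mean_degree, 2 * (net$n - 1) / net$n)
  expect_equal(s$kmax, max(net$degree))
  expect_true(s$diameter_exact && s$avg_path_exact)
})

test_that("beta, alpha and diameter order monotonically in f", {
  stats <- sapply(c(0.1, 0.5, 1), function(f) {
    v <- sapply(1:3, function(r) {
      net <- fpa_network(20000, m = 1, f = f,
                         seed = derive_seed(404L, 1, f, r))
      c(fit_ccdf_exponent(net)$exponent, fit_alpha(net)$exponent,
        net_diameter(net)$value)
    })
    rowMeans(v)
  })
  expect_true(all(diff(stats[1, ]) > 0))  # beta grows with f
  expect_true(all(diff(stats[2, ]) > 0))  # alpha rises toward 0
  expect_true(all(diff(stats[3, ]) > 0))  # diameter grows with f
})
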