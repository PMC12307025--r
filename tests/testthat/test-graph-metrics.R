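test_that("weight normalisation rescales to [0,1] and preserves zeros", {
  w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 2; w[2, 3] <- w[3, 2] <- 4
  g <- normalize_weights(weighted_graph(w))
  expect_equal(sort(unique(g$weights[upper.tri(g$weights)])), c(0, 0.5, 1))

  expect_equal(normalize_weights(g)$weights, g$weights)  # idempotent

  u <- matrix(0.37, 4, 4); diag(u) <- 0
  gu <- normalize_weights(weighted_graph(u))
  expect_true(all(gu$weights[upper.tri(gu$weights)] == 1))

  expect_error(normalize_weights(weighted_graph(matrix(0, 3, 3))), "zero")
})

test_that("clustering closed forms: triangle, star, weighted apex", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  cc <- clustering_coefficient(weighted_graph(tri))
  expect_equal(unname(cc$per_node), rep(1, 3))
  expect_equal(cc$mean, 1)

  star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1
  cs <- clustering_coefficient(weighted_graph(star))
  expect_equal(unname(cs$per_node[1]), 0)           # hub: no triangles
  expect_true(all(is.na(cs$per_node[2:5])))         # leaves: degree < 2
  expect_equal(cs$mean, 0)

  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1; w[1, 3] <- w[3, 1] <- 1; w[2, 3] <- w[3, 2] <- 0.125
  cw <- clustering_coefficient(weighted_graph(w))
  expect_equal(unname(cw$per_node[1]), 0.5)         # (1*1*0.125)^(1/3)

  # a two-node edge: no node reaches degree 2 -> mean is missing
  e <- matrix(0, 2, 2); e[1, 2] <- e[2, 1] <- 1
  expect_true(is.na(clustering_coefficient(weighted_graph(e))$mean))
})

test_that("modularity closed forms: cliques and planted modules", {
  w <- matrix(0, 8, 8); w[1:4, 1:4] <- 1; w[5:8, 5:8] <- 1; diag(w) <- 0
  m <- modularity(weighted_graph(w))
  expect_equal(m$Q, 0.5)
  expect_equal(length(unique(m$partition[1:4])), 1)
  expect_equal(length(unique(m$partition[5:8])), 1)
  expect_false(m$partition[1] == m$partition[5])

  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  mk <- modularity(weighted_graph(k5))
  expect_equal(mk$Q, 0, tolerance = 1e-12)  # no partition beats one community

  # planted weighted modules, large enough to use the Louvain path
  set.seed(61)
  n <- 10
  w2 <- matrix(0.05, n, n)
  w2[1:5, 1:5] <- 0.9; w2[6:10, 6:10] <- 0.9; diag(w2) <- 0
  m2 <- modularity(weighted_graph(w2), restarts = 10, seed = 2)
  expect_identical(m2$method, "louvain")
  expect_equal(length(unique(m2$partition[1:5])), 1)
  expect_equal(length(unique(m2$partition[6:10])), 1)
  expect_false(m2$partition[1] == m2$partition[6])

  expect_error(modularity(weighted_graph(matrix(0, 3, 3))), "zero")
})

test_that("Louvain never falls below the one-community partition and Q stays in range", {
  set.seed(62)
  for (rep in 1:8) {
    w <- random_weight_matrix(12, density = 0.5)
    if (sum(w) == 0) next
    m <- modularity(weighted_graph(w), restarts = 5, seed = rep, exact_max_n = 0)
    trivial_q <- 0   # one community: sum(w - s s'/2m)/2m = 0
    expect_gte(m$Q, trivial_q - 1e-12)
    expect_gte(m$Q, -0.5)
    expect_lte(m$Q, 1)
  }
})

test_that("path length closed forms and disconnection contract", {
  pth <- matrix(0, 3, 3); pth[1, 2] <- pth[2, 1] <- 1; pth[2, 3] <- pth[3, 2] <- 1
  expect_equal(characteristic_path_length(weighted_graph(pth)), 4 / 3)

  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  expect_equal(characteristic_path_length(weighted_graph(k4)), 1)

  disc <- matrix(0, 4, 4); disc[1, 2] <- disc[2, 1] <- 1; disc[3, 4] <- disc[4, 3] <- 1
  expect_true(is.na(characteristic_path_length(weighted_graph(disc))))
})

test_that("small-world index is missing on trees and errors on bad n_null", {
  tree <- matrix(0, 5, 5)
  tree[1, 2:5] <- tree[2:5, 1] <- 0.8
  g <- normalize_weights(weighted_graph(tree))
  sw <- small_world_index(g, n_null = 5, seed = 1)
  expect_true(is.na(sw$sigma))
  expect_error(small_world_index(g, n_null = 0), "n_null")
})

test_that("all indices are invariant to positive rescaling of the weights", {
  set.seed(63)
  w <- random_weight_matrix(10, density = 0.8)
  for (c in c(0.01, 3, 250)) {
    g1 <- normalize_weights(weighted_graph(w))
    g2 <- normalize_weights(weighted_graph(c * w))
    expect_equal(g2$weights, g1$weights, tolerance = 1e-12)
    expect_equal(clustering_coefficient(g2)$mean, clustering_coefficient(g1)$mean)
    expect_equal(modularity(g2, seed = 1)$Q, modularity(g1, seed = 1)$Q)
    expect_equal(characteristic_path_length(g2), characteristic_path_length(g1))
    expect_equal(small_world_index(g2, n_null = 3, seed = 1)$sigma,
                 small_world_index(g1, n_null = 3, seed = 1)$sigma)
  }
})

test_that("metrics match brute-force enumeration on small random graphs", {
  set.seed(64)
  parts <- list(`4` = brute_partitions(4), `5` = brute_partitions(5),
                `6` = brute_partitions(6))
  for (rep in 1:60) {
    n <- sample(4:6, 1)
    w <- random_weight_matrix(n, density = runif(1, 0.4, 1))
    if (sum(w) == 0) next
    g <- weighted_graph(w)
    cc <- clustering_coefficient(g)
    bc <- brute_clustering(w)
    expect_equal(unname(cc$per_node), bc$per_node, tolerance = 1e-10)
    expect_equal(cc$mean, bc$mean, tolerance = 1e-10)
    expect_equal(modularity(g)$Q,
                 brute_max_modularity(w, parts[[as.character(n)]])$Q,
                 tolerance = 1e-10)
    expect_equal(characteristic_path_length(g), brute_path_length(w),
                 tolerance = 1e-10)
    expect_equal(global_efficiency(g), brute_global_efficiency(w),
                 tolerance = 1e-10)
  }
})

test_that("metric records carry explicit missingness into the long layout", {
  tree <- matrix(0, 5, 5)
  tree[1, 2:5] <- tree[2:5, 1] <- 0.8
  rec <- graph_metric_record(weighted_graph(tree), subject_id = "s1",
                             band = "alpha", n_null = 3, seed = 1)
  expect_true(is.na(rec$small_world))
  expect_equal(rec$clustering, 0)
  expect_false(is.na(rec$path_length))
  long <- metrics_long(rec)
  expect_equal(nrow(long), 5)
  expect_true(long$missing_flag[long$measure == "small_world"])
  expect_false(long$missing_flag[long$measure == "path_length"])
})
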