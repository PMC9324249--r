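test_that("edge rule thresholds the standardized Fisher statistic", {
  z <- matrix(0, 3, 3)
  z[1, 2] <- z[2, 1] <- atanh(0.2)   # z_stat ~ 2.54 at T = 160
  z[1, 3] <- z[3, 1] <- atanh(0.1)   # z_stat ~ 1.26
  conn <- structure(list(z = z, T_effective = 160L, subject_id = "s"),
                    class = "conn_matrix")
  g <- threshold_graph(conn)
  expect_true(g$adjacency[1, 2])
  expect_false(g$adjacency[1, 3])
  # empty graph at zero connectivity
  conn0 <- structure(list(z = matrix(0, 4, 4), T_effective = 160L,
                          subject_id = "s"), class = "conn_matrix")
  expect_equal(sum(threshold_graph(conn0)$adjacency), 0)
  conn$T_effective <- 3L
  expect_error(threshold_graph(conn), "exceed 3")
})

test_that("negative correlations never create edges by default", {
  z <- matrix(0, 2, 2)
  z[1, 2] <- z[2, 1] <- -atanh(0.5)
  conn <- structure(list(z = z, T_effective = 160L, subject_id = "s"),
                    class = "conn_matrix")
  expect_equal(sum(threshold_graph(conn)$adjacency), 0)
  two_sided <- threshold_spec(positive_only = FALSE)
  expect_true(threshold_graph(conn, two_sided)$adjacency[1, 2])
})

test_that("shortest paths match hand enumeration on canonical graphs", {
  # ring C5: distance multiset {1, 1, 2, 2} per node
  A <- lattice_adjacency(5, 1)
  d <- shortest_paths(binary_graph(A))
  for (i in 1:5) expect_equal(sort(d[i, -i]), c(1, 1, 2, 2))
  # complete K4
  K <- matrix(1, 4, 4); diag(K) <- 0
  dk <- shortest_paths(binary_graph(K))
  expect_true(all(dk[row(dk) != col(dk)] == 1))
  # two disjoint edges
  D <- matrix(0, 4, 4); D[1, 2] <- D[2, 1] <- D[3, 4] <- D[4, 3] <- 1
  dd <- shortest_paths(binary_graph(D))
  expect_equal(dd[1, 3], Inf)
  expect_equal(dd[2, 4], Inf)
})

test_that("all seven metrics agree with the brute-force oracle", {
  set.seed(20)
  for (rep in 1:40) {
    n <- sample(5:12, 1)
    A <- rand_adjacency(n, sample(c(0.2, 0.5, 0.8), 1))
    got <- nodal_metrics(binary_graph(A))
    want <- oracle_metrics(A)
    for (m in names(want)) {
      expect_equal(got[[m]], want[[m]], tolerance = 1e-10,
                   info = paste("metric", m))
    }
  }
})

test_that("metrics agree with igraph on larger dense and sparse graphs", {
  skip_if_not_installed("igraph")
  set.seed(21)
  for (p in c(0.1, 0.5, 0.9)) {
    A <- rand_adjacency(60, p)
    g <- binary_graph(A)
    m <- nodal_metrics(g)
    ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(m$degree, unname(igraph::degree(ig)))
    expect_equal(m$betweenness,
                 unname(igraph::betweenness(ig, normalized = TRUE)),
                 tolerance = 1e-10)
    expect_equal(m$clustering,
                 unname(igraph::transitivity(ig, "local",
                                             isolates = "zero")),
                 tolerance = 1e-10)
    expect_true(all(shortest_paths(g) == igraph::distances(ig)))
  }
})

test_that("isolated-node conventions keep all metrics finite", {
  A <- matrix(0, 5, 5); A[1, 2] <- A[2, 1] <- 1
  m <- nodal_metrics(binary_graph(A))
  expect_true(all(is.finite(as.matrix(m[, -1]))))
  expect_equal(m$path_length[3], 0)
  expect_equal(m$clustering[3], 0)
  expect_equal(m$local_efficiency[3], 0)
  expect_equal(m$global_efficiency[1], 1 / 4)
})

test_that("network summaries are consistent means over node subsets", {
  set.seed(22)
  A <- rand_adjacency(10, 0.5)
  g <- binary_graph(A)
  m <- nodal_metrics(g)
  full <- network_summary(m)
  expect_equal(full$degree, mean(m$degree))
  one <- network_summary(m, node_subset = 3, scope_label = "single")
  expect_equal(one$clustering, m$clustering[m$roi_id == 3])
  # size-weighted half means recover the global mean
  h1 <- network_summary(m, 0:4); h2 <- network_summary(m, 5:9)
  expect_equal((5 * h1$global_efficiency + 5 * h2$global_efficiency) / 10,
               full$global_efficiency)
  expect_error(network_summary(m, integer(0)), "empty")
  expect_error(network_summary(m, 99), "outside")
})

test_that("lattices are more clustered and longer-path than matched random graphs", {
  set.seed(23)
  n <- 30; k <- 3  # density 6/29
  L <- lattice_adjacency(n, k)
  ml <- colMeans(nodal_metrics(binary_graph(L))[, -1])
  p <- sum(L) / (n * (n - 1))
  mr <- colMeans(nodal_metrics(binary_graph(rand_adjacency(n, p)))[, -1])
  expect_gt(ml[["clustering"]], mr[["clustering"]])
  expect_gt(ml[["path_length"]], mr[["path_length"]])
})

test_that("hemispheric metrics equal metrics of the rebuilt submatrix graph", {
  set.seed(24)
  parc <- make_parcellation(20)
  spec <- cohort_spec(n_per_group = c(HC = 2, LGG = 2, HGG = 2))
  S <- build_covariance(parc, spec, effect_spec("HC"))
  x <- simulate_timeseries(S, 120, 0.2, seed = 1)
  conn <- correlation_matrix(x)
  g <- threshold_graph(conn)
  left <- parc$roi_id[parc$hemisphere == "L"]
  sub <- graph_subgraph(g, left)
  idx <- left + 1
  conn_l <- structure(list(z = conn$z[idx, idx], T_effective = 120L,
                           subject_id = "s"), class = "conn_matrix")
  rebuilt <- threshold_graph(conn_l, node_ids = left)
  expect_identical(sub$adjacency, rebuilt$adjacency)
  expect_equal(nodal_metrics(sub), nodal_metrics(rebuilt))
})

test_that("graphs round-trip through TSV", {
  set.seed(25)
  g <- binary_graph(rand_adjacency(8, 0.4), node_ids = 10:17)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_graph_tsv(g, path)
  back <- read_graph_tsv(path)
  expect_identical(back$adjacency, g$adjacency)
  expect_identical(back$node_ids, g$node_ids)
})
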