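test_that("synth_config validates its fields", {
  expect_s3_class(synth_config(0.5, n = 10, m = 5), "synth_config")
  expect_error(synth_config(0), "phi")
  expect_error(synth_config(0.5, sigma = -1), "sigma")
  expect_error(synth_config(0.5, n = 5, n_extra_edges = 100), "non-adjacent")
})

test_that("phi = 1 grows a star: the first node absorbs all children", {
  set.seed(42)
  net <- grow_structural_network(synth_config(1, n = 6, n_extra_edges = 0L))
  expect_equal(nrow(net$edges), 5L)
  expect_equal(net$edges$node_a, rep(0L, 5))
  expect_equal(sort(net$edges$node_b), 1:5)
})

test_that("tree phase yields n-1 edges, connected and acyclic; extra edges add cycles", {
  skip_if_not_installed("igraph")
  for (phi in c(0.2, 0.5, 0.8)) {
    set.seed(round(100 * phi))
    net <- grow_structural_network(synth_config(phi, n = 500, n_extra_edges = 0L))
    expect_equal(nrow(net$edges), 499L)
    g <- igraph::graph_from_edgelist(
      cbind(net$edges$node_a, net$edges$node_b) + 1L, directed = FALSE)
    expect_equal(igraph::components(g)$no, 1L)

    set.seed(round(100 * phi) + 1L)
    net10 <- grow_structural_network(synth_config(phi, n = 500, n_extra_edges = 10L))
    expect_equal(nrow(net10$edges), 509L)
    expect_false(any(duplicated(
      paste(pmin(net10$edges$node_a, net10$edges$node_b),
            pmax(net10$edges$node_a, net10$edges$node_b)))))
    expect_false(any(net10$edges$node_a == net10$edges$node_b))
    g10 <- igraph::graph_from_edgelist(
      cbind(net10$edges$node_a, net10$edges$node_b) + 1L, directed = FALSE)
    comp <- igraph::components(g10)$no
    expect_equal(comp, 1L)
    # cyclomatic number |E| - |V| + components = number of extra edges
    expect_equal(509L - 500L + comp, 10L)
  }
})

test_that("polarity assignment labels exactly floor(|E|/2) edges positive", {
  net4 <- path_network(5)
  net4$edges$polarity <- NA_integer_
  set.seed(1)
  p4 <- assign_edge_polarities(net4)
  expect_equal(sum(p4$edges$polarity == 1L), 2L)
  expect_equal(sum(p4$edges$polarity == -1L), 2L)

  set.seed(2)
  net <- grow_structural_network(synth_config(0.8, n = 500))
  net <- assign_edge_polarities(net)
  expect_equal(sum(net$edges$polarity == 1L), 254L)
  expect_equal(sum(net$edges$polarity == -1L), 255L)
})

test_that("target mean follows the signed neighbor average", {
  # neighbors a,b,c valued 1,2,3 with polarities -,+,-: (2 - 1 - 3) / 3
  expect_equal(mlbundle:::node_target_mean(c(1, 2, 3), c(-1, 1, -1)), -2 / 3)
  expect_equal(mlbundle:::node_target_mean(5, -1), -5)
})

test_that("sigma = 0 collapses every sample to zeros", {
  set.seed(3)
  net <- assign_edge_polarities(
    grow_structural_network(synth_config(0.7, n = 50, n_extra_edges = 2L)))
  s <- synthesize_sample(net, 0)
  expect_equal(s, rep(0, 50))
  expect_error(synthesize_sample(net, -0.1), "nonnegative")
})

test_that("a single positive edge induces the closed-form correlation", {
  # seed ~ N(0, s), other node = seed + N(0, s): cor = s^2 / (s * s*sqrt(2))
  net <- path_network(2, polarity = 1L)
  set.seed(4)
  S <- synthesize_feature_matrix(
    net, synth_config(1, n = 2, m = 400, sigma = 0.2, n_extra_edges = 0L))
  expect_equal(dim(S), c(400L, 2L))
  r <- cor(S[, 1], S[, 2])
  expect_gt(r, 0.55)
  expect_equal(r, 1 / sqrt(2), tolerance = 0.1)

  # a negative edge flips the sign
  netm <- path_network(2, polarity = -1L)
  set.seed(4)
  Sm <- synthesize_feature_matrix(
    netm, synth_config(1, n = 2, m = 400, sigma = 0.2, n_extra_edges = 0L))
  expect_lt(cor(Sm[, 1], Sm[, 2]), -0.55)
})

test_that("empirical correlation signs match edge polarities", {
  set.seed(5)
  for (i in 1:10) {
    net <- random_tree_network(40)
    S <- synthesize_feature_matrix(net, synth_config(0.5, n = 40, m = 400, sigma = 0.2))
    R <- cor(S)
    r_edge <- R[cbind(net$edges$node_a + 1L, net$edges$node_b + 1L)]
    expect_true(all(sign(r_edge) == net$edges$polarity))
  }
})

test_that("feature matrix has the configured shape and finite entries", {
  cfg <- synth_config(0.8, n = 80, m = 60, sigma = 0.2, seed = 6)
  d <- simulate_mlb_data(cfg)
  expect_equal(dim(d$features), c(60L, 80L))
  expect_true(all(is.finite(d$features)))
  expect_equal(colnames(d$features), paste0("f", 0:79))
})

test_that("generation is reproducible for a fixed seed", {
  cfg <- synth_config(0.6, n = 60, m = 30, sigma = 0.2, seed = 99)
  d1 <- simulate_mlb_data(cfg)
  d2 <- simulate_mlb_data(cfg)
  expect_identical(d1$network$edges, d2$network$edges)
  expect_identical(d1$features, d2$features)
})

test_that("stalled growth at tiny phi still reaches n nodes", {
  set.seed(7)
  net <- grow_structural_network(synth_config(0.05, n = 100, n_extra_edges = 0L))
  expect_equal(net$n, 100L)
  expect_equal(nrow(net$edges), 99L)
})

test_that("barbell network plants a single cut node joining two trees", {
  skip_if_not_installed("igraph")
  set.seed(8)
  net <- grow_barbell_network(n_side = 50, phi = 0.5)
  expect_equal(net$n, 101L)
  expect_equal(nrow(net$edges), 100L)
  g <- igraph::graph_from_edgelist(
    cbind(net$edges$node_a, net$edges$node_b) + 1L, directed = FALSE)
  expect_equal(igraph::components(g)$no, 1L)
  # removing the cut node (id 100) disconnects the two sides
  g2 <- igraph::delete_vertices(g, 101)
  expect_equal(igraph::components(g2)$no, 2L)
})
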