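test_that("bundle affinity averages exactly the cross-bundle entries", {
  # |bx| = 2, |by| = 3, all six cross entries 0.5 -> H = 0.5
  A <- matrix(0, 5, 5)
  A[1:2, 3:5] <- 0.5; A[3:5, 1:2] <- 0.5
  layer <- form_bundles(make_regimes(list(c(1, 1, 2, 2, 2))), 1)
  H <- bundle_affinity_matrix(A, layer)
  # canonical ids: size-3 bundle is 1, size-2 bundle is 2
  expect_equal(H[1, 2], 0.5)
  # two singleton bundles pass the raw affinity through
  A2 <- matrix(c(0, .3, .3, 0), 2, 2)
  l2 <- form_bundles(make_regimes(list(c(1, 2))), 1)
  expect_equal(bundle_affinity_matrix(A2, l2)[1, 2], 0.3)
})

test_that("H equals the brute-force double loop on random instances", {
  set.seed(30)
  for (i in 1:20) {
    n <- sample(8:30, 1)
    A <- matrix(runif(n * n), n, n)
    A <- (A + t(A)) / 2; diag(A) <- 0
    labs <- random_label_list(n, 1)[[1]]
    layer <- form_bundles(make_regimes(list(labs)), 1)
    H <- bundle_affinity_matrix(A, layer)
    expect_equal(unname(H), oracle_H(A, layer$labels), tolerance = 1e-12)
  }
})

test_that("the worked six-feature co-cluster entry is exactly 2", {
  regimes <- make_regimes(list(
    rep(1, 6),                 # C1: everything together
    c(1, 1, 1, 2, 2, 2),       # C2: two halves
    c(1, 1, 2, 2, 3, 3)        # C3: three pairs (cluster {3,4} spans both)
  ))
  layer <- form_bundles(regimes, 2)   # bundles {1,2,3} and {4,5,6}
  expect_equal(layer$n_bundles, 2L)
  L <- bundle_cocluster_matrix(regimes, layer, k = 2, r = 3)
  expect_equal(L[1, 2], 2)           # (3+3)/6 + 0 + (1+1)/2
  expect_equal(diag(L), c(`1` = 0, `2` = 0))
})

test_that("r = k leaves only the co-membership term", {
  regimes <- make_regimes(list(rep(1, 6), c(1, 1, 1, 2, 2, 2)))
  layer <- form_bundles(regimes, 2)
  L <- bundle_cocluster_matrix(regimes, layer, k = 2, r = 2)
  expect_equal(L[1, 2], (3 + 3) / 6)  # regime 2 splits them, only regime 1 counts
})

test_that("L equals the set-arithmetic oracle on random regime stacks", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(10:30, 1)
    r <- sample(3:6, 1)
    k <- sample(1:min(3, r), 1)
    labs <- random_label_list(n, r)
    regimes <- make_regimes(labs)
    layer <- form_bundles(regimes, k)
    L <- bundle_cocluster_matrix(regimes, layer, k = k, r = r)
    expect_equal(unname(L), oracle_L(labs, layer$labels, k, r),
                 tolerance = 1e-12)
  }
})

test_that("H and L transform equivariantly under feature permutation", {
  set.seed(32)
  n <- 20
  A <- matrix(runif(n * n), n, n); A <- (A + t(A)) / 2; diag(A) <- 0
  labs <- random_label_list(n, 3)
  regimes <- make_regimes(labs)
  layer <- form_bundles(regimes, 2)
  H <- bundle_affinity_matrix(A, layer)
  L <- bundle_cocluster_matrix(regimes, layer, k = 2, r = 3)
  p <- sample(n)
  regimes_p <- make_regimes(lapply(labs, function(v) v[p]))
  layer_p <- form_bundles(regimes_p, 2)
  H_p <- bundle_affinity_matrix(A[p, p], layer_p)
  L_p <- bundle_cocluster_matrix(regimes_p, layer_p, k = 2, r = 3)
  # canonical bundle order may differ (min-member tie-break follows the
  # permuted positions), so compare as sorted off-diagonal multisets
  expect_equal(sort(H[upper.tri(H)]), sort(H_p[upper.tri(H_p)]),
               tolerance = 1e-12)
  expect_equal(sort(L[upper.tri(L)]), sort(L_p[upper.tri(L_p)]),
               tolerance = 1e-12)
})

test_that("combining proportional scores preserves the network", {
  set.seed(33)
  N <- 6
  H <- matrix(runif(N * N), N, N); H <- (H + t(H)) / 2; diag(H) <- 0
  LH <- combine_scores(H, 3 * H)
  n1 <- score_matrix_to_network(H, "H")
  n2 <- score_matrix_to_network(LH, "LH")
  expect_equal(n1$edges, n2$edges)
  # constant off-diagonals in both matrices give constant combined scores
  C <- matrix(1, N, N); diag(C) <- 0
  comb <- combine_scores(C, 2 * C)
  expect_equal(length(unique(comb[upper.tri(comb)])), 1L)
})

test_that("row-maximum step builds the hand-traced network", {
  M <- matrix(0, 4, 4)
  M[1, 2] <- M[2, 1] <- 0.9
  M[2, 3] <- M[3, 2] <- 0.3
  M[2, 4] <- M[4, 2] <- 0.2
  M[3, 4] <- M[4, 3] <- 0.1
  M[1, 3] <- M[3, 1] <- 0.05
  M[1, 4] <- M[4, 1] <- 0.05
  net <- score_matrix_to_network(M)
  expect_equal(as.data.frame(net$edges),
               data.frame(bundle_a = c(1L, 2L, 2L), bundle_b = c(2L, 3L, 4L)))
})

test_that("component-merging step adds exactly the strongest cross edge", {
  M <- matrix(0, 4, 4)
  M[1, 2] <- M[2, 1] <- 0.9
  M[3, 4] <- M[4, 3] <- 0.8
  M[1, 3] <- M[3, 1] <- 0.2
  M[1, 4] <- M[4, 1] <- 0.1
  M[2, 3] <- M[3, 2] <- 0.15
  M[2, 4] <- M[4, 2] <- 0.05
  net <- score_matrix_to_network(M)
  expect_equal(as.data.frame(net$edges),
               data.frame(bundle_a = c(1L, 1L, 3L), bundle_b = c(2L, 3L, 4L)))
})

test_that("reconstructions always end connected with few step-1 edges", {
  skip_if_not_installed("igraph")
  set.seed(34)
  for (i in 1:20) {
    N <- sample(2:25, 1)
    M <- matrix(runif(N * N), N, N); M <- (M + t(M)) / 2; diag(M) <- 0
    net <- score_matrix_to_network(M)
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = data.frame(name = 1:N))
    expect_equal(igraph::components(g)$no, 1L)
  }
  n1 <- score_matrix_to_network(matrix(0, 1, 1))
  expect_equal(nrow(n1$edges), 0L)
})

test_that("jaccard index behaves as a set overlap", {
  mk <- function(a, b) {
    structure(list(n_nodes = 4L,
                   edges = tibble::tibble(bundle_a = a, bundle_b = b),
                   method = "x"), class = "bundle_network")
  }
  expect_equal(jaccard_index(mk(c(1, 2), c(2, 3)), mk(c(1, 2), c(2, 3))), 1)
  expect_equal(jaccard_index(mk(1, 2), mk(3, 4)), 0)
  # E_r = {ab, bc}, E_t = {ab, cd} -> 1/3
  expect_equal(jaccard_index(mk(c(1, 2), c(2, 3)), mk(c(1, 3), c(2, 4))), 1 / 3)
  expect_equal(jaccard_index(mk(integer(0), integer(0)),
                             mk(integer(0), integer(0))), 1)
  # symmetry
  expect_equal(jaccard_index(mk(1, 2), mk(c(1, 3), c(2, 4))),
               jaccard_index(mk(c(1, 3), c(2, 4)), mk(1, 2)))
})

test_that("edge classification counts satisfy the partition identities", {
  set.seed(35)
  mk <- function(df) structure(list(n_nodes = 10L, edges = df, method = "x"),
                               class = "bundle_network")
  for (i in 1:100) {
    all_pairs <- t(combn(10, 2))
    er <- all_pairs[sample(nrow(all_pairs), sample(0:15, 1)), , drop = FALSE]
    et <- all_pairs[sample(nrow(all_pairs), sample(0:15, 1)), , drop = FALSE]
    cr <- classify_edges(
      mk(tibble::tibble(bundle_a = er[, 1], bundle_b = er[, 2])),
      mk(tibble::tibble(bundle_a = et[, 1], bundle_b = et[, 2])))
    expect_equal(cr$counts$tp + cr$counts$fp, nrow(er))
    expect_equal(cr$counts$tp + cr$counts$fn, nrow(et))
  }
  # identical networks have empty FP/FN
  same <- mk(tibble::tibble(bundle_a = 1L, bundle_b = 2L))
  cr <- classify_edges(same, same)
  expect_equal(cr$counts$fp, 0L)
  expect_equal(cr$counts$fn, 0L)
})

test_that("target network matches the group-projection rule", {
  net <- path_network(5)
  layer <- form_bundles(make_regimes(list(c(1, 1, 2, 2, 3))), 1)
  tgt <- target_bundle_network(layer, net)
  expect_equal(tgt$method, "target")
  adj <- project_group_adjacency(layer, net)
  expect_equal(tgt$edges$bundle_a, adj$group_a)
  expect_equal(tgt$edges$bundle_b, adj$group_b)
})
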