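#' Configuration for synthetic network and data generation
#'
#' Bundles the parameters of the synthetic-data generator: a signed
#' branched structural network is grown first, then a sample-by-feature
#' matrix whose correlations follow that network is synthesized from it.
#'
#' @param phi Branching parameter in (0, 1]. While growing the network,
#'   children are repeatedly attached to the node currently at the head of
#'   the creation-order queue for as long as fresh uniform draws fall below
#'   `phi`. High `phi` yields hub-dominated networks, low `phi` chain-like
#'   ones.
#' @param n Number of nodes (features). Default 500.
#' @param m Number of samples (synthesis replicates). Default 400.
#' @param sigma Standard deviation of the Gaussian noise added at every
#'   node-value assignment. Default 0.2.
#' @param n_extra_edges Number of extra edges added between non-adjacent
#'   node pairs after the tree phase, creating cycles. Default 10.
#' @param seed Integer seed recorded in the configuration; the top-level
#'   generators call `set.seed(seed)` so a configuration fully determines
#'   its outputs.
#'
#' @return An object of class `synth_config` (a named list).
#' @examples
#' synth_config(phi = 0.8, n = 50, m = 40, seed = 1)
#' @export
synth_config <- function(phi, n = 500L, m = 400L, sigma = 0.2,
                         n_extra_edges = 10L, seed = NULL) {
  stopifnot(is.numeric(phi), length(phi) == 1, phi > 0, phi <= 1)
  n <- as.integer(n); m <- as.integer(m); n_extra_edges <- as.integer(n_extra_edges)
  stopifnot(n >= 2, m >= 2, n_extra_edges >= 0)
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0)
    stop("`sigma` must be a single nonnegative number", call. = FALSE)
  max_extra <- n * (n - 1) / 2 - (n - 1)
  if (n_extra_edges > max_extra)
    stop("`n_extra_edges` exceeds the number of non-adjacent pairs a tree leaves free",
         call. = FALSE)
  structure(
    list(phi = phi, n = n, m = m, sigma = sigma,
         n_extra_edges = n_extra_edges, seed = seed),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config> phi=", x$phi, " n=", x$n, " m=", x$m,
      " sigma=", x$sigma, " extra edges=", x$n_extra_edges,
      " seed=", if (is.null(x$seed)) "NULL" else x$seed, "\n", sep = "")
  invisible(x)
}

#' Construct a structural network from an edge table
#'
#' @param n Node count; node ids are `0..n-1`.
#' @param edges Tibble/data frame with integer columns `node_a`, `node_b`
#'   (0-based) and `polarity` (+1, -1, or NA when not yet assigned).
#' @return An object of class `structural_network`.
#' @export
new_structural_network <- function(n, edges) {
  structure(list(n = as.integer(n), edges = edges),
            class = "structural_network")
}

#' @export
print.structural_network <- function(x, ...) {
  pol <- x$edges$polarity
  cat("<structural_network> ", x$n, " nodes, ", nrow(x$edges), " edges",
      if (!all(is.na(pol)))
        paste0(" (", sum(pol == 1L), " positive / ", sum(pol == -1L), " negative)"),
      "\n", sep = "")
  invisible(x)
}

#' Grow a branched structural network
#'
#' Grows a random rooted tree by a branching process and then adds extra
#' edges to create cycles. Nodes are processed in FIFO order of creation:
#' for the node at the head of the queue, children are attached one per
#' uniform draw `u < phi`, and attachment to that node stops at the first
#' draw `u >= phi`. Growth halts the moment the node count reaches `n`,
#' even mid-batch. If the queue empties before `n` nodes exist, a
#' uniformly chosen existing node is re-enqueued so growth always
#' terminates. Finally `n_extra_edges` edges are added between uniformly
#' sampled non-adjacent node pairs.
#'
#' Uses the current RNG state; seed it (or use [simulate_mlb_data()])
#' for reproducibility. Edge polarities are unassigned (`NA`) until
#' [assign_edge_polarities()] is called.
#'
#' @param config A [synth_config()].
#' @return A `structural_network`: node ids `0..n-1` and an edge tibble
#'   with columns `node_a`, `node_b`, `polarity`.
#' @examples
#' set.seed(1)
#' grow_structural_network(synth_config(phi = 0.8, n = 20, n_extra_edges = 2))
#' @export
grow_structural_network <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n
  phi <- config$phi
  from <- integer(n - 1L)
  to <- integer(n - 1L)
  n_nodes <- 1L
  n_edges <- 0L
  queue <- 0L
  while (n_nodes < n) {
    if (length(queue) == 0L) {
      # growth stalled: resume from a uniformly chosen existing node
      queue <- sample.int(n_nodes, 1L) - 1L
    }
    parent <- queue[1L]
    queue <- queue[-1L]
    while (stats::runif(1) < phi) {
      child <- n_nodes          # 0-based id of the new node
      n_nodes <- n_nodes + 1L
      n_edges <- n_edges + 1L
      from[n_edges] <- parent
      to[n_edges] <- child
      queue <- c(queue, child)
      if (n_nodes == n) break   # truncate mid-batch
    }
  }
  edges <- tibble::tibble(node_a = from[seq_len(n_edges)],
                          node_b = to[seq_len(n_edges)],
                          polarity = NA_integer_)
  net <- new_structural_network(n, edges)
  add_random_edges(net, config$n_extra_edges)
}

# Add `k` edges between uniformly sampled non-adjacent node pairs
# (rejection sampling; no self-loops, no duplicates).
add_random_edges <- function(net, k) {
  if (k == 0L) return(net)
  n <- net$n
  have <- new.env(hash = TRUE, size = nrow(net$edges) + k)
  pair_key <- function(a, b) paste0(min(a, b), "_", max(a, b))
  for (i in seq_len(nrow(net$edges)))
    assign(pair_key(net$edges$node_a[i], net$edges$node_b[i]), TRUE, envir = have)
  if (n * (n - 1) / 2 - nrow(net$edges) < k)
    stop("not enough non-adjacent node pairs to add ", k, " edges", call. = FALSE)
  added_a <- integer(k); added_b <- integer(k)
  got <- 0L
  while (got < k) {
    ab <- sample.int(n, 2L) - 1L
    key <- pair_key(ab[1L], ab[2L])
    if (!exists(key, envir = have, inherits = FALSE)) {
      assign(key, TRUE, envir = have)
      got <- got + 1L
      added_a[got] <- min(ab); added_b[got] <- max(ab)
    }
  }
  net$edges <- dplyr::bind_rows(
    net$edges,
    tibble::tibble(node_a = added_a, node_b = added_b, polarity = NA_integer_)
  )
  net
}

#' Assign random edge polarities
#'
#' Labels a uniformly random subset of exactly `floor(|E|/2)` edges with
#' polarity `+1` and the remaining edges with `-1`.
#'
#' @param net A `structural_network`.
#' @return The network with the `polarity` column filled in.
#' @export
assign_edge_polarities <- function(net) {
  stopifnot(inherits(net, "structural_network"))
  ne <- nrow(net$edges)
  if (ne == 0L) return(net)
  pol <- rep(-1L, ne)
  n_pos <- ne %/% 2L
  if (n_pos > 0L) pol[sample.int(ne, n_pos)] <- 1L
  net$edges$polarity <- pol
  net
}

# Sorted adjacency list with matching edge polarities, used by the
# value-assignment traversal. adj[[i+1]] = neighbor ids of node i
# (ascending), pol[[i+1]] = polarity of the connecting edges.
adjacency_list <- function(net) {
  n <- net$n
  e <- net$edges
  nbr <- vector("list", n)
  pol <- vector("list", n)
  deg <- integer(n)
  ends_a <- e$node_a + 1L; ends_b <- e$node_b + 1L
  for (i in seq_len(nrow(e))) {
    a <- ends_a[i]; b <- ends_b[i]; p <- e$polarity[i]
    nbr[[a]] <- c(nbr[[a]], b - 1L); pol[[a]] <- c(pol[[a]], p)
    nbr[[b]] <- c(nbr[[b]], a - 1L); pol[[b]] <- c(pol[[b]], p)
  }
  for (i in seq_len(n)) {
    o <- order(nbr[[i]])
    nbr[[i]] <- nbr[[i]][o]
    pol[[i]] <- pol[[i]][o]
  }
  list(nbr = nbr, pol = pol)
}

# Target mean for a node given the values and edge polarities of its
# already-assigned neighbors: mu = sum(eps_j * c_j) / |N*|.
node_target_mean <- function(values, polarities) {
  stopifnot(length(values) == length(polarities), length(values) >= 1)
  sum(polarities * values) / length(values)
}

#' Synthesize one sample of node values
#'
#' Assigns a value to every node of a polarized structural network. A seed
#' node is chosen uniformly and drawn from Normal(0, sigma); the remaining
#' nodes are visited breadth-first from the seed (children in ascending id
#' order). A node whose neighbors are all still unassigned draws from
#' Normal(0, sigma); otherwise its target mean is the polarity-signed
#' average of its assigned neighbors' values and it draws from
#' Normal(mean, sigma). Positive edges therefore induce positive
#' correlation between adjacent features, negative edges negative
#' correlation.
#'
#' @param net A polarized, connected `structural_network`.
#' @param sigma Noise standard deviation (>= 0).
#' @param adj Optional precomputed adjacency list (internal reuse).
#' @return Numeric vector of length `n`, one value per node id `0..n-1`.
#' @export
synthesize_sample <- function(net, sigma, adj = NULL) {
  stopifnot(inherits(net, "structural_network"))
  if (sigma < 0) stop("`sigma` must be nonnegative", call. = FALSE)
  if (anyNA(net$edges$polarity))
    stop("network has unpolarized edges; call assign_edge_polarities() first",
         call. = FALSE)
  if (is.null(adj)) adj <- adjacency_list(net)
  n <- net$n
  values <- numeric(n)
  assigned <- logical(n)
  seed <- sample.int(n, 1L) - 1L
  # breadth-first visit order from the seed, children ascending by id
  order_visit <- integer(n)
  seen <- logical(n)
  order_visit[1L] <- seed; seen[seed + 1L] <- TRUE
  head <- 1L; filled <- 1L
  while (head <= filled) {
    cur <- order_visit[head]; head <- head + 1L
    for (nb in adj$nbr[[cur + 1L]]) {
      if (!seen[nb + 1L]) {
        seen[nb + 1L] <- TRUE
        filled <- filled + 1L
        order_visit[filled] <- nb
      }
    }
  }
  if (filled < n) stop("structural network is not connected", call. = FALSE)
  for (v in order_visit) {
    nbrs <- adj$nbr[[v + 1L]]
    ok <- assigned[nbrs + 1L]
    mu <- if (any(ok)) {
      node_target_mean(values[nbrs[ok] + 1L], adj$pol[[v + 1L]][ok])
    } else 0
    values[v + 1L] <- stats::rnorm(1L, mean = mu, sd = sigma)
    assigned[v + 1L] <- TRUE
  }
  values
}

#' Synthesize a sample-by-feature matrix
#'
#' Stacks `m` independent [synthesize_sample()] replicates as rows.
#'
#' @param net A polarized `structural_network`.
#' @param config A [synth_config()]; `m` and `sigma` are used.
#' @return An `m x n` numeric matrix with feature columns `f0..f{n-1}`.
#' @export
synthesize_feature_matrix <- function(net, config) {
  stopifnot(inherits(config, "synth_config"))
  adj <- adjacency_list(net)
  S <- matrix(0, nrow = config$m, ncol = net$n,
              dimnames = list(NULL, paste0("f", seq_len(net$n) - 1L)))
  for (i in seq_len(config$m))
    S[i, ] <- synthesize_sample(net, config$sigma, adj = adj)
  S
}

#' Generate a full synthetic dataset
#'
#' One-call generator: seeds the RNG from `config$seed` (when present),
#' grows the structural network, polarizes its edges and synthesizes the
#' feature matrix, so a configuration determines the dataset completely.
#'
#' @param config A [synth_config()].
#' @return A list with elements `network` (a `structural_network`),
#'   `features` (an `m x n` matrix) and `config`.
#' @examples
#' d <- simulate_mlb_data(synth_config(phi = 0.8, n = 40, m = 60, seed = 7))
#' dim(d$features)
#' @export
simulate_mlb_data <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  net <- grow_structural_network(config)
  net <- assign_edge_polarities(net)
  S <- synthesize_feature_matrix(net, config)
  list(network = net, features = S, config = config)
}

#' Grow a planted two-community "barbell" network
#'
#' Benchmark network with a known global bridge: two branched trees of
#' `n_side` nodes each are grown independently with branching parameter
#' `phi`, and a single cut node (the last node id, `2 * n_side`) is
#' attached to the root of each tree. Removing the cut node disconnects
#' the two communities, so it is the planted bridge set.
#'
#' Uses the current RNG state. Polarities are assigned (half "+").
#'
#' @param n_side Nodes per community (default 50).
#' @param phi Branching parameter used to grow each side.
#' @return A polarized `structural_network` with `2 * n_side + 1` nodes;
#'   the cut node has id `2 * n_side`.
#' @export
grow_barbell_network <- function(n_side = 50L, phi = 0.5) {
  n_side <- as.integer(n_side)
  stopifnot(n_side >= 2)
  cfg_side <- synth_config(phi = phi, n = n_side, m = 2L, n_extra_edges = 0L)
  t1 <- grow_structural_network(cfg_side)
  t2 <- grow_structural_network(cfg_side)
  cut <- 2L * n_side
  edges <- dplyr::bind_rows(
    t1$edges,
    dplyr::mutate(t2$edges, node_a = .data$node_a + n_side,
                  node_b = .data$node_b + n_side),
    tibble::tibble(node_a = c(0L, n_side), node_b = c(cut, cut),
                   polarity = NA_integer_)
  )
  assign_edge_polarities(new_structural_network(cut + 1L, edges))
}
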