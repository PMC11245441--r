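# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (set arithmetic, double loops) so they check the
# vectorized implementations from a different route.

# A partition as a canonical set of sets (each sorted, ordered by first
# member) so partitions can be compared independent of label values.
partition_sets <- function(labels) {
  s <- unname(split(seq_along(labels), labels))
  s <- lapply(s, sort)
  s[order(vapply(s, min, integer(1)))]
}

# Brute-force bundle enumeration: all combinations of one cluster per
# regime, intersected, nonempty kept.
oracle_bundles <- function(label_matrix) {
  regs <- lapply(seq_len(ncol(label_matrix)), function(j) {
    split(seq_len(nrow(label_matrix)), label_matrix[, j])
  })
  combos <- expand.grid(lapply(regs, seq_along))
  out <- list()
  for (i in seq_len(nrow(combos))) {
    members <- Reduce(intersect,
                      lapply(seq_along(regs),
                             function(j) regs[[j]][[combos[i, j]]]))
    if (length(members) > 0) out[[length(out) + 1L]] <- sort(members)
  }
  out[order(vapply(out, min, integer(1)))]
}

# Double-loop bundle affinity mean.
oracle_H <- function(A, labels) {
  N <- max(labels)
  H <- matrix(0, N, N)
  for (x in seq_len(N)) {
    for (y in seq_len(N)) {
      bx <- which(labels == x); by <- which(labels == y)
      H[x, y] <- sum(A[bx, by]) / (length(bx) * length(by))
    }
  }
  H
}

# Set-arithmetic co-cluster score: for every regime 1..r and every
# cluster with members of both bundles, add the bundles' joint fraction
# of the cluster. For regimes <= k bundles sit wholly inside one
# cluster, so this reduces to the first-term formula.
oracle_L <- function(regime_labels, bundle_labels, k, r) {
  N <- max(bundle_labels)
  bundles <- lapply(seq_len(N), function(b) which(bundle_labels == b))
  L <- matrix(0, N, N)
  for (x in seq_len(N)) {
    for (y in seq_len(N)) {
      if (x == y) next
      s <- 0
      for (l in seq_len(r)) {
        rl <- regime_labels[[l]]
        for (z in unique(rl)) {
          cz <- which(rl == z)
          ix <- length(intersect(bundles[[x]], cz))
          iy <- length(intersect(bundles[[y]], cz))
          if (ix > 0 && iy > 0) {
            if (l <= k) {
              s <- s + (length(bundles[[x]]) + length(bundles[[y]])) / length(cz)
            } else {
              s <- s + (ix + iy) / length(cz)
            }
          }
        }
      }
      L[x, y] <- s
    }
  }
  L
}

# Exhaustive all-pairs edge scan for group adjacency.
oracle_adjacency <- function(labels, net) {
  N <- max(labels)
  out <- NULL
  for (x in seq_len(N - 1)) {
    for (y in (x + 1):N) {
      mx <- which(labels == x) - 1L
      my <- which(labels == y) - 1L
      hit <- any((net$edges$node_a %in% mx & net$edges$node_b %in% my) |
                 (net$edges$node_a %in% my & net$edges$node_b %in% mx))
      if (hit) out <- rbind(out, c(x, y))
    }
  }
  if (is.null(out)) {
    tibble::tibble(group_a = integer(), group_b = integer())
  } else {
    tibble::tibble(group_a = out[, 1], group_b = out[, 2])
  }
}

# Wrap plain label vectors as clustering_regime objects.
make_regime <- function(labels, rank = 1L) {
  structure(list(rank = rank, n_clusters = max(labels),
                 labels = as.integer(labels)),
            class = "clustering_regime")
}

make_regimes <- function(label_list) {
  lapply(seq_along(label_list), function(i) make_regime(label_list[[i]], i))
}

# Block-diagonal affinity: unit weights inside blocks, zero across,
# zero diagonal.
block_affinity <- function(sizes) {
  n <- sum(sizes)
  A <- matrix(0, n, n)
  stops <- cumsum(sizes)
  starts <- c(1, utils::head(stops, -1) + 1)
  for (b in seq_along(sizes)) {
    idx <- starts[b]:stops[b]
    A[idx, idx] <- 1
  }
  diag(A) <- 0
  A
}

# Random label list: `r` regimes over n features with 1..max_k clusters.
random_label_list <- function(n, r, max_k = 4L) {
  lapply(seq_len(r), function(i) {
    k <- sample(1:max_k, 1)
    labs <- sample(seq_len(k), n, replace = TRUE)
    # guarantee every label occurs so max(labs) = cluster count
    labs[seq_len(k)] <- seq_len(k)
    labs
  })
}

# Path structural network 0-1-2-...-(n-1).
path_network <- function(n, polarity = 1L) {
  new_structural_network(n, tibble::tibble(
    node_a = 0:(n - 2), node_b = 1:(n - 1),
    polarity = rep(as.integer(polarity), n - 1)))
}

# Random tree via random parent attachment, polarized.
random_tree_network <- function(n) {
  parent <- vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1))
  assign_edge_polarities(new_structural_network(n, tibble::tibble(
    node_a = parent - 1L, node_b = 1:(n - 1), polarity = NA_integer_)))
}
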