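# Extract an integer per-node label vector from a partition object
# (clustering_regime, bundle_layer, or a plain integer vector).
partition_labels <- function(partition) {
  if (inherits(partition, "clustering_regime") ||
      inherits(partition, "bundle_layer")) {
    partition$labels
  } else if (is.numeric(partition)) {
    as.integer(partition)
  } else {
    stop("unsupported partition object", call. = FALSE)
  }
}

#' Project a partition onto a structural network
#'
#' Two groups are adjacent iff at least one structural edge joins a
#' member of one to a member of the other. This is the ground-truth
#' neighbor graph used both for bridge factors and as the target bundle
#' network.
#'
#' @param partition A `clustering_regime`, `bundle_layer`, or integer
#'   label vector over the network's nodes (node id i -> element i+1).
#' @param net A `structural_network` with the same node count.
#' @return Tibble with columns `group_a`, `group_b` (`group_a < group_b`),
#'   one row per adjacent group pair; no self-adjacency.
#' @examples
#' net <- new_structural_network(5, tibble::tibble(
#'   node_a = 0:3, node_b = 1:4, polarity = 1L))
#' project_group_adjacency(c(1, 1, 2, 2, 3), net)
#' @export
project_group_adjacency <- function(partition, net) {
  labels <- partition_labels(partition)
  stopifnot(inherits(net, "structural_network"))
  if (length(labels) != net$n)
    stop("partition covers ", length(labels), " nodes but the network has ",
         net$n, call. = FALSE)
  ga <- labels[net$edges$node_a + 1L]
  gb <- labels[net$edges$node_b + 1L]
  keep <- ga != gb
  tibble::tibble(group_a = pmin(ga, gb)[keep],
                 group_b = pmax(ga, gb)[keep]) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$group_a, .data$group_b)
}

#' Bridge factors of a partition
#'
#' The bridge factor of a group x with neighbor set N_x is the product of
#' the neighbor-to-self size ratios, `prod(|y| / |x|)` over `y` in `N_x`,
#' when x has more than one neighbor, and 0 otherwise. It is large for a
#' small group that joins two or more much larger groups — the signature
#' of a bridge set. The product is accumulated in log space so that many
#' large ratios cannot overflow; both `gamma` and `log10_gamma` are
#' reported (`log10_gamma = -Inf` where `gamma = 0`).
#'
#' @param partition A `clustering_regime`, `bundle_layer`, or integer
#'   label vector.
#' @param adjacency Group adjacency tibble from
#'   [project_group_adjacency()] (columns `group_a`, `group_b`).
#' @return A `bridge_report` tibble: `group_id`, `size`, `n_neighbors`,
#'   `gamma`, `log10_gamma`, sorted by descending `gamma` with ties by
#'   smaller `group_id`.
#' @examples
#' adj <- tibble::tibble(group_a = c(1, 1), group_b = c(2, 3))
#' bridge_factors(c(rep(1, 2), rep(2, 10), rep(3, 20)), adj)
#' @export
bridge_factors <- function(partition, adjacency) {
  labels <- partition_labels(partition)
  sizes <- tabulate(labels)
  if (any(sizes == 0)) stop("empty group in partition", call. = FALSE)
  groups <- seq_along(sizes)
  nbrs <- lapply(groups, function(g) {
    c(adjacency$group_b[adjacency$group_a == g],
      adjacency$group_a[adjacency$group_b == g])
  })
  log10_gamma <- vapply(groups, function(g) {
    ny <- nbrs[[g]]
    if (length(ny) <= 1) return(-Inf)
    sum(log10(sizes[ny]) - log10(sizes[g]))
  }, numeric(1))
  out <- tibble::tibble(
    group_id = groups,
    size = sizes,
    n_neighbors = lengths(nbrs),
    gamma = ifelse(is.infinite(log10_gamma) & log10_gamma < 0,
                   0, 10^log10_gamma),
    log10_gamma = log10_gamma
  ) |>
    dplyr::arrange(dplyr::desc(.data$gamma), .data$group_id)
  class(out) <- c("bridge_report", class(out))
  out
}

#' Bridge report across all bundle layers
#'
#' Convenience wrapper: bridge factors of every layer of a fitted MLB
#' object against a structural network (or any other neighbor-graph
#' source you pass as `adjacency_fun`).
#'
#' @param fit An `mlb_fit` from [mlb()].
#' @param net A `structural_network` over the same features.
#' @return Tibble `layer, group_id, size, n_neighbors, gamma,
#'   log10_gamma`.
#' @export
bridge_factors_by_layer <- function(fit, net) {
  stopifnot(inherits(fit, "mlb_fit"))
  purrr::map_dfr(fit$bundles, function(layer) {
    adj <- project_group_adjacency(layer, net)
    rep <- bridge_factors(layer, adj)
    dplyr::mutate(tibble::as_tibble(rep), layer = layer$layer, .before = 1)
  })
}
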