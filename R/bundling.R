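# Canonical bundle ids: descending size, ties by smallest member id.
# `raw` is any integer group labeling; returns labels in 1..N.
canonicalize_groups <- function(raw) {
  raw <- match(raw, unique(raw))
  sizes <- tabulate(raw)
  min_member <- rep(NA_integer_, length(sizes))
  first_seen <- !duplicated(raw)
  min_member[raw[first_seen]] <- which(first_seen)
  ord <- order(-sizes, min_member)
  rank_of <- integer(length(ord))
  rank_of[ord] <- seq_along(ord)
  rank_of[raw]
}

#' Form bundles at a given layer
#'
#' A layer-`layer` bundle is a maximal set of features that share a
#' cluster in every one of the `layer` most prominent clustering regimes;
#' equivalently the nonempty intersections of one cluster drawn from each
#' regime. Implemented as equivalence classes of the per-feature label
#' tuple, which enumerates exactly the nonempty intersections. Bundle ids
#' are canonical: descending bundle size, ties broken by the smallest
#' member feature index.
#'
#' @param regimes List of `clustering_regime` objects (prominence order),
#'   all over the same feature set.
#' @param layer Number of regimes to intersect (`1..length(regimes)`).
#' @return A `bundle_layer`: list with `layer`, `n_bundles`, integer
#'   `labels` (length n, values `1..n_bundles`), `sizes`, and
#'   `provenance` (matrix of defining regime labels, one row per bundle).
#' @examples
#' r1 <- structure(list(rank = 1, n_clusters = 2L,
#'                      labels = c(1L, 1L, 2L, 2L)), class = "clustering_regime")
#' r2 <- structure(list(rank = 2, n_clusters = 2L,
#'                      labels = c(1L, 2L, 1L, 2L)), class = "clustering_regime")
#' form_bundles(list(r1, r2), 2)$n_bundles  # 4 singletons
#' @export
form_bundles <- function(regimes, layer) {
  stopifnot(layer >= 1, layer <= length(regimes))
  labs <- vapply(regimes[seq_len(layer)], function(r) {
    stopifnot(inherits(r, "clustering_regime"))
    r$labels
  }, integer(length(regimes[[1]]$labels)))
  labs <- matrix(labs, ncol = layer)
  if (layer == 1L) {
    key <- labs[, 1L]
  } else {
    key <- do.call(paste, c(lapply(seq_len(layer), function(j) labs[, j]),
                            sep = "\r"))
  }
  labels <- canonicalize_groups(match(key, unique(key)))
  n_b <- max(labels)
  first_row <- match(seq_len(n_b), labels)
  structure(
    list(layer = as.integer(layer), n_bundles = n_b,
         labels = labels, sizes = tabulate(labels),
         provenance = labs[first_row, , drop = FALSE]),
    class = "bundle_layer"
  )
}

#' @export
print.bundle_layer <- function(x, ...) {
  cat("<bundle_layer> layer ", x$layer, ": ", x$n_bundles,
      " bundle(s); sizes ", paste(utils::head(x$sizes, 10), collapse = ", "),
      if (x$n_bundles > 10) ", ...", "\n", sep = "")
  invisible(x)
}

#' All bundle layers up to k
#'
#' @param regimes List of `clustering_regime`s in prominence order.
#' @param k Deepest layer.
#' @return List of `bundle_layer` objects for layers `1..k`.
#' @export
bundle_layers <- function(regimes, k) {
  stopifnot(k >= 1, k <= length(regimes))
  lapply(seq_len(k), function(l) form_bundles(regimes, l))
}

#' Bundle-size profile across layers
#'
#' For each layer, counts the bundles with at least `t` members for each
#' threshold `t`. The profile is how one picks a stopping layer: the
#' bundle count can only grow with depth, and a layer where the counts at
#' every threshold stop changing ("plateau") is a natural stopping point.
#' The first such layer is flagged in the `plateau_layer` attribute (NA
#' when no plateau occurs within the provided layers).
#'
#' @param layers List of `bundle_layer`s, ordered by layer.
#' @param thresholds Integer vector of minimum bundle sizes
#'   (default `c(1, 5, 50)`; threshold 1 counts all bundles).
#' @return A tibble with columns `layer`, `threshold`, `count`.
#' @export
bundle_size_profile <- function(layers, thresholds = c(1L, 5L, 50L)) {
  stopifnot(length(layers) >= 1)
  thresholds <- sort(unique(as.integer(thresholds)))
  tab <- tidyr::expand_grid(
    layer = vapply(layers, function(l) l$layer, integer(1)),
    threshold = thresholds
  )
  tab$count <- purrr::map2_int(tab$layer, tab$threshold, function(l, t) {
    sz <- layers[[which(vapply(layers, function(x) x$layer, integer(1)) == l)]]$sizes
    sum(sz >= t)
  })
  plateau <- NA_integer_
  if (length(layers) >= 2) {
    counts_by_layer <- split(tab$count, tab$layer)
    lys <- as.integer(names(counts_by_layer))
    for (i in 2:length(lys)) {
      if (identical(counts_by_layer[[i]], counts_by_layer[[i - 1L]])) {
        plateau <- lys[i]
        break
      }
    }
  }
  attr(tab, "plateau_layer") <- plateau
  tab
}

#' Plot the bundle-size profile
#'
#' @param profile Output of [bundle_size_profile()].
#' @return A ggplot object: bundle counts vs layer, one line per size
#'   threshold.
#' @export
plot_size_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$layer, y = .data$count,
                               colour = factor(.data$threshold))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "bundle layer", y = "number of bundles",
                  colour = "min size") +
    ggplot2::theme_minimal()
}

#' Bundle eigengene
#'
#' First principal component of a bundle's feature submatrix across
#' samples, the standard one-vector summary of a co-expression module.
#' Features are standardized (mean 0, unit variance) before the
#' decomposition, and the sign is fixed so the eigengene correlates
#' nonnegatively with the bundle's mean standardized feature.
#'
#' @param S Sample-by-feature matrix (or data frame).
#' @param features Feature selector for the bundle: column names or
#'   1-based column indices.
#' @return Numeric vector of length `m` (the PC1 score per sample), with
#'   attribute `explained_variance` (fraction of bundle variance carried
#'   by the eigengene).
#' @export
bundle_eigengene <- function(S, features) {
  S <- as.matrix(S)
  X <- S[, features, drop = FALSE]
  if (ncol(X) == 0) stop("empty bundle", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance feature in bundle; eigengene undefined", call. = FALSE)
  Xs <- scale(X)
  sv <- svd(Xs, nu = 1, nv = 0)
  eg <- sv$u[, 1] * sv$d[1]
  ref <- rowMeans(Xs)
  if (sum(eg * ref) < 0) eg <- -eg
  attr(eg, "explained_variance") <- sv$d[1]^2 / sum(sv$d^2)
  eg
}

#' Sankey-style membership flow between consecutive layers
#'
#' @param layers List of `bundle_layer`s ordered by layer.
#' @return Tibble `layer_from, bundle_from, layer_to, bundle_to,
#'   n_members`, one row per parent/child bundle pair with shared
#'   members; suitable for external alluvial/Sankey plotting.
#' @export
bundle_flow <- function(layers) {
  if (length(layers) < 2) {
    return(tibble::tibble(layer_from = integer(), bundle_from = integer(),
                          layer_to = integer(), bundle_to = integer(),
                          n_members = integer()))
  }
  purrr::map_dfr(seq_len(length(layers) - 1L), function(i) {
    a <- layers[[i]]; b <- layers[[i + 1L]]
    tibble::tibble(bundle_from = a$labels, bundle_to = b$labels) |>
      dplyr::count(.data$bundle_from, .data$bundle_to, name = "n_members") |>
      dplyr::mutate(layer_from = a$layer, layer_to = b$layer,
                    .before = 1) |>
      dplyr::relocate("layer_from", "bundle_from", "layer_to", "bundle_to")
  })
}
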