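#' Fit a multi-layer bundling model
#'
#' End-to-end fit: Pearson |correlation| affinity from the data (or a
#' user-supplied affinity), normalized-Laplacian spectrum with eigengap
#' ranking, the `r` most prominent clustering regimes, and bundle layers
#' `1..k` by recursive intersection of the regimes.
#'
#' @param S Sample-by-feature matrix or data frame (ignored if
#'   `affinity` is given as an `mlb_affinity`).
#' @param k Deepest bundle layer (default 5).
#' @param r Regime horizon used by the co-cluster matrix, `r >= k`
#'   (default 12).
#' @param affinity Optional precomputed `mlb_affinity` or symmetric
#'   affinity matrix.
#' @return An `mlb_fit`: list with `affinity`, `spectrum`, `regimes`
#'   (list of `clustering_regime`), `bundles` (list of `bundle_layer`),
#'   `k`, `r`, `n_features`, `n_samples`.
#' @examples
#' d <- simulate_mlb_data(synth_config(0.8, n = 60, m = 80, seed = 3))
#' fit <- mlb(d$features, k = 3, r = 5)
#' glance(fit)
#' @export
mlb <- function(S = NULL, k = 5L, r = 12L, affinity = NULL) {
  k <- as.integer(k); r <- as.integer(r)
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  if (r < k) stop("`r` must be >= `k`", call. = FALSE)
  n_samples <- NA_integer_
  if (is.null(affinity)) {
    if (is.null(S)) stop("supply `S` or `affinity`", call. = FALSE)
    n_samples <- nrow(S)
    affinity <- compute_affinity(S)
  } else if (!inherits(affinity, "mlb_affinity")) {
    affinity <- as_affinity(affinity)
  }
  spectrum <- spectral_decompose(affinity)
  n <- length(spectrum$values)
  if (r > n - 1)
    stop("`r` must be <= n - 1 = ", n - 1L, call. = FALSE)
  regimes <- top_regimes(spectrum, r)
  bundles <- bundle_layers(regimes, k)
  structure(
    list(affinity = affinity, spectrum = spectrum, regimes = regimes,
         bundles = bundles, k = k, r = r,
         n_features = n, n_samples = n_samples),
    class = "mlb_fit"
  )
}

#' @export
print.mlb_fit <- function(x, ...) {
  cat("<mlb_fit> ", x$n_features, " features",
      if (!is.na(x$n_samples)) paste0(", ", x$n_samples, " samples"),
      "; k=", x$k, ", r=", x$r, "\n", sep = "")
  cat("  regime cluster counts: ",
      paste(vapply(x$regimes, function(r) r$n_clusters, integer(1)),
            collapse = ", "), "\n", sep = "")
  cat("  bundles per layer: ",
      paste(vapply(x$bundles, function(b) b$n_bundles, integer(1)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy per-feature bundle assignments
#'
#' @param x An `mlb_fit`.
#' @param ... Unused.
#' @return Tibble `feature_id` (0-based), `feature`, `layer`, `bundle`.
#' @method tidy mlb_fit
#' @export
tidy.mlb_fit <- function(x, ...) {
  ids <- x$spectrum$feature_ids
  purrr::map_dfr(x$bundles, function(b) {
    tibble::tibble(feature_id = seq_along(ids) - 1L, feature = ids,
                   layer = b$layer, bundle = b$labels)
  })
}

#' One-row fit summary
#'
#' @param x An `mlb_fit`.
#' @param ... Unused.
#' @return Tibble with `n_features`, `n_samples`, `k`, `r`,
#'   `n_bundles_deepest`, `largest_eigengap_at`.
#' @method glance mlb_fit
#' @export
glance.mlb_fit <- function(x, ...) {
  tibble::tibble(
    n_features = x$n_features,
    n_samples = x$n_samples,
    k = x$k,
    r = x$r,
    n_bundles_deepest = x$bundles[[x$k]]$n_bundles,
    largest_eigengap_at = x$spectrum$kappa[1]
  )
}
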