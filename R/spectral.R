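#' Affinity matrix from a sample-by-feature matrix
#'
#' Computes the Pearson correlation matrix `R` between feature columns and
#' the affinity matrix `A = |R|` with its diagonal set to zero, so that
#' the affinity graph has no self-edges and the degree of a feature is the
#' sum of its affinities to the other features.
#'
#' @param S An `m x n` numeric matrix or data frame, rows = samples,
#'   columns = features. At least 3 samples; no feature may have zero
#'   variance (its correlations would be undefined).
#' @return An object of class `mlb_affinity` with matrix fields `R` and `A`.
#' @examples
#' S <- cbind(a = rnorm(30), b = rnorm(30))
#' compute_affinity(cbind(S, c = S[, "a"] + rnorm(30, sd = 0.1)))
#' @export
compute_affinity <- function(S) {
  S <- as.matrix(S)
  if (!is.numeric(S)) stop("`S` must be numeric", call. = FALSE)
  if (nrow(S) < 3) stop("need at least 3 samples to estimate correlations",
                        call. = FALSE)
  if (anyNA(S) || any(!is.finite(S)))
    stop("`S` contains missing or non-finite values", call. = FALSE)
  sds <- apply(S, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(S)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0) - 1L
    stop("zero-variance feature(s): ", paste(bad, collapse = ", "),
         "; correlation is undefined", call. = FALSE)
  }
  R <- stats::cor(S)
  A <- abs(R)
  diag(A) <- 0
  structure(list(R = R, A = A), class = "mlb_affinity")
}

#' @export
print.mlb_affinity <- function(x, ...) {
  cat("<mlb_affinity> ", nrow(x$A), " features; |Pearson| affinity, zero diagonal\n",
      sep = "")
  invisible(x)
}

#' Wrap a precomputed affinity matrix
#'
#' For users supplying their own similarity matrix instead of raw data.
#' The matrix must be symmetric and nonnegative; its diagonal is zeroed.
#'
#' @param A A symmetric nonnegative numeric matrix.
#' @param R Optional signed matrix (e.g. correlations) to carry alongside.
#' @return An `mlb_affinity` object.
#' @export
as_affinity <- function(A, R = NULL) {
  A <- as.matrix(A)
  if (!isSymmetric(unname(A), tol = 1e-10))
    stop("affinity matrix must be symmetric", call. = FALSE)
  if (any(A < 0)) stop("affinity matrix must be nonnegative", call. = FALSE)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  if (is.null(R)) R <- A
  structure(list(R = R, A = A), class = "mlb_affinity")
}

# Rank eigengaps: delta_i = lambda_{i+1} - lambda_i, kappa = eigenvalue
# indices ordered by descending gap, ties broken by the smaller index.
rank_eigengaps <- function(lambda) {
  delta <- diff(lambda)
  kappa <- order(-delta, seq_along(delta))
  list(delta = delta, kappa = kappa)
}

#' Spectral decomposition of the affinity graph
#'
#' Builds the degree matrix `D` (`D_ii = sum_{j != i} A_ij`), the graph
#' Laplacian `Q = D - A` and its symmetric normalization
#' `Qhat = D^{-1/2} Q D^{-1/2}`, then eigendecomposes `Qhat`. Eigenvalues
#' are returned in ascending order (`lambda_1 ~ 0` for a connected
#' affinity graph; the multiplicity of 0 equals the number of connected
#' components). Eigengaps `delta_i = lambda_{i+1} - lambda_i` are ranked
#' in descending order: the i-th most prominent clustering regime has
#' `kappa_i` clusters, where `kappa_i` is the index of the i-th largest
#' gap. Ties go to the smaller index.
#'
#' @param x An `mlb_affinity` (from [compute_affinity()] or
#'   [as_affinity()]) or a raw symmetric nonnegative matrix.
#' @return An object of class `mlb_spectrum` with fields `degree`,
#'   `Qhat`, `values`, `vectors`, `gaps`, `kappa`.
#' @examples
#' S <- matrix(rnorm(200), 20, 10)
#' sp <- spectral_decompose(compute_affinity(S))
#' sp$kappa[1:3]
#' @export
spectral_decompose <- function(x) {
  if (!inherits(x, "mlb_affinity")) x <- as_affinity(x)
  A <- x$A
  d <- rowSums(A)
  if (any(d <= 0)) {
    bad <- which(d <= 0) - 1L
    stop("isolated feature(s) with zero affinity degree: ",
         paste(utils::head(bad, 5), collapse = ", "),
         "; normalized Laplacian undefined", call. = FALSE)
  }
  inv_sqrt_d <- 1 / sqrt(d)
  # Qhat = I - D^{-1/2} A D^{-1/2} since diag(A) = 0
  Qhat <- -A * tcrossprod(inv_sqrt_d)
  diag(Qhat) <- 1
  Qhat <- (Qhat + t(Qhat)) / 2
  eig <- eigen(Qhat, symmetric = TRUE)
  values <- rev(eig$values)
  vectors <- eig$vectors[, rev(seq_along(eig$values)), drop = FALSE]
  if (values[1] < -1e-8 || abs(values[1]) > 1e-6)
    warning("smallest eigenvalue of the normalized Laplacian is ",
            format(values[1]), "; expected ~0")
  rk <- rank_eigengaps(values)
  structure(
    list(degree = d, Qhat = Qhat, values = values, vectors = vectors,
         gaps = rk$delta, kappa = rk$kappa,
         feature_ids = colnames(A) %||% paste0("f", seq_len(ncol(A)) - 1L)),
    class = "mlb_spectrum"
  )
}

#' @export
print.mlb_spectrum <- function(x, ...) {
  cat("<mlb_spectrum> ", length(x$values), " features\n", sep = "")
  cat("  top regimes (clusters): ",
      paste(utils::head(x$kappa, 8), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy eigenvalue/eigengap table
#'
#' @param x An `mlb_spectrum`.
#' @param ... Unused.
#' @return A tibble with columns `index`, `eigenvalue`, `eigengap`
#'   (`NA` for the last index) and `prominence` (rank of the gap; 1 =
#'   largest, `NA` for the last index).
#' @method tidy mlb_spectrum
#' @export
tidy.mlb_spectrum <- function(x, ...) {
  n <- length(x$values)
  prom <- rep(NA_integer_, n - 1L)
  prom[x$kappa] <- seq_along(x$kappa)
  tibble::tibble(
    index = seq_len(n),
    eigenvalue = x$values,
    eigengap = c(x$gaps, NA_real_),
    prominence = c(prom, NA_integer_)
  )
}

# cluster-qr label assignment (Damle, Minden & Ying 2019): a
# column-pivoted QR of the transposed spectral embedding picks k anchor
# rows; the polar factor of the anchor block rotates the embedding so
# that each row is labeled by the arg-max of its absolute entries.
# Deterministic for a fixed embedding and robust to eigenvector signs.
cluster_qr <- function(V) {
  k <- ncol(V)
  piv <- qr(t(V), LAPACK = TRUE)$pivot
  anchors <- piv[seq_len(k)]
  sv <- svd(t(V[anchors, , drop = FALSE]))
  rotation <- sv$u %*% t(sv$v)
  max.col(abs(V %*% rotation), ties.method = "first")
}

#' Extract one clustering regime
#'
#' The i-th most prominent clustering regime partitions the features into
#' `kappa_i` clusters, where `kappa_i` indexes the i-th largest eigengap.
#' The spectral embedding uses the eigenvectors of the `kappa_i` smallest
#' eigenvalues of the normalized Laplacian with rows rescaled by
#' `D^{-1/2}` (the random-walk eigenvectors, as in scikit-learn's
#' spectral embedding), and is labeled with the cluster-qr algorithm;
#' with `kappa_i = 1` all features share one cluster. Label values are
#' arbitrary; only the partition is meaningful, and it is deterministic
#' for a fixed spectrum.
#'
#' @param spectrum An `mlb_spectrum`.
#' @param rank Prominence rank `i` of the regime (1 = most prominent).
#' @return A `clustering_regime`: list with `rank`, `n_clusters`, and
#'   integer `labels` (length n, values in `1..n_clusters`).
#' @export
cluster_regime <- function(spectrum, rank) {
  stopifnot(inherits(spectrum, "mlb_spectrum"))
  n <- length(spectrum$values)
  if (rank < 1 || rank > n - 1) stop("`rank` must be in 1..n-1", call. = FALSE)
  k <- spectrum$kappa[rank]
  labels <- if (k == 1L) {
    rep(1L, n)
  } else {
    V <- spectrum$vectors[, seq_len(k), drop = FALSE] / sqrt(spectrum$degree)
    cluster_qr(V)
  }
  structure(list(rank = rank, n_clusters = as.integer(k),
                 labels = as.integer(labels)),
            class = "clustering_regime")
}

#' @export
print.clustering_regime <- function(x, ...) {
  cat("<clustering_regime> rank ", x$rank, ": ", x$n_clusters,
      " cluster(s) over ", length(x$labels), " features\n", sep = "")
  invisible(x)
}

#' The r most prominent clustering regimes
#'
#' @param spectrum An `mlb_spectrum`.
#' @param r Number of regimes, in `1..n-1`.
#' @return List of `clustering_regime` objects in prominence order.
#' @export
top_regimes <- function(spectrum, r) {
  stopifnot(inherits(spectrum, "mlb_spectrum"))
  n <- length(spectrum$values)
  if (r < 1 || r > n - 1) stop("`r` must be in 1..n-1", call. = FALSE)
  lapply(seq_len(r), function(i) cluster_regime(spectrum, i))
}

#' Eigenvalue spectrum plot
#'
#' Ascending eigenvalues of the normalized Laplacian with the most
#' prominent eigengaps annotated; the standard visual aid for choosing
#' cluster numbers.
#'
#' @param object An `mlb_spectrum`.
#' @param n_show Number of smallest eigenvalues to display (default 15).
#' @param n_label Number of top eigengaps to annotate (default 5).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mlb_spectrum
#' @export
autoplot.mlb_spectrum <- function(object, n_show = 15, n_label = 5, ...) {
  tab <- tidy.mlb_spectrum(object)
  tab <- tab[seq_len(min(n_show, nrow(tab))), ]
  lab <- tab[!is.na(tab$prominence) & tab$prominence <= n_label, ]
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$index, y = .data$eigenvalue)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(linetype = "dotted") +
    ggplot2::geom_text(
      data = lab,
      ggplot2::aes(label = paste0("κ=", .data$index)),
      vjust = -0.8, size = 3
    ) +
    ggplot2::labs(x = "eigenvalue index", y = "eigenvalue",
                  title = "Normalized Laplacian spectrum") +
    ggplot2::theme_minimal()
}
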