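new_bundle_network <- function(n_nodes, edges, method) {
  structure(list(n_nodes = as.integer(n_nodes),
                 edges = edges, method = method),
            class = "bundle_network")
}

#' @export
print.bundle_network <- function(x, ...) {
  cat("<bundle_network> [", x$method, "] ", x$n_nodes, " bundles, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Bundle affinity matrix H
#'
#' Entry (x, y) is the mean of the affinities between every member of
#' bundle x and every member of bundle y (|beta_x| * |beta_y| values).
#' The diagonal is computed by the same formula (the zero affinity
#' diagonal contributes) but is never used for edge selection.
#'
#' @param affinity An `mlb_affinity` (or raw affinity matrix).
#' @param layer A `bundle_layer` partitioning the affinity's features.
#' @return A symmetric `N x N` matrix, N = number of bundles, with
#'   bundle ids as dimnames.
#' @export
bundle_affinity_matrix <- function(affinity, layer) {
  A <- if (inherits(affinity, "mlb_affinity")) affinity$A else as.matrix(affinity)
  stopifnot(inherits(layer, "bundle_layer"))
  if (nrow(A) != length(layer$labels))
    stop("affinity and bundle layer cover different feature sets", call. = FALSE)
  N <- layer$n_bundles
  B <- matrix(0, nrow(A), N)
  B[cbind(seq_len(nrow(A)), layer$labels)] <- 1
  H <- crossprod(B, A %*% B) / tcrossprod(layer$sizes)
  H <- (H + t(H)) / 2
  dimnames(H) <- list(seq_len(N), seq_len(N))
  H
}

#' Bundle co-cluster matrix L
#'
#' Accumulates, over clustering regimes 1..r, how strongly two layer-k
#' bundles share clusters. For regimes l <= k each bundle lies wholly
#' inside one cluster; if bundles x and y share that cluster xi, the term
#' `(|beta_x| + |beta_y|) / |xi|` (their joint fraction of the cluster)
#' is added, else 0. For deeper regimes l in (k+1)..r the bundles break
#' apart: every regime-l cluster xi containing members of both bundles
#' contributes `(|beta_x n xi| + |beta_y n xi|) / |xi|`. The diagonal is
#' defined as 0 and never used for edge selection.
#'
#' @param regimes List of `clustering_regime`s 1..r (prominence order).
#' @param layer The `bundle_layer` at layer k, built from regimes 1..k.
#' @param k Bundle layer (defaults to `layer$layer`).
#' @param r Regime horizon, `k <= r <= length(regimes)` (default
#'   `length(regimes)`).
#' @return A symmetric nonnegative `N x N` matrix with zero diagonal.
#' @export
bundle_cocluster_matrix <- function(regimes, layer, k = layer$layer,
                                    r = length(regimes)) {
  stopifnot(inherits(layer, "bundle_layer"))
  if (r < k) stop("`r` must be >= `k`", call. = FALSE)
  if (length(regimes) < r) stop("regimes 1..r required", call. = FALSE)
  N <- layer$n_bundles
  sz <- layer$sizes
  L <- matrix(0, N, N)
  for (l in seq_len(k)) {
    rl <- regimes[[l]]$labels
    # bundle -> its (unique) cluster at regime l
    cl <- rl[match(seq_len(N), layer$labels)]
    csize <- tabulate(rl)
    same <- outer(cl, cl, "==")
    term <- outer(sz, sz, "+") / csize[cl]   # row x divided by |cluster(x)|
    term[!same] <- 0
    L <- L + term
  }
  if (r > k) {
    for (l in (k + 1L):r) {
      rl <- regimes[[l]]$labels
      csize <- tabulate(rl)
      ov <- matrix(0L, N, max(rl))
      tt <- table(factor(layer$labels, levels = seq_len(N)),
                  factor(rl, levels = seq_len(max(rl))))
      ov[] <- as.integer(tt)
      for (z in seq_len(ncol(ov))) {
        memb <- which(ov[, z] > 0L)
        if (length(memb) < 2L) next
        contrib <- outer(ov[memb, z], ov[memb, z], "+") / csize[z]
        L[memb, memb] <- L[memb, memb] + contrib
      }
    }
  }
  diag(L) <- 0
  L <- (L + t(L)) / 2
  dimnames(L) <- list(seq_len(N), seq_len(N))
  L
}

# Min-max scale the off-diagonal entries of a symmetric matrix to [0,1]
# (constant off-diagonals map to 0); diagonal forced to 0.
minmax_offdiag <- function(M) {
  off <- row(M) != col(M)
  v <- M[off]
  rng <- range(v)
  out <- matrix(0, nrow(M), ncol(M), dimnames = dimnames(M))
  if (diff(rng) > 0) out[off] <- (M[off] - rng[1]) / diff(rng)
  out
}

#' Combine H and L into the LH score matrix
#'
#' Each matrix is min-max scaled over its off-diagonal entries to [0,1]
#' and the two are summed; the diagonal stays 0.
#'
#' @param H Bundle affinity matrix.
#' @param L Bundle co-cluster matrix (same layer and dimension).
#' @return Symmetric combined score matrix.
#' @export
combine_scores <- function(H, L) {
  if (!all(dim(H) == dim(L)))
    stop("H and L have different dimensions", call. = FALSE)
  if (nrow(H) == 1L) return(matrix(0, 1, 1, dimnames = dimnames(H)))
  minmax_offdiag(H) + minmax_offdiag(L)
}

# Minimal union-find over 1..n for the incremental component merging in
# the reconstruction's second step.
uf_new <- function(n) seq_len(n)
uf_find <- function(uf, i) {
  while (uf[i] != i) {
    uf[i] <- uf[uf[i]]
    i <- uf[i]
  }
  i
}

#' Reconstruct a bundle network from a score matrix
#'
#' Two-step edge selection. Step 1: each row contributes an edge to the
#' column of its maximal off-diagonal entry (ties to the smallest column
#' index); duplicate pairs collapse, so at most N-1 distinct edges
#' result. Step 2: if more than one connected component remains, the
#' unused off-diagonal entries are scanned once in descending order (ties
#' broken lexicographically by (row, col)); an edge is added iff it
#' reduces the component count, stopping at a single component.
#'
#' @param M Symmetric score matrix (H, L, or LH); diagonal ignored.
#' @param method Tag stored on the result (`"H"`, `"L"`, `"LH"`, ...).
#' @return A `bundle_network` with a single connected component.
#' @export
score_matrix_to_network <- function(M, method = "score") {
  M <- as.matrix(M)
  N <- nrow(M)
  if (N == 0L) stop("empty score matrix", call. = FALSE)
  empty <- tibble::tibble(bundle_a = integer(), bundle_b = integer())
  if (N == 1L) return(new_bundle_network(1L, empty, method))
  # step 1: row maxima
  a <- integer(N); b <- integer(N)
  for (i in seq_len(N)) {
    v <- M[i, ]
    v[i] <- -Inf
    j <- which.max(v)            # first max = smallest column index
    a[i] <- min(i, j); b[i] <- max(i, j)
  }
  edges <- dplyr::distinct(tibble::tibble(bundle_a = a, bundle_b = b))
  uf <- uf_new(N)
  n_comp <- N
  for (i in seq_len(nrow(edges))) {
    ra <- uf_find(uf, edges$bundle_a[i]); rb <- uf_find(uf, edges$bundle_b[i])
    if (ra != rb) { uf[ra] <- rb; n_comp <- n_comp - 1L }
  }
  # step 2: single descending pass over unused entries
  if (n_comp > 1L) {
    ij <- which(upper.tri(M), arr.ind = TRUE)
    cand <- tibble::tibble(bundle_a = ij[, 1], bundle_b = ij[, 2],
                           score = M[ij])
    cand <- dplyr::anti_join(cand, edges, by = c("bundle_a", "bundle_b"))
    cand <- cand[order(-cand$score, cand$bundle_a, cand$bundle_b), ]
    add_a <- integer(0); add_b <- integer(0)
    for (i in seq_len(nrow(cand))) {
      ra <- uf_find(uf, cand$bundle_a[i]); rb <- uf_find(uf, cand$bundle_b[i])
      if (ra != rb) {
        uf[ra] <- rb
        n_comp <- n_comp - 1L
        add_a <- c(add_a, cand$bundle_a[i]); add_b <- c(add_b, cand$bundle_b[i])
        if (n_comp == 1L) break
      }
    }
    edges <- dplyr::bind_rows(edges,
                              tibble::tibble(bundle_a = add_a, bundle_b = add_b))
  }
  edges <- dplyr::arrange(edges, .data$bundle_a, .data$bundle_b)
  new_bundle_network(N, edges, method)
}

#' Ground-truth target bundle network
#'
#' Bundles are adjacent iff some structural edge joins a member of one to
#' a member of the other (the projection rule shared with
#' [project_group_adjacency()]).
#'
#' @param layer A `bundle_layer` over the network's nodes.
#' @param net The generating `structural_network`.
#' @return A `bundle_network` tagged `"target"`.
#' @export
target_bundle_network <- function(layer, net) {
  adj <- project_group_adjacency(layer, net)
  new_bundle_network(layer$n_bundles,
                     tibble::tibble(bundle_a = adj$group_a,
                                    bundle_b = adj$group_b),
                     "target")
}

edge_keys <- function(net) {
  if (nrow(net$edges) == 0) return(character(0))
  paste(pmin(net$edges$bundle_a, net$edges$bundle_b),
        pmax(net$edges$bundle_a, net$edges$bundle_b), sep = "-")
}

#' Jaccard index of two bundle networks
#'
#' `|E_r intersect E_t| / |E_r union E_t|` over unordered edge pairs;
#' defined as 1 when both edge sets are empty (identical networks).
#'
#' @param net_r,net_t `bundle_network`s over the same node universe.
#' @return A number in [0, 1].
#' @export
jaccard_index <- function(net_r, net_t) {
  er <- edge_keys(net_r); et <- edge_keys(net_t)
  un <- union(er, et)
  if (length(un) == 0) return(1)
  length(intersect(er, et)) / length(un)
}

#' Classify reconstructed edges against a target network
#'
#' @param net_r Reconstructed `bundle_network`.
#' @param net_t Target `bundle_network`.
#' @return List with edge tibbles `true_positive`, `false_negative`,
#'   `false_positive` and a one-row `counts` tibble
#'   (`n_edges`, `tp`, `fn`, `fp`, `jaccard`).
#' @export
classify_edges <- function(net_r, net_t) {
  er <- edge_keys(net_r); et <- edge_keys(net_t)
  split_key <- function(keys) {
    if (length(keys) == 0)
      return(tibble::tibble(bundle_a = integer(), bundle_b = integer()))
    parts <- strsplit(keys, "-", fixed = TRUE)
    tibble::tibble(bundle_a = as.integer(vapply(parts, `[`, "", 1)),
                   bundle_b = as.integer(vapply(parts, `[`, "", 2)))
  }
  tp <- sort(intersect(er, et))
  fn <- sort(setdiff(et, er))
  fp <- sort(setdiff(er, et))
  list(
    true_positive = split_key(tp),
    false_negative = split_key(fn),
    false_positive = split_key(fp),
    counts = tibble::tibble(
      n_edges = length(er), tp = length(tp), fn = length(fn),
      fp = length(fp), jaccard = jaccard_index(net_r, net_t))
  )
}

#' Tidy edge table of a bundle network
#'
#' @param x A `bundle_network`.
#' @param ... Unused.
#' @return Tibble `bundle_a, bundle_b, method`.
#' @method tidy bundle_network
#' @export
tidy.bundle_network <- function(x, ...) {
  dplyr::mutate(x$edges, method = x$method)
}

#' Reconstruct and evaluate H-, L- and LH-bundle networks
#'
#' Runs the full network-of-bundles analysis at layer k of a fitted MLB
#' object: builds H and L, reconstructs the three networks, and (when a
#' structural network is supplied) scores each against the target bundle
#' network.
#'
#' @param fit An `mlb_fit` from [mlb()].
#' @param layer Bundle layer k to evaluate (default `fit$k`).
#' @param net Optional `structural_network` ground truth.
#' @return List with `H`, `L`, `LH` (score matrices), `networks` (named
#'   list of `bundle_network`s incl. `target` when available), and
#'   `report` (tibble `method, n_edges, tp, fn, fp, jaccard`; NA columns
#'   without ground truth).
#' @export
evaluate_reconstructions <- function(fit, layer = fit$k, net = NULL) {
  stopifnot(inherits(fit, "mlb_fit"))
  bl <- fit$bundles[[layer]]
  H <- bundle_affinity_matrix(fit$affinity, bl)
  L <- bundle_cocluster_matrix(fit$regimes, bl, k = layer, r = fit$r)
  LH <- combine_scores(H, L)
  nets <- list(
    H = score_matrix_to_network(H, "H"),
    L = score_matrix_to_network(L, "L"),
    LH = score_matrix_to_network(LH, "LH")
  )
  if (!is.null(net)) {
    nets$target <- target_bundle_network(bl, net)
    report <- purrr::map_dfr(c("H", "L", "LH"), function(mth) {
      dplyr::mutate(classify_edges(nets[[mth]], nets$target)$counts,
                    method = mth, .before = 1)
    })
  } else {
    report <- purrr::map_dfr(c("H", "L", "LH"), function(mth) {
      tibble::tibble(method = mth, n_edges = nrow(nets[[mth]]$edges),
                     tp = NA_integer_, fn = NA_integer_, fp = NA_integer_,
                     jaccard = NA_real_)
    })
  }
  list(H = H, L = L, LH = LH, networks = nets, report = report)
}
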