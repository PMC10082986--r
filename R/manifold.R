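#' Build a symmetrized k-nearest-neighbour graph
#'
#' Each point is connected to its `k` nearest neighbours under Euclidean
#' distance; the directed relation is then symmetrized by union, so an edge
#' is kept whenever either endpoint lists the other. Distance ties are broken
#' by lower point index.
#'
#' @param X Numeric matrix of points (rows).
#' @param k Neighbour count, `1 <= k <= nrow(X) - 1`.
#' @return An `n x n` symmetric weight matrix with `Inf` for absent edges and
#'   a zero diagonal, of class `isoga_knn_graph`.
#' @export
build_knn_graph <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 1 || k > n - 1) {
    abort(sprintf("k must lie in [1, %d], got %s.", n - 1, k))
  }
  dmat <- as.matrix(dist(X))
  W <- matrix(Inf, n, n)
  diag(W) <- 0
  for (i in seq_len(n)) {
    d <- dmat[, i]
    d[i] <- Inf
    ord <- order(d, method = "radix")  # stable: ties -> lower index first
    nb <- ord[seq_len(k)]
    W[i, nb] <- dmat[nb, i]
    W[nb, i] <- dmat[nb, i]            # union symmetrization
  }
  structure(W, class = c("isoga_knn_graph", "matrix"))
}

#' All-pairs shortest-path (geodesic) distances
#'
#' Runs Floyd-Warshall on the neighbourhood graph. Disconnection is reported
#' through the `connected` attribute rather than an error, so callers can
#' decide (the GA maps it to worst fitness, k tuning skips the k).
#'
#' @param graph Weight matrix from [build_knn_graph()] (`Inf` = no edge).
#' @return Matrix of geodesic distances with attribute `connected` (logical);
#'   cross-component entries are `Inf`.
#' @export
shortest_paths <- function(graph) {
  D <- .fw_shortest_paths(unclass(graph))
  D <- pmin(D, t(D))   # guard symmetry against float asymmetry
  structure(D, connected = all(is.finite(D)))
}

graph_components <- function(graph) {
  finite <- is.finite(unclass(graph))
  n <- nrow(finite)
  comp <- integer(n)
  id <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    id <- id + 1L
    queue <- s
    comp[s] <- id
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(finite[v, ] & comp == 0L)
      comp[nb] <- id
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Classical multidimensional scaling
#'
#' Double-centres the squared distance matrix, `K = -1/2 J D^2 J` with
#' `J = I - (1/n) 11'`, eigendecomposes `K`, and returns the top-`d`
#' eigenvectors scaled by the square roots of their eigenvalues. Negative
#' eigenvalues (non-Euclidean input) are clamped to zero. The sign of each
#' coordinate axis is fixed by making the largest-magnitude entry of each
#' eigenvector positive, so results are reproducible across runs.
#'
#' @param D Symmetric matrix of pairwise distances (finite, zero diagonal).
#' @param d Target dimension, `1 <= d <= n - 1`.
#' @return An object of class `isoga_embedding`: list with `points`
#'   (`n x d`, centred), `eigenvalues` (descending, all returned), `d`.
#' @export
classical_mds <- function(D, d) {
  D <- unclass(D)
  n <- nrow(D)
  if (d < 1 || d > n - 1) abort(sprintf("d must lie in [1, %d].", n - 1))
  if (!all(is.finite(D))) abort("D must be finite; embed connected data only.")
  D2 <- D^2
  rm <- rowMeans(D2)
  K <- -0.5 * (D2 - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + mean(D2))
  K <- (K + t(K)) / 2
  eig <- eigen(K, symmetric = TRUE)
  lambda <- eig$values
  lambda[lambda <= 1e-12 * max(abs(lambda), 1)] <- 0   # clamp negatives & noise
  n_pos <- sum(lambda > 0)
  if (d > n_pos) {
    warn(sprintf("only %d positive eigenvalue(s); padding %d coordinate(s) with zeros.",
                 n_pos, d - n_pos))
  }
  V <- eig$vectors[, seq_len(d), drop = FALSE]
  # deterministic sign: largest-|entry| of each axis made positive
  for (j in seq_len(d)) {
    i_max <- which.max(abs(V[, j]))
    if (V[i_max, j] < 0) V[, j] <- -V[, j]
  }
  pts <- V %*% diag(sqrt(lambda[seq_len(d)]), nrow = d)
  structure(list(points = pts, eigenvalues = eig$values, d = d),
            class = "isoga_embedding")
}

#' @export
print.isoga_embedding <- function(x, ...) {
  cat(sprintf("<isoga_embedding> %d points in %d dimension(s)\n",
              nrow(x$points), x$d))
  invisible(x)
}

#' Isomap embedding
#'
#' Composition of [build_knn_graph()], [shortest_paths()], and
#' [classical_mds()] applied to the geodesic distances. A disconnected
#' neighbourhood graph raises a condition of class `isoga_disconnected`
#' carrying the component sizes; it never silently embeds the largest
#' component, because that would change the sample set between candidate
#' gene subsets and make their fitness values incomparable.
#'
#' @param X Numeric point matrix (rows = points).
#' @param k Neighbourhood size.
#' @param d Target embedding dimension.
#' @return An `isoga_embedding` (see [classical_mds()]) with an extra
#'   element `geodesic`, the geodesic distance matrix.
#' @export
isomap <- function(X, k, d) {
  g <- build_knn_graph(X, k)
  D <- shortest_paths(g)
  if (!attr(D, "connected")) {
    sizes <- as.integer(table(graph_components(g)))
    abort(sprintf("k-NN graph (k=%d) is disconnected: component sizes %s.",
                  k, paste(sizes, collapse = ", ")),
          class = "isoga_disconnected", component_sizes = sizes)
  }
  emb <- classical_mds(D, d)
  emb$geodesic <- D
  emb
}

#' Maximum-likelihood intrinsic-dimension estimate
#'
#' Levina-Bickel estimator: for each point, the inverse dimension estimate at
#' neighbourhood size `k` is the mean of `log(T_k / T_j)` over
#' `j = 1..k-1`, with `T_j` the distance to the j-th nearest neighbour.
#' Point-level estimates are combined by inverse averaging (average the
#' inverses, then invert), the per-`k` estimates are averaged over
#' `neighbor_range`, and the result is rounded to the nearest integer,
#' floored at 1 and capped at `min(n - 2, max_dim)`.
#'
#' @param X Numeric point matrix.
#' @param neighbor_range Integer range `c(k1, k2)` of neighbourhood sizes,
#'   `3 <= k1 <= k2 < n` (clipped to `n - 1`).
#' @param max_dim Optional upper cap (the GA caller passes its subset size
#'   minus one).
#' @return Integer dimension estimate `>= 1`.
#' @export
estimate_intrinsic_dim <- function(X, neighbor_range = c(5, 12),
                                   max_dim = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  k1 <- max(3L, neighbor_range[1])
  k2 <- min(n - 1L, neighbor_range[2])
  if (k2 < k1) abort("too few points for the requested neighbor_range.")
  dmat <- as.matrix(dist(X))
  diag(dmat) <- Inf
  Ts <- t(apply(dmat, 1, sort))[, seq_len(k2), drop = FALSE]
  had_zero <- FALSE
  per_k <- vapply(k1:k2, function(k) {
    inv <- vapply(seq_len(n), function(i) {
      tk <- Ts[i, k]
      tj <- Ts[i, seq_len(k - 1)]
      ok <- tj > 0 & tk > 0
      if (!any(ok)) return(NA_real_)
      if (!all(ok)) had_zero <<- TRUE
      mean(log(tk / tj[ok]))
    }, numeric(1))
    inv <- inv[is.finite(inv)]
    if (length(inv) == 0) return(NA_real_)
    1 / mean(inv)
  }, numeric(1))
  if (had_zero) warn("duplicate points: zero neighbour distances skipped.")
  per_k <- per_k[is.finite(per_k)]
  if (length(per_k) == 0) abort("cannot estimate dimension: data are all duplicates.")
  d <- max(1L, as.integer(round(mean(per_k))))
  cap <- n - 2L
  if (!is.null(max_dim)) cap <- min(cap, as.integer(max_dim))
  min(d, max(1L, cap))
}

#' Tune the Isomap neighbourhood size by Davies-Bouldin grid search
#'
#' Evaluates each `k` in `k_range` by embedding the full matrix with Isomap
#' at dimension `d` and scoring the embedded labelled points with the
#' Davies-Bouldin index; returns the `k` with the smallest index. Values of
#' `k` whose neighbourhood graph is disconnected are skipped; ties go to the
#' smaller `k`.
#'
#' @param X Numeric sample-by-feature matrix.
#' @param y Integer class labels.
#' @param d Embedding dimension.
#' @param k_range Candidate neighbourhood sizes (default `5:20`, clipped to
#'   `n - 1`).
#' @return The selected `k` (integer), with the per-k scores attached as
#'   attribute `scores` (tibble: `k`, `db`, `connected`).
#' @export
tune_k <- function(X, y, d, k_range = 5:20) {
  n <- nrow(X)
  k_range <- sort(unique(pmin(pmax(k_range, 1L), n - 1L)))
  scores <- purrr::map_dfr(k_range, function(k) {
    emb <- tryCatch(isomap(X, k, d), isoga_disconnected = function(e) NULL)
    if (is.null(emb)) {
      tibble::tibble(k = k, db = NA_real_, connected = FALSE)
    } else {
      tibble::tibble(k = k, db = db_index(emb$points, y), connected = TRUE)
    }
  })
  ok <- scores[scores$connected & is.finite(scores$db), ]
  if (nrow(ok) == 0) {
    abort("every k in k_range gives a disconnected graph; enlarge k_range.")
  }
  best <- ok$k[which.min(ok$db)]   # which.min takes the first = smallest k on ties
  structure(as.integer(best), scores = scores)
}

#' Turn an embedding into a tibble
#'
#' @param x An `isoga_embedding`.
#' @param labels Optional class labels to attach.
#' @param ... Unused.
#' @return Tibble with `sample` index, `dim1..dimd`, and optional `class`.
#' @export
tidy.isoga_embedding <- function(x, labels = NULL, ...) {
  pts <- x$points
  colnames(pts) <- paste0("dim", seq_len(ncol(pts)))
  out <- tibble::as_tibble(pts)
  out <- tibble::add_column(out, sample = seq_len(nrow(pts)), .before = 1)
  if (!is.null(labels)) out$class <- factor(labels)
  out
}

#' Plot the first two coordinates of an embedding
#'
#' @param object An `isoga_embedding`.
#' @param labels Optional class labels used for colour.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.isoga_embedding <- function(object, labels = NULL, ...) {
  df <- tidy(object, labels = labels)
  if (!"dim2" %in% names(df)) df$dim2 <- 0
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2))
  if (!is.null(labels)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$class))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::labs(x = "dimension 1", y = "dimension 2")
}
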