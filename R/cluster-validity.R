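#' Davies-Bouldin cluster-validity index
#'
#' For class centroids `mu_i`, mean within-class distances
#' `S_i = mean(||x - mu_i||)` and centroid separations
#' `M_ij = ||mu_i - mu_j||`, the index is
#' `DB = (1/C) * sum_i max_{j != i} (S_i + S_j) / M_ij`.
#' Lower values mean clearer class separation. When two class centroids
#' coincide while their scatters are nonzero the index is `Inf` (rather
#' than an error, so a minimiser simply avoids such configurations).
#'
#' @param points Numeric matrix of embedded points (rows).
#' @param labels Integer class labels `1..C`, at least two classes present.
#' @return Nonnegative real (possibly `Inf`).
#' @export
db_index <- function(points, labels) {
  points <- as.matrix(points)
  classes <- sort(unique(labels))
  C <- length(classes)
  if (C < 2) abort("db_index needs at least 2 classes.")
  mu <- vapply(classes, function(c) colMeans(points[labels == c, , drop = FALSE]),
               numeric(ncol(points)))
  mu <- if (is.matrix(mu)) t(mu) else matrix(mu, ncol = 1)
  S <- vapply(seq_len(C), function(i) {
    pts <- points[labels == classes[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2, mu[i, ])^2)))
  }, numeric(1))
  M <- as.matrix(dist(mu))
  total <- 0
  for (i in seq_len(C)) {
    r <- (S[i] + S[-i]) / M[i, -i]       # 0/0 -> NaN means coincident singletons
    r[M[i, -i] == 0 & (S[i] + S[-i]) == 0] <- 0
    r[M[i, -i] == 0 & (S[i] + S[-i]) > 0] <- Inf
    total <- total + max(r)
  }
  total / C
}

#' Build a memoized gene-subset fitness function
#'
#' Returns `function(subset) -> fitness` where the fitness is the
#' Davies-Bouldin index of the embedded in-bag samples restricted to the
#' subset's gene columns. The embedding is Isomap (`mode = "isomap"`),
#' classical MDS on Euclidean distances (`mode = "mds"`), or no embedding at
#' all (`mode = "none"`, DB on the raw subset columns). A disconnected
#' Isomap graph maps to `Inf` — the worst value under minimisation — so the
#' search simply moves away from such subsets. Results are memoized on the
#' sorted index tuple because the GA revisits subsets frequently and the
#' embedding is the expensive step.
#'
#' @param X Numeric in-bag expression matrix (samples x genes).
#' @param y Integer labels for the in-bag samples.
#' @param k Isomap neighbourhood size.
#' @param d Embedding dimension.
#' @param mode `"isomap"`, `"mds"`, or `"none"`.
#' @return A function taking an integer index vector and returning the
#'   fitness; its environment carries the cache (attribute access via
#'   `environment(fn)$cache`).
#' @export
make_fitness <- function(X, y, k, d, mode = c("isomap", "mds", "none")) {
  mode <- match.arg(mode)
  cache <- new.env(parent = emptyenv())
  force(X); force(y); force(k); force(d)
  function(subset) {
    key <- paste(sort(subset), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    Xs <- X[, subset, drop = FALSE]
    val <- switch(mode,
      isomap = tryCatch(
        db_index(isomap(Xs, k, d)$points, y),
        isoga_disconnected = function(e) Inf
      ),
      mds = db_index(classical_mds(as.matrix(dist(Xs)), d)$points, y),
      none = db_index(Xs, y)
    )
    if (is.na(val)) val <- Inf
    cache[[key]] <- val
    val
  }
}
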