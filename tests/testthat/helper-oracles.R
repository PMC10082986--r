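# Independent oracles used to cross-check the package implementation.
# These are deliberately naive (loops, enumeration) and share no code with
# the functions they validate.

# textbook Davies-Bouldin: explicit loops over classes and pairs
db_oracle <- function(points, labels) {
  points <- as.matrix(points)
  cls <- sort(unique(labels))
  C <- length(cls)
  mu <- list(); S <- numeric(C)
  for (i in seq_len(C)) {
    pts <- points[labels == cls[i], , drop = FALSE]
    mu[[i]] <- colMeans(pts)
    s <- 0
    for (r in seq_len(nrow(pts))) s <- s + sqrt(sum((pts[r, ] - mu[[i]])^2))
    S[i] <- s / nrow(pts)
  }
  total <- 0
  for (i in seq_len(C)) {
    worst <- -Inf
    for (j in seq_len(C)) {
      if (j == i) next
      M <- sqrt(sum((mu[[i]] - mu[[j]])^2))
      r <- if (M == 0) { if (S[i] + S[j] == 0) 0 else Inf } else (S[i] + S[j]) / M
      worst <- max(worst, r)
    }
    total <- total + worst
  }
  total / C
}

# exhaustive shortest paths by enumerating all simple paths (n <= 7)
bf_shortest_paths <- function(W) {
  n <- nrow(W)
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  explore <- function(path, len, target) {
    v <- path[length(path)]
    if (v == target) {
      if (len < best[path[1], target]) best[path[1], target] <<- len
      return(invisible())
    }
    for (u in seq_len(n)) {
      if (u %in% path) next
      if (!is.finite(W[v, u])) next
      explore(c(path, u), len + W[v, u], target)
    }
  }
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s != t) explore(s, 0, t)
  }
  best
}

# random connected-ish weighted graph for the shortest-path suite
random_graph <- function(n, edge_prob = 0.6) {
  W <- matrix(Inf, n, n)
  diag(W) <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < edge_prob) {
      w <- round(runif(1, 0.1, 10), 3)
      W[i, j] <- w; W[j, i] <- w
    }
  }
  W
}

# small labelled point cloud for validity-index checks
random_labeled_points <- function(n = 30, d = 3, C = 3) {
  pts <- matrix(rnorm(n * d), n, d)
  labels <- sample(rep(seq_len(C), length.out = n))
  list(points = pts, labels = labels)
}

# minimal selection-result stub for report round-trip tests
fake_selection_result <- function(counts, c_val, bags = 10, seed = 3) {
  structure(list(
    s_best = names(counts)[counts >= c_val],
    s_best_idx = which(counts >= c_val),
    counts = counts,
    threshold = list(c = c_val, prob = 0.1, n_gene = length(counts),
                     v = 30, runs = bags, alpha = 0.05),
    per_bag = list(), k = 7L, d = 2L,
    config = run_config(seed = seed, bags = bags),
    gene_ids = names(counts)
  ), class = "iso_ga_result")
}
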