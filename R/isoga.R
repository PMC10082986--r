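#' Run configuration
#'
#' Collects every tunable of the selection framework in one validated list.
#' Defaults follow common practice for subset-selection genetic algorithms;
#' the subset size of 30, the 10 bootstrap bags, the 5% non-randomness level
#' and the 5..20 neighbourhood grid are the framework's standard operating
#' point for microarray-scale data.
#'
#' @param m Genes per candidate subset (fixed GA cardinality).
#' @param pop_size GA population size.
#' @param generations GA generations.
#' @param tournament_size Tournament size for parent selection.
#' @param mutation_rate Per-index mutation probability.
#' @param elitism Elites copied unchanged each generation.
#' @param bags Number of stratified bootstrap bags `B`.
#' @param alpha Binomial non-randomness level for the inclusion threshold.
#' @param k_range Isomap neighbourhood grid (clipped to `n - 1` at run time).
#' @param embedding `"isomap"`, `"mds"` (linear ablation), or `"none"`.
#' @param seed Master seed; per-bag streams use `seed + bag index`.
#' @param outer_folds Outer cross-validation folds.
#' @param top_candidates GA finalists validated on the out-of-bag samples.
#' @param mlde_range Neighbourhood range of the intrinsic-dimension estimator.
#' @return A validated list of class `isoga_config`.
#' @export
run_config <- function(m = 30, pop_size = 100, generations = 100,
                       tournament_size = 2, mutation_rate = 0.01, elitism = 1,
                       bags = 10, alpha = 0.05, k_range = 5:20,
                       embedding = c("isomap", "mds", "none"), seed = 1,
                       outer_folds = 5, top_candidates = 10,
                       mlde_range = c(5, 12)) {
  embedding <- match.arg(embedding)
  if (m < 2) abort("subset size m must be >= 2.")
  if (bags < 1) abort("bags must be >= 1.")
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1).")
  if (any(k_range < 1)) abort("k_range must be positive.")
  structure(list(m = as.integer(m), pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 tournament_size = as.integer(tournament_size),
                 mutation_rate = mutation_rate, elitism = as.integer(elitism),
                 bags = as.integer(bags), alpha = alpha,
                 k_range = as.integer(k_range), embedding = embedding,
                 seed = as.integer(seed), outer_folds = as.integer(outer_folds),
                 top_candidates = as.integer(top_candidates),
                 mlde_range = as.integer(mlde_range)),
            class = "isoga_config")
}

#' Binomial inclusion threshold for repeated GA selections
#'
#' Under the null that every gene is equally likely to enter a size-`v`
#' subset out of `n_gene` genes, a gene's selection count over `runs`
#' independent searches is `X ~ Binomial(runs, v / n_gene)`. The threshold
#' is the smallest count `c` with `P(X >= c) < alpha` — a gene reaching `c`
#' selections by chance is a sub-`alpha` probability event — floored at 2,
#' since a single appearance can never be distinguished from chance. When
#' even `c = runs` is not improbable enough (`v = n_gene`), `runs + 1` is
#' returned with a warning: no gene can qualify.
#'
#' @param n_gene Number of genes available after filtering.
#' @param v Subset size of each search (the GA cardinality).
#' @param runs Number of repeated searches (bootstrap bags).
#' @param alpha Tail-probability level.
#' @return Integer threshold `c`, with the per-run selection probability
#'   attached as attribute `prob`.
#' @export
selection_threshold <- function(n_gene, v = 30, runs = 10, alpha = 0.05) {
  if (n_gene < v) abort(sprintf("n_gene (%d) must be >= v (%d).", n_gene, v))
  if (v < 1) abort("v must be >= 1.")
  prob <- v / n_gene
  c_val <- NA_integer_
  for (cc in seq_len(runs)) {
    if (1 - pbinom(cc - 1, runs, prob) < alpha) { c_val <- cc; break }
  }
  if (is.na(c_val)) {
    warn("no selection count within `runs` is improbable enough; no gene can qualify.")
    c_val <- runs + 1L
  }
  structure(max(2L, as.integer(c_val)), prob = prob)
}

# out-of-bag accuracy of a fixed-hyperparameter RBF SVM (median-heuristic
# kernel width, unit cost) trained on the in-bag samples of one candidate
svm_oob_accuracy <- function(X_in, y_in, X_oob, y_oob) {
  med <- stats::median(dist(X_in))
  if (!is.finite(med) || med <= 0) med <- 1
  fit <- e1071::svm(x = X_in, y = factor(y_in, levels = seq_len(max(y_in))),
                    kernel = "radial", gamma = 1 / (2 * med^2), cost = 1)
  pred <- as.integer(as.character(predict(fit, X_oob)))
  mean(pred == y_oob)
}

#' One GA search on a bootstrap bag
#'
#' Evolves the population against the Davies-Bouldin-of-embedding fitness on
#' the in-bag samples, then validates the best `top_candidates` distinct
#' finalists by out-of-bag accuracy of a fixed-hyperparameter RBF-SVM and
#' returns the finalist with the highest accuracy (ties: lower fitness, then
#' lexicographic subset order). If the out-of-bag set holds a single class,
#' the best-fitness finalist is returned instead, with a warning.
#'
#' @param X_inbag,y_inbag In-bag expression matrix and labels.
#' @param X_oob,y_oob Out-of-bag validation samples and labels.
#' @param k Isomap neighbourhood size (ignored for non-Isomap embeddings).
#' @param d Embedding dimension.
#' @param config An [run_config()] list (GA budget, embedding mode).
#' @return List with `subset` (sorted gene indices), `fitness`,
#'   `oob_accuracy`, and `candidates` (validation table of the finalists).
#' @export
run_single_search <- function(X_inbag, y_inbag, X_oob, y_oob, k, d, config) {
  fit_fn <- make_fitness(X_inbag, y_inbag, k, d, mode = config$embedding)
  state <- init_population(ncol(X_inbag), config$m, config$pop_size)
  state <- evolve(state, fit_fn, generations = config$generations,
                  tournament_size = config$tournament_size,
                  elitism = config$elitism,
                  mutation_rate = config$mutation_rate)
  finalists <- top_k(state, min(config$top_candidates, config$pop_size))
  if (length(unique(y_oob)) < 2) {
    warn("out-of-bag set holds a single class; returning the best-fitness finalist.")
    return(list(subset = finalists$subsets[[1]], fitness = finalists$fitness[1],
                oob_accuracy = NA_real_, candidates = NULL))
  }
  acc <- vapply(finalists$subsets, function(s) {
    svm_oob_accuracy(X_inbag[, s, drop = FALSE], y_inbag,
                     X_oob[, s, drop = FALSE], y_oob)
  }, numeric(1))
  # finalists are already (fitness, lexicographic)-ordered, so the first
  # index attaining the max implements the tie-breaking rule
  best <- which.max(acc)
  list(subset = finalists$subsets[[best]], fitness = finalists$fitness[best],
       oob_accuracy = acc[best],
       candidates = tibble::tibble(rank = seq_along(acc),
                                   fitness = finalists$fitness,
                                   oob_accuracy = acc))
}

#' Select genes by repeated manifold-aware GA search
#'
#' The full selection pipeline on one (preprocessed) training set:
#' \enumerate{
#'   \item estimate the embedding dimension `d` on the full gene matrix by
#'     maximum likelihood ([estimate_intrinsic_dim()]);
#'   \item tune the Isomap neighbourhood size `k` over `config$k_range` by
#'     the Davies-Bouldin index ([tune_k()]; skipped for non-Isomap modes);
#'   \item draw `B` stratified bootstrap bags (per-bag RNG streams seeded
#'     `seed + bag`, so bags are independent but reproducible);
#'   \item run one GA search per bag ([run_single_search()]);
#'   \item compute the binomial inclusion threshold `c`
#'     ([selection_threshold()]) and keep every gene selected in at least
#'     `c` of the `B` per-bag subsets.
#' }
#' An empty final set is returned as such with a warning (lower `alpha` or
#' increase the GA budget), never as an error.
#'
#' @param ds A preprocessed (standardised, filtered) [expression_dataset()].
#' @param config An [run_config()].
#' @return Object of class `iso_ga_result`: `s_best` (gene ids), `s_best_idx`
#'   (column indices), `counts` (named per-gene selection counts),
#'   `threshold` (list `c`, `prob`, `n_gene`, `v`, `runs`, `alpha`),
#'   `per_bag` (per-bag search results), `k`, `d`, `config`.
#' @export
iso_ga_select <- function(ds, config = run_config()) {
  stopifnot(inherits(ds, "expression_dataset"))
  X <- ds$matrix; y <- ds$labels
  if (config$m > ds$p) abort("config$m exceeds the number of genes.")
  d <- if (config$embedding == "none") NA_integer_ else
    estimate_intrinsic_dim(X, config$mlde_range, max_dim = config$m - 1L)
  k <- NA_integer_
  if (config$embedding == "isomap") {
    k <- as.integer(tune_k(X, y, d, config$k_range))
  }
  per_bag <- vector("list", config$bags)
  ever_inbag <- rep(FALSE, ds$n)
  for (b in seq_len(config$bags)) {
    set.seed(config$seed + b)
    split <- stratified_bootstrap(y, B = 1)[[1]]
    ever_inbag[unique(split$in_bag)] <- TRUE
    per_bag[[b]] <- run_single_search(
      X[split$in_bag, , drop = FALSE], y[split$in_bag],
      X[split$oob, , drop = FALSE], y[split$oob],
      k = k, d = d, config = config)
    per_bag[[b]]$in_bag <- split$in_bag
    per_bag[[b]]$oob <- split$oob
  }
  if (!all(ever_inbag)) {
    warn(sprintf("%d sample(s) never entered any in-bag set.", sum(!ever_inbag)))
  }
  counts <- integer(ds$p)
  for (res in per_bag) counts[res$subset] <- counts[res$subset] + 1L
  names(counts) <- colnames(X)
  c_val <- selection_threshold(ds$p, v = config$m, runs = config$bags,
                               alpha = config$alpha)
  s_idx <- which(counts >= c_val)
  if (length(s_idx) == 0L) {
    warn("no gene reached the inclusion threshold; s_best is empty.")
  }
  structure(list(
    s_best = colnames(X)[s_idx], s_best_idx = s_idx, counts = counts,
    threshold = list(c = as.integer(c_val), prob = attr(c_val, "prob"),
                     n_gene = ds$p, v = config$m, runs = config$bags,
                     alpha = config$alpha),
    per_bag = per_bag, k = k, d = d, config = config,
    gene_ids = colnames(X)
  ), class = "iso_ga_result")
}

#' @export
print.iso_ga_result <- function(x, ...) {
  cat(sprintf("<iso_ga_result> %d/%d genes selected (threshold c=%d over B=%d bags)\n",
              length(x$s_best), length(x$gene_ids), x$threshold$c,
              x$config$bags))
  cat(sprintf("  embedding: %s, k=%s, d=%s, seed=%d\n", x$config$embedding,
              x$k, x$d, x$config$seed))
  invisible(x)
}

#' Per-gene selection counts as a tibble
#'
#' @param x An `iso_ga_result`.
#' @param ... Unused.
#' @return Tibble with `gene_id`, `selection_count`, `included`.
#' @export
tidy.iso_ga_result <- function(x, ...) {
  tibble::tibble(gene_id = x$gene_ids,
                 selection_count = as.integer(x$counts),
                 included = x$counts >= x$threshold$c)
}

#' One-row summary of a selection run
#'
#' @param x An `iso_ga_result`.
#' @param ... Unused.
#' @return One-row tibble: gene counts, tuned `k` and `d`, threshold, mean
#'   out-of-bag accuracy of the per-bag winners.
#' @export
glance.iso_ga_result <- function(x, ...) {
  tibble::tibble(
    n_gene = length(x$gene_ids), n_selected = length(x$s_best),
    k = x$k, d = x$d, c = x$threshold$c, bags = x$config$bags,
    embedding = x$config$embedding,
    mean_oob_accuracy = mean(vapply(x$per_bag, function(b) b$oob_accuracy,
                                    numeric(1)), na.rm = TRUE)
  )
}

#' Plot selection counts against the inclusion threshold
#'
#' @param object An `iso_ga_result`.
#' @param top Show only the `top` most-selected genes (default 40).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.iso_ga_result <- function(object, top = 40, ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$selection_count > 0) |>
    dplyr::arrange(dplyr::desc(.data$selection_count)) |>
    head(top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$gene_id, .data$selection_count),
    y = .data$selection_count, fill = .data$included)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$threshold$c - 0.5,
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = sprintf("selections out of %d bags",
                                        object$config$bags))
}
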