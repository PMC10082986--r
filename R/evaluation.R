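#' Stratified k-fold assignment
#'
#' Shuffles each class independently and deals its samples round-robin over
#' the folds, so per-class fold proportions differ from the population
#' proportions by at most one sample.
#'
#' @param labels Integer class labels.
#' @param folds Number of folds.
#' @return Integer vector of fold assignments in `1..folds`.
#' @export
stratified_kfold <- function(labels, folds = 5) {
  assignment <- integer(length(labels))
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    if (length(idx) < folds) {
      abort(sprintf("class %s has %d samples, fewer than %d folds.",
                    cls, length(idx), folds))
    }
    idx <- idx[sample.int(length(idx))]
    assignment[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assignment
}

#' Stratified bootstrap bags
#'
#' Each bag resamples every class with replacement to its own size, so the
#' in-bag multiset has exactly the training-set size and class composition;
#' the unsampled indices form the out-of-bag validation set.
#'
#' @param labels Integer class labels of the training samples.
#' @param B Number of bags.
#' @return List of `B` lists, each with `in_bag` (index multiset) and `oob`
#'   (index set, possibly empty per class — logged when a class vanishes).
#' @export
stratified_bootstrap <- function(labels, B = 10) {
  n <- length(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) abort("need at least 2 classes.")
  purrr::map(seq_len(B), function(b) {
    in_bag <- unlist(lapply(classes, function(cls) {
      idx <- which(labels == cls)
      idx[sample.int(length(idx), length(idx), replace = TRUE)]
    }))
    oob <- setdiff(seq_len(n), in_bag)
    missing_cls <- setdiff(classes, unique(labels[oob]))
    if (length(missing_cls) > 0) {
      inform(sprintf("bag without out-of-bag samples for class(es): %s",
                     paste(missing_cls, collapse = ", ")))
    }
    list(in_bag = sort(in_bag), oob = oob)
  })
}

#' Classification accuracy
#'
#' Fraction of correctly predicted samples, `(TP + TN) / (P + N)` in the
#' binary case and `sum_i tp_i / n` for multiclass.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @return Real in `[0, 1]`.
#' @export
accuracy <- function(y_true, y_pred) {
  if (length(y_true) == 0) abort("empty input.")
  if (length(y_true) != length(y_pred)) abort("length mismatch.")
  mean(y_true == y_pred)
}

# midrank (tie-aware) one-vs-rest AUC of a score for a 0/1 indicator
auc_midrank <- function(indicator, score) {
  n1 <- sum(indicator == 1)
  n0 <- sum(indicator == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)     # midranks on ties
  (sum(r[indicator == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro- and micro-averaged one-vs-rest AUC
#'
#' Per class, the one-vs-rest AUC of that class's probability column.
#' Macro averages the per-class AUCs; micro pools every (sample, class)
#' indicator/score pair into one big binary problem before computing the
#' AUC. For two complementary probability columns the macro average equals
#' the standard binary AUC; the pooled micro average also compares scores
#' across columns and can legitimately differ from it.
#'
#' @param y_true Integer labels `1..C`.
#' @param scores `n x C` matrix of class probabilities (rows sum to 1).
#' @return Named list `macro`, `micro`.
#' @export
macro_micro_auc <- function(y_true, scores) {
  scores <- as.matrix(scores)
  if (!all(is.finite(scores))) abort("scores must be finite.")
  if (max(abs(rowSums(scores) - 1)) > 1e-6) {
    abort("score rows must sum to 1 (class probabilities).")
  }
  C <- ncol(scores)
  per_class <- vapply(seq_len(C), function(cls) {
    auc_midrank(as.integer(y_true == cls), scores[, cls])
  }, numeric(1))
  if (anyNA(per_class)) {
    warn("class absent from y_true excluded from the macro average.")
  }
  pooled_ind <- as.integer(as.vector(vapply(seq_len(C), function(cls)
    as.integer(y_true == cls), integer(length(y_true)))))
  pooled_score <- as.vector(scores)
  list(macro = mean(per_class, na.rm = TRUE),
       micro = auc_midrank(pooled_ind, pooled_score))
}

#' Default classifier tuning grids
#'
#' The RBF-SVM grid crosses kernel widths `0.001, 0.011, ..., 0.091` with
#' costs `1..10`; the neural-network grid crosses first-hidden-layer sizes
#' `10, 12, ..., 30` with second-hidden-layer sizes `4, 6, ..., 20`.
#'
#' @return A data frame, one row per grid point.
#' @export
default_svm_grid <- function() {
  expand.grid(sigma = seq(0.001, 0.091, by = 0.010), cost = 1:10,
              KEEP.OUT.ATTRS = FALSE)
}

#' @rdname default_svm_grid
#' @export
default_mlp_grid <- function() {
  expand.grid(hn1 = seq(10, 30, by = 2), hn2 = seq(4, 20, by = 2),
              KEEP.OUT.ATTRS = FALSE)
}

#' Grid-search classifier tuning by repeated stratified cross-validation
#'
#' Scores every grid row by mean accuracy over `repeats` runs of
#' `folds`-fold stratified cross-validation and returns the first row (in
#' grid order) attaining the maximum. A grid point whose training fails
#' scores 0 and is logged.
#'
#' @param X Feature matrix (training samples).
#' @param y Integer labels.
#' @param grid Data frame of candidate hyperparameter rows.
#' @param builder Function mapping one grid row (as a list) to a classifier
#'   contract (see [classifier_svm()]).
#' @param repeats,folds Cross-validation design (defaults 2 x 3-fold).
#' @return List: `best` (chosen grid row as a list), `scores` (tibble of
#'   per-row mean accuracy).
#' @export
tune_classifier <- function(X, y, grid, builder, repeats = 2, folds = 3) {
  if (nrow(grid) == 0) abort("empty grid.")
  mean_acc <- vapply(seq_len(nrow(grid)), function(gi) {
    row <- as.list(grid[gi, , drop = FALSE])
    accs <- c()
    for (r in seq_len(repeats)) {
      fold_of <- stratified_kfold(y, folds)
      for (f in seq_len(folds)) {
        tr <- fold_of != f; te <- !tr
        acc <- tryCatch({
          clf <- builder(row)
          model <- clf$fit(X[tr, , drop = FALSE], y[tr])
          accuracy(y[te], predict_class(clf, model, X[te, , drop = FALSE]))
        }, error = function(e) {
          inform(sprintf("grid point %d failed to train: %s", gi,
                         conditionMessage(e)))
          0
        })
        accs <- c(accs, acc)
      }
    }
    mean(accs)
  }, numeric(1))
  best_i <- which.max(mean_acc)   # first maximizer = first in grid order
  list(best = as.list(grid[best_i, , drop = FALSE]),
       scores = tibble::tibble(grid, mean_accuracy = mean_acc))
}

#' Nested cross-validation of the selection framework
#'
#' Outer loop: stratified `outer_folds`-fold split. Per fold, the training
#' portion alone is standardised (training statistics applied to the test
#' fold), gene selection runs on it ([iso_ga_select()]), the classifiers
#' are tuned and fitted on the training samples restricted to the selected
#' genes, and metrics are computed on the untouched test fold. Test indices
#' never participate in selection or tuning; the `audit` element records the
#' index sets so this can be verified.
#'
#' @param ds An [expression_dataset()] (filtered; per-fold standardisation
#'   is handled internally).
#' @param config An [run_config()]; `config$seed + 1000 * fold` seeds each
#'   fold's selection.
#' @param classifiers Named list of classifier builders, each a function
#'   taking a hyperparameter row (list) and returning a contract; defaults
#'   to the RBF-SVM and the Rprop neural network.
#' @param grids Named list of tuning grids matching `classifiers`.
#' @param tune_repeats,tune_folds Inner tuning design.
#' @return Object of class `nested_cv_result`: `metrics` (tibble: fold,
#'   classifier, accuracy, macro_auc, micro_auc, n_selected), `selections`
#'   (per-fold `iso_ga_result`s), `audit` (per-fold index bookkeeping),
#'   `fold_of` (outer assignment).
#' @export
nested_cv_evaluate <- function(ds, config = run_config(),
                               classifiers = NULL, grids = NULL,
                               tune_repeats = 2, tune_folds = 3) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.null(classifiers)) {
    classifiers <- list(
      svm = function(row) classifier_svm(sigma = row$sigma, cost = row$cost),
      mlp = function(row) classifier_mlp(hn1 = row$hn1, hn2 = row$hn2)
    )
  }
  if (is.null(grids)) {
    grids <- list(svm = default_svm_grid(), mlp = default_mlp_grid())
  }
  stopifnot(identical(sort(names(classifiers)), sort(names(grids))))
  set.seed(config$seed)
  fold_of <- stratified_kfold(ds$labels, config$outer_folds)
  metrics <- list(); selections <- list(); audit <- list()
  for (f in seq_len(config$outer_folds)) {
    te_idx <- which(fold_of == f)
    tr_idx <- which(fold_of != f)
    tr_ds <- expression_dataset(ds$matrix[tr_idx, , drop = FALSE],
                                ds$labels[tr_idx], ds$label_levels)
    tr_ds <- remove_constant_genes(tr_ds)
    std <- standardize(tr_ds)
    fold_config <- config
    fold_config$seed <- config$seed + 1000L * f
    sel <- iso_ga_select(std$dataset, fold_config)
    selections[[f]] <- sel
    # indices touched by selection/tuning, recorded for the leakage audit
    touched <- sort(unique(c(tr_idx,
                             tr_idx[unlist(lapply(sel$per_bag, function(b)
                               c(b$in_bag, b$oob)))])))
    audit[[f]] <- tibble::tibble(fold = f,
                                 n_train = length(tr_idx),
                                 n_test = length(te_idx),
                                 overlap = length(intersect(touched, te_idx)))
    if (length(sel$s_best_idx) == 0L) {
      warn(sprintf("fold %d selected no genes; metrics recorded as missing.", f))
      for (nm in names(classifiers)) {
        metrics[[length(metrics) + 1L]] <- tibble::tibble(
          fold = f, classifier = nm, accuracy = NA_real_,
          macro_auc = NA_real_, micro_auc = NA_real_, n_selected = 0L)
      }
      next
    }
    X_tr <- std$dataset$matrix[, sel$s_best_idx, drop = FALSE]
    te_mat <- ds$matrix[te_idx, colnames(tr_ds$matrix), drop = FALSE]
    te_std <- sweep(sweep(te_mat, 2, std$params$mean, "-"), 2, std$params$sd, "/")
    X_te <- te_std[, sel$s_best_idx, drop = FALSE]
    y_tr <- ds$labels[tr_idx]; y_te <- ds$labels[te_idx]
    for (nm in names(classifiers)) {
      tuned <- tune_classifier(X_tr, y_tr, grids[[nm]], classifiers[[nm]],
                               repeats = tune_repeats, folds = tune_folds)
      clf <- classifiers[[nm]](tuned$best)
      model <- clf$fit(X_tr, y_tr)
      prob <- clf$predict_prob(model, X_te)
      aucs <- macro_micro_auc(y_te, prob)
      metrics[[length(metrics) + 1L]] <- tibble::tibble(
        fold = f, classifier = nm,
        accuracy = accuracy(y_te, apply(prob, 1, which.max)),
        macro_auc = aucs$macro, micro_auc = aucs$micro,
        n_selected = length(sel$s_best_idx))
    }
  }
  structure(list(metrics = dplyr::bind_rows(metrics),
                 selections = selections,
                 audit = dplyr::bind_rows(audit),
                 fold_of = fold_of, config = config),
            class = "nested_cv_result")
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat(sprintf("<nested_cv_result> %d outer folds\n", x$config$outer_folds))
  print(glance(x))
  invisible(x)
}

#' Per-fold metrics of a nested cross-validation run
#'
#' @param x A `nested_cv_result`.
#' @param ... Unused.
#' @return The per-fold metrics tibble.
#' @export
tidy.nested_cv_result <- function(x, ...) x$metrics

#' Mean and standard deviation of metrics across folds
#'
#' @param x A `nested_cv_result`.
#' @param ... Unused.
#' @return One row per classifier with mean and sd of each metric and the
#'   mean selected-subset size.
#' @export
glance.nested_cv_result <- function(x, ...) {
  x$metrics |>
    dplyr::group_by(.data$classifier) |>
    dplyr::summarise(dplyr::across(c("accuracy", "macro_auc", "micro_auc"),
                                   list(mean = ~mean(.x, na.rm = TRUE),
                                        sd = ~sd(.x, na.rm = TRUE))),
                     mean_n_selected = mean(.data$n_selected),
                     .groups = "drop")
}

#' Ranking score over methods, datasets, and metrics
#'
#' Ranks methods within every (dataset, metric) cell (rank 1 = highest
#' metric; ties share the average rank) and within every dataset by selected
#' subset size (rank 1 = smallest). A method's score is its metric-rank sum
#' normalised by (number of methods x number of metrics), plus its summed
#' size rank; lower is better.
#'
#' @param table Tibble/data frame with columns `method`, `dataset`,
#'   `metric`, `value`, `subset_size` (one `subset_size` per
#'   method-dataset pair).
#' @return Tibble: `method`, `metric_rank_sum`, `size_rank_sum`,
#'   `ranking_score`, sorted ascending by score.
#' @export
ranking_score <- function(table) {
  table <- tibble::as_tibble(table)
  need <- c("method", "dataset", "metric", "value", "subset_size")
  if (!all(need %in% names(table))) {
    abort(sprintf("table needs columns: %s.", paste(need, collapse = ", ")))
  }
  if (anyNA(table$value)) {
    warn("missing metric values: ranks computed over available methods only.")
  }
  n_model <- dplyr::n_distinct(table$method)
  n_metric <- dplyr::n_distinct(table$metric)
  metric_ranks <- table |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$dataset, .data$metric) |>
    dplyr::mutate(r = rank(-.data$value, ties.method = "average")) |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(metric_rank_sum = sum(.data$r), .groups = "drop")
  size_ranks <- table |>
    dplyr::distinct(.data$method, .data$dataset, .data$subset_size) |>
    dplyr::group_by(.data$dataset) |>
    dplyr::mutate(r = rank(.data$subset_size, ties.method = "average")) |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(size_rank_sum = sum(.data$r), .groups = "drop")
  dplyr::left_join(metric_ranks, size_ranks, by = "method") |>
    dplyr::mutate(ranking_score =
                    .data$metric_rank_sum / (n_model * n_metric) +
                    .data$size_rank_sum) |>
    dplyr::arrange(.data$ranking_score)
}
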