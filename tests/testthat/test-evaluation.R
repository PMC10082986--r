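test_that("stratified folds preserve class proportions within one sample", {
  y <- rep(1:2, c(40, 20))
  set.seed(1)
  f <- stratified_kfold(y, 5)
  for (k in 1:5) {
    expect_equal(sum(f == k & y == 1), 8)
    expect_equal(sum(f == k & y == 2), 4)
  }
  y2 <- rep(1:2, c(7, 5))
  set.seed(2)
  f2 <- stratified_kfold(y2, 5)
  for (k in 1:5) {
    expect_lte(abs(sum(f2 == k & y2 == 1) - 7 / 5), 1)
    expect_lte(abs(sum(f2 == k & y2 == 2) - 5 / 5), 1)
  }
  set.seed(3); a <- stratified_kfold(y, 5)
  set.seed(3); b <- stratified_kfold(y, 5)
  expect_identical(a, b)
  expect_error(stratified_kfold(rep(1:2, c(10, 3)), 5), "class 2")
})

test_that("stratified bootstrap resamples each class to its own size", {
  y <- rep(1:2, c(40, 20))
  set.seed(4)
  bags <- stratified_bootstrap(y, B = 5)
  for (bag in bags) {
    expect_length(bag$in_bag, 60)
    expect_equal(sum(y[bag$in_bag] == 1), 40)
    expect_equal(sum(y[bag$in_bag] == 2), 20)
    expect_length(intersect(bag$oob, bag$in_bag), 0)
  }
})

test_that("out-of-bag fraction concentrates near 1/e", {
  y <- rep(1:2, each = 30)
  set.seed(5)
  fracs <- vapply(suppressMessages(stratified_bootstrap(y, B = 200)),
                  function(b) length(b$oob) / 60, numeric(1))
  # per class (1 - 1/n)^n -> e^-1; 3-sigma band for the mean of 200 bags
  se <- sd(fracs) / sqrt(200)
  expect_lt(abs(mean(fracs) - exp(-1)), 3 * se + 0.01)
})

test_that("accuracy follows its contingency definition", {
  expect_equal(accuracy(c(rep(1, 5), rep(2, 5)),
                        c(1, 1, 1, 2, 2, 2, 2, 2, 2, 1)), 0.7)
  expect_equal(accuracy(1:4, 1:4), 1)
  expect_equal(accuracy(rep(1:3, c(4, 3, 3)),
                        c(1, 1, 1, 3, 2, 2, 1, 3, 2, 1)), 0.6)
  expect_error(accuracy(integer(0), integer(0)), "empty")
})

test_that("macro and micro AUC behave correctly on binary and degenerate cases", {
  # perfectly ordered scores
  y <- rep(1:2, each = 5)
  s2 <- cbind(c(0.9, 0.8, 0.85, 0.7, 0.95, 0.1, 0.2, 0.3, 0.15, 0.25))
  scores <- cbind(s2, 1 - s2)
  out <- macro_micro_auc(y, scores)
  expect_equal(out$macro, 1)
  expect_equal(out$micro, 1)
  # binary macro average equals the standard AUC (both one-vs-rest AUCs
  # coincide for complementary columns); micro is the pooled variant
  set.seed(6)
  p1 <- runif(40)
  yb <- sample(rep(1:2, 20))
  res <- macro_micro_auc(yb, cbind(p1, 1 - p1))
  ref <- as.numeric(suppressMessages(pROC::auc(yb == 1, p1,
                                               direction = "<")))
  expect_equal(res$macro, ref, tolerance = 1e-9)
  expect_true(res$micro >= 0 && res$micro <= 1)
  # reversing scores flips the AUC
  rev <- macro_micro_auc(yb, cbind(1 - p1, p1))
  expect_equal(rev$macro, 1 - res$macro, tolerance = 1e-12)
  # label-independent scores sit near 1/2
  set.seed(7)
  n <- 4000
  pr <- runif(n)
  yr <- sample(rep(1:2, n / 2))
  rnd <- macro_micro_auc(yr, cbind(pr, 1 - pr))
  expect_lt(abs(rnd$macro - 0.5), 3 / sqrt(n))
  expect_error(macro_micro_auc(yb, cbind(p1, p1)), "sum to 1")
})

test_that("multiclass micro pooling matches a direct flat computation", {
  set.seed(8)
  y <- sample(rep(1:3, each = 10))
  raw <- matrix(runif(90), 30, 3) + 0.5 * outer(y, 1:3, "==")
  scores <- raw / rowSums(raw)
  out <- macro_micro_auc(y, scores)
  flat_ind <- c(y == 1, y == 2, y == 3)
  flat_score <- c(scores[, 1], scores[, 2], scores[, 3])
  r <- rank(flat_score)
  n1 <- sum(flat_ind); n0 <- sum(!flat_ind)
  expect_equal(out$micro, (sum(r[flat_ind]) - n1 * (n1 + 1) / 2) / (n1 * n0))
  per <- vapply(1:3, function(k) as.numeric(suppressMessages(
    pROC::auc(y == k, scores[, k], direction = "<"))), numeric(1))
  expect_equal(out$macro, mean(per), tolerance = 1e-9)
})

test_that("grid tuning maximises cross-validated accuracy with first-in-grid ties", {
  gen <- fixture_suite()$separable
  X <- gen$dataset$matrix; y <- gen$dataset$labels
  one <- data.frame(sigma = 0.01, cost = 1)
  set.seed(9)
  t1 <- tune_classifier(X, y, one,
                        function(row) classifier_svm(row$sigma, row$cost))
  expect_equal(t1$best$sigma, 0.01)
  # linearly separable data: every sensible grid point reaches accuracy 1,
  # so the tie rule must return the first grid row
  grid <- data.frame(sigma = c(0.01, 0.02, 0.05), cost = c(1, 1, 1))
  set.seed(10)
  t2 <- tune_classifier(X, y, grid,
                        function(row) classifier_svm(row$sigma, row$cost))
  expect_equal(max(t2$scores$mean_accuracy), 1)
  first_max <- which.max(t2$scores$mean_accuracy)
  expect_equal(t2$best$sigma, grid$sigma[first_max])
  set.seed(11); a <- tune_classifier(X, y, grid,
                                     function(row) classifier_svm(row$sigma, row$cost))
  set.seed(11); b <- tune_classifier(X, y, grid,
                                     function(row) classifier_svm(row$sigma, row$cost))
  expect_identical(a$best, b$best)
})

test_that("the Rprop network learns a separable problem through the contract", {
  gen <- fixture_suite()$separable
  X <- gen$dataset$matrix; y <- gen$dataset$labels
  set.seed(12)
  clf <- classifier_mlp(hn1 = 8, hn2 = 4, epochs = 200)
  model <- clf$fit(X, y)
  prob <- clf$predict_prob(model, X)
  expect_equal(dim(prob), c(40, 2))
  expect_equal(unname(rowSums(prob)), rep(1, 40), tolerance = 1e-9)
  expect_gte(accuracy(y, apply(prob, 1, which.max)), 0.95)
})

test_that("nested cross-validation produces per-fold metrics without leakage", {
  gen <- generate_expression(sim_spec(n = 50, p = 40, C = 2, m_info = 6,
                                      sigma = 0.1, seed = 41))
  cfg <- run_config(m = 5, pop_size = 10, generations = 5, bags = 3,
                    seed = 19, outer_folds = 5, k_range = 5:8)
  res <- suppressWarnings(nested_cv_evaluate(
    gen$dataset, cfg,
    classifiers = list(svm = function(row) classifier_svm(row$sigma, row$cost)),
    grids = list(svm = data.frame(sigma = c(0.05, 0.2), cost = c(1, 1)))))
  expect_equal(nrow(res$metrics), 5)
  expect_true(all(res$metrics$accuracy >= 0 & res$metrics$accuracy <= 1,
                  na.rm = TRUE))
  expect_true(all(res$metrics$macro_auc >= 0 & res$metrics$macro_auc <= 1,
                  na.rm = TRUE))
  # leakage audit: test-fold indices never intersect selection/tuning indices
  expect_true(all(res$audit$overlap == 0))
  expect_equal(res$audit$n_train + res$audit$n_test, rep(50, 5))
  g <- glance(res)
  expect_equal(nrow(g), 1)
  expect_true(is.finite(g$accuracy_mean))
})

test_that("ranking scores reward dominance and average tied ranks", {
  t1 <- tibble::tibble(
    method = rep(c("A", "B"), each = 1),
    dataset = "d1", metric = "auc",
    value = c(0.9, 0.8), subset_size = c(10, 20))
  r1 <- ranking_score(t1)
  expect_lt(r1$ranking_score[r1$method == "A"],
            r1$ranking_score[r1$method == "B"])
  t2 <- t1; t2$value <- c(0.9, 0.9); t2$subset_size <- c(10, 10)
  r2 <- ranking_score(t2)
  expect_equal(r2$ranking_score[1], r2$ranking_score[2])
})

test_that("the ranking score matches a hand-worked 3x2x2 table", {
  tab <- expand.grid(method = c("A", "B", "C"), dataset = c("d1", "d2"),
                     metric = c("m1", "m2"), stringsAsFactors = FALSE)
  tab$value <- c(0.9, 0.8, 0.7,   0.6, 0.7, 0.8,    # m1 on d1, d2
                 0.5, 0.5, 0.4,   0.9, 0.6, 0.3)    # m2 on d1, d2
  sizes <- c(A = 10, B = 30, C = 20)
  tab$subset_size <- sizes[tab$method]
  out <- ranking_score(tab)
  # hand ranks -- m1/d1: A1 B2 C3; m1/d2: A3 B2 C1; m2/d1: A1.5 B1.5 C3;
  # m2/d2: A1 B2 C3. Sums: A 6.5, B 7.5, C 10. Sizes (both datasets):
  # A 1+1, B 3+3, C 2+2. Score = metric_sum / (3 * 2) + size_sum.
  expect_equal(out$metric_rank_sum[out$method == "A"], 6.5)
  expect_equal(out$metric_rank_sum[out$method == "B"], 7.5)
  expect_equal(out$metric_rank_sum[out$method == "C"], 10)
  expect_equal(out$ranking_score[out$method == "A"], 6.5 / 6 + 2)
  expect_equal(out$ranking_score[out$method == "B"], 7.5 / 6 + 6)
  expect_equal(out$ranking_score[out$method == "C"], 10 / 6 + 4)
})
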