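test_that("the binomial inclusion threshold reproduces derived values and edge cases", {
  # independent check: smallest c with 1 - pbinom(c-1, runs, v/n) < alpha
  oracle <- function(n_gene, v = 30, runs = 10, alpha = 0.05) {
    p <- v / n_gene
    for (cc in 1:runs) if (1 - pbinom(cc - 1, runs, p) < alpha) return(max(2, cc))
    runs + 1
  }
  set.seed(101)
  for (n_gene in sample(31:5000, 25)) {
    expect_equal(as.integer(selection_threshold(n_gene)), oracle(n_gene))
  }
  expect_equal(attr(selection_threshold(300), "prob"), 0.1)
  # v == n_gene: every gene always selected, nothing can be non-random
  expect_warning(c_cert <- selection_threshold(30, v = 30, runs = 10), "qualify")
  expect_equal(as.integer(c_cert), 11L)
  expect_error(selection_threshold(10, v = 30), "must be >=")
})

test_that("a single search returns a deterministic, validated finalist", {
  gen <- generate_expression(sim_spec(n = 48, p = 60, C = 2, m_info = 6,
                                      sigma = 0.1, seed = 31))
  X <- gen$dataset$matrix; y <- gen$dataset$labels
  set.seed(5)
  split <- stratified_bootstrap(y, B = 1)[[1]]
  cfg <- run_config(m = 8, pop_size = 16, generations = 12, seed = 5)
  run <- function() {
    set.seed(99)
    run_single_search(X[split$in_bag, ], y[split$in_bag],
                      X[split$oob, ], y[split$oob],
                      k = 6, d = 2, config = cfg)
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$subset, r2$subset)
  expect_length(r1$subset, 8)
  expect_true(r1$oob_accuracy >= 0 && r1$oob_accuracy <= 1)
  expect_equal(nrow(r1$candidates), length(unique(vapply(
    r1$candidates$rank, identity, numeric(1)))))
  # single-class out-of-bag: falls back to the best-fitness finalist
  oob1 <- which(y[split$oob] == 1)
  expect_warning(
    fb <- run_single_search(X[split$in_bag, ], y[split$in_bag],
                            X[split$oob[oob1], , drop = FALSE],
                            y[split$oob][oob1],
                            k = 6, d = 2, config = cfg),
    "single class")
  expect_true(is.na(fb$oob_accuracy))
})

test_that("searched subsets beat a random-subset baseline on held-out accuracy", {
  gen <- generate_expression(sim_spec(n = 50, p = 120, C = 2, m_info = 8,
                                      sigma = 0.1, seed = 77))
  X <- gen$dataset$matrix; y <- gen$dataset$labels
  set.seed(7)
  split <- stratified_bootstrap(y, B = 1)[[1]]
  cfg <- run_config(m = 10, pop_size = 20, generations = 15, seed = 7)
  set.seed(7)
  found <- run_single_search(X[split$in_bag, ], y[split$in_bag],
                             X[split$oob, ], y[split$oob],
                             k = 7, d = 2, config = cfg)
  set.seed(8)
  base <- replicate(20, {
    s <- sort(sample(120, 10))
    isoga:::svm_oob_accuracy(X[split$in_bag, s], y[split$in_bag],
                             X[split$oob, s, drop = FALSE], y[split$oob])
  })
  expect_gte(found$oob_accuracy, median(base))
})

test_that("full selection satisfies its structural invariants and is reproducible", {
  gen <- generate_expression(sim_spec(n = 40, p = 60, C = 2, m_info = 6,
                                      sigma = 0.1, seed = 13))
  cfg <- run_config(m = 6, pop_size = 12, generations = 8, bags = 4, seed = 17)
  res <- suppressWarnings(iso_ga_select(gen$dataset, cfg))
  bag_union <- sort(unique(unlist(lapply(res$per_bag, `[[`, "subset"))))
  expect_true(all(res$s_best_idx %in% bag_union))
  expect_true(all(res$counts[res$s_best_idx] >= res$threshold$c))
  expect_equal(sum(vapply(res$per_bag, function(b) length(b$subset), 1L)),
               sum(res$counts))
  expect_equal(res$threshold$c,
               as.integer(selection_threshold(60, v = 6, runs = 4)))
  res2 <- suppressWarnings(iso_ga_select(gen$dataset, cfg))
  expect_identical(res$counts, res2$counts)
  expect_identical(res$s_best, res2$s_best)
  expect_identical(res$k, res2$k)
  # tidy/glance accessors agree with the raw object
  td <- tidy(res)
  expect_equal(sum(td$included), length(res$s_best))
  expect_equal(glance(res)$n_selected, length(res$s_best))
})

test_that("B = 1 exercises the impossible-threshold warning path", {
  gen <- generate_expression(sim_spec(n = 30, p = 40, C = 2, m_info = 4,
                                      sigma = 0.1, seed = 23))
  cfg <- run_config(m = 5, pop_size = 8, generations = 4, bags = 1, seed = 3)
  expect_warning(res <- iso_ga_select(gen$dataset, cfg))
  # with one bag the floor c >= 2 can never be reached
  expect_length(res$s_best, 0)
})

test_that("ablation modes run the identical pipeline without the Isomap step", {
  gen <- generate_expression(sim_spec(n = 36, p = 40, C = 2, m_info = 5,
                                      sigma = 0.1, seed = 29))
  for (mode in c("mds", "none")) {
    cfg <- run_config(m = 5, pop_size = 10, generations = 5, bags = 3,
                      seed = 11, embedding = mode)
    res <- suppressWarnings(iso_ga_select(gen$dataset, cfg))
    expect_s3_class(res, "iso_ga_result")
    expect_true(is.na(res$k))
    expect_equal(res$config$embedding, mode)
  }
})

test_that("Isomap and MDS fitness agree in the linear limit k = n - 1", {
  # data confined to an affine subspace: geodesic = Euclidean on the
  # complete graph, so the two embeddings give identical distance geometry
  set.seed(37)
  n <- 20
  basis <- qr.Q(qr(matrix(rnorm(6 * 2), 6, 2)))
  scores <- matrix(rnorm(n * 2), n, 2)
  X <- scores %*% t(basis) + 3
  y <- rep(1:2, each = n / 2)
  f_iso <- make_fitness(X, y, k = n - 1, d = 2, mode = "isomap")
  f_mds <- make_fitness(X, y, k = NA, d = 2, mode = "mds")
  for (s in list(1:3, c(2L, 4L, 6L), 1:6)) {
    expect_equal(f_iso(s), f_mds(s), tolerance = 1e-6)
  }
})
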