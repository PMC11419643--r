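test_that("Lloyd iterations solve trivial instances exactly", {
  X <- rbind(c(0, 0), c(0, 0), c(9, 9), c(9, 9))
  km <- kmeans_run(X, 2, seed = 1)
  expect_equal(km$sse, 0)
  expect_setequal(split(seq_len(4), km$assignments),
                  list(1:2, 3:4))
  expect_equal(km$centers[order(km$centers[, 1]), ],
               rbind(c(0, 0), c(9, 9)))

  X2 <- matrix(rnorm(30), 10, 3)
  km1 <- kmeans_run(X2, 1, seed = 2)
  expect_equal(as.numeric(km1$centers), colMeans(X2))
  expect_true(all(km1$assignments == 1L))

  expect_error(kmeans_run(X2, 11), "exceeds")
})

test_that("k-means matches the exhaustive enumeration optimum in 1-D", {
  set.seed(4)
  X <- matrix(c(0.1, 0.2, 0.3, 5.0, 5.2, 5.4), ncol = 1)
  opt <- enumerate_sse_optimum(X, 2)
  km <- kmeans_run(X, 2, seed = 3)
  expect_equal(km$sse, opt, tolerance = 1e-10)
})

test_that("chromosome objective follows its definition", {
  X <- matrix(c(0, 1, 2, 3), ncol = 1)
  # singleton clusters have zero objective
  expect_equal(as.numeric(sse_fitness(1:4, X)), 0)
  # split {0,1} vs {2,3}: members are 0.5 away from each centroid
  expect_equal(as.numeric(sse_fitness(c(1, 1, 2, 2), X)), 4 * 0.5)
  # label permutation leaves the objective unchanged
  expect_equal(as.numeric(sse_fitness(c(2, 2, 1, 1), X)),
               as.numeric(sse_fitness(c(1, 1, 2, 2), X)))
  # empty cluster flags degeneracy
  expect_true(attr(sse_fitness(c(1, 1, 1, 1), X, k = 2), "degenerate"))
})

test_that("roulette probabilities implement the shifted-goodness rule", {
  expect_equal(roulette_probabilities(c(5, 5, 5)), rep(1 / 3, 3))
  expect_equal(roulette_probabilities(c(1, 2, 3)), c(0, 1 / 3, 2 / 3))
  expect_error(roulette_probabilities(numeric(0)), "empty")
  for (i in 1:20) {
    p <- roulette_probabilities(rnorm(sample(2:10, 1)))
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0))
  }
})

test_that("GA evolution preserves gene range and never worsens the best", {
  set.seed(8)
  X <- matrix(rnorm(24), 12, 2)
  k <- 3
  cfg <- ga_config(population_size = 8, crossover_prob = 0.8,
                   mutation_prob = 0.3, elitism_count = 1, seed = 1)
  pop <- lapply(1:8, function(i)
    strokerisk:::new_individual(sample.int(k, 12, TRUE), X, k))
  best <- min(vapply(pop, function(p) p$fitness, 0))
  for (g in 1:50) {
    pop <- evolve_population(pop, X, cfg, k)
    fits <- vapply(pop, function(p) p$fitness, 0)
    genes <- unlist(lapply(pop, function(p) p$chromosome))
    expect_true(all(genes >= 1 & genes <= k))
    expect_lte(min(fits), best + 1e-12)
    best <- min(fits)
  }
})

test_that("no-op evolution returns an identical generation", {
  X <- matrix(rnorm(10), 5, 2)
  cfg <- ga_config(population_size = 4, crossover_prob = 0,
                   mutation_prob = 0, elitism_count = 4)
  pop <- lapply(1:4, function(i)
    strokerisk:::new_individual(sample.int(2, 5, TRUE), X, 2))
  nxt <- evolve_population(pop, X, cfg, 2)
  expect_setequal(lapply(nxt, `[[`, "chromosome"),
                  lapply(pop, `[[`, "chromosome"))
})

test_that("HKGA repairs empty clusters and does not exceed Phase 1", {
  # three tight groups; k = 3 with few records tempts empty clusters
  X <- rbind(matrix(rnorm(8, 0, 0.1), 4),
             matrix(rnorm(8, 5, 0.1), 4),
             matrix(rnorm(8, 10, 0.1), 4))
  for (seed in 1:5) {
    cfg <- ga_config(population_size = 12, generations = 15, seed = seed)
    model <- hkga_cluster(X, 3, cfg)
    expect_true(all(tabulate(model$assignments, 3) > 0))
    phase1 <- kmeans_run(X, 3, seed = cfg$seed)
    expect_lte(model$sse, phase1$sse + 1e-9)
  }
})

test_that("HKGA attains the enumeration optimum on a small instance", {
  set.seed(2)
  X <- matrix(c(rnorm(4, 0, 0.3), rnorm(4, 4, 0.3)), ncol = 1)
  opt <- enumerate_sse_optimum(X, 2)
  hits <- 0
  for (seed in 1:5) {
    m <- hkga_cluster(X, 2, ga_config(population_size = 12,
                                      generations = 20, seed = seed))
    if (abs(m$sse - opt) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("imputation fills cluster means and never touches observed cells", {
  vals <- cbind(x = c(1, 1, 9, 9), bmi = c(24, NA, 40, 42))
  tab <- feature_table(vals)
  model <- kmeans_run(tab, 2, seed = 1)
  # force the natural pairing for a deterministic check
  filled <- impute_missing(tab, model, "impute")
  cl_of_2 <- model$assignments[2]
  expected <- mean(vals[model$assignments == cl_of_2 & !is.na(vals[, 2]), 2])
  expect_equal(unname(filled$values[2, "bmi"]), expected)
  expect_false(any(filled$missing_mask))
  obs <- !tab$missing_mask
  expect_identical(filled$values[obs], tab$values[obs])

  dropped <- impute_missing(tab, model, "drop")
  expect_equal(nrow(dropped$values), 3)
})

test_that("cluster-mean example: missing bmi in a cluster with mean 25", {
  vals <- cbind(x = c(0, 0, 0), bmi = c(24, 26, NA))
  tab <- feature_table(vals)
  model <- kmeans_run(tab, 1, seed = 1)
  model$k <- 1
  filled <- impute_missing(tab, model, "impute")
  expect_equal(unname(filled$values[3, "bmi"]), 25)
})

test_that("aggregation statistics match the printed divisors", {
  ag <- aggregate_stats(matrix(rep(5, 4), ncol = 1))
  expect_equal(unname(ag$mean), 5)
  expect_equal(unname(ag$median), 5)
  expect_equal(unname(ag$sd), 0)
  expect_equal(unname(ag$var), 0)

  ag2 <- aggregate_stats(matrix(1:4, ncol = 1))
  expect_equal(unname(ag2$mean), 2.5)
  expect_equal(unname(ag2$median), 2.5)
  expect_equal(unname(ag2$sd), sqrt(5 / 4))
  expect_equal(unname(ag2$var), 5 / 3)

  for (i in 1:10) {
    b <- sample(3:20, 1)
    ag3 <- aggregate_stats(matrix(rnorm(b), ncol = 1))
    expect_equal(unname(ag3$sd^2 * b / (b - 1)), unname(ag3$var))
  }
  expect_error(aggregate_stats(matrix(1, 1, 1)), "fewer than 2")
})
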