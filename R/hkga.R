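# Hybrid k-means + genetic-algorithm clustering (HKGA) and imputation --------

#' GA configuration for HKGA
#'
#' @param population_size population size (>= 2).
#' @param generations number of GA generations.
#' @param crossover_prob per-gene uniform crossover probability.
#' @param mutation_prob per-individual mutation probability.
#' @param elitism_count number of best individuals copied unchanged.
#' @param seed RNG seed.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(population_size = 30L, generations = 50L,
                      crossover_prob = 0.8, mutation_prob = 0.1,
                      elitism_count = 1L, seed = 1L) {
  if (population_size < 2) stop_arg("population_size must be >= 2")
  if (crossover_prob < 0 || crossover_prob > 1 ||
      mutation_prob < 0 || mutation_prob > 1)
    stop_arg("probabilities must lie in [0, 1]")
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 elitism_count = as.integer(elitism_count),
                 seed = as.integer(seed)),
            class = "ga_config")
}

# numeric matrix of observed values with NA at masked cells
masked_matrix <- function(table) {
  if (inherits(table, "feature_table")) {
    v <- table$values
    v[table$missing_mask] <- NA_real_
    v
  } else {
    as.matrix(table)
  }
}

# partial-distance rule: squared distance on observed coordinates scaled by
# d / |observed|; rows with no observed coordinate are disallowed upstream
partial_dist2 <- function(X, C) {
  d <- ncol(X)
  obs <- !is.na(X)
  X0 <- X; X0[!obs] <- 0
  # ||x - c||^2 over observed coords = sum_obs x^2 - 2 x.c + sum_obs c^2
  t1 <- rowSums(X0^2)
  t2 <- X0 %*% t(C)
  t3 <- obs %*% t(C^2)
  D <- (t1 - 2 * t2 + t3)
  nobs <- rowSums(obs)
  pmax(D, 0) * (d / nobs)
}

#' Lloyd k-means with the partial-distance rule
#'
#' Standard Lloyd iterations: nearest-center assignment followed by the mean
#' update, stopping when the centers repeat or `max_iter` is reached. Masked
#' cells are handled by the partial-distance rule (distances over observed
#' coordinates, rescaled by `d/|observed|`); center updates average observed
#' values only. The within-cluster sum of euclidean distances (the clustering
#' objective, see [sse_fitness()]) is non-increasing in the complete-data
#' case.
#'
#' @param table a [feature_table()] or numeric matrix.
#' @param k number of clusters (<= number of records).
#' @param max_iter iteration cap.
#' @param seed RNG seed for the arbitrary initial centers.
#' @return an object of class `cluster_model`: `centers` (k x d),
#'   `assignments` (length n, in 1..k), `sse` (the [sse_fitness()] value),
#'   `iterations`.
#' @export
kmeans_run <- function(table, k, max_iter = 100L, seed = 1L) {
  X <- masked_matrix(table)
  n <- nrow(X); d <- ncol(X)
  if (k > n) stop_arg("k (%d) exceeds the number of records (%d)", k, n)
  if (any(rowSums(!is.na(X)) == 0))
    stop_arg("records with no observed value cannot be clustered")
  with_seed(seed, {
    centers <- X[sample.int(n, k), , drop = FALSE]
    # arbitrary initial centers must be complete; fill holes with column means
    cm <- colMeans(X, na.rm = TRUE)
    for (j in seq_len(d)) centers[is.na(centers[, j]), j] <- cm[j]
    assign_old <- rep(0L, n)
    it <- 0L
    repeat {
      it <- it + 1L
      D <- partial_dist2(X, centers)
      assignments <- max.col(-D, ties.method = "first")
      new_centers <- centers
      for (j in seq_len(k)) {
        rows <- X[assignments == j, , drop = FALSE]
        if (nrow(rows) > 0) {
          mu <- colMeans(rows, na.rm = TRUE)
          mu[is.nan(mu)] <- centers[j, is.nan(mu)]
          new_centers[j, ] <- mu
        }
      }
      if (identical(assignments, assign_old) &&
          max(abs(new_centers - centers)) < 1e-12) {
        centers <- new_centers
        break
      }
      centers <- new_centers
      assign_old <- assignments
      if (it >= max_iter) break
    }
    cluster_model(centers, assignments, X)
  })
}

cluster_model <- function(centers, assignments, X) {
  structure(list(centers = centers,
                 assignments = as.integer(assignments),
                 sse = sse_value(assignments, X, centers),
                 k = nrow(centers)),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d, objective = %.6g, sizes: %s\n",
              x$k, x$sse, paste(tabulate(x$assignments, x$k),
                                collapse = "/")))
  invisible(x)
}

# objective given explicit centers (partial-distance aware)
sse_value <- function(assignments, X, centers) {
  D <- partial_dist2(X, centers)
  sum(sqrt(D[cbind(seq_len(nrow(X)), assignments)]))
}

#' Clustering objective of an assignment chromosome
#'
#' The objective is the total within-cluster sum of euclidean distances of
#' each member to its cluster centroid (the centroid of the members encoded
#' by the chromosome). Empty clusters contribute zero but mark the
#' chromosome as degenerate (attribute `"degenerate"`).
#'
#' @param chromosome integer vector of cluster indices in `1..k` (or a list
#'   with a `chromosome` field).
#' @param table a [feature_table()] or numeric matrix (complete rows are
#'   assumed for exact evaluation; masked cells use the partial-distance
#'   rule).
#' @param k number of clusters; defaults to `max(chromosome)`.
#' @return the scalar objective, with attribute `degenerate`.
#' @export
sse_fitness <- function(chromosome, table, k = NULL) {
  if (is.list(chromosome)) chromosome <- chromosome$chromosome
  X <- masked_matrix(table)
  chromosome <- as.integer(chromosome)
  if (is.null(k)) k <- max(chromosome)
  centers <- matrix(NA_real_, k, ncol(X))
  sizes <- tabulate(chromosome, k)
  for (j in which(sizes > 0)) {
    centers[j, ] <- colMeans(X[chromosome == j, , drop = FALSE], na.rm = TRUE)
  }
  centers[is.na(centers)] <- 0
  tot <- sse_value(chromosome, X, centers)
  attr(tot, "degenerate") <- any(sizes == 0)
  tot
}

#' Roulette-wheel selection probabilities
#'
#' `p(x) = (g(x) - g_min) / sum(g - g_min)` over the population goodness
#' values. When all goodness values are equal the rule degenerates to 0/0 and
#' uniform probabilities are returned.
#'
#' @param goodness numeric vector of finite goodness values (larger is
#'   better; for the clustering objective pass the negated objective).
#' @return a probability vector (nonnegative, sums to one).
#' @export
roulette_probabilities <- function(goodness) {
  if (length(goodness) == 0) stop_arg("empty goodness vector")
  if (!all(is.finite(goodness))) stop_arg("goodness must be finite")
  sh <- goodness - min(goodness)
  tot <- sum(sh)
  if (tot <= 0) return(rep(1 / length(goodness), length(goodness)))
  sh / tot
}

new_individual <- function(chromosome, table, k) {
  f <- sse_fitness(chromosome, table, k)
  list(chromosome = as.integer(chromosome), fitness = as.numeric(f),
       degenerate = isTRUE(attr(f, "degenerate")))
}

#' Evolve one GA generation of assignment chromosomes
#'
#' One generation: roulette selection on goodness = -objective, per-gene
#' uniform crossover with probability `cfg$crossover_prob`, mutation that
#' resamples two randomly chosen gene positions, and elitism keeping the
#' `cfg$elitism_count` best individuals. With elitism >= 1 the best objective
#' never worsens.
#'
#' @param pop list of individuals (each with `chromosome`, `fitness`).
#' @param table a [feature_table()] or numeric matrix.
#' @param cfg a [ga_config()].
#' @param k number of clusters.
#' @return the next-generation population (same size, sorted by fitness).
#' @export
evolve_population <- function(pop, table, cfg, k) {
  if (length(pop) == 0) stop_arg("population must be non-empty")
  P <- length(pop)
  n <- length(pop[[1]]$chromosome)
  fit <- vapply(pop, function(p) p$fitness, 0)
  probs <- roulette_probabilities(-fit)
  ord <- order(fit)
  elite <- pop[ord[seq_len(min(cfg$elitism_count, P))]]
  children <- vector("list", P - length(elite))
  i <- 1L
  while (i <= length(children)) {
    pa <- pop[[sample.int(P, 1, prob = probs)]]$chromosome
    pb <- pop[[sample.int(P, 1, prob = probs)]]$chromosome
    child <- pa
    if (cfg$crossover_prob > 0) {
      take_b <- stats::runif(n) < cfg$crossover_prob * 0.5
      child[take_b] <- pb[take_b]
    }
    if (stats::runif(1) < cfg$mutation_prob) {
      pos <- sample.int(n, min(2L, n))
      child[pos] <- sample.int(k, length(pos), replace = TRUE)
    }
    children[[i]] <- new_individual(child, table, k)
    i <- i + 1L
  }
  out <- c(elite, children)
  out[order(vapply(out, function(p) p$fitness, 0))]
}

#' Hybrid k-means / genetic-algorithm clustering
#'
#' Phase 1 runs Lloyd k-means; its assignment seeds the GA population
#' (remaining individuals are random chromosomes plus mutated copies of the
#' seed). The GA evolves assignment chromosomes under the within-cluster
#' distance objective. Degenerate (empty-cluster) solutions are repaired by
#' reassigning the farthest point of the largest cluster to each empty
#' cluster, so the returned model never has an empty cluster, and its
#' objective never exceeds the Phase-1 k-means objective.
#'
#' @param table a [feature_table()] or numeric matrix.
#' @param k number of clusters (>= 2).
#' @param cfg a [ga_config()].
#' @param max_iter Lloyd iteration cap for Phase 1.
#' @return a `cluster_model` (see [kmeans_run()]).
#' @export
hkga_cluster <- function(table, k, cfg = ga_config(), max_iter = 100L) {
  if (k < 2) stop_arg("hkga_cluster requires k >= 2")
  X <- masked_matrix(table)
  n <- nrow(X)
  phase1 <- kmeans_run(X, k, max_iter, seed = cfg$seed)
  with_seed(derive_seed(cfg$seed, 1L), {
    seed_chrom <- repair_chromosome(phase1$assignments, X, k)
    pop <- vector("list", cfg$population_size)
    pop[[1]] <- new_individual(seed_chrom, X, k)
    for (i in seq_len(cfg$population_size - 1L)) {
      ch <- if (i %% 2 == 0) {
        m <- seed_chrom
        pos <- sample.int(n, max(1L, n %/% 5))
        m[pos] <- sample.int(k, length(pos), replace = TRUE)
        m
      } else {
        sample.int(k, n, replace = TRUE)
      }
      pop[[i + 1L]] <- new_individual(ch, X, k)
    }
    for (g in seq_len(cfg$generations)) {
      pop <- evolve_population(pop, X, cfg, k)
    }
    best <- pop[[1]]
    chrom <- repair_chromosome(best$chromosome, X, k)
    centers <- matrix(0, k, ncol(X))
    for (j in seq_len(k)) {
      mu <- colMeans(X[chrom == j, , drop = FALSE], na.rm = TRUE)
      mu[is.na(mu)] <- 0
      centers[j, ] <- mu
    }
    model <- cluster_model(centers, chrom, X)
    if (model$sse > phase1$sse + 1e-9) {
      model <- cluster_model(phase1$centers,
                             repair_chromosome(phase1$assignments, X, k), X)
    }
    model
  })
}

# give every empty cluster the farthest member of the largest cluster
repair_chromosome <- function(chrom, X, k) {
  chrom <- as.integer(chrom)
  repeat {
    sizes <- tabulate(chrom, k)
    empty <- which(sizes == 0)
    if (length(empty) == 0) return(chrom)
    big <- which.max(sizes)
    members <- which(chrom == big)
    ctr <- colMeans(X[members, , drop = FALSE], na.rm = TRUE)
    ctr[is.na(ctr)] <- 0
    D <- partial_dist2(X[members, , drop = FALSE],
                       matrix(ctr, 1))
    chrom[members[which.max(D)]] <- empty[1]
  }
}

#' Impute or drop masked cells using a cluster model
#'
#' `mode = "impute"` fills each masked cell with the mean of that attribute
#' over the observed members of the record's cluster and clears the mask;
#' if a cluster has no observed value for an attribute, the global attribute
#' mean is used (with a message). `mode = "drop"` removes records containing
#' any masked cell. Observed cells never change.
#'
#' @param table a [feature_table()].
#' @param model a `cluster_model` fitted on the table's observed values.
#' @param mode `"impute"` (default) or `"drop"`.
#' @return a new `feature_table` with no masked cells.
#' @export
impute_missing <- function(table, model, mode = c("impute", "drop")) {
  mode <- match.arg(mode)
  validate_feature_table(table)
  if (mode == "drop") {
    keep <- rowSums(table$missing_mask) == 0
    return(feature_table(table$values[keep, , drop = FALSE],
                         table$missing_mask[keep, , drop = FALSE],
                         table$attribute_names, table$codebook,
                         table$labels[keep], table$record_ids[keep]))
  }
  X <- masked_matrix(table)
  global_mean <- colMeans(X, na.rm = TRUE)
  values <- table$values
  fell_back <- character(0)
  for (j in seq_len(model$k)) {
    rows <- which(model$assignments == j)
    if (length(rows) == 0) next
    mu <- colMeans(X[rows, , drop = FALSE], na.rm = TRUE)
    nohit <- is.nan(mu)
    if (any(nohit)) {
      mu[nohit] <- global_mean[nohit]
      fell_back <- union(fell_back, colnames(X)[nohit])
    }
    for (attr in which(colSums(table$missing_mask[rows, , drop = FALSE]) > 0)) {
      miss <- rows[table$missing_mask[rows, attr]]
      fill <- mu[attr]
      if (colnames(values)[attr] %in% names(table$codebook))
        fill <- round(fill)
      values[miss, attr] <- fill
    }
  }
  if (length(fell_back))
    message("impute_missing: global-mean fallback for attribute(s) ",
            paste(fell_back, collapse = ", "))
  feature_table(values, matrix(FALSE, nrow(values), ncol(values)),
                table$attribute_names, table$codebook, table$labels,
                table$record_ids)
}

#' Per-attribute aggregation statistics
#'
#' For each attribute of a complete table: mean, median, population standard
#' deviation (divisor `b`) and sample variance (divisor `b - 1`). On
#' complete data `sd^2 = var * (b - 1) / b`.
#'
#' @param table a [feature_table()] or numeric matrix with no masked cells.
#' @return an object of class `aggregate_stats`: list with numeric vectors
#'   `mean`, `median`, `sd`, `var` named by attribute.
#' @export
aggregate_stats <- function(table) {
  X <- masked_matrix(table)
  if (anyNA(X)) stop_arg("aggregate_stats requires a complete table")
  b <- nrow(X)
  if (b < 2) stop_arg("sample variance undefined for fewer than 2 records")
  mu <- colMeans(X)
  med <- apply(X, 2, stats::median)
  ss <- colSums(sweep(X, 2, mu)^2)
  structure(list(mean = mu, median = med,
                 sd = sqrt(ss / b), var = ss / (b - 1), n = b),
            class = "aggregate_stats")
}

#' @export
print.aggregate_stats <- function(x, ...) {
  cat(sprintf("<aggregate_stats> %d records\n", x$n))
  print(round(rbind(mean = x$mean, median = x$median, sd = x$sd,
                    var = x$var), 4))
  invisible(x)
}
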