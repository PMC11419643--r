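# T-test / Spearman pre-filter and the UD-GSRBEHO wrapper feature selector --
#
# The wrapper hybridizes elephant herding optimization (EHO: clan updating and
# separating operators) with the gradient search rule (GSR), a direction of
# movement (DM) term and a local escape operator (LEO), with an elitist
# best-so-far bookkeeping. Feature subsets are encoded as continuous
# positions in [0,1]^d thresholded at 0.5.

#' Pooled two-sample T statistic
#'
#' `tau = (mean(a) - mean(b)) / sqrt(delta^2 * (d_a + d_b) / (d_a * d_b))`
#' with `delta` the pooled standard deviation. A zero pooled deviation with
#' equal means gives 0; with unequal means, a signed infinite statistic
#' (flagged with attribute `"infinite"`).
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return the signed statistic.
#' @export
t_statistic <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop_arg("both groups need at least 2 values")
  da <- length(a); db <- length(b)
  delta2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (da + db - 2)
  num <- mean(a) - mean(b)
  den <- sqrt(delta2 * (da + db) / (da * db))
  if (den == 0) {
    if (num == 0) return(0)
    out <- sign(num) * Inf
    attr(out, "infinite") <- TRUE
    return(out)
  }
  num / den
}

#' Spearman-style correlation summary of T statistics
#'
#' `lambda = 1 - 6 * sum(taus^2) / (l * (l^2 - 1))`, evaluated literally.
#' When `taus` are the true rank differences of two permutations of `1..l`,
#' this equals the classical Spearman rank correlation.
#'
#' @param taus numeric vector of statistics (or rank differences).
#' @param l number of features (>= 2).
#' @return the scalar correlation summary.
#' @export
spearman_lambda <- function(taus, l) {
  if (l < 2) stop_arg("l must be >= 2")
  1 - 6 * sum(taus^2) / (l * (l^2 - 1))
}

#' Per-feature T statistics and correlation summaries
#'
#' In `"class"` mode (the pipeline default) the statistic for each feature
#' compares its values across the two label classes; in `"adjacent"` mode it
#' compares each feature with the next one, as a fidelity variant. The
#' per-feature correlation summary is `1 - 6*tau_r^2 / (l*(l^2-1))`.
#'
#' @param table [feature_table()] or numeric matrix (complete).
#' @param labels 0/1 labels (required in `"class"` mode).
#' @param mode `"class"` or `"adjacent"`.
#' @return object of class `feature_stats`: `tau`, `lambda` (named numeric
#'   vectors), `mode`.
#' @export
feature_stats <- function(table, labels = NULL,
                          mode = c("class", "adjacent")) {
  mode <- match.arg(mode)
  X <- masked_matrix(table)
  if (anyNA(X)) stop_arg("feature_stats requires a complete table")
  l <- ncol(X)
  tau <- numeric(l)
  if (mode == "class") {
    if (is.null(labels) && inherits(table, "feature_table"))
      labels <- table$labels
    if (is.null(labels)) stop_arg("class mode requires labels")
    g1 <- labels == 1
    for (r in seq_len(l)) {
      t <- t_statistic(X[g1, r], X[!g1, r])
      tau[r] <- as.numeric(t)
    }
  } else {
    for (r in seq_len(l)) {
      s <- if (r < l) r + 1L else 1L
      tau[r] <- as.numeric(t_statistic(X[, r], X[, s]))
    }
  }
  lambda <- vapply(tau, function(t)
    spearman_lambda(if (is.finite(t)) t else sqrt(l * (l^2 - 1) / 6), l), 0)
  names(tau) <- names(lambda) <- colnames(X)
  structure(list(tau = tau, lambda = lambda, mode = mode, l = l),
            class = "feature_stats")
}

#' Keep features with non-zero correlation summary, unioned with a reduced set
#'
#' Features whose correlation summary differs from zero (tolerance 1e-12)
#' are kept and unioned with the indices contributed by the ICA reduction.
#' The result is never empty: if nothing passes, all features are kept (with
#' a warning).
#'
#' @param stats a [feature_stats()] object (or numeric vector of lambda
#'   values).
#' @param ica_set integer indices contributed by the ICA-reduced components.
#' @param n_features total number of features (defaults from `stats`).
#' @return sorted integer vector of candidate feature indices.
#' @export
correlation_filter <- function(stats, ica_set = integer(0),
                               n_features = NULL) {
  lambda <- if (inherits(stats, "feature_stats")) stats$lambda else stats
  if (is.null(n_features)) n_features <- length(lambda)
  kept <- which(abs(lambda) > 1e-12)
  out <- sort(union(kept, as.integer(ica_set)))
  if (length(out) == 0) {
    warning("correlation_filter: all correlation summaries are zero; ",
            "keeping the full feature set")
    out <- seq_len(n_features)
  }
  out
}

#' Rand index between two partitions
#'
#' Fraction of record pairs on which two partitions agree (both together or
#' both apart), computed by pair counting.
#'
#' @param a,b integer vectors of cluster/class memberships.
#' @return scalar in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_arg("partitions must have equal length")
  n <- length(a)
  if (n < 2) return(1)
  tab <- table(a, b)
  nij2 <- sum(choose(tab, 2))
  ai2 <- sum(choose(rowSums(tab), 2))
  bj2 <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * nij2 - ai2 - bj2) / total
}

#' Rand-index fitness of a feature subset
#'
#' Clusters the records on the selected feature columns with seeded k-means
#' (k = number of label classes) and scores the clustering against the
#' labels by the Rand index. The empty subset scores 0.
#'
#' @param subset logical mask over feature columns.
#' @param table [feature_table()] or numeric matrix.
#' @param labels integer class labels.
#' @param seed RNG seed for k-means.
#' @return scalar fitness in `[0, 1]`.
#' @export
rand_index_fitness <- function(subset, table, labels, seed = 1L) {
  X <- masked_matrix(table)
  if (!any(subset)) return(0)
  k <- length(unique(labels))
  Xs <- X[, subset, drop = FALSE]
  cl <- tryCatch(
    with_seed(seed,
              stats::kmeans(Xs, centers = k, nstart = 3L,
                            iter.max = 20L)$cluster),
    error = function(e) NULL)
  if (is.null(cl)) return(0)
  rand_index(cl, labels)
}

# GBO schedules ---------------------------------------------------------------

#' Adaptive convergence coefficient schedule of the gradient search rule
#'
#' `beta = beta_min + (beta_max - beta_min) * (1 - (m/M)^3)^2` with default
#' bounds 1.2 and 0.2, so `beta(0) = beta_max` and `beta(M) = beta_min`,
#' decreasing monotonically in between.
#'
#' @param m current iteration (0..M).
#' @param M maximum iteration.
#' @param beta_min,beta_max schedule bounds.
#' @return the coefficient value.
#' @examples
#' gbo_beta(100, 100)  # 0.2
#' @export
gbo_beta <- function(m, M, beta_min = 0.2, beta_max = 1.2) {
  beta_min + (beta_max - beta_min) * (1 - (m / M)^3)^2
}

# alpha controls the convergence pace; large early, shrinking with beta
gbo_alpha <- function(beta) {
  abs(beta * sin(3 * pi / 2 + sin(beta * 3 * pi / 2)))
}

#' One gradient-search-rule step for a single agent
#'
#' Computes the GSR and DM displacement terms and the three candidate
#' vectors X1 (current position improved by GSR + DM), X2 (the same rule
#' anchored at the best agent) and X3 (a contraction between them), and
#' blends them with two uniform random weights. All random draws come from
#' the current RNG stream, so the step is deterministic given the stream
#' state.
#'
#' @param x_n current position (numeric vector).
#' @param x_best,x_worst best and worst positions in the population.
#' @param peers 4-row matrix of randomly selected peer positions.
#' @param m,M current and maximum iteration.
#' @param beta_min,beta_max schedule bounds of [gbo_beta()].
#' @return list with `position` (the blended new position), and the
#'   intermediates `X1`, `X2`, `X3`, `rho1` (used by the escape operator).
#' @export
gbo_step <- function(x_n, x_best, x_worst, peers, m, M,
                     beta_min = 0.2, beta_max = 1.2) {
  beta <- gbo_beta(m, M, beta_min, beta_max)
  alpha <- gbo_alpha(beta)
  rho1 <- 2 * stats::runif(1) * alpha - alpha
  rho2 <- 2 * stats::runif(1) * alpha - alpha
  eps <- stats::runif(1, 0, 0.1)
  xr1 <- peers[1, ]; xr2 <- peers[2, ]
  delta <- 2 * stats::runif(1) * abs(colMeans(peers) - x_n)
  step <- ((x_best - xr1) + delta) / 2
  dx <- stats::runif(length(x_n)) * abs(step)
  denom <- x_worst - x_best + eps
  gsr <- stats::runif(1) * rho1 * (2 * dx * x_n) / denom
  dm <- stats::runif(1) * rho2 * (x_best - x_n)
  X1 <- x_n - gsr + dm
  z <- x_n - stats::runif(1) * (2 * dx * x_n) / denom
  y <- (x_n + z) / 2
  yp <- y + dx
  yq <- y - dx
  X2 <- x_best -
    stats::runif(1) * rho1 * (2 * dx * x_n) / (yp - yq + eps) +
    stats::runif(1) * rho2 * (xr1 - xr2)
  X3 <- x_n - rho1 * (X2 - X1)
  ra <- stats::runif(1); rb <- stats::runif(1)
  pos <- ra * (rb * X1 + (1 - rb) * X2) + (1 - ra) * X3
  list(position = pos, X1 = X1, X2 = X2, X3 = X3, rho1 = rho1)
}

#' Local escape operator
#'
#' Probabilistic jump mixing the best position, a blended population/random
#' position and the X1/X2 intermediates, used to leave local optima. The
#' caller gates the invocation with probability `pr`; this function applies
#' one escape unconditionally.
#'
#' @param candidate the position produced by [gbo_step()].
#' @param x_best best position.
#' @param X1,X2 intermediates from [gbo_step()].
#' @param peers matrix of peer positions (rows; at least 2).
#' @param rho1 the rho1 draw from the step.
#' @param lower,upper bounds (vectors or scalars).
#' @return the escaped position, clamped to bounds.
#' @export
leo_escape <- function(candidate, x_best, X1, X2, peers, rho1,
                       lower, upper) {
  d <- length(candidate)
  f1 <- stats::runif(1, -1, 1)
  f2 <- stats::rnorm(1)
  mu1 <- stats::runif(1)
  L1 <- if (mu1 < 0.5) 1 else 0
  u1 <- L1 * 2 * stats::runif(1) + (1 - L1)
  u2 <- L1 * stats::runif(1) + (1 - L1)
  u3 <- L1 * stats::runif(1) + (1 - L1)
  mu2 <- stats::runif(1)
  L2 <- if (mu2 < 0.5) 1 else 0
  xp <- peers[sample.int(nrow(peers), 1), ]
  xrand <- lower + stats::runif(d) * (upper - lower)
  xk <- L2 * xp + (1 - L2) * xrand
  xr1 <- peers[1, ]; xr2 <- peers[min(2, nrow(peers)), ]
  tail_term <- f2 * rho1 *
    (u3 * (X2 - X1) + u2 * (xr1 - xr2)) / 2
  head <- f1 * (u1 * x_best - u2 * xk)
  pos <- if (stats::runif(1) < 0.5) candidate + head + tail_term
         else x_best + head + tail_term
  clamp(pos, lower, upper)
}

# Swarm state -----------------------------------------------------------------

#' Control parameters for the UD-GSRBEHO optimizer
#'
#' @param n_clans number of elephant clans.
#' @param clan_size elephants per clan.
#' @param iterations iteration cap (R_max).
#' @param omega clan-updating influence of the matriarch.
#' @param delta clan-center influence on the matriarch move.
#' @param pr local-escape-operator gate probability.
#' @param beta_min,beta_max GSR schedule bounds.
#' @param threshold mask binarization threshold for feature selection.
#' @param seed RNG seed.
#' @return an object of class `gsrbeho_control`.
#' @export
gsrbeho_control <- function(n_clans = 5L, clan_size = 10L,
                            iterations = 100L, omega = 0.5, delta = 0.1,
                            pr = 0.5, beta_min = 0.2, beta_max = 1.2,
                            threshold = 0.5, seed = 1L) {
  structure(list(n_clans = as.integer(n_clans),
                 clan_size = as.integer(clan_size),
                 iterations = as.integer(iterations),
                 omega = omega, delta = delta, pr = pr,
                 beta_min = beta_min, beta_max = beta_max,
                 threshold = threshold, seed = as.integer(seed)),
            class = "gsrbeho_control")
}

#' Initialize a swarm of elephant clans
#'
#' Positions are drawn uniformly within the bounds; fitness is evaluated with
#' the supplied function and the elitist best-so-far records are set.
#'
#' @param fn fitness function (vector position -> scalar, larger is better).
#' @param dim position dimension.
#' @param lower,upper bounds.
#' @param control a [gsrbeho_control()].
#' @return an object of class `swarm_state`.
#' @export
swarm_init <- function(fn, dim, lower, upper, control = gsrbeho_control()) {
  N <- control$n_clans * control$clan_size
  lower <- rep_len(lower, dim); upper <- rep_len(upper, dim)
  pos <- matrix(stats::runif(N * dim), N, dim)
  pos <- sweep(sweep(pos, 2, upper - lower, "*"), 2, lower, "+")
  clan <- rep(seq_len(control$n_clans), each = control$clan_size)
  fit <- apply(pos, 1, fn)
  best_i <- which.max(fit)
  clan_best <- lapply(seq_len(control$n_clans), function(cl) {
    i <- which(clan == cl)[which.max(fit[clan == cl])]
    list(position = pos[i, ], fitness = fit[i])
  })
  structure(list(positions = pos, clan = clan, fitness = fit,
                 lower = lower, upper = upper, control = control,
                 clan_best = clan_best,
                 best_position = pos[best_i, ],
                 best_fitness = fit[best_i],
                 iteration = 0L),
            class = "swarm_state")
}

# refresh fitness, clan-best and global-best records (elitist: never worsen)
swarm_bookkeep <- function(state, fn) {
  state$fitness <- apply(state$positions, 1, fn)
  for (cl in seq_len(state$control$n_clans)) {
    idx <- which(state$clan == cl)
    wi <- idx[which.max(state$fitness[idx])]
    if (state$fitness[wi] > state$clan_best[[cl]]$fitness) {
      state$clan_best[[cl]] <- list(position = state$positions[wi, ],
                                    fitness = state$fitness[wi])
    } else {
      # elitism: reinsert the recorded clan best over the clan's worst
      lo <- idx[which.min(state$fitness[idx])]
      state$positions[lo, ] <- state$clan_best[[cl]]$position
      state$fitness[lo] <- state$clan_best[[cl]]$fitness
    }
    if (state$clan_best[[cl]]$fitness > state$best_fitness) {
      state$best_fitness <- state$clan_best[[cl]]$fitness
      state$best_position <- state$clan_best[[cl]]$position
    }
  }
  state
}

#' EHO clan-updating operator
#'
#' Every non-matriarch elephant moves toward its clan's matriarch (the
#' fittest member) by `omega * (matriarch - x) * gamma` with
#' `gamma ~ U(0,1)`; the matriarch itself moves to `delta * clan_center`.
#' Positions are clamped to bounds and the elitist records refreshed.
#'
#' @param state a `swarm_state`.
#' @param fn fitness function (larger is better).
#' @return the updated `swarm_state`.
#' @export
eho_clan_update <- function(state, fn) {
  ctl <- state$control
  for (cl in seq_len(ctl$n_clans)) {
    idx <- which(state$clan == cl)
    mi <- idx[which.max(state$fitness[idx])]
    mat <- state$positions[mi, ]
    center <- colMeans(state$positions[idx, , drop = FALSE])
    for (i in idx) {
      if (i == mi) next
      gamma <- stats::runif(1)
      state$positions[i, ] <- state$positions[i, ] +
        ctl$omega * (mat - state$positions[i, ]) * gamma
    }
    state$positions[mi, ] <- ctl$delta * center
    for (i in idx)
      state$positions[i, ] <- clamp(state$positions[i, ],
                                    state$lower, state$upper)
  }
  swarm_bookkeep(state, fn)
}

#' EHO clan-separating operator
#'
#' Each clan's worst elephant is replaced by
#' `lower + (upper - lower + 1) * rand`, clamped to the bounds.
#'
#' @param state a `swarm_state`.
#' @param fn fitness function.
#' @return the updated `swarm_state`.
#' @export
eho_clan_separate <- function(state, fn) {
  for (cl in seq_len(state$control$n_clans)) {
    idx <- which(state$clan == cl)
    wi <- idx[which.min(state$fitness[idx])]
    d <- ncol(state$positions)
    raw <- state$lower +
      (state$upper - state$lower + 1) * stats::runif(d)
    state$positions[wi, ] <- clamp(raw, state$lower, state$upper)
  }
  swarm_bookkeep(state, fn)
}

#' Run the UD-GSRBEHO optimizer
#'
#' Per iteration: EHO clan update and separation, then a [gbo_step()] for
#' every elephant (peers drawn without replacement from the population) with
#' a [leo_escape()] applied with probability `pr`. The best-so-far fitness is
#' monotone non-decreasing by the elitist bookkeeping.
#'
#' @param fn objective function (vector -> scalar).
#' @param dim dimension.
#' @param lower,upper bounds.
#' @param control a [gsrbeho_control()].
#' @param maximize if `FALSE` (default) `fn` is minimized.
#' @return list with `par` (best position), `value` (best objective on the
#'   original scale), `trace` (best objective per iteration), `state`.
#' @export
gsrbeho_optimize <- function(fn, dim, lower = 0, upper = 1,
                             control = gsrbeho_control(),
                             maximize = FALSE) {
  sgn <- if (maximize) 1 else -1
  f <- function(x) sgn * fn(x)
  with_seed(control$seed, {
    state <- swarm_init(f, dim, lower, upper, control)
    initial_value <- sgn * state$best_fitness
    M <- control$iterations
    trace <- numeric(M)
    N <- nrow(state$positions)
    for (m in seq_len(M)) {
      state <- eho_clan_update(state, f)
      if (control$clan_size >= 2) state <- eho_clan_separate(state, f)
      wi <- which.min(state$fitness)
      for (i in seq_len(N)) {
        others <- setdiff(seq_len(N), i)
        peers <- state$positions[sample(others, min(4, length(others))), ,
                                 drop = FALSE]
        st <- gbo_step(state$positions[i, ], state$best_position,
                       state$positions[wi, ], peers, m, M,
                       control$beta_min, control$beta_max)
        pos <- st$position
        if (stats::runif(1) < control$pr) {
          pos <- leo_escape(pos, state$best_position, st$X1, st$X2,
                            peers, st$rho1, state$lower, state$upper)
        }
        state$positions[i, ] <- clamp(pos, state$lower, state$upper)
      }
      state <- swarm_bookkeep(state, f)
      state$iteration <- m
      trace[m] <- sgn * state$best_fitness
    }
    list(par = state$best_position, value = sgn * state$best_fitness,
         initial = initial_value, trace = trace, state = state)
  })
}

#' Wrapper feature selection with Rand-index fitness
#'
#' Runs [gsrbeho_optimize()] over continuous positions in `[0,1]^d` (one
#' coordinate per candidate feature); a position is decoded into a feature
#' mask by thresholding at `control$threshold` and scored with
#' [rand_index_fitness()]. Returns the globally best mask; reproducible per
#' seed.
#'
#' @param table [feature_table()] or numeric matrix (complete).
#' @param labels integer class labels.
#' @param candidates integer indices of candidate features (non-empty).
#' @param control a [gsrbeho_control()].
#' @return object of class `feature_selection`: `selected` (indices into the
#'   original features, in selection order), `mask`, `fitness`, `trace`,
#'   `candidates`.
#' @export
select_features <- function(table, labels, candidates,
                            control = gsrbeho_control()) {
  if (length(candidates) == 0) stop_arg("candidates must be non-empty")
  X <- masked_matrix(table)[, candidates, drop = FALSE]
  d <- ncol(X)
  km_seed <- derive_seed(control$seed, 7L)
  fn <- function(pos) {
    rand_index_fitness(pos > control$threshold, X, labels, seed = km_seed)
  }
  res <- gsrbeho_optimize(fn, d, 0, 1, control, maximize = TRUE)
  mask <- res$par > control$threshold
  if (!any(mask)) mask[which.max(res$par)] <- TRUE
  structure(list(selected = candidates[mask], mask = mask,
                 fitness = res$value, trace = res$trace,
                 candidates = candidates,
                 names = colnames(X)[mask]),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("<feature_selection> %d/%d features, fitness %.4f\n",
              length(x$selected), length(x$candidates), x$fitness))
  if (!is.null(x$names)) cat("  ", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}
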