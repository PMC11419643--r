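zero_params <- function(input = 1, classes = 2, hidden = 4) {
  p <- bilstm_init(input, classes, hidden_size = hidden, seed = 1)
  for (d in c("fwd", "bwd"))
    for (nm in names(p[[d]])) p[[d]][[nm]][] <- 0
  p$V[] <- 0; p$b[] <- 0
  p
}

test_that("the cell step matches hand-unrolled arithmetic", {
  # all-zero weights: sigma(0) = 0.5, tanh(0) = 0
  pz <- zero_params()
  st <- lstm_cell_step(0.7, rep(0, 4), rep(0, 4), pz$fwd)
  expect_equal(unname(st$gates$i[1, ]), rep(0.5, 4))
  expect_equal(unname(st$gates$f[1, ]), rep(0.5, 4))
  expect_equal(unname(st$gates$o[1, ]), rep(0.5, 4))
  expect_equal(unname(st$h[1, ]), rep(0, 4))
  expect_equal(unname(st$c[1, ]), rep(0, 4))

  # 1-unit cell with hand-picked weights
  w <- list(Wi = matrix(c(0.1, 0.2), 1), Wf = matrix(c(-0.3, 0.4), 1),
            Wo = matrix(c(0.5, -0.6), 1), Wc = matrix(c(0.7, 0.8), 1),
            bi = 0.01, bf = 0.02, bo = 0.03, bc = 0.04)
  x <- 0.9; h0 <- 0.2; c0 <- -0.1
  sig <- function(z) 1 / (1 + exp(-z))
  i <- sig(0.1 * h0 + 0.2 * x + 0.01)
  f <- sig(-0.3 * h0 + 0.4 * x + 0.02)
  o <- sig(0.5 * h0 - 0.6 * x + 0.03)
  g <- tanh(0.7 * h0 + 0.8 * x + 0.04)
  ct <- f * c0 + i * g
  ht <- o * tanh(ct)
  st2 <- lstm_cell_step(x, h0, c0, w)
  expect_equal(st2$h[1, 1], ht, tolerance = 1e-12)
  expect_equal(st2$c[1, 1], ct, tolerance = 1e-12)

  expect_error(lstm_cell_step(NaN, h0, c0, w), "non-finite")
})

test_that("gates stay in (0,1) and hidden states are bounded by 1", {
  p <- bilstm_init(1, 2, hidden_size = 8, seed = 3)
  set.seed(4)
  h <- matrix(rnorm(5 * 8), 5); cc <- matrix(rnorm(5 * 8), 5)
  st <- lstm_cell_step(matrix(rnorm(5), 5, 1), h, cc, p$fwd)
  for (gt in st$gates[c("i", "f", "o")])
    expect_true(all(gt > 0 & gt < 1))
  expect_true(all(abs(st$h) <= 1))
})

test_that("forward pass is a proper softmax and honours direction swap", {
  p <- bilstm_init(1, 3, hidden_size = 6, seed = 5)
  set.seed(6)
  X <- matrix(rnorm(40), 10, 4)
  probs <- bilstm_forward(X, p)
  expect_equal(rowSums(probs), rep(1, 10), tolerance = 1e-12)

  # zero weights give uniform probabilities
  expect_equal(unname(bilstm_forward(X, zero_params(1, 3, 6))),
               matrix(1 / 3, 10, 3), tolerance = 1e-12)

  # reversing sequences equals exchanging the direction parameters
  H <- p$hidden_size
  p_swap <- p
  p_swap$fwd <- p$bwd; p_swap$bwd <- p$fwd
  p_swap$V <- p$V[, c(H + seq_len(H), seq_len(H)), drop = FALSE]
  expect_equal(bilstm_forward(X[, 4:1], p_swap), bilstm_forward(X, p),
               tolerance = 1e-12)
})

test_that("the three losses match hand values and limits", {
  probs <- rbind(c(1, 0), c(0, 1))
  expect_equal(loss_eval(probs, c(1, 2), "square"), 0)
  expect_equal(loss_eval(probs, c(1, 2), "abs"), 0)
  expect_equal(loss_eval(probs, c(1, 2), "huber"), 0)

  # one residual of 0.5 in each cell: huber (delta 1) is 0.5 * 0.25
  probs2 <- rbind(c(0.5, 0.5))
  expect_equal(loss_eval(probs2, 1, "huber", delta = 1), 0.125)
  expect_equal(loss_eval(probs2, 1, "square"), 0.25)
  expect_equal(loss_eval(probs2, 1, "abs"), 0.5)

  # huber -> square/2-scale for large delta; -> abs regime beyond delta
  set.seed(7)
  r <- matrix(runif(10, 0, 0.4), 5, 2)
  pr <- r / rowSums(r)
  tg <- sample(1:2, 5, TRUE)
  expect_equal(loss_eval(pr, tg, "huber", delta = 100),
               loss_eval(pr, tg, "square") / 2, tolerance = 1e-12)
  expect_error(loss_eval(pr, tg, "logcosh"), "arg")
})

test_that("BPTT gradients match central finite differences", {
  set.seed(42)
  p <- bilstm_init(1, 2, hidden_size = 1, seed = 5)
  X <- matrix(rnorm(6), 3, 2)
  y <- c(1, 2, 1)
  gr <- bilstm_gradients(X, y, p, "square", 1)
  eps <- 1e-6
  check <- function(get, set, g_an) {
    p1 <- set(p, get(p) + eps); p2 <- set(p, get(p) - eps)
    g_num <- (loss_eval(bilstm_forward(X, p1), y, "square") -
                loss_eval(bilstm_forward(X, p2), y, "square")) / (2 * eps)
    abs(g_num - g_an) / max(abs(g_num), abs(g_an), 1e-8)
  }
  worst <- 0
  for (d in c("fwd", "bwd")) for (nm in names(p[[d]])) {
    W <- p[[d]][[nm]]
    for (j in seq_along(W)) {
      worst <- max(worst, check(
        function(q) q[[d]][[nm]][j],
        function(q, v) { q[[d]][[nm]][j] <- v; q },
        gr[[d]][[nm]][j]))
    }
  }
  for (j in seq_along(p$V))
    worst <- max(worst, check(function(q) q$V[j],
                              function(q, v) { q$V[j] <- v; q }, gr$V[j]))
  expect_lt(worst, 1e-4)
})

test_that("branch selection adopts the smallest loss when unperturbed", {
  set.seed(8)
  p <- bilstm_init(1, 2, hidden_size = 2, seed = 9)
  X <- matrix(rnorm(12), 6, 2)
  y <- rep(1:2, 3)
  cfg <- train_config(epochs = 1, batch_size = 6, perturbation_scale = 0,
                      seed = 1)
  res <- adaptive_train_epoch(X, y, p, cfg, shuffle = FALSE)
  # recompute the three branch losses independently
  losses <- vapply(c("square", "abs", "huber"), function(kind) {
    gr <- bilstm_gradients(X, y, p, kind, cfg$huber_delta)
    cand <- strokerisk:::apply_gradients(p, gr, cfg$learning_rate)
    loss_eval(bilstm_forward(X, cand), y, kind, cfg$huber_delta)
  }, 0)
  expect_identical(res$trace$branch, names(which.min(losses)))
  expect_equal(res$trace$loss, unname(min(losses)))
})

test_that("training reduces the loss on separable data across seeds", {
  drops <- 0
  for (s in 1:3) {
    set.seed(s)
    n <- 120
    y <- rep(1:2, each = n / 2)
    X <- matrix(rnorm(n * 3), n, 3) + 2.5 * (y == 2)
    p <- bilstm_init(1, 2, hidden_size = 8, seed = s)
    tr <- adaptive_train(X, y, p, train_config(epochs = 8, seed = s))
    first <- tr$trace$mean_loss[1]
    last <- utils::tail(tr$trace$mean_loss, 1)
    if (last < first) drops <- drops + 1
  }
  expect_gte(drops, 3)
})

test_that("training is capacity-sufficient on separable sequences", {
  set.seed(10)
  n <- 200
  y <- rep(1:2, each = n / 2)
  X <- matrix(rnorm(n * 4), n, 4) + 2.5 * (y == 2)
  p <- bilstm_init(1, 2, hidden_size = 16, seed = 2)
  tr <- adaptive_train(X, y, p, train_config(epochs = 25, seed = 3))
  acc <- mean(bilstm_predict(tr$params, X)$codes == y)
  expect_gte(acc, 0.95)
})

test_that("prediction is an argmax with deterministic ties, batch-stable", {
  p <- bilstm_init(1, 3, hidden_size = 4, seed = 11)
  probs <- rbind(c(0.1, 0.7, 0.2), c(0.4, 0.4, 0.2))
  idx <- max.col(probs, ties.method = "first")
  expect_identical(idx, c(2L, 1L))

  set.seed(12)
  X <- matrix(rnorm(30), 10, 3)
  codes <- bilstm_predict(p, X)$codes
  perm <- sample(10)
  expect_identical(bilstm_predict(p, X[perm, ])$codes, codes[perm])
})

test_that("seeded training is exactly reproducible", {
  set.seed(13)
  X <- matrix(rnorm(60), 20, 3)
  y <- rep(1:2, 10)
  p <- bilstm_init(1, 2, hidden_size = 4, seed = 7)
  t1 <- adaptive_train(X, y, p, train_config(epochs = 3, seed = 5))
  t2 <- adaptive_train(X, y, p, train_config(epochs = 3, seed = 5))
  expect_identical(t1$params, t2$params)
  expect_identical(t1$trace, t2$trace)
})

test_that("feature importance ranks by input-to-gate weight magnitude", {
  p <- bilstm_init(3, 2, hidden_size = 4, seed = 14)
  # zero out the columns of feature 2
  H <- p$hidden_size
  for (d in c("fwd", "bwd"))
    for (nm in c("Wi", "Wf", "Wo", "Wc"))
      p[[d]][[nm]][, H + 2] <- 0
  imp <- feature_importance(p, c("a", "b", "c"))
  expect_identical(imp$feature[3], "b")
  expect_equal(imp$importance[3], 0)

  # independent column-mean scan
  acc <- numeric(3)
  for (d in c("fwd", "bwd"))
    for (nm in c("Wi", "Wf", "Wo", "Wc"))
      acc <- acc + colMeans(abs(p[[d]][[nm]][, H + 1:3]))
  acc <- acc / 8
  expect_equal(sort(imp$importance, decreasing = TRUE), sort(acc,
                                                            decreasing = TRUE))

  # scaling all weights leaves the ranking unchanged
  p2 <- p
  for (d in c("fwd", "bwd"))
    for (nm in c("Wi", "Wf", "Wo", "Wc"))
      p2[[d]][[nm]] <- 2 * p2[[d]][[nm]]
  expect_identical(feature_importance(p2, c("a", "b", "c"))$feature,
                   imp$feature)
})

test_that("parameters survive a JSON round trip at full double precision", {
  p <- bilstm_init(2, 3, hidden_size = 5, seed = 15)
  f <- withr::local_tempfile(fileext = ".json")
  save_bilstm(p, f)
  q <- load_bilstm(f)
  expect_equal(q$fwd, p$fwd)
  expect_equal(q$bwd, p$bwd)
  expect_equal(q$V, p$V)
  expect_equal(q$b, p$b)
  set.seed(16)
  X <- array(rnorm(40), c(5, 4, 2))   # 2 inputs per step
  expect_equal(bilstm_forward(X, q), bilstm_forward(X, p),
               tolerance = 1e-12)
})
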