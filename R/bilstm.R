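# Bidirectional LSTM from first principles with adaptive-weight training ----
#
# Records enter as short sequences (one selected feature per time step, with
# the defuzzified crisp risk value optionally appended); the readout acts on
# the concatenated final hidden states of the forward and backward passes.
# Training spawns three mutation branches per batch (square / absolute /
# Huber loss), each perturbed and updated by one backpropagation-through-time
# step, and adopts the branch with the smallest batch loss.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Training configuration for the adaptive-weight Bi-LSTM
#'
#' @param epochs training epochs.
#' @param learning_rate gradient-descent step size.
#' @param hidden_size hidden units per direction.
#' @param batch_size minibatch size.
#' @param perturbation_scale scale of the Gaussian weight mutation (applied
#'   per input column, proportional to that feature's mean absolute value).
#' @param huber_delta Huber loss threshold.
#' @param seed RNG seed.
#' @return an object of class `train_config` (three mutation branches bound
#'   to the square, absolute and Huber losses).
#' @export
train_config <- function(epochs = 30L, learning_rate = 0.5,
                         hidden_size = 16L, batch_size = 64L,
                         perturbation_scale = 0.01, huber_delta = 1,
                         seed = 1L) {
  structure(list(epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 hidden_size = as.integer(hidden_size),
                 batch_size = as.integer(batch_size),
                 perturbation_scale = perturbation_scale,
                 huber_delta = huber_delta,
                 losses = c("square", "abs", "huber"),
                 n_mutations = 3L,
                 seed = as.integer(seed)),
            class = "train_config")
}

# one direction's gate weights: each hidden x (hidden + input)
init_direction <- function(hidden, input) {
  s <- 1 / sqrt(hidden + input)
  mk <- function() matrix(stats::runif(hidden * (hidden + input), -s, s),
                          hidden, hidden + input)
  list(Wi = mk(), Wf = mk(), Wo = mk(), Wc = mk(),
       bi = rep(0, hidden), bf = rep(1, hidden), bo = rep(0, hidden),
       bc = rep(0, hidden))
}

#' Initialize Bi-LSTM parameters
#'
#' Gate weights for both directions plus a linear readout from the
#' concatenated final hidden states. Initialization is deterministic per
#' seed (uniform, fan-in scaled; forget-gate bias 1).
#'
#' @param input_size input dimension per time step.
#' @param n_classes number of output classes.
#' @param hidden_size hidden units per direction.
#' @param classes optional vector of class labels (defaults to
#'   `1:n_classes`).
#' @param seed RNG seed.
#' @return an object of class `bilstm_params`.
#' @export
bilstm_init <- function(input_size, n_classes, hidden_size = 16L,
                        classes = NULL, seed = 1L) {
  with_seed(seed, {
    H <- as.integer(hidden_size)
    s <- 1 / sqrt(2 * H)
    structure(list(fwd = init_direction(H, input_size),
                   bwd = init_direction(H, input_size),
                   V = matrix(stats::runif(n_classes * 2 * H, -s, s),
                              n_classes, 2 * H),
                   b = rep(0, n_classes),
                   hidden_size = H,
                   input_size = as.integer(input_size),
                   n_classes = as.integer(n_classes),
                   classes = classes %||% seq_len(n_classes),
                   seed = as.integer(seed)),
              class = "bilstm_params")
  })
}

#' @export
print.bilstm_params <- function(x, ...) {
  cat(sprintf("<bilstm_params> input %d, hidden %d/direction, %d classes\n",
              x$input_size, x$hidden_size, x$n_classes))
  invisible(x)
}

#' One LSTM cell step
#'
#' Gate equations with sigmoid input/forget/output gates and a tanh cell
#' candidate: `i,f,o = sigma(W [h_prev, x_t] + b)`,
#' `c_t = f * c_prev + i * tanh(W_c [h_prev, x_t] + b_c)`,
#' `h_t = o * tanh(c_t)`.
#'
#' @param x_t input at time t: vector of length `input`, or a batch matrix
#'   (records x input).
#' @param h_prev,c_prev previous hidden and cell state (vector or batch
#'   matrix, records x hidden).
#' @param wts one direction's weights (`Wi`, `Wf`, `Wo`, `Wc`, `bi`, `bf`,
#'   `bo`, `bc`), e.g. `params$fwd`.
#' @return list with `h`, `c` and the `gates` record (`i`, `f`, `o`, `g`).
#' @export
lstm_cell_step <- function(x_t, h_prev, c_prev, wts) {
  if (is.null(dim(x_t))) x_t <- matrix(x_t, 1)
  if (is.null(dim(h_prev))) h_prev <- matrix(h_prev, 1)
  if (is.null(dim(c_prev))) c_prev <- matrix(c_prev, 1)
  if (!all(is.finite(x_t)))
    stop_arg("non-finite input to LSTM cell")
  n <- nrow(x_t); H <- nrow(wts$Wi)
  Z <- cbind(h_prev, x_t)
  brow <- function(b) matrix(b, n, H, byrow = TRUE)
  i <- sigmoid(Z %*% t(wts$Wi) + brow(wts$bi))
  f <- sigmoid(Z %*% t(wts$Wf) + brow(wts$bf))
  o <- sigmoid(Z %*% t(wts$Wo) + brow(wts$bo))
  g <- tanh(Z %*% t(wts$Wc) + brow(wts$bc))
  c_t <- f * c_prev + i * g
  h_t <- o * tanh(c_t)
  list(h = h_t, c = c_t, gates = list(i = i, f = f, o = o, g = g))
}

# run one direction over the (already direction-ordered) time axis,
# keeping the caches BPTT needs
dir_forward <- function(Xarr, wts) {
  n <- dim(Xarr)[1]; T_ <- dim(Xarr)[2]
  H <- nrow(wts$Wi)
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  caches <- vector("list", T_)
  for (t in seq_len(T_)) {
    x_t <- matrix(Xarr[, t, ], n)
    st <- lstm_cell_step(x_t, h, cc, wts)
    caches[[t]] <- list(x = x_t, h_prev = h, c_prev = cc,
                        i = st$gates$i, f = st$gates$f, o = st$gates$o,
                        g = st$gates$g, c = st$c)
    h <- st$h; cc <- st$c
  }
  list(h_final = h, caches = caches)
}

# BPTT for one direction given the gradient at the final hidden state
dir_backward <- function(caches, wts, dh_final) {
  T_ <- length(caches)
  H <- nrow(wts$Wi)
  grads <- lapply(wts, function(w) w * 0)
  dh <- dh_final
  dc <- dh * 0
  for (t in rev(seq_len(T_))) {
    ch <- caches[[t]]
    tc <- tanh(ch$c)
    do <- dh * tc
    dc <- dc + dh * ch$o * (1 - tc^2)
    di <- dc * ch$g
    dg <- dc * ch$i
    df <- dc * ch$c_prev
    dc <- dc * ch$f
    d_ib <- di * ch$i * (1 - ch$i)
    d_fb <- df * ch$f * (1 - ch$f)
    d_ob <- do * ch$o * (1 - ch$o)
    d_gb <- dg * (1 - ch$g^2)
    Z <- cbind(ch$h_prev, ch$x)
    grads$Wi <- grads$Wi + t(d_ib) %*% Z
    grads$Wf <- grads$Wf + t(d_fb) %*% Z
    grads$Wo <- grads$Wo + t(d_ob) %*% Z
    grads$Wc <- grads$Wc + t(d_gb) %*% Z
    grads$bi <- grads$bi + colSums(d_ib)
    grads$bf <- grads$bf + colSums(d_fb)
    grads$bo <- grads$bo + colSums(d_ob)
    grads$bc <- grads$bc + colSums(d_gb)
    dh <- d_ib %*% wts$Wi[, seq_len(H), drop = FALSE] +
      d_fb %*% wts$Wf[, seq_len(H), drop = FALSE] +
      d_ob %*% wts$Wo[, seq_len(H), drop = FALSE] +
      d_gb %*% wts$Wc[, seq_len(H), drop = FALSE]
  }
  grads
}

# coerce a records x T matrix (or array) to n x T x p
as_seq_array <- function(X) {
  if (length(dim(X)) == 3) return(X)
  X <- as.matrix(X)
  array(X, dim = c(nrow(X), ncol(X), 1))
}

#' Bi-LSTM forward pass
#'
#' Runs the forward direction left to right and the backward direction right
#' to left, concatenates the two final hidden states, applies the linear
#' readout and a row-wise softmax.
#'
#' @param X input sequences: records x T matrix (scalar steps) or an
#'   n x T x p array.
#' @param params a [bilstm_params()].
#' @param return_cache keep the per-step caches (used by training).
#' @return matrix of class probabilities (rows sum to one); with
#'   `return_cache = TRUE`, a list `probs`, `hcat`, `fwd`, `bwd`.
#' @export
bilstm_forward <- function(X, params, return_cache = FALSE) {
  Xarr <- as_seq_array(X)
  T_ <- dim(Xarr)[2]
  fw <- dir_forward(Xarr, params$fwd)
  bw <- dir_forward(Xarr[, rev(seq_len(T_)), , drop = FALSE], params$bwd)
  hcat <- cbind(fw$h_final, bw$h_final)
  logits <- hcat %*% t(params$V) +
    matrix(params$b, nrow(hcat), params$n_classes, byrow = TRUE)
  logits <- logits - apply(logits, 1, max)
  e <- exp(logits)
  probs <- e / rowSums(e)
  if (!return_cache) return(probs)
  list(probs = probs, hcat = hcat, fwd = fw, bwd = bw)
}

#' Loss between class probabilities and one-hot targets
#'
#' Mean square / absolute / Huber loss over all probability entries against
#' the one-hot encoding of the targets.
#'
#' @param probs probability matrix (records x classes).
#' @param targets integer class indices in `1..ncol(probs)`.
#' @param kind `"square"`, `"abs"` or `"huber"`.
#' @param delta Huber threshold.
#' @return nonnegative scalar loss.
#' @export
loss_eval <- function(probs, targets, kind = c("square", "abs", "huber"),
                      delta = 1) {
  kind <- match.arg(kind)
  Y <- matrix(0, nrow(probs), ncol(probs))
  Y[cbind(seq_len(nrow(probs)), targets)] <- 1
  r <- probs - Y
  switch(kind,
         square = mean(r^2),
         abs = mean(abs(r)),
         huber = mean(ifelse(abs(r) <= delta, 0.5 * r^2,
                             delta * (abs(r) - 0.5 * delta))))
}

# dL/dprobs for the three losses (mean over all entries)
loss_grad_probs <- function(probs, targets, kind, delta) {
  Y <- matrix(0, nrow(probs), ncol(probs))
  Y[cbind(seq_len(nrow(probs)), targets)] <- 1
  r <- probs - Y
  nK <- length(r)
  switch(kind,
         square = 2 * r / nK,
         abs = sign(r) / nK,
         huber = clamp(r, -delta, delta) / nK)
}

# full gradient of the chosen loss w.r.t. every parameter
bilstm_gradients <- function(X, targets, params, kind = "square",
                             delta = 1) {
  cache <- bilstm_forward(X, params, return_cache = TRUE)
  p <- cache$probs
  gp <- loss_grad_probs(p, targets, kind, delta)
  # softmax backward: dz = p * (g - rowSums(g * p))
  dz <- p * (gp - rowSums(gp * p))
  dV <- t(dz) %*% cache$hcat
  db <- colSums(dz)
  dhcat <- dz %*% params$V
  H <- params$hidden_size
  gf <- dir_backward(cache$fwd$caches, params$fwd,
                     dhcat[, seq_len(H), drop = FALSE])
  gb <- dir_backward(cache$bwd$caches, params$bwd,
                     dhcat[, H + seq_len(H), drop = FALSE])
  list(fwd = gf, bwd = gb, V = dV, b = db,
       loss = loss_eval(p, targets, kind, delta))
}

apply_gradients <- function(params, grads, lr) {
  for (d in c("fwd", "bwd"))
    for (nm in names(params[[d]]))
      params[[d]][[nm]] <- params[[d]][[nm]] - lr * grads[[d]][[nm]]
  params$V <- params$V - lr * grads$V
  params$b <- params$b - lr * grads$b
  params
}

# Gaussian mutation: input-to-gate columns scaled by that feature's mean
# absolute value, all other parameters by the overall input magnitude
perturb_params <- function(params, scale, feature_scale) {
  if (scale <= 0) return(params)
  H <- params$hidden_size
  p <- params$input_size
  colscale <- c(rep(mean(feature_scale), H), feature_scale)
  for (d in c("fwd", "bwd")) {
    for (nm in c("Wi", "Wf", "Wo", "Wc")) {
      W <- params[[d]][[nm]]
      noise <- matrix(stats::rnorm(length(W)), nrow(W)) *
        matrix(scale * colscale, nrow(W), ncol(W), byrow = TRUE)
      params[[d]][[nm]] <- W + noise
    }
  }
  params
}

#' One adaptive-weight training epoch
#'
#' Per minibatch: snapshot the parameters, spawn three mutation branches
#' (square, absolute, Huber loss), perturb each with Gaussian noise scaled
#' by `perturbation_scale` times the per-feature mean absolute input value,
#' apply one backpropagation-through-time gradient step under the branch's
#' loss, and adopt the branch with the smallest batch loss. Branches with
#' non-finite loss are disqualified; if all three are, training stops with
#' an error.
#'
#' @param X input sequences (records x T matrix or n x T x p array).
#' @param targets integer class indices in `1..n_classes`.
#' @param params a [bilstm_params()].
#' @param cfg a [train_config()].
#' @param shuffle permute records before batching.
#' @return list `params` (updated), `trace` (data frame: batch, winning
#'   branch, loss).
#' @export
adaptive_train_epoch <- function(X, targets, params, cfg = train_config(),
                                 shuffle = TRUE) {
  Xarr <- as_seq_array(X)
  n <- dim(Xarr)[1]
  feature_scale <- pmax(apply(abs(Xarr), 3, mean), 1e-8)
  ord <- if (shuffle) sample.int(n) else seq_len(n)
  starts <- seq(1, n, by = cfg$batch_size)
  trace <- data.frame(batch = integer(0), branch = character(0),
                      loss = numeric(0))
  for (bi in seq_along(starts)) {
    idx <- ord[starts[bi]:min(starts[bi] + cfg$batch_size - 1L, n)]
    Xb <- Xarr[idx, , , drop = FALSE]
    yb <- targets[idx]
    snapshot <- params
    best_loss <- Inf; best_params <- NULL; best_branch <- NA_character_
    for (kind in cfg$losses) {
      cand <- perturb_params(snapshot, cfg$perturbation_scale,
                             feature_scale)
      gr <- bilstm_gradients(Xb, yb, cand, kind, cfg$huber_delta)
      cand <- apply_gradients(cand, gr, cfg$learning_rate)
      l <- loss_eval(bilstm_forward(Xb, cand), yb, kind, cfg$huber_delta)
      if (!is.finite(l)) next
      if (l < best_loss) {
        best_loss <- l; best_params <- cand; best_branch <- kind
      }
    }
    if (is.null(best_params))
      stop_arg("all mutation branches produced non-finite loss")
    params <- best_params
    trace <- rbind(trace, data.frame(batch = bi, branch = best_branch,
                                     loss = best_loss))
  }
  list(params = params, trace = trace)
}

#' Train the adaptive-weight Bi-LSTM
#'
#' Runs [adaptive_train_epoch()] for `cfg$epochs` epochs under a seeded RNG
#' stream; the parameter trajectory is fully determined by the config and
#' seed.
#'
#' @inheritParams adaptive_train_epoch
#' @return list `params`, `trace` (per epoch: mean loss, winning-branch
#'   tallies).
#' @export
adaptive_train <- function(X, targets, params, cfg = train_config()) {
  with_seed(cfg$seed, {
    epoch_trace <- data.frame(epoch = integer(0), mean_loss = numeric(0),
                              square = integer(0), abs = integer(0),
                              huber = integer(0))
    for (e in seq_len(cfg$epochs)) {
      res <- adaptive_train_epoch(X, targets, params, cfg)
      params <- res$params
      tr <- res$trace
      epoch_trace <- rbind(epoch_trace, data.frame(
        epoch = e, mean_loss = mean(tr$loss),
        square = sum(tr$branch == "square"),
        abs = sum(tr$branch == "abs"),
        huber = sum(tr$branch == "huber")))
    }
    list(params = params, trace = epoch_trace)
  })
}

#' Predict classes from a trained Bi-LSTM
#'
#' Argmax over class probabilities with a deterministic lowest-index
#' tie-break.
#'
#' @param params a trained [bilstm_params()].
#' @param X input sequences.
#' @return list `codes` (class labels), `probabilities`.
#' @export
bilstm_predict <- function(params, X) {
  probs <- bilstm_forward(X, params)
  idx <- max.col(probs, ties.method = "first")
  list(codes = params$classes[idx], probabilities = probs)
}

#' Feature importance from input-to-gate weights
#'
#' Ranks input features by the mean absolute input-to-gate weight across
#' both directions and all four gates (meaningful in the vector input mode,
#' where each input column is one feature). Ties break deterministically by
#' name.
#'
#' @param params a [bilstm_params()].
#' @param feature_names names of the `input_size` input columns.
#' @return data frame `feature`, `importance`, sorted decreasing.
#' @export
feature_importance <- function(params, feature_names) {
  p <- params$input_size
  if (length(feature_names) != p)
    stop_arg("need one name per input column (%d)", p)
  H <- params$hidden_size
  acc <- numeric(p)
  for (d in c("fwd", "bwd"))
    for (nm in c("Wi", "Wf", "Wo", "Wc"))
      acc <- acc + colMeans(abs(params[[d]][[nm]][, H + seq_len(p),
                                                  drop = FALSE]))
  acc <- acc / 8
  ord <- order(-acc, feature_names)
  data.frame(feature = feature_names[ord], importance = acc[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}
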