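# ICA feature reduction with tanh contrast and mean-activation filter -------

#' Center and whiten a data matrix
#'
#' Columns are centered and linearly transformed so the sample covariance of
#' the output is the identity (to 1e-6). Whitening is the eigendecomposition
#' of the covariance; directions with eigenvalues below a relative tolerance
#' are dropped (rank reduction, reported via a message), so constant columns
#' and exact collinearities are removed.
#'
#' @param X numeric matrix with at least 2 rows.
#' @param tol relative eigenvalue tolerance for the numerical rank.
#' @return list with `Z` (whitened matrix, n x r), `whitening` (r x d),
#'   `center` (length d), `rank` (r).
#' @export
center_whiten <- function(X, tol = 1e-10) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop_arg("whitening requires at least 2 rows")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  S <- crossprod(Xc) / (nrow(X) - 1)
  eg <- eigen(S, symmetric = TRUE)
  keep <- eg$values > tol * max(eg$values, 0)
  if (!any(keep)) stop_arg("data matrix has numerical rank 0")
  if (sum(keep) < ncol(X))
    message(sprintf("center_whiten: rank reduced from %d to %d",
                    ncol(X), sum(keep)))
  W <- diag(1 / sqrt(eg$values[keep]), sum(keep)) %*%
    t(eg$vectors[, keep, drop = FALSE])
  list(Z = Xc %*% t(W), whitening = W, center = mu, rank = sum(keep))
}

# symmetric orthogonalization: W <- (W W^T)^(-1/2) W
sym_orth <- function(W) {
  eg <- eigen(W %*% t(W), symmetric = TRUE)
  vals <- pmax(eg$values, .Machine$double.eps)
  eg$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(eg$vectors) %*% W
}

#' Fit independent components with the tanh contrast
#'
#' Fixed-point iteration with the tanh nonlinearity and symmetric
#' orthogonalization on the whitened data. Convergence is declared when the
#' largest rowwise update of the unmixing matrix falls below `tol`; on
#' non-convergence a warning is raised and the best iterate returned.
#'
#' @param X numeric data matrix (records x attributes).
#' @param n_components number of components (defaults to, and at most, the
#'   numerical rank of the whitened data).
#' @param seed RNG seed for the random orthogonal start.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the unmixing update.
#' @return an object of class `ica_transform`: `whitening`, `center`,
#'   `unmixing` (c x r, rows orthonormal in whitened space), `converged`,
#'   `component_means` (mean absolute activations on the training data),
#'   `selected` (filter flags at the 0.1 threshold), `seed`.
#' @export
ica_fit <- function(X, n_components = NULL, seed = 1L, max_iter = 200L,
                    tol = 1e-4) {
  cw <- center_whiten(X)
  Z <- cw$Z
  r <- cw$rank
  if (is.null(n_components)) n_components <- r
  if (n_components > r)
    stop_arg("n_components (%d) exceeds numerical rank (%d)",
             n_components, r)
  n <- nrow(Z)
  with_seed(seed, {
    W <- matrix(stats::rnorm(n_components * r), n_components, r)
    W <- sym_orth(W)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      WX <- Z %*% t(W)              # n x c activations
      G <- tanh(WX)
      Gp <- 1 - G^2                 # derivative of tanh
      W_new <- (t(G) %*% Z) / n - diag(colMeans(Gp), n_components) %*% W
      W_new <- sym_orth(W_new)
      # rowwise update magnitude, invariant to sign flips
      delta <- 1 - abs(rowSums(W_new * W))
      W <- W_new
      if (max(delta) < tol) { converged <- TRUE; break }
    }
    if (!converged)
      warning("ica_fit: fixed-point iteration did not converge in ",
              max_iter, " iterations; returning best iterate")
    obj <- structure(list(whitening = cw$whitening, center = cw$center,
                          unmixing = W, converged = converged,
                          n_components = n_components,
                          seed = as.integer(seed)),
                     class = "ica_transform")
    A <- ica_activations(obj, X)
    obj$component_means <- colMeans(abs(A))
    obj$selected <- obj$component_means > 0.1
    obj
  })
}

#' @export
print.ica_transform <- function(x, ...) {
  cat(sprintf("<ica_transform> %d components (converged: %s)\n",
              x$n_components, x$converged))
  cat("  mean |activation|:",
      paste(sprintf("%.3f", x$component_means), collapse = " "), "\n")
  invisible(x)
}

#' Component activations of new data
#'
#' @param transform an `ica_transform`.
#' @param X data matrix on the original attribute scale.
#' @return n x c activation matrix.
#' @export
ica_activations <- function(transform, X) {
  Xc <- sweep(as.matrix(X), 2, transform$center)
  (Xc %*% t(transform$whitening)) %*% t(transform$unmixing)
}

#' Filter components by mean absolute activation
#'
#' Keeps the components whose mean absolute activation exceeds `threshold`
#' (default 0.1). Components are zero-mean by construction, so the raw
#' average would discard everything; the mean absolute activation is the
#' magnitude the filter operates on. If no component passes, the single
#' largest is kept (with a message).
#'
#' @param transform an `ica_transform`.
#' @param Y activation matrix produced by [ica_activations()] (defaults to
#'   recomputing from `X`).
#' @param threshold selection threshold on mean absolute activation.
#' @return the reduced activation matrix, with attribute `selected` (logical
#'   flags per component).
#' @export
select_components <- function(transform, Y, threshold = 0.1) {
  means <- colMeans(abs(Y))
  selected <- means > threshold
  if (!any(selected)) {
    message("select_components: no component above threshold; ",
            "keeping the single largest")
    selected[which.max(means)] <- TRUE
  }
  out <- Y[, selected, drop = FALSE]
  attr(out, "selected") <- selected
  attr(out, "component_means") <- means
  out
}
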