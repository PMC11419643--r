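`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from a global seed
#'
#' Stage seeds are derived deterministically from one global seed by a
#' counter scheme so that no two pipeline stages share an RNG stream.
#' The result always fits in a 32-bit signed integer.
#'
#' @param seed integer global seed.
#' @param stage integer stage counter (>= 0).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  s <- (abs(as.double(seed)) * 1009 + 97 * as.double(stage) + 1) %% 2147483647
  as.integer(s)
}

# set the RNG locally when a seed is supplied; restores the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# squared euclidean distances between rows of X (n x d) and rows of C (k x d)
row_dist2 <- function(X, C) {
  n <- nrow(X); k <- nrow(C)
  XX <- rowSums(X^2)
  CC <- rowSums(C^2)
  D <- outer(XX, CC, "+") - 2 * X %*% t(C)
  pmax(D, 0)
}
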