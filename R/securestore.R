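# MD5-salted EC-ElGamal encryption of predicted risk records ----------------
#
# All arithmetic stays in a prime-field Weierstrass group small enough that
# every modular product is exact in double precision (p < 2^26). The MD5
# digest of the encoded public key concatenated with a random salt is mapped
# to a scalar s_k mod n; the corresponding point s_k * B is added to both
# ciphertext components, so the salted secret participates in the group.

mod_reduce <- function(x, p) ((x %% p) + p) %% p

mod_inv <- function(a, p) {
  a <- mod_reduce(a, p)
  if (a == 0) stop_arg("no inverse of 0")
  # extended euclid on doubles (exact: all values < p < 2^26)
  r0 <- p; r1 <- a; t0 <- 0; t1 <- 1
  while (r1 != 0) {
    q <- r0 %/% r1
    tmp <- r0 - q * r1; r0 <- r1; r1 <- tmp
    tmp <- t0 - q * t1; t0 <- t1; t1 <- tmp
  }
  if (r0 != 1) stop_arg("element not invertible")
  mod_reduce(t0, p)
}

powmod <- function(b, e, p) {
  b <- mod_reduce(b, p); r <- 1
  while (e > 0) {
    if (e %% 2 == 1) r <- (r * b) %% p
    b <- (b * b) %% p
    e <- e %/% 2
  }
  r
}

# square root mod p: direct scan for tiny fields, (p+1)/4 exponent otherwise
mod_sqrt <- function(a, p) {
  a <- mod_reduce(a, p)
  if (p < 10000) {
    for (y in 0:(p - 1)) if ((y * y) %% p == a) return(y)
    return(NA_real_)
  }
  if (p %% 4 != 3)
    stop_arg("modular square root implemented for p = 3 (mod 4) only")
  y <- powmod(a, (p + 1) %/% 4, p)
  if ((y * y) %% p == a) y else NA_real_
}

#' Define a prime-field Weierstrass curve
#'
#' `y^2 = x^3 + a x + b` over `F_p`, with base point `(gx, gy)` and group
#' order `n`. The discriminant condition `4a^3 + 27b^2 != 0 (mod p)`, the
#' on-curve check of the base point and `n * B = identity` are verified at
#' construction. `p` must stay below 2^26 so every modular product is exact
#' in double precision.
#'
#' @param p prime modulus.
#' @param a,b curve coefficients.
#' @param gx,gy base point coordinates.
#' @param n group order.
#' @param name identifier stored with ciphertexts.
#' @return an object of class `ec_curve`.
#' @export
ec_curve <- function(p, a, b, gx, gy, n, name = "custom") {
  if (p >= 2^26) stop_arg("p must be below 2^26")
  disc <- mod_reduce(4 * powmod(a, 3, p) + 27 * (b * b) %% p, p)
  if (disc == 0) stop_arg("singular curve: 4a^3 + 27b^2 = 0 (mod p)")
  curve <- structure(list(p = p, a = a, b = b, base = c(gx, gy), n = n,
                          name = name), class = "ec_curve")
  if (!ec_on_curve(curve$base, curve))
    stop_arg("base point is not on the curve")
  if (!is.null(ec_scalar_mult(n, curve$base, curve)))
    stop_arg("n * base point is not the identity")
  curve
}

#' @rdname ec_curve
#' @details `ec_curve_toy()` is the tiny exhaustively checkable test curve
#'   `y^2 = x^3 + 2x + 2` over `F_17` with base point (5, 1) and order 19;
#'   `ec_curve_default()` is the operational curve `y^2 = x^3 + x` over
#'   `F_16777199` (supersingular, group order p + 1).
#' @export
ec_curve_toy <- function() ec_curve(17, 2, 2, 5, 1, 19, "toy17")

#' @rdname ec_curve
#' @export
ec_curve_default <- function() {
  p <- 16777199  # prime, p = 3 (mod 4)
  ec_curve(p, 1, 0, 2, 2295784, p + 1, "ss24")
}

#' @export
print.ec_curve <- function(x, ...) {
  cat(sprintf("<ec_curve %s> y^2 = x^3 + %dx + %d over F_%d, base (%d, %d), order %d\n",
              x$name, x$a, x$b, x$p, x$base[1], x$base[2], x$n))
  invisible(x)
}

#' Curve membership test
#'
#' @param P numeric `c(x, y)` or `NULL` (the identity).
#' @param curve an [ec_curve()].
#' @return logical.
#' @export
ec_on_curve <- function(P, curve) {
  if (is.null(P)) return(TRUE)
  p <- curve$p
  lhs <- (P[2] * P[2]) %% p
  rhs <- mod_reduce(powmod(P[1], 3, p) + (curve$a * P[1]) %% p + curve$b, p)
  lhs == rhs
}

#' Group law: point addition
#'
#' @param P,Q points (`c(x, y)` or `NULL` for the identity).
#' @param curve an [ec_curve()].
#' @return the sum point.
#' @export
ec_add <- function(P, Q, curve) {
  if (is.null(P)) return(Q)
  if (is.null(Q)) return(P)
  p <- curve$p
  if (P[1] == Q[1]) {
    if (mod_reduce(P[2] + Q[2], p) == 0) return(NULL)  # inverse points
    # doubling
    lam <- ((3 * ((P[1] * P[1]) %% p) + curve$a) %% p *
              mod_inv(2 * P[2], p)) %% p
  } else {
    lam <- (mod_reduce(Q[2] - P[2], p) *
              mod_inv(mod_reduce(Q[1] - P[1], p), p)) %% p
  }
  x3 <- mod_reduce((lam * lam) %% p - P[1] - Q[1], p)
  y3 <- mod_reduce((lam * mod_reduce(P[1] - x3, p)) %% p - P[2], p)
  c(x3, y3)
}

ec_neg <- function(P, curve) {
  if (is.null(P)) return(NULL)
  c(P[1], mod_reduce(-P[2], curve$p))
}

ec_sub <- function(P, Q, curve) ec_add(P, ec_neg(Q, curve), curve)

#' Scalar multiplication by double-and-add
#'
#' `0 * P` is the identity (`NULL`); `1 * P = P`.
#'
#' @param k nonnegative integer scalar.
#' @param P a point on the curve (validated).
#' @param curve an [ec_curve()].
#' @return the product point (or `NULL`).
#' @export
ec_scalar_mult <- function(k, P, curve) {
  if (!ec_on_curve(P, curve)) stop_arg("point is not on the curve")
  if (k < 0) stop_arg("scalar must be nonnegative")
  R <- NULL
  addend <- P
  while (k > 0) {
    if (k %% 2 == 1) R <- ec_add(R, addend, curve)
    addend <- ec_add(addend, addend, curve)
    k <- k %/% 2
  }
  R
}

# MD5 of raw bytes via the standard digest (file-based)
md5_raw <- function(bytes) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(bytes, tf)
  unname(tools::md5sum(tf))
}

# hex digest -> integer mod n (horner over hex digits, exact in doubles)
hex_mod <- function(hex, n) {
  digits <- strtoi(strsplit(hex, "")[[1]], 16L)
  Reduce(function(acc, d) (acc * 16 + d) %% n, digits, init = 0)
}

encode_point_bytes <- function(P) {
  # x || y, 4 bytes each, big-endian
  enc1 <- function(v) as.raw(c(v %/% 16777216, (v %/% 65536) %% 256,
                               (v %/% 256) %% 256, v %% 256))
  c(enc1(P[1]), enc1(P[2]))
}

#' Generate an MD5-salted EC-ElGamal key ring
#'
#' Draws a private key `K` uniform in `[1, n-1]`, the public key
#' `A = K * B`, a fresh random salt, the secret digest
#' `S_k = MD5(encode(A) || salt)` (public key encoded as x||y big-endian),
#' the secret scalar `s_k = int(S_k) mod n` and the secret point
#' `S_kP = s_k * B`. Deterministic per seed.
#'
#' @param curve an [ec_curve()].
#' @param seed RNG seed.
#' @param salt_bytes salt length in bytes.
#' @return an object of class `keyring`.
#' @export
generate_keys <- function(curve, seed = 1L, salt_bytes = 16L) {
  with_seed(seed, {
    K <- sample.int(curve$n - 1L, 1)
    A <- ec_scalar_mult(K, curve$base, curve)
    salt <- as.raw(sample.int(256, salt_bytes, replace = TRUE) - 1L)
    digest <- md5_raw(c(encode_point_bytes(A), salt))
    s_k <- hex_mod(digest, curve$n)
    structure(list(private = K, public = A, salt = salt,
                   secret_digest = digest, secret_scalar = s_k,
                   secret_point = ec_scalar_mult(s_k, curve$base, curve),
                   curve_name = curve$name),
              class = "keyring")
  })
}

#' @export
print.keyring <- function(x, ...) {
  cat(sprintf("<keyring> curve %s, public (%d, %d), salt %d bytes\n",
              x$curve_name, x$public[1], x$public[2], length(x$salt)))
  invisible(x)
}

#' Koblitz message-to-point embedding
#'
#' Maps an integer message `m` to the point with `x = m*kappa + j` for the
#' smallest `j` in `[0, kappa)` making `x^3 + ax + b` a quadratic residue;
#' the inverse recovers `m = floor(x / kappa)` exactly.
#'
#' @param m nonnegative integer with `(m + 1) * kappa <= p`.
#' @param curve an [ec_curve()].
#' @param kappa padding window.
#' @return a curve point.
#' @export
koblitz_encode <- function(m, curve, kappa = 64L) {
  if (m < 0 || (m + 1) * kappa > curve$p)
    stop_arg("message %d too large for the padding window", m)
  p <- curve$p
  for (j in 0:(kappa - 1)) {
    x <- m * kappa + j
    if (x >= p) break
    rhs <- mod_reduce(powmod(x, 3, p) + (curve$a * x) %% p + curve$b, p)
    y <- mod_sqrt(rhs, p)
    if (!is.na(y)) return(c(x, y))
  }
  stop_arg("no curve embedding for message %d within window %d", m, kappa)
}

#' @rdname koblitz_encode
#' @param P an embedded point.
#' @export
koblitz_decode <- function(P, kappa = 64L) {
  if (is.null(P)) stop_arg("cannot decode the identity")
  P[1] %/% kappa
}

# plaintext bytes -> integer blocks (2 bytes each) with a 2-byte length prefix
bytes_to_blocks <- function(bytes) {
  len <- length(bytes)
  if (len > 65535) stop_arg("plaintext too long")
  framed <- c(as.raw(len %/% 256), as.raw(len %% 256), bytes)
  if (length(framed) %% 2 == 1) framed <- c(framed, as.raw(0))
  ints <- as.integer(framed)
  ints[c(TRUE, FALSE)] * 256 + ints[c(FALSE, TRUE)]
}

blocks_to_bytes <- function(blocks) {
  if (any(blocks < 0 | blocks > 65535))
    stop_arg("integrity error: block value out of range")
  bytes <- as.raw(rbind(blocks %/% 256, blocks %% 256))
  len <- as.integer(bytes[1]) * 256 + as.integer(bytes[2])
  if (len > length(bytes) - 2)
    stop_arg("integrity error: invalid length prefix")
  bytes[2 + seq_len(len)]
}

#' Encrypt a record under MD5-salted EC-ElGamal
#'
#' A fresh ephemeral scalar `R` is drawn per record. The ciphertext is
#' `E1 = R*B + S_kP` plus one block point `E2 = M + R*A + S_kP` per 2-byte
#' message block (Koblitz-embedded, with a length prefix for integrity).
#' The plaintext is never stored.
#'
#' @param plaintext a character string or raw vector.
#' @param keys a [generate_keys()] key ring.
#' @param curve the matching [ec_curve()].
#' @param kappa Koblitz padding window.
#' @param record_id identifier stored with the ciphertext.
#' @return an object of class `cipher_record`.
#' @export
encrypt_record <- function(plaintext, keys, curve, kappa = 64L,
                           record_id = NA_integer_) {
  bytes <- if (is.raw(plaintext)) plaintext else charToRaw(plaintext)
  blocks <- bytes_to_blocks(bytes)
  R <- sample.int(curve$n - 1L, 1)
  RB <- ec_scalar_mult(R, curve$base, curve)
  RA <- ec_scalar_mult(R, keys$public, curve)
  E1 <- ec_add(RB, keys$secret_point, curve)
  mask <- ec_add(RA, keys$secret_point, curve)
  E2 <- lapply(blocks, function(m)
    ec_add(koblitz_encode(m, curve, kappa), mask, curve))
  structure(list(E1 = E1, E2_blocks = E2,
                 salt = paste(format(keys$salt), collapse = ""),
                 curve_id = curve$name, kappa = as.integer(kappa),
                 record_id = record_id),
            class = "cipher_record")
}

#' Decrypt a record
#'
#' Applies the inverse consistent with the encryption:
#' `M = (E2 - S_kP) - K*(E1 - S_kP)`. Off-curve points, failed embeddings
#' and inconsistent length prefixes raise an integrity error.
#'
#' @param record a `cipher_record`.
#' @param keys the matching [generate_keys()] key ring.
#' @param curve the matching [ec_curve()].
#' @return the plaintext as a character string (attribute `"raw"` holds the
#'   bytes).
#' @export
decrypt_record <- function(record, keys, curve) {
  pts <- c(list(record$E1), record$E2_blocks)
  for (P in pts)
    if (!ec_on_curve(P, curve))
      stop_arg("integrity error: ciphertext point off curve")
  RB <- ec_sub(record$E1, keys$secret_point, curve)
  shared <- ec_scalar_mult(keys$private, RB, curve)  # K * (R*B) = R*A
  blocks <- vapply(record$E2_blocks, function(E2) {
    M <- ec_sub(ec_sub(E2, keys$secret_point, curve), shared, curve)
    if (is.null(M)) stop_arg("integrity error: identity message point")
    koblitz_decode(M, record$kappa)
  }, 0)
  bytes <- blocks_to_bytes(blocks)
  out <- rawToChar(bytes)
  attr(out, "raw") <- bytes
  out
}

# JSON-lines persistence ------------------------------------------------------

point_hex <- function(P) sprintf("%08x:%08x", P[1], P[2])

hex_point <- function(s) {
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop_arg("malformed point '%s'", s)
  as.numeric(strtoi(parts, 16L))
}

#' Persist cipher records as JSON lines
#'
#' One record per line with hex-encoded point coordinates, salt, curve id
#' and record id. No plaintext bytes are written.
#'
#' @param records list of `cipher_record`s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
persist_records <- function(records, path) {
  lines <- vapply(records, function(r) {
    jsonlite::toJSON(list(record_id = r$record_id, curve_id = r$curve_id,
                          kappa = r$kappa, salt = r$salt,
                          E1 = point_hex(r$E1),
                          E2 = vapply(r$E2_blocks, point_hex, "")),
                    auto_unbox = TRUE)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname persist_records
#' @param curve curve used to validate the loaded points.
#' @export
load_records <- function(path, curve) {
  lines <- readLines(path)
  lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e)
                      stop_arg("parse error at line %d: %s", i,
                               conditionMessage(e)))
    E1 <- hex_point(obj$E1)
    E2 <- lapply(obj$E2, hex_point)
    for (P in c(list(E1), E2))
      if (!ec_on_curve(P, curve))
        stop_arg("off-curve point at line %d", i)
    structure(list(E1 = E1, E2_blocks = E2, salt = obj$salt,
                   curve_id = obj$curve_id, kappa = obj$kappa,
                   record_id = obj$record_id),
              class = "cipher_record")
  })
}
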