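toy <- ec_curve_toy()

# all points of the toy group, by repeated addition of the base point
toy_group <- local({
  pts <- list(NULL)
  P <- toy$base
  acc <- NULL
  for (k in 1:19) {
    acc <- ec_add(acc, P, toy)
    pts[k + 1] <- list(acc)   # keeps NULL (the identity) as an element
  }
  pts  # pts[[k+1]] = k * B, pts[[1]] = identity
})

test_that("group laws hold exhaustively on the toy curve", {
  expect_null(toy_group[[20]])  # 19 * B = identity
  expect_equal(ec_scalar_mult(1, toy$base, toy), toy$base)
  expect_null(ec_scalar_mult(0, toy$base, toy))
  # one explicit doubling: 2 * (5,1) on y^2 = x^3 + 2x + 2 over F_17
  expect_equal(ec_add(toy$base, toy$base, toy), c(6, 3))

  # scalar multiplication matches repeated addition for every scalar
  for (k in 0:19)
    expect_equal(ec_scalar_mult(k, toy$base, toy),
                 toy_group[[(k %% 19) + 1]])

  # distributivity (j + k) P = jP + kP over the whole group
  for (j in 0:18) for (k in 0:18) {
    lhs <- ec_scalar_mult((j + k) %% 19, toy$base, toy)
    rhs <- ec_add(toy_group[[j + 1]], toy_group[[k + 1]], toy)
    expect_equal(lhs, rhs)
  }
  # closure
  for (P in toy_group) expect_true(ec_on_curve(P, toy))
})

test_that("curve construction validates its invariants", {
  expect_error(ec_curve(17, 0, 0, 5, 1, 19), "singular")
  expect_error(ec_curve(17, 2, 2, 5, 2, 19), "not on the curve")
  expect_error(ec_curve(17, 2, 2, 5, 1, 18), "identity")
  expect_error(ec_scalar_mult(2, c(4, 4), toy), "not on the curve")
  dflt <- ec_curve_default()
  expect_true(ec_on_curve(dflt$base, dflt))
})

test_that("the MD5 wrapper reproduces known digests and salts matter", {
  # standard MD5 test vectors
  expect_equal(strokerisk:::md5_raw(raw(0)),
               "d41d8cd98f00b204e9800998ecf8427e")
  expect_equal(strokerisk:::md5_raw(charToRaw("abc")),
               "900150983cd24fb0d6963f7d28e17f72")

  k1 <- generate_keys(toy, seed = 1)
  k2 <- generate_keys(toy, seed = 1)
  expect_identical(k1$private, k2$private)
  expect_identical(k1$secret_digest, k2$secret_digest)
  expect_true(ec_on_curve(k1$public, toy))
  expect_true(k1$secret_scalar >= 0 && k1$secret_scalar < toy$n)

  # same public key, different salt -> different secret digest
  d1 <- strokerisk:::md5_raw(c(strokerisk:::encode_point_bytes(k1$public),
                               as.raw(1:8)))
  d2 <- strokerisk:::md5_raw(c(strokerisk:::encode_point_bytes(k1$public),
                               as.raw(2:9)))
  expect_false(identical(d1, d2))
  # single-byte salt change flips the digest (avalanche spot check)
  d3 <- strokerisk:::md5_raw(c(strokerisk:::encode_point_bytes(k1$public),
                               as.raw(c(1:7, 9))))
  expect_false(identical(d1, d3))
})

test_that("Koblitz embedding inverts exactly and flags failures", {
  kappa <- 4L
  for (m in 0:2) {
    P <- koblitz_encode(m, toy, kappa)
    expect_true(ec_on_curve(P, toy))
    expect_equal(koblitz_decode(P, kappa), m)
  }
  expect_error(koblitz_encode(100, toy, kappa), "too large")

  # kappa = 1 leaves no padding: find an x with a non-residue rhs
  nonres <- NULL
  for (x in 0:16) {
    rhs <- (x^3 + 2 * x + 2) %% 17
    if (is.na(strokerisk:::mod_sqrt(rhs, 17))) { nonres <- x; break }
  }
  expect_false(is.null(nonres))
  expect_error(koblitz_encode(nonres, toy, 1L), "no curve embedding")

  dflt <- ec_curve_default()
  set.seed(5)
  for (m in sample(0:65535, 25)) {
    P <- koblitz_encode(m, dflt, 64L)
    expect_equal(koblitz_decode(P, 64L), m)
  }
})

test_that("encrypt/decrypt is the identity and randomness is fresh", {
  dflt <- ec_curve_default()
  keys <- generate_keys(dflt, seed = 3)
  set.seed(6)
  r1 <- encrypt_record("risk:3;id:42", keys, dflt)
  r2 <- encrypt_record("risk:3;id:42", keys, dflt)
  expect_false(identical(r1$E1, r2$E1))
  expect_true(all(vapply(r1$E2_blocks, ec_on_curve, TRUE, curve = dflt)))
  expect_equal(decrypt_record(r1, keys, dflt), "risk:3;id:42",
               ignore_attr = TRUE)

  # wrong private key never silently succeeds
  wrong <- generate_keys(dflt, seed = 4)
  bad <- tryCatch(decrypt_record(r1, wrong, dflt), error = function(e) e)
  expect_true(inherits(bad, "error") ||
                !identical(as.character(bad), "risk:3;id:42"))

  set.seed(7)
  for (i in 1:100) {
    txt <- paste(sample(c(letters, 0:9), sample(1:40, 1), TRUE),
                 collapse = "")
    rec <- encrypt_record(txt, keys, dflt)
    expect_equal(decrypt_record(rec, keys, dflt), txt, ignore_attr = TRUE)
  }
})

test_that("with the secret point zeroed the scheme is textbook ElGamal", {
  dflt <- ec_curve_default()
  keys <- generate_keys(dflt, seed = 8)
  keys0 <- keys
  keys0$secret_scalar <- 0
  keys0$secret_point <- NULL   # identity
  set.seed(9)
  rec <- encrypt_record("plain", keys0, dflt)
  # independent textbook decryption: M = E2 - K * E1
  blocks <- vapply(rec$E2_blocks, function(E2) {
    M <- strokerisk:::ec_sub(E2,
                             ec_scalar_mult(keys0$private, rec$E1, dflt),
                             dflt)
    koblitz_decode(M, rec$kappa)
  }, 0)
  expect_equal(rawToChar(strokerisk:::blocks_to_bytes(blocks)), "plain")
  expect_equal(decrypt_record(rec, keys0, dflt), "plain",
               ignore_attr = TRUE)
})

test_that("persistence round-trips and rejects tampering", {
  dflt <- ec_curve_default()
  keys <- generate_keys(dflt, seed = 10)
  set.seed(11)
  recs <- lapply(1:5, function(i)
    encrypt_record(sprintf("id:%d;code:%d", i, i %% 6 + 1), keys, dflt,
                   record_id = i))
  f <- withr::local_tempfile(fileext = ".jsonl")
  persist_records(recs, f)
  # no plaintext fragments in the store
  expect_false(any(grepl("code:", readLines(f), fixed = TRUE)))
  back <- load_records(f, dflt)
  expect_equal(back, recs)
  for (i in 1:5)
    expect_equal(decrypt_record(back[[i]], keys, dflt),
                 sprintf("id:%d;code:%d", i, i %% 6 + 1),
                 ignore_attr = TRUE)

  persist_records(list(), f)
  expect_length(readLines(f), 0)

  # tamper one coordinate -> off-curve rejection with line number
  persist_records(recs, f)
  lines <- readLines(f)
  lines[3] <- sub("\"E1\":\"[0-9a-f:]+\"", "\"E1\":\"00000000:00000001\"",
                  lines[3])
  writeLines(lines, f)
  err <- tryCatch(load_records(f, dflt), error = function(e)
    conditionMessage(e))
  expect_match(err, "line 3")
})
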