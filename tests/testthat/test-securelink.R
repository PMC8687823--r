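test_that("record serialization is deterministic, invertible and injective", {
  rec <- vital_record(75, 97, 36.6875, timestamp = 1700000000, subject_id = "p1")
  b1 <- serialize_record(rec)
  b2 <- serialize_record(rec)
  expect_identical(b1, b2)
  expect_true(isTRUE(all.equal(deserialize_record(b1), rec)))
  # one quantization step in temperature changes the bytes
  rec2 <- vital_record(75, 97, 36.6875 + 0.0625, 1700000000, "p1")
  expect_false(identical(serialize_record(rec2), b1))
  expect_error(deserialize_record(charToRaw("not a record")), "cannot parse")
})

test_that("encrypt/decrypt round-trips random records and rejects bad keys", {
  key <- secret_key(nist_key, "k1")
  withr::with_seed(7, {
    for (i in 1:100) {
      rec <- random_record()
      enc <- encrypt_record(rec, key)
      expect_s3_class(enc, "encrypted_record")
      back <- decrypt_record(enc, key)
      expect_true(isTRUE(all.equal(back, rec)))
    }
  })
  rec <- vital_record(80, 98, 36.5, 0, "x")
  enc <- encrypt_record(rec, key)
  other <- secret_key(strrep("a5", 16), "k1")  # same id, different bytes
  expect_error(decrypt_record(enc, other), "authentication failure")
  wrong_id <- secret_key(nist_key, "k2")
  expect_error(decrypt_record(enc, wrong_id), "key mismatch")
})

test_that("two encryptions of one record differ through their IVs", {
  key <- secret_key(nist_key)
  rec <- vital_record(70, 99, 37.0, 0, "s")
  withr::with_seed(1, {
    e1 <- encrypt_record(rec, key)
    e2 <- encrypt_record(rec, key)
    expect_false(identical(e1$iv, e2$iv))
    expect_false(identical(e1$ciphertext_b64, e2$ciphertext_b64))
  })
  # and with the same iv, ciphertext is deterministic
  iv <- as.raw(1:16)
  expect_identical(encrypt_record(rec, key, iv)$ciphertext_b64,
                   encrypt_record(rec, key, iv)$ciphertext_b64)
})

test_that("Base64 payloads are unwrapped RFC 4648 and length-checked", {
  key <- secret_key(nist_key)
  rec <- vital_record(80, 98, 36.5, 0, paste(rep("longsubject", 20), collapse = ""))
  enc <- encrypt_record(rec, key, iv = as.raw(1:16))
  expect_false(grepl("[\r\n]", enc$ciphertext_b64))
  expect_true(grepl("^[A-Za-z0-9+/]+=*$", enc$ciphertext_b64))
  # truncated ciphertext (not a block multiple) is rejected on construction
  expect_error(
    encrypted_record(jsonlite::base64_enc(as.raw(1:20)), as.raw(1:16), "k"),
    "multiple of 16")
})

test_that("per-field payloads encode a single vital each", {
  key <- secret_key(nist_key)
  rec <- vital_record(84, 96, 36.6875, 0, "p9")
  for (f in c("heart_rate", "spo2", "temperature")) {
    enc <- encrypt_record(rec, key, field = f)
    expect_equal(enc$field_tag, f)
    val <- decrypt_field(enc, key)
    expected <- switch(f, heart_rate = "84", spo2 = "96",
                       temperature = "36.6875")
    expect_equal(val, expected)
    expect_error(decrypt_record(enc, key), "per-field")
  }
})

test_that("telemetry round trip delivers all records on the send schedule", {
  key <- secret_key(nist_key, "node-1")
  records <- withr::with_seed(3, replicate(5, random_record(), simplify = FALSE))
  trip <- telemetry_roundtrip(records, key, period_s = 5, seed = 21L)
  expect_length(trip$failed, 0)
  for (i in 1:5)
    expect_true(isTRUE(all.equal(trip$delivered[[i]], records[[i]])))
  expect_equal(trip$transcript$time_s, c(0, 5, 10, 15, 20))
  expect_true(all(trip$transcript$delivered))
})

test_that("the store holds no plaintext rendering of any field", {
  key <- secret_key(nist_key)
  rec <- vital_record(123, 87, 39.1250, 1234567, "subject-zz")
  trip <- telemetry_roundtrip(list(rec), key, seed = 5L)
  b64 <- paste(trip$store$contents(), collapse = "")
  decoded <- rawToChar(jsonlite::base64_dec(trip$store$contents()[[1]]))
  Encoding(decoded) <- "bytes"
  needles <- c("subject-zz", "hr: 123", "spo2: 87", "temp: 39.1250",
               "timestamp: 1234567")
  for (needle in needles) {
    expect_false(grepl(needle, b64, fixed = TRUE))
    expect_false(grepl(needle, decoded, fixed = TRUE, useBytes = TRUE))
  }
})

test_that("a corrupted ciphertext fails in isolation", {
  key <- secret_key(nist_key)
  records <- withr::with_seed(8, replicate(5, random_record(), simplify = FALSE))
  trip <- telemetry_roundtrip(records, key, corrupt = 3L, seed = 13L)
  expect_equal(trip$failed, 3L)
  expect_null(trip$delivered[[3]])
  for (i in c(1, 2, 4, 5))
    expect_true(isTRUE(all.equal(trip$delivered[[i]], records[[i]])))
})

test_that("key files hold 32 hex characters and round-trip", {
  key <- secret_key(nist_key, "filekey")
  path <- tempfile(fileext = ".hex")
  write_key_file(key, path)
  expect_equal(nchar(readLines(path)), 32)
  back <- read_key_file(path, "filekey")
  expect_identical(back$key_bytes, key$key_bytes)
  expect_error(read_key_file(tempfile()), "not found")
  unlink(path)
})
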