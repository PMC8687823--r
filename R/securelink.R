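#' A 128-bit secret key with an identifier
#'
#' @param key 16 raw bytes, or a 32-hex-character string.
#' @param key_id identifier carried alongside ciphertexts so a receiver can
#'   select the matching key.
#' @return An object of class \code{secret_key}.
#' @export
secret_key <- function(key, key_id = "default") {
  if (is.character(key)) key <- hex_to_raw(key)
  if (!is.raw(key) || length(key) != 16L)
    stop("invalid key: need exactly 16 bytes (128 bits)", call. = FALSE)
  structure(list(key_bytes = key, key_id = as.character(key_id)),
            class = "secret_key")
}

#' @export
print.secret_key <- function(x, ...) {
  cat(sprintf("<secret_key '%s'> 128 bits\n", x$key_id))
  invisible(x)
}

#' Read / write a key file (32 hex characters on one line)
#'
#' @param path file path.
#' @param key_id identifier to attach on read.
#' @return \code{read_key_file}: a \code{\link{secret_key}}.
#' @export
read_key_file <- function(path, key_id = "default") {
  if (!file.exists(path))
    stop("key file not found: ", path, call. = FALSE)
  line <- trimws(readLines(path, n = 1L))
  if (nchar(line) != 32L)
    stop("key file must hold exactly 32 hex characters", call. = FALSE)
  secret_key(line, key_id)
}

#' @rdname read_key_file
#' @param key a \code{secret_key} (for \code{write_key_file}).
#' @export
write_key_file <- function(key, path) {
  stopifnot(inherits(key, "secret_key"))
  writeLines(raw_to_hex(key$key_bytes), path)
  invisible(path)
}

# RFC 4648 base64, standard alphabet, no line wrapping
base64_nowrap <- function(x) gsub("[\r\n]", "", jsonlite::base64_enc(x))

base64_decode <- function(s) {
  if (grepl("[^A-Za-z0-9+/=\r\n]", s))
    stop("malformed Base64 input", call. = FALSE)
  tryCatch(jsonlite::base64_dec(s),
           error = function(e) stop("malformed Base64 input", call. = FALSE))
}

#' Canonical byte serialization of a vital record
#'
#' Deterministic \code{key: value} lines in fixed order (subject_id,
#' timestamp, hr, spo2, temp), UTF-8, one trailing newline. Heart rate and
#' saturation are rendered as integers and temperature with 4 decimals, i.e.
#' at the precision the measurement chain actually delivers, so
#' \code{deserialize(serialize(x))} is the identity on records whose fields
#' are on that grid.
#'
#' @param rec a \code{\link{vital_record}}.
#' @return Raw vector (\code{serialize_record}); \code{vital_record}
#'   (\code{deserialize_record}).
#' @export
serialize_record <- function(rec) {
  stopifnot(inherits(rec, "vital_record"))
  txt <- paste0(
    "subject_id: ", rec$subject_id, "\n",
    "timestamp: ", sprintf("%.0f", rec$timestamp), "\n",
    "hr: ", sprintf("%d", as.integer(round(rec$heart_rate_bpm))), "\n",
    "spo2: ", sprintf("%d", as.integer(round(rec$spo2_percent))), "\n",
    "temp: ", sprintf("%.4f", rec$temperature_c), "\n")
  charToRaw(txt)
}

#' @rdname serialize_record
#' @param bytes raw vector produced by \code{serialize_record}.
#' @export
deserialize_record <- function(bytes) {
  stopifnot(is.raw(bytes))
  txt <- rawToChar(bytes)
  if (!validUTF8(txt))
    stop("cannot parse record: invalid encoding", call. = FALSE)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  fields <- c("subject_id", "timestamp", "hr", "spo2", "temp")
  if (length(lines) != 5L)
    stop("cannot parse record: expected 5 lines", call. = FALSE)
  vals <- character(5)
  for (i in seq_along(fields)) {
    prefix <- paste0(fields[i], ": ")
    if (!startsWith(lines[i], prefix))
      stop("cannot parse record: bad field '", lines[i], "'", call. = FALSE)
    vals[i] <- substring(lines[i], nchar(prefix) + 1L)
  }
  num <- suppressWarnings(as.numeric(vals[2:5]))
  if (any(is.na(num)))
    stop("cannot parse record: non-numeric field", call. = FALSE)
  vital_record(heart_rate_bpm = num[2], spo2_percent = num[3],
               temperature_c = num[4], timestamp = num[1],
               subject_id = vals[1])
}

#' An encrypted, Base64-encoded record as stored in the cloud
#'
#' @param ciphertext_b64 Base64 text (standard alphabet, no wrapping) whose
#'   decoded length is a positive multiple of 16.
#' @param iv raw 16-byte initialization vector.
#' @param key_id identifier of the key that encrypted it.
#' @param field_tag which vital the payload encodes: \code{"full_record"}
#'   (default) or one of \code{"heart_rate"}, \code{"spo2"},
#'   \code{"temperature"}.
#' @return An object of class \code{encrypted_record}.
#' @export
encrypted_record <- function(ciphertext_b64, iv, key_id,
                             field_tag = "full_record") {
  stopifnot(is.character(ciphertext_b64), length(ciphertext_b64) == 1L)
  if (!is.raw(iv) || length(iv) != 16L)
    stop("invalid iv: need exactly 16 bytes", call. = FALSE)
  ct <- base64_decode(ciphertext_b64)
  if (length(ct) == 0L || length(ct) %% 16L != 0L)
    stop("ciphertext must decode to a positive multiple of 16 bytes",
         call. = FALSE)
  field_tag <- match.arg(field_tag,
                         c("full_record", "heart_rate", "spo2", "temperature"))
  structure(list(ciphertext_b64 = ciphertext_b64, iv = iv,
                 key_id = as.character(key_id), field_tag = field_tag),
            class = "encrypted_record")
}

#' @export
print.encrypted_record <- function(x, ...) {
  cat(sprintf("<encrypted_record [%s] key='%s'> %d Base64 chars, iv %s...\n",
              x$field_tag, x$key_id, nchar(x$ciphertext_b64),
              substr(raw_to_hex(x$iv), 1, 8)))
  invisible(x)
}

#' Encrypt a vital record (AES-128-CBC + Base64)
#'
#' Serializes the record canonically, PKCS#7-pads, encrypts with
#' AES-128-CBC under the given key and IV, and Base64-encodes the result.
#' With \code{field} other than \code{"full_record"}, only that vital's
#' rendered value is encrypted (the per-field storage layout some telemetry
#' dashboards use); the default encrypts the whole record as one payload.
#'
#' @param rec a \code{\link{vital_record}}.
#' @param key a \code{\link{secret_key}}.
#' @param iv raw 16-byte IV; if \code{NULL} a fresh random IV is drawn. CBC
#'   with a repeated IV leaks equality of payloads, so callers should pass
#'   \code{NULL} outside of reproducibility tests.
#' @param field payload granularity, see above.
#' @return An \code{\link{encrypted_record}}.
#' @export
encrypt_record <- function(rec, key, iv = NULL, field = "full_record") {
  stopifnot(inherits(rec, "vital_record"), inherits(key, "secret_key"))
  field <- match.arg(field, c("full_record", "heart_rate", "spo2", "temperature"))
  if (is.null(iv)) iv <- as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)
  if (!is.raw(iv) || length(iv) != 16L)
    stop("invalid iv: need exactly 16 bytes", call. = FALSE)
  plaintext <- switch(field,
    full_record = serialize_record(rec),
    heart_rate  = charToRaw(sprintf("%d", as.integer(round(rec$heart_rate_bpm)))),
    spo2        = charToRaw(sprintf("%d", as.integer(round(rec$spo2_percent)))),
    temperature = charToRaw(sprintf("%.4f", rec$temperature_c)))
  ct <- aes_cbc_encrypt(plaintext, key$key_bytes, iv)
  encrypted_record(base64_nowrap(ct), iv, key$key_id, field)
}

#' Decrypt an encrypted record back to a vital record
#'
#' Base64-decodes, AES-128-CBC-decrypts, strips padding, and (for
#' \code{"full_record"} payloads) deserializes. A wrong key surfaces as an
#' authentication failure — padding or parse errors never yield a partial
#' record.
#'
#' @param enc an \code{\link{encrypted_record}} with
#'   \code{field_tag == "full_record"}; use \code{decrypt_field} for per-field
#'   payloads.
#' @param key the matching \code{\link{secret_key}}.
#' @return A \code{\link{vital_record}}.
#' @export
decrypt_record <- function(enc, key) {
  stopifnot(inherits(enc, "encrypted_record"), inherits(key, "secret_key"))
  if (enc$key_id != key$key_id)
    stop("key mismatch: record encrypted under key '", enc$key_id, "'",
         call. = FALSE)
  if (enc$field_tag != "full_record")
    stop("per-field payload; use decrypt_field()", call. = FALSE)
  ct <- base64_decode(enc$ciphertext_b64)
  if (length(ct) == 0L || length(ct) %% 16L != 0L)
    stop("malformed ciphertext: not a multiple of the block size", call. = FALSE)
  tryCatch({
    pt <- aes_cbc_decrypt(ct, key$key_bytes, enc$iv)
    deserialize_record(pt)
  }, error = function(e)
    stop("authentication failure: wrong key or corrupted ciphertext",
         call. = FALSE))
}

#' @rdname decrypt_record
#' @export
decrypt_field <- function(enc, key) {
  stopifnot(inherits(enc, "encrypted_record"), inherits(key, "secret_key"))
  if (enc$key_id != key$key_id)
    stop("key mismatch: record encrypted under key '", enc$key_id, "'",
         call. = FALSE)
  ct <- base64_decode(enc$ciphertext_b64)
  tryCatch({
    pt <- aes_cbc_decrypt(ct, key$key_bytes, enc$iv)
    rawToChar(pt)
  }, error = function(e)
    stop("authentication failure: wrong key or corrupted ciphertext",
         call. = FALSE))
}

#' In-process ciphertext store emulating the cloud database
#'
#' A minimal put/get key-value store holding only ciphertext. Stands in for
#' the real-time cloud database of the device architecture, which is out of
#' scope; the contract (store ciphered payloads, deliver them unchanged to
#' the consumer side) is the same.
#'
#' @return An environment with \code{put(id, enc)}, \code{get(id)},
#'   \code{ids()}, and \code{contents()} (all stored Base64 payloads,
#'   for at-rest inspection).
#' @export
cipher_store <- function() {
  env <- new.env(parent = emptyenv())
  env$data <- list()
  store <- list(
    put = function(id, enc) {
      stopifnot(inherits(enc, "encrypted_record"))
      env$data[[as.character(id)]] <- enc
      invisible(id)
    },
    get = function(id) env$data[[as.character(id)]],
    ids = function() names(env$data),
    contents = function() vapply(env$data, function(e) e$ciphertext_b64, character(1)))
  class(store) <- "cipher_store"
  store
}

#' Simulated secure telemetry round trip
#'
#' Serializes, encrypts (fresh random IV per message), stores, fetches and
#' decrypts a stream of vital records, on a virtual clock ticking once per
#' send period. Corruption injected into the store (via \code{corrupt})
#' surfaces as isolated per-record failures; the stream continues.
#'
#' @param records list of \code{\link{vital_record}}s.
#' @param key a \code{\link{secret_key}}.
#' @param period_s send period in seconds (> 0); the default models a device
#'   publishing every five seconds.
#' @param corrupt integer indices of messages to corrupt in the store (test
#'   hook: one ciphertext byte is flipped after storage).
#' @param seed integer seed for the per-message IVs.
#' @return A list with \code{delivered} (decrypted \code{vital_record}s, NULL
#'   where delivery failed), \code{failed} (indices), \code{transcript}
#'   (data.frame of virtual send times and outcomes), and \code{store}.
#' @export
telemetry_roundtrip <- function(records, key, period_s = 5, corrupt = integer(0),
                                seed = 1L) {
  stopifnot(is.list(records), inherits(key, "secret_key"))
  if (!(period_s > 0)) stop("period_s must be > 0", call. = FALSE)
  store <- cipher_store()
  n <- length(records)
  withr::with_seed(seed, {
    for (i in seq_len(n)) {
      enc <- encrypt_record(records[[i]], key)
      if (i %in% corrupt) {
        ct <- base64_decode(enc$ciphertext_b64)
        ct[1] <- as.raw(bitwXor(as.integer(ct[1]), 0xffL))
        enc$ciphertext_b64 <- base64_nowrap(ct)
      }
      store$put(i, enc)
    }
  })
  delivered <- vector("list", n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    delivered[[i]] <- tryCatch(decrypt_record(store$get(i), key),
                               error = function(e) NULL)
    ok[i] <- !is.null(delivered[[i]])
  }
  list(delivered = delivered,
       failed = which(!ok),
       transcript = data.frame(index = seq_len(n),
                               time_s = (seq_len(n) - 1) * period_s,
                               key_id = key$key_id,
                               delivered = ok),
       store = store)
}
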