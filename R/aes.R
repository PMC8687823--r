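# AES-128 block cipher in pure R, plus CBC mode and PKCS#7 padding.
#
# The cipher tables are derived algebraically rather than hardcoded: the
# S-box is the multiplicative inverse in GF(2^8) (modulus x^8+x^4+x^3+x+1)
# followed by the standard affine map, and the MixColumns byte products use
# GF multiplication tables for the fixed constants. Correctness is pinned by
# published known-answer vectors in the test suite, not by these derivations
# alone.

# GF(2^8) product, Russian-peasant style
gf_mul <- function(a, b) {
  p <- 0L
  a <- as.integer(a); b <- as.integer(b)
  for (k in 1:8) {
    if (bitwAnd(b, 1L) == 1L) p <- bitwXor(p, a)
    hi <- bitwAnd(a, 0x80L)
    a <- bitwAnd(bitwShiftL(a, 1L), 0xFFL)
    if (hi != 0L) a <- bitwXor(a, 0x1BL)
    b <- bitwShiftR(b, 1L)
  }
  p
}

.aes <- local({
  rotl8 <- function(x, n) bitwAnd(bitwOr(bitwShiftL(x, n), bitwShiftR(x, 8L - n)), 0xFFL)
  # exp/log tables over generator 0x03
  exp_t <- integer(256)
  log_t <- integer(256)
  v <- 1L
  for (i in 0:254) {
    exp_t[i + 1L] <- v
    log_t[v + 1L] <- i
    v <- bitwXor(v, bitwAnd(bitwShiftL(v, 1L), 0xFFL))
    if (bitwAnd(exp_t[i + 1L], 0x80L) != 0L) v <- bitwXor(v, 0x1BL)
  }
  inv_t <- integer(256)  # inv_t[x+1] = x^-1, with 0 -> 0
  for (x in 1:255) inv_t[x + 1L] <- exp_t[(255L - log_t[x + 1L]) %% 255L + 1L]
  sbox <- integer(256)
  for (x in 0:255) {
    b <- inv_t[x + 1L]
    s <- bitwXor(b, rotl8(b, 1L))
    s <- bitwXor(s, rotl8(b, 2L))
    s <- bitwXor(s, rotl8(b, 3L))
    s <- bitwXor(s, rotl8(b, 4L))
    sbox[x + 1L] <- bitwXor(s, 0x63L)
  }
  inv_sbox <- integer(256)
  inv_sbox[sbox + 1L] <- 0:255
  mul <- function(c) vapply(0:255, gf_mul, integer(1), a = c)
  list(sbox = sbox, inv_sbox = inv_sbox,
       m2 = mul(2L), m3 = mul(3L),
       m9 = mul(9L), m11 = mul(11L), m13 = mul(13L), m14 = mul(14L),
       # ShiftRows permutation on the 16-byte column-major state, and inverse
       sr = c(1L, 6L, 11L, 16L, 5L, 10L, 15L, 4L, 9L, 14L, 3L, 8L, 13L, 2L, 7L, 12L),
       rcon = c(0x01L, 0x02L, 0x04L, 0x08L, 0x10L, 0x20L, 0x40L, 0x80L, 0x1BL, 0x36L))
})
.aes$isr <- integer(16)
.aes$isr[.aes$sr] <- 1:16

# 16-byte key -> 176-byte round-key schedule (11 round keys), integer vector
aes_expand_key <- function(key) {
  key <- as.integer(key)
  stopifnot(length(key) == 16L)
  w <- integer(176)
  w[1:16] <- key
  for (i in 4:43) {
    tmp <- w[(4L * i - 3L):(4L * i)]
    if (i %% 4L == 0L) {
      tmp <- .aes$sbox[tmp[c(2L, 3L, 4L, 1L)] + 1L]
      tmp[1L] <- bitwXor(tmp[1L], .aes$rcon[i %/% 4L])
    }
    w[(4L * i + 1L):(4L * i + 4L)] <- bitwXor(w[(4L * (i - 4L) + 1L):(4L * (i - 4L) + 4L)], tmp)
  }
  w
}

mix_columns <- function(st) {
  a0 <- st[c(1L, 5L, 9L, 13L)]; a1 <- st[c(2L, 6L, 10L, 14L)]
  a2 <- st[c(3L, 7L, 11L, 15L)]; a3 <- st[c(4L, 8L, 12L, 16L)]
  out <- integer(16)
  out[c(1L, 5L, 9L, 13L)] <- bitwXor(bitwXor(.aes$m2[a0 + 1L], .aes$m3[a1 + 1L]), bitwXor(a2, a3))
  out[c(2L, 6L, 10L, 14L)] <- bitwXor(bitwXor(a0, .aes$m2[a1 + 1L]), bitwXor(.aes$m3[a2 + 1L], a3))
  out[c(3L, 7L, 11L, 15L)] <- bitwXor(bitwXor(a0, a1), bitwXor(.aes$m2[a2 + 1L], .aes$m3[a3 + 1L]))
  out[c(4L, 8L, 12L, 16L)] <- bitwXor(bitwXor(.aes$m3[a0 + 1L], a1), bitwXor(a2, .aes$m2[a3 + 1L]))
  out
}

inv_mix_columns <- function(st) {
  a0 <- st[c(1L, 5L, 9L, 13L)]; a1 <- st[c(2L, 6L, 10L, 14L)]
  a2 <- st[c(3L, 7L, 11L, 15L)]; a3 <- st[c(4L, 8L, 12L, 16L)]
  out <- integer(16)
  out[c(1L, 5L, 9L, 13L)] <- bitwXor(bitwXor(.aes$m14[a0 + 1L], .aes$m11[a1 + 1L]),
                                     bitwXor(.aes$m13[a2 + 1L], .aes$m9[a3 + 1L]))
  out[c(2L, 6L, 10L, 14L)] <- bitwXor(bitwXor(.aes$m9[a0 + 1L], .aes$m14[a1 + 1L]),
                                      bitwXor(.aes$m11[a2 + 1L], .aes$m13[a3 + 1L]))
  out[c(3L, 7L, 11L, 15L)] <- bitwXor(bitwXor(.aes$m13[a0 + 1L], .aes$m9[a1 + 1L]),
                                      bitwXor(.aes$m14[a2 + 1L], .aes$m11[a3 + 1L]))
  out[c(4L, 8L, 12L, 16L)] <- bitwXor(bitwXor(.aes$m11[a0 + 1L], .aes$m13[a1 + 1L]),
                                      bitwXor(.aes$m9[a2 + 1L], .aes$m14[a3 + 1L]))
  out
}

# single-block primitives; block and round keys are integer vectors in 0..255
aes_encrypt_block_int <- function(block, w) {
  st <- bitwXor(block, w[1:16])
  for (r in 1:9) {
    st <- .aes$sbox[st + 1L]
    st <- st[.aes$sr]
    st <- mix_columns(st)
    st <- bitwXor(st, w[(16L * r + 1L):(16L * r + 16L)])
  }
  st <- .aes$sbox[st + 1L]
  st <- st[.aes$sr]
  bitwXor(st, w[161:176])
}

aes_decrypt_block_int <- function(block, w) {
  st <- bitwXor(block, w[161:176])
  for (r in 9:1) {
    st <- st[.aes$isr]
    st <- .aes$inv_sbox[st + 1L]
    st <- bitwXor(st, w[(16L * r + 1L):(16L * r + 16L)])
    st <- inv_mix_columns(st)
  }
  st <- st[.aes$isr]
  st <- .aes$inv_sbox[st + 1L]
  bitwXor(st, w[1:16])
}

#' Low-level AES-128 single-block encryption/decryption
#'
#' Operates on one 16-byte block with a 16-byte key (ECB of a single block).
#' Exposed mainly so the cipher core can be validated against published
#' known-answer vectors.
#'
#' @param block raw vector of exactly 16 bytes.
#' @param key raw vector of exactly 16 bytes.
#' @return Raw vector of 16 bytes.
#' @export
aes_encrypt_block <- function(block, key) {
  stopifnot(is.raw(block), length(block) == 16L, is.raw(key), length(key) == 16L)
  w <- aes_expand_key(as.integer(key))
  as.raw(aes_encrypt_block_int(as.integer(block), w))
}

#' @rdname aes_encrypt_block
#' @export
aes_decrypt_block <- function(block, key) {
  stopifnot(is.raw(block), length(block) == 16L, is.raw(key), length(key) == 16L)
  w <- aes_expand_key(as.integer(key))
  as.raw(aes_decrypt_block_int(as.integer(block), w))
}

#' PKCS#7 padding to the AES block size
#'
#' Appends n bytes of value n so the length becomes a positive multiple of
#' 16; a whole extra block is added when the input is already aligned.
#'
#' @param x raw vector.
#' @return Padded raw vector (\code{pkcs7_pad}); unpadded raw vector
#'   (\code{pkcs7_unpad}), erroring on malformed padding.
#' @export
pkcs7_pad <- function(x) {
  stopifnot(is.raw(x))
  n <- 16L - length(x) %% 16L
  c(x, as.raw(rep(n, n)))
}

#' @rdname pkcs7_pad
#' @export
pkcs7_unpad <- function(x) {
  stopifnot(is.raw(x))
  if (length(x) == 0L || length(x) %% 16L != 0L)
    stop("padded data must be a positive multiple of 16 bytes", call. = FALSE)
  n <- as.integer(x[length(x)])
  if (n < 1L || n > 16L || n > length(x))
    stop("invalid PKCS#7 padding", call. = FALSE)
  pad <- as.integer(x[(length(x) - n + 1L):length(x)])
  if (any(pad != n))
    stop("invalid PKCS#7 padding", call. = FALSE)
  x[seq_len(length(x) - n)]
}

#' AES-128-CBC encryption and decryption of arbitrary byte strings
#'
#' \code{aes_cbc_encrypt} PKCS#7-pads the plaintext and chains 16-byte blocks
#' through the cipher, each block XORed with the previous ciphertext block
#' (the IV for the first). \code{aes_cbc_decrypt} inverts the chain and strips
#' the padding. \code{aes_cbc_encrypt_raw} encrypts without padding (input
#' length must already be a multiple of 16); it exists so the mode can be
#' checked against published multi-block vectors.
#'
#' @param plaintext,ciphertext raw vectors.
#' @param key raw 16-byte key.
#' @param iv raw 16-byte initialization vector.
#' @return Raw vector.
#' @export
aes_cbc_encrypt <- function(plaintext, key, iv) {
  aes_cbc_encrypt_raw(pkcs7_pad(plaintext), key, iv)
}

#' @rdname aes_cbc_encrypt
#' @export
aes_cbc_encrypt_raw <- function(plaintext, key, iv) {
  stopifnot(is.raw(plaintext), is.raw(key), is.raw(iv))
  if (length(key) != 16L) stop("invalid key: need exactly 16 bytes", call. = FALSE)
  if (length(iv) != 16L) stop("invalid iv: need exactly 16 bytes", call. = FALSE)
  if (length(plaintext) %% 16L != 0L)
    stop("unpadded CBC input must be a multiple of 16 bytes", call. = FALSE)
  w <- aes_expand_key(as.integer(key))
  prev <- as.integer(iv)
  p <- as.integer(plaintext)
  out <- integer(length(p))
  for (b in seq_len(length(p) %/% 16L)) {
    i <- (b - 1L) * 16L
    prev <- aes_encrypt_block_int(bitwXor(p[(i + 1L):(i + 16L)], prev), w)
    out[(i + 1L):(i + 16L)] <- prev
  }
  as.raw(out)
}

#' @rdname aes_cbc_encrypt
#' @export
aes_cbc_decrypt <- function(ciphertext, key, iv) {
  stopifnot(is.raw(ciphertext), is.raw(key), is.raw(iv))
  if (length(key) != 16L) stop("invalid key: need exactly 16 bytes", call. = FALSE)
  if (length(iv) != 16L) stop("invalid iv: need exactly 16 bytes", call. = FALSE)
  if (length(ciphertext) == 0L || length(ciphertext) %% 16L != 0L)
    stop("ciphertext must be a positive multiple of 16 bytes", call. = FALSE)
  w <- aes_expand_key(as.integer(key))
  prev <- as.integer(iv)
  ct <- as.integer(ciphertext)
  out <- integer(length(ct))
  for (b in seq_len(length(ct) %/% 16L)) {
    i <- (b - 1L) * 16L
    blk <- ct[(i + 1L):(i + 16L)]
    out[(i + 1L):(i + 16L)] <- bitwXor(aes_decrypt_block_int(blk, w), prev)
    prev <- blk
  }
  pkcs7_unpad(as.raw(out))
}

#' Hex string / raw vector conversions
#'
#' @param hex a string of hex digit pairs (case-insensitive, whitespace ignored).
#' @param x a raw vector.
#' @return \code{hex_to_raw}: raw vector; \code{raw_to_hex}: lowercase string.
#' @export
hex_to_raw <- function(hex) {
  hex <- gsub("[[:space:]]", "", hex)
  if (nchar(hex) %% 2L != 0L || grepl("[^0-9a-fA-F]", hex))
    stop("malformed hex string", call. = FALSE)
  pairs <- substring(hex, seq(1, nchar(hex), 2), seq(2, nchar(hex), 2))
  as.raw(strtoi(pairs, 16L))
}

#' @rdname hex_to_raw
#' @export
raw_to_hex <- function(x) paste(sprintf("%02x", as.integer(x)), collapse = "")
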