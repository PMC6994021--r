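# Internal helpers shared across modules.

# 32-bit FNV-1a over UTF-8 bytes. R has no native unsigned 32-bit arithmetic,
# so the multiply-mod-2^32 is done in 16-bit limbs on doubles (exact: all
# intermediates stay below 2^53).
fnv1a32 <- function(x) {
  vapply(x, function(s) {
    bytes <- as.integer(charToRaw(enc2utf8(s)))
    h <- 2166136261
    for (b in bytes) {
      lo8 <- h %% 256
      h <- h - lo8 + bitwXor(as.integer(lo8), b)
      hi <- h %/% 65536
      lo <- h %% 65536
      h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
    }
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# One RNG stream per stage: derive a 31-bit seed from the master seed and a
# stage label, so stages can rerun independently without perturbing others.
derive_seed <- function(seed, label) {
  as.integer((as.numeric(seed) + fnv1a32(label)) %% 2147483647)
}

checksum_file <- function(path) {
  h <- fnv1a32(rawToChar(readBin(path, "raw", file.info(path)$size)))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

month_index <- function(d) {
  as.integer(format(d, "%Y")) * 12L + as.integer(format(d, "%m"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
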