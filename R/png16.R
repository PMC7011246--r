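# Minimal 16-bit grayscale PNG writer. The png package reads 16-bit PNGs but
# writes only 8-bit, and no other installed package emits 16-bit grayscale
# PNG, so the few required chunks are assembled here directly (verified
# against png::readPNG round trips in the test suite).

crc32_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (is.null(crc32_env$tab)) {
    tab <- numeric(256)
    for (n in 0:255) {
      c <- n
      for (k in 1:8) {
        c <- if (c %% 2 == 1) bitwXor_dbl(3988292384, c %/% 2) else c %/% 2
      }
      tab[n + 1] <- c
    }
    crc32_env$tab <- tab
  }
  crc32_env$tab
}

# CRC-32 in double arithmetic (values stay below 2^32, no sign issues)
crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- 4294967295
  ints <- as.integer(bytes)
  for (b in ints) {
    idx <- bitwXor(as.integer(crc %% 256), b)
    crc <- bitwXor_dbl(crc %/% 256, tab[idx + 1])
  }
  bitwXor_dbl(crc, 4294967295)
}

# XOR of two non-negative doubles < 2^32
bitwXor_dbl <- function(a, b) {
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi * 65536 + lo
}

u32_raw <- function(x) {
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  payload <- c(charToRaw(type), data)
  c(u32_raw(length(data)), payload, u32_raw(crc32(payload)))
}

# Write a [0,1] matrix as a 16-bit grayscale PNG (big-endian samples,
# filter 0 per scanline, one zlib-wrapped IDAT).
png_write_gray16 <- function(m, path) {
  # pmin/pmax with a scalar first argument drop the dim attribute
  v <- matrix(round(pmin(1, pmax(0, m)) * 65535), nrow(m), ncol(m))
  # PNG stores row-major scanlines: row r of the image = row r of the matrix
  hi <- as.raw(t(v) %/% 256)
  lo <- as.raw(t(v) %% 256)
  dim(hi) <- dim(lo) <- c(ncol(m), nrow(m))
  scanlines <- lapply(seq_len(nrow(m)), function(r) {
    bytes <- rbind(hi[, r], lo[, r])
    c(as.raw(0), as.vector(bytes))
  })
  raw_data <- do.call(c, scanlines)
  # despite the type name, memCompress emits an RFC-1950 zlib stream,
  # which is exactly what IDAT carries
  zlib <- memCompress(raw_data, type = "gzip")
  ihdr <- c(u32_raw(ncol(m)), u32_raw(nrow(m)),
            as.raw(c(16, 0, 0, 0, 0)))  # bit depth 16, grayscale
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", zlib), con)
  writeBin(png_chunk("IEND", raw()), con)
  invisible(path)
}
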