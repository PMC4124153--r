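# Minimal STORED (uncompressed) zip writer.  Used to package generated
# DwC-A fixtures; entries carry a fixed timestamp so the same content
# always yields byte-identical archives.

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256L)
      for (i in 0:255) {
        c <- i
        for (k in 1:8) {
          c <- if (bitwAnd(c, 1L) != 0L) {
            bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1L))  # 0xEDB88320
          } else {
            bitwShiftR(bitwAnd(c, -2L), 1L)
          }
        }
        t[i + 1L] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(crc, b), 255L)
    crc <- bitwXor(bitwShiftR(bitwAnd(crc, -256L), 8L), tab[idx + 1L])
  }
  bitwXor(crc, -1L)
}

uint_bytes <- function(x, n) {
  # little-endian unsigned integer as n raw bytes; x may be a double
  x <- as.numeric(x) %% 2^(8 * n)
  out <- raw(n)
  for (i in seq_len(n)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

# files: named list of raw vectors (name -> content).  Deterministic:
# fixed DOS date/time, entries written in list order.
write_stored_zip <- function(files, path) {
  stopifnot(length(names(files)) == length(files))
  dos_time <- uint_bytes(0, 2)                       # 00:00:00
  dos_date <- uint_bytes(bitwShiftL(34L, 9) + bitwShiftL(1L, 5) + 1L, 2)  # 2014-01-01
  locals <- list(); centrals <- list(); offset <- 0
  for (i in seq_along(files)) {
    name <- charToRaw(names(files)[i])
    data <- files[[i]]
    crc <- uint_bytes(crc32(data), 4)
    sz <- uint_bytes(length(data), 4)
    common <- c(uint_bytes(20, 2),        # version needed
                uint_bytes(0, 2),         # flags
                uint_bytes(0, 2),         # method: stored
                dos_time, dos_date, crc, sz, sz,
                uint_bytes(length(name), 2),
                uint_bytes(0, 2))         # extra length
    locals[[i]] <- c(as.raw(c(0x50, 0x4b, 0x03, 0x04)), common, name, data)
    centrals[[i]] <- c(as.raw(c(0x50, 0x4b, 0x01, 0x02)),
                       uint_bytes(20, 2), common,
                       uint_bytes(0, 2), uint_bytes(0, 2), uint_bytes(0, 2),
                       uint_bytes(0, 4),                 # external attrs
                       uint_bytes(offset, 4), name)
    offset <- offset + length(locals[[i]])
  }
  central <- do.call(c, centrals)
  eocd <- c(as.raw(c(0x50, 0x4b, 0x05, 0x06)),
            uint_bytes(0, 2), uint_bytes(0, 2),
            uint_bytes(length(files), 2), uint_bytes(length(files), 2),
            uint_bytes(length(central), 4), uint_bytes(offset, 4),
            uint_bytes(0, 2))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(do.call(c, c(locals, list(central), list(eocd))), con)
  invisible(path)
}
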