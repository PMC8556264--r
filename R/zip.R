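# Minimal deterministic ZIP writer.
#
# Entries are deflate-compressed via memCompress(), whose output is a zlib
# stream: 2-byte header, raw deflate data, 4-byte Adler-32. The deflate bytes
# are lifted out and paired with a CRC-32 computed here (zip requires CRC-32,
# not Adler). Entry order is sorted and all timestamps fixed, so archives of
# identical content are byte-identical.

.le_bytes <- function(x, n) {
  b <- raw(n)
  for (i in seq_len(n)) {
    b[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  b
}

.crc32_table <- local({
  vapply(0:255, function(n) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(bitwShiftR(c, 1L), -306674912L)  # reversed poly 0xEDB88320
      } else bitwShiftR(c, 1L)
    }
    c
  }, integer(1))
})

.crc32 <- function(data) {
  c <- -1L
  for (b in as.integer(data)) {
    c <- bitwXor(bitwShiftR(c, 8L),
                 .crc32_table[bitwAnd(bitwXor(c, b), 255L) + 1L])
  }
  c <- bitwXor(c, -1L)
  if (c < 0) c + 2^32 else as.double(c)
}

.deflate_with_crc <- function(data) {
  zl <- memCompress(data, type = "gzip")  # zlib-framed stream
  n <- length(zl)
  list(deflate = zl[3:(n - 4)], crc = .le_bytes(.crc32(data), 4),
       size = length(data))
}

#' Write a zip archive (deterministic, deflate-compressed)
#'
#' @param zipfile Output path.
#' @param files Character vector of files to archive.
#' @param root Directory; stored entry names are relative to it.
#' @return `zipfile`, invisibly.
#' @export
write_zip <- function(zipfile, files, root = ".") {
  files <- sort(files)
  rel <- sub("^/+", "", sub(paste0("^", .rx_escape(normalizePath(root)), "/?"), "",
                            normalizePath(files)))
  con <- file(zipfile, "wb")
  on.exit(close(con))
  offsets <- integer(length(files))
  entries <- vector("list", length(files))
  pos <- 0L

  for (i in seq_along(files)) {
    data <- readBin(files[i], "raw", file.info(files[i])$size)
    z <- .deflate_with_crc(data)
    name <- charToRaw(rel[i])
    local_hdr <- c(
      .le_bytes(0x04034b50, 4), .le_bytes(20, 2), .le_bytes(0, 2),
      .le_bytes(8, 2),                       # method: deflate
      .le_bytes(0, 2), .le_bytes(0x21, 2),   # fixed time/date (1980-01-01)
      z$crc, .le_bytes(length(z$deflate), 4), .le_bytes(z$size, 4),
      .le_bytes(length(name), 2), .le_bytes(0, 2), name)
    writeBin(local_hdr, con)
    writeBin(z$deflate, con)
    offsets[i] <- pos
    entries[[i]] <- list(name = name, crc = z$crc,
                         csize = length(z$deflate), usize = z$size)
    pos <- pos + length(local_hdr) + length(z$deflate)
  }

  cd_start <- pos
  for (i in seq_along(files)) {
    e <- entries[[i]]
    cd <- c(.le_bytes(0x02014b50, 4), .le_bytes(20, 2), .le_bytes(20, 2),
            .le_bytes(0, 2), .le_bytes(8, 2),
            .le_bytes(0, 2), .le_bytes(0x21, 2),
            e$crc, .le_bytes(e$csize, 4), .le_bytes(e$usize, 4),
            .le_bytes(length(e$name), 2), .le_bytes(0, 2), .le_bytes(0, 2),
            .le_bytes(0, 2), .le_bytes(0, 2), .le_bytes(0, 4),
            .le_bytes(offsets[i], 4), e$name)
    writeBin(cd, con)
    pos <- pos + length(cd)
  }
  eocd <- c(.le_bytes(0x06054b50, 4), .le_bytes(0, 2), .le_bytes(0, 2),
            .le_bytes(length(files), 2), .le_bytes(length(files), 2),
            .le_bytes(pos - cd_start, 4), .le_bytes(cd_start, 4),
            .le_bytes(0, 2))
  writeBin(eocd, con)
  invisible(zipfile)
}

#' List the entry names of a zip archive
#'
#' @param zipfile Archive path.
#' @return Character vector of stored entry names, in archive order.
#' @export
zip_entries <- function(zipfile) {
  raw <- readBin(zipfile, "raw", file.info(zipfile)$size)
  sig <- as.raw(c(0x50, 0x4b, 0x01, 0x02))
  hits <- which(raw == sig[1])
  hits <- hits[vapply(hits, function(i)
    i + 3 <= length(raw) && identical(raw[i:(i + 3)], sig), logical(1))]
  vapply(hits, function(i) {
    nlen <- as.integer(raw[i + 28]) + 256L * as.integer(raw[i + 29])
    rawToChar(raw[(i + 46):(i + 45 + nlen)])
  }, character(1))
}
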