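# BGZF codec: the blocked-gzip container underlying BAM. Each block is an
# independent gzip member carrying a 'BC' extra subfield with the total block
# size, so disjoint block ranges can be located and decompressed concurrently.

BGZF_MAGIC <- as.raw(c(0x1f, 0x8b, 0x08, 0x04))

#' Standard 28-byte BGZF end-of-file marker
#'
#' The fixed empty-payload block that terminates every well-formed BGZF file.
#' @return A raw vector of length 28.
#' @export
bgzf_eof_marker <- function() {
  as.raw(c(0x1f, 0x8b, 0x08, 0x04, 0x00, 0x00, 0x00, 0x00, 0x00, 0xff,
           0x06, 0x00, 0x42, 0x43, 0x02, 0x00, 0x1b, 0x00, 0x03, 0x00,
           0x00, 0x00, 0x00, 0x00, 0x00, 0x00, 0x00, 0x00))
}

#' Test whether bytes are exactly the BGZF end-of-file marker
#'
#' @param bytes A raw vector.
#' @return `TRUE` iff `bytes` equals the fixed 28-byte EOF marker.
#' @export
bgzf_is_eof_block <- function(bytes) {
  is.raw(bytes) && length(bytes) == 28L && all(bytes == bgzf_eof_marker())
}

# gzip-compress a payload through a gzfile connection: this is the one base-R
# entry point that emits a genuine RFC1952 member (memCompress emits zlib),
# giving us both the raw deflate stream and the zlib-computed CRC32 trailer.
gzip_member <- function(payload, level = 6L) {
  tf <- tempfile(fileext = ".gz")
  on.exit(unlink(tf))
  con <- gzfile(tf, "wb", compression = level)
  if (length(payload)) writeBin(payload, con)
  close(con)
  readBin(tf, raw(), file.size(tf))
}

#' Encode one BGZF block
#'
#' Frames `payload` as a single gzip member with the BC extra subfield
#' required by BGZF. Output is deterministic for a fixed payload and
#' compression level; an empty payload yields exactly the standard EOF
#' marker.
#'
#' @param payload Raw vector, at most 65535 bytes.
#' @param level Deflate compression level (1-9); default 6.
#' @return Raw vector holding the complete block.
#' @export
bgzf_write_block <- function(payload, level = 6L) {
  if (!is.raw(payload)) stop("payload must be raw")
  if (length(payload) > 65535L)
    stop_with("bgzf_size_error", "payload of %d bytes exceeds the 65535-byte BGZF limit",
              length(payload))
  gz <- gzip_member(payload, level)
  # strip the 10-byte plain gzip header; keep deflate data + CRC32/ISIZE
  body <- gz[11:length(gz)]
  bsize <- 18L + length(body)
  if (bsize > 65536L)
    stop_with("bgzf_size_error",
              "payload compresses to a %d-byte block, exceeding the 65536-byte BGZF limit",
              bsize)
  c(BGZF_MAGIC,
    raw(4),                                  # MTIME = 0
    as.raw(c(0x00, 0xff)),                   # XFL = 0, OS = unknown
    as.raw(c(0x06, 0x00)),                   # XLEN = 6
    as.raw(c(0x42, 0x43, 0x02, 0x00)),       # 'B','C', SLEN = 2
    wr_u16(bsize - 1L),
    body)
}

# Parse the BSIZE value out of a block header; returns NA if the extra field
# carries no BC subfield.
bgzf_bsize <- function(hdr_and_extra, xlen) {
  off <- 0L
  while (off + 4L <= xlen) {
    si1 <- rd_u8(hdr_and_extra, 12L + off)
    si2 <- rd_u8(hdr_and_extra, 13L + off)
    slen <- rd_u16(hdr_and_extra, 14L + off)
    if (si1 == 66L && si2 == 67L && slen == 2L)
      return(rd_u16(hdr_and_extra, 16L + off) + 1L)
    off <- off + 4L + slen
  }
  NA_integer_
}

#' Decode the BGZF block starting at a file offset
#'
#' Reads and fully decompresses one block. Decoding is side-effect-free with
#' respect to other readers of the same source; the stored CRC32 is always
#' verified (by zlib) against the decompressed payload.
#'
#' @param src Raw vector (file image) or file path.
#' @param offset 0-based byte offset of the first byte of the block.
#' @return A list of class `bgzf_block` with fields `coffset`, `csize`,
#'   `payload`.
#' @export
bgzf_read_block <- function(src, offset = 0) {
  hdr <- src_read(src, offset, 18L)
  if (length(hdr) < 18L || any(hdr[1:4] != BGZF_MAGIC))
    stop_with("bgzf_malformed_error",
              "no BGZF block at offset %.0f: bad magic bytes", offset)
  xlen <- rd_u16(hdr, 10L)
  full_hdr <- if (xlen > 6L) src_read(src, offset, 12L + xlen) else hdr
  bsize <- bgzf_bsize(full_hdr, xlen)
  if (is.na(bsize) || bsize < 26L || bsize > 65536L)
    stop_with("bgzf_malformed_error",
              "block at offset %.0f lacks a valid BC size subfield", offset)
  block <- src_read(src, offset, bsize)
  if (length(block) < bsize)
    stop_with("bgzf_truncated_error",
              "block at offset %.0f declares %d bytes but file ends early",
              offset, bsize)
  payload <- tryCatch(
    memDecompress(block, type = "gzip"),
    error = function(e) stop_with("bgzf_corruption_error",
                                  "block at offset %.0f failed to decompress (CRC or stream error)",
                                  offset))
  isize <- rd_u32d(block, bsize - 4L)
  if (length(payload) != isize)
    stop_with("bgzf_corruption_error",
              "block at offset %.0f: stored length %.0f != decompressed length %d",
              offset, isize, length(payload))
  structure(list(coffset = as.numeric(offset), csize = bsize,
                 payload = payload),
            class = "bgzf_block")
}

#' Pack / unpack BGZF virtual offsets
#'
#' A virtual offset addresses a decompressed byte as (compressed offset of
#' its block, offset within the block's payload), packed as
#' `coffset * 2^16 + uoffset`. The packed scalar is stored in an R double and
#' is exact while `coffset < 2^37` (compressed files up to 128 GiB); larger
#' component values are rejected rather than silently rounded.
#'
#' @param coffset Compressed-file offset(s) of the containing block.
#' @param uoffset Offset(s) within the decompressed payload, `< 2^16`.
#' @return `voff_pack`: numeric packed offset(s); `voff_unpack`: a list with
#'   components `coffset` and `uoffset`.
#' @export
voff_pack <- function(coffset, uoffset) {
  coffset <- as.numeric(coffset); uoffset <- as.numeric(uoffset)
  if (any(coffset < 0) || any(uoffset < 0) ||
      any(uoffset >= 65536) || any(coffset >= 2^48))
    stop_with("voffset_range_error",
              "virtual offset components out of range (coffset < 2^48, uoffset < 2^16)")
  if (any(coffset >= 2^37))
    stop_with("voffset_range_error",
              "coffset >= 2^37 is not exactly representable in a double")
  coffset * 65536 + uoffset
}

#' @rdname voff_pack
#' @param v Packed virtual offset(s).
#' @export
voff_unpack <- function(v) {
  v <- as.numeric(v)
  if (any(v < 0) || any(v > 2^53))
    stop_with("voffset_range_error", "packed virtual offset out of range")
  u <- v %% 65536
  list(coffset = (v - u) / 65536, uoffset = u)
}

#' Decompress the byte range between two virtual offsets
#'
#' Returns exactly the decompressed bytes from `v_beg` (inclusive) to `v_end`
#' (exclusive). Ranges opened concurrently on one file never interfere: each
#' call decodes its own blocks independently.
#'
#' @param src Raw vector or file path.
#' @param v_beg,v_end Packed virtual offsets, `v_beg <= v_end`. A `v_end`
#'   addressing the EOF marker (or any block at/after end of data) truncates
#'   at end of data.
#' @return Raw vector of decompressed bytes.
#' @export
bgzf_read_range <- function(src, v_beg, v_end) {
  if (v_beg > v_end) stop("v_beg must be <= v_end")
  if (v_beg == v_end) return(raw(0))
  b <- voff_unpack(v_beg); e <- voff_unpack(v_end)
  total <- src_size(src)
  out <- list(); i <- 1L
  coff <- b$coffset
  skip <- b$uoffset
  repeat {
    if (coff >= total) break
    if (coff > e$coffset || (coff == e$coffset && e$uoffset == 0)) break
    blk <- bgzf_read_block(src, coff)
    p <- blk$payload
    take_to <- if (coff == e$coffset) min(e$uoffset, length(p)) else length(p)
    if (skip > length(p))
      stop_with("voffset_range_error",
                "uoffset %.0f beyond payload of block at %.0f", skip, coff)
    if (take_to > skip) {
      out[[i]] <- p[(skip + 1):take_to]
      i <- i + 1L
    }
    if (coff == e$coffset) break
    coff <- coff + blk$csize
    skip <- 0
  }
  if (length(out) == 0L) raw(0) else do.call(c, out)
}

#' Compress a byte stream into a BGZF file image
#'
#' Chunks `payload` into blocks of at most 65280 decompressed bytes (the
#' conventional margin that keeps even incompressible blocks within the
#' 65536-byte frame) and appends the EOF marker once.
#'
#' @param payload Raw vector of any length.
#' @param level Deflate level.
#' @param block_payload Maximum decompressed bytes per block.
#' @return A list with `bytes` (the file image), `block_coffsets`
#'   (0-based start offset of every block including the EOF marker),
#'   `block_usizes` (decompressed payload length per data block).
#' @export
bgzf_compress <- function(payload, level = 6L, block_payload = 65280L) {
  stopifnot(is.raw(payload), block_payload >= 1L, block_payload <= 65535L)
  n <- length(payload)
  starts <- if (n == 0L) integer(0) else seq(0L, n - 1L, by = block_payload)
  blocks <- vector("list", length(starts) + 1L)
  usizes <- integer(length(starts))
  for (k in seq_along(starts)) {
    lo <- starts[k] + 1L
    hi <- min(n, starts[k] + block_payload)
    blocks[[k]] <- bgzf_write_block(payload[lo:hi], level)
    usizes[k] <- hi - lo + 1L
  }
  blocks[[length(blocks)]] <- bgzf_eof_marker()
  csizes <- vapply(blocks, length, integer(1))
  coffs <- cumsum(c(0, csizes[-length(csizes)]))
  list(bytes = do.call(c, blocks), block_coffsets = coffs,
       block_usizes = usizes)
}

#' Decompress a whole BGZF file image
#'
#' Walks blocks from `offset` to end of data. A missing EOF marker is
#' tolerated with a warning so that truncated files remain scannable.
#'
#' @param src Raw vector or file path.
#' @param offset Starting compressed offset (default 0).
#' @return A list with `payload` (all decompressed bytes), `block_coffsets`,
#'   `block_csizes`, `block_usizes` (per data block, EOF marker excluded).
#' @export
bgzf_decompress <- function(src, offset = 0) {
  total <- src_size(src)
  coffs <- numeric(0); csz <- integer(0); usz <- integer(0)
  chunks <- list(); i <- 1L
  saw_eof <- FALSE
  coff <- as.numeric(offset)
  while (coff < total) {
    blk <- bgzf_read_block(src, coff)
    if (length(blk$payload) == 0L && blk$csize == 28L &&
        bgzf_is_eof_block(src_read(src, coff, 28L))) {
      saw_eof <- TRUE
      coff <- coff + blk$csize
      next
    }
    coffs[i] <- coff; csz[i] <- blk$csize; usz[i] <- length(blk$payload)
    chunks[[i]] <- blk$payload
    i <- i + 1L
    coff <- coff + blk$csize
  }
  if (!saw_eof)
    warning("BGZF stream ends without the EOF marker; file may be truncated")
  list(payload = if (length(chunks)) do.call(c, chunks) else raw(0),
       block_coffsets = coffs, block_csizes = csz, block_usizes = usz)
}
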