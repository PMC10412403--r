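# Low-level binary helpers. All buffer offsets in this package are 0-based
# (matching the on-disk format descriptions); conversion to R's 1-based
# indexing happens only inside these helpers.

rd_u8 <- function(buf, off) as.integer(buf[off + 1L])

rd_u16 <- function(buf, off) {
  readBin(buf[(off + 1L):(off + 2L)], "integer", size = 2L, signed = FALSE,
          endian = "little")
}

rd_i32 <- function(buf, off) {
  readBin(buf[(off + 1L):(off + 4L)], "integer", size = 4L, endian = "little")
}

# unsigned 32-bit as double (block sizes, counts)
rd_u32d <- function(buf, off) {
  x <- rd_i32(buf, off)
  if (x < 0) x + 4294967296 else as.numeric(x)
}

# unsigned 64-bit little-endian as double; exact below 2^53
rd_u64d <- function(buf, off) {
  rd_u32d(buf, off) + rd_u32d(buf, off + 4L) * 4294967296
}

# vectorised i32 reads at many 0-based offsets
rd_i32_vec <- function(buf, offs) {
  if (length(offs) == 0L) return(integer(0))
  idx <- rep(offs, each = 4L) + rep(1:4, times = length(offs))
  readBin(buf[idx], "integer", n = length(offs), size = 4L, endian = "little")
}

rd_u16_vec <- function(buf, offs) {
  if (length(offs) == 0L) return(integer(0))
  idx <- rep(offs, each = 2L) + rep(1:2, times = length(offs))
  readBin(buf[idx], "integer", n = length(offs), size = 2L, signed = FALSE,
          endian = "little")
}

wr_u8 <- function(x) as.raw(x)

wr_u16 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, x %/% 256 %% 256))
}

wr_i32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

wr_u32d <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, x %/% 256 %% 256, x %/% 65536 %% 256,
           x %/% 16777216 %% 256))
}

wr_u64d <- function(x) {
  x <- as.numeric(x)
  c(wr_u32d(x %% 4294967296), wr_u32d(x %/% 4294967296))
}

# A random-access byte source: either a raw vector (in-memory file image) or
# a file path. Fixture-scale files are small enough that path sources are
# materialised once per reader; every call is side-effect-free so concurrent
# readers never interfere.
src_bytes <- function(src) {
  if (is.raw(src)) return(src)
  if (is.character(src) && length(src) == 1L) {
    n <- file.size(src)
    if (is.na(n)) stop("cannot read file: ", src)
    return(readBin(src, raw(), n))
  }
  stop("byte source must be a raw vector or a file path")
}

src_size <- function(src) {
  if (is.raw(src)) length(src) else file.size(src)
}

src_read <- function(src, offset, n) {
  # returns up to n bytes starting at 0-based offset
  if (is.raw(src)) {
    if (offset >= length(src)) return(raw(0))
    end <- min(length(src), offset + n)
    return(src[(offset + 1):end])
  }
  con <- file(src, "rb")
  on.exit(close(con))
  seek(con, offset)
  readBin(con, raw(), n)
}

stop_with <- function(class, fmt, ...) {
  stop(structure(class = c(class, "bamscatter_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
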