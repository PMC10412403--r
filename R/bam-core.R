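# BAM binary core: header and alignment-record parsing/serialisation, flag
# constants, CIGAR and sequence codecs. All coordinates are 0-based,
# half-open internally; 1-based conversions happen only at VCF/CSV/CLI
# boundaries.

BAM_MAGIC <- as.raw(c(0x42, 0x41, 0x4d, 0x01)) # "BAM\1"

SEQ_NT16 <- strsplit("=ACMGRSVTWYHKDBN", "")[[1]]
CIGAR_OPS <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")
CIGAR_CONSUMES_REF <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE)
CIGAR_CONSUMES_QRY <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE)

#' SAM flag bit constants
#'
#' Named integer vector of the twelve SAM flag bits (PAIRED, PROPER_PAIR,
#' UNMAP, MUNMAP, REVERSE, MREVERSE, READ1, READ2, SECONDARY, QCFAIL, DUP,
#' SUPPLEMENTARY).
#' @return Named integer vector.
#' @export
bam_flags <- function() {
  c(PAIRED = 0x1L, PROPER_PAIR = 0x2L, UNMAP = 0x4L, MUNMAP = 0x8L,
    REVERSE = 0x10L, MREVERSE = 0x20L, READ1 = 0x40L, READ2 = 0x80L,
    SECONDARY = 0x100L, QCFAIL = 0x200L, DUP = 0x400L,
    SUPPLEMENTARY = 0x800L)
}
FLAGS <- c(PAIRED = 0x1L, PROPER_PAIR = 0x2L, UNMAP = 0x4L, MUNMAP = 0x8L,
           REVERSE = 0x10L, MREVERSE = 0x20L, READ1 = 0x40L, READ2 = 0x80L,
           SECONDARY = 0x100L, QCFAIL = 0x200L, DUP = 0x400L,
           SUPPLEMENTARY = 0x800L)

has_flag <- function(flag, bit) bitwAnd(flag, bit) != 0L

#' Construct a BAM header
#'
#' @param references Data frame with columns `name` (unique, non-empty) and
#'   `length` (positive integer), order defining refID numbering from 0; or
#'   NULL for an empty reference list.
#' @param text SAM header text (may be empty).
#' @return An object of class `bam_header`.
#' @export
bam_header <- function(references = NULL, text = "") {
  if (is.null(references))
    references <- data.frame(name = character(0), length = numeric(0))
  references <- as.data.frame(references)
  stopifnot(all(c("name", "length") %in% names(references)))
  references$name <- as.character(references$name)
  references$length <- as.numeric(references$length)
  if (anyDuplicated(references$name) || any(!nzchar(references$name)))
    stop("reference names must be unique and non-empty")
  if (any(references$length <= 0)) stop("reference lengths must be positive")
  structure(list(text = text, references = references), class = "bam_header")
}

#' @method print bam_header
#' @export
print.bam_header <- function(x, ...) {
  cat(sprintf("BAM header: %d reference(s), %d bytes of SAM text\n",
              nrow(x$references), nchar(x$text)))
  invisible(x)
}

n_refs <- function(header) nrow(header$references)

#' Serialise a BAM header
#'
#' @param header A `bam_header`.
#' @return Raw vector: magic, l_text, text, n_ref and the reference
#'   dictionary, in the standard binary layout.
#' @export
bam_write_header <- function(header) {
  stopifnot(inherits(header, "bam_header"))
  text <- charToRaw(header$text)
  parts <- list(BAM_MAGIC, wr_i32(length(text)), text,
                wr_i32(n_refs(header)))
  for (i in seq_len(n_refs(header))) {
    nm <- charToRaw(header$references$name[i])
    parts <- c(parts, list(wr_i32(length(nm) + 1L), nm, as.raw(0),
                           wr_i32(header$references$length[i])))
  }
  do.call(c, parts)
}

#' Parse a BAM header from a decompressed byte stream
#'
#' @param buf Raw vector beginning with the BAM magic.
#' @return List with `header` (a `bam_header`) and `bytes_consumed`, the
#'   decompressed-stream offset of the first alignment record.
#' @export
bam_read_header <- function(buf) {
  if (length(buf) < 4L || any(buf[1:4] != BAM_MAGIC))
    stop_with("not_a_bam_error", "stream does not begin with the BAM magic")
  if (length(buf) < 8L)
    stop_with("bam_truncation_error", "header truncated before l_text")
  l_text <- rd_i32(buf, 4L)
  off <- 8L
  if (l_text < 0 || off + l_text + 4L > length(buf))
    stop_with("bam_truncation_error", "declared SAM text exceeds available data")
  traw <- if (l_text > 0) buf[(off + 1L):(off + l_text)] else raw(0)
  while (length(traw) && traw[length(traw)] == as.raw(0))
    traw <- traw[-length(traw)]
  text <- rawToChar(traw)
  off <- off + l_text
  nref <- rd_i32(buf, off); off <- off + 4L
  nm <- character(nref); ln <- numeric(nref)
  for (i in seq_len(nref)) {
    if (off + 4L > length(buf))
      stop_with("bam_truncation_error", "reference dictionary truncated")
    l_name <- rd_i32(buf, off); off <- off + 4L
    if (l_name < 1 || off + l_name + 4L > length(buf))
      stop_with("bam_truncation_error", "reference name exceeds available data")
    nm[i] <- rawToChar(buf[(off + 1L):(off + l_name - 1L)])
    off <- off + l_name
    ln[i] <- rd_i32(buf, off); off <- off + 4L
  }
  list(header = bam_header(data.frame(name = nm, length = ln), text = text),
       bytes_consumed = off)
}

#' Construct an alignment record
#'
#' @param read_name Query name, 1-254 characters.
#' @param flag Unsigned 16-bit SAM flag.
#' @param refID 0-based reference index, -1 for unplaced.
#' @param pos0 0-based leftmost coordinate, -1 for unplaced.
#' @param mapq Mapping quality 0-255.
#' @param cigar List with components `op` (characters from MIDNSHP=X) and
#'   `len` (positive integers), or NULL for no CIGAR.
#' @param seq Character string over the 16-letter nibble alphabet.
#' @param qual Integer vector of per-base qualities (0-255) of the same
#'   length as `seq`, or NULL for absent (stored as 0xFF fill).
#' @param next_refID,next_pos0 Mate coordinates (-1 when absent).
#' @param tlen Signed template length.
#' @param tags Opaque raw vector of auxiliary data (never decoded).
#' @return An object of class `bam_record`.
#' @export
bam_record <- function(read_name, flag = 0L, refID = -1L, pos0 = -1L,
                       mapq = 0L, cigar = NULL, seq = "", qual = NULL,
                       next_refID = -1L, next_pos0 = -1L, tlen = 0L,
                       tags = raw(0)) {
  if (is.null(cigar)) cigar <- list(op = character(0), len = integer(0))
  cigar$op <- as.character(cigar$op); cigar$len <- as.integer(cigar$len)
  if (nchar(read_name) < 1L || nchar(read_name) > 254L)
    stop_with("bam_size_error", "read name must be 1-254 characters")
  if (!is.null(qual) && length(qual) != nchar(seq))
    stop_with("bam_consistency_error", "qual length must equal seq length")
  if (refID == -1L && pos0 != -1L)
    stop("refID -1 requires pos0 -1")
  structure(list(refID = as.integer(refID), pos0 = as.integer(pos0),
                 mapq = as.integer(mapq), flag = as.integer(flag),
                 read_name = read_name, cigar = cigar, seq = seq,
                 qual = if (is.null(qual)) NULL else as.integer(qual),
                 next_refID = as.integer(next_refID),
                 next_pos0 = as.integer(next_pos0), tlen = as.integer(tlen),
                 tags = tags),
            class = "bam_record")
}

#' @method print bam_record
#' @export
print.bam_record <- function(x, ...) {
  cat(sprintf("bam_record %s flag=%d refID=%d pos0=%d mapq=%d cigar=%s\n",
              x$read_name, x$flag, x$refID, x$pos0, x$mapq,
              if (length(x$cigar$op)) paste0(x$cigar$len, x$cigar$op, collapse = "")
              else "*"))
  invisible(x)
}

#' Reference span of a CIGAR
#'
#' Sum of the lengths of operations that consume the reference
#' (M, D, N, =, X).
#' @param cigar List with `op` and `len` components.
#' @return Non-negative integer.
#' @export
cigar_reference_span <- function(cigar) {
  if (length(cigar$op) == 0L) return(0L)
  codes <- match(cigar$op, CIGAR_OPS)
  if (anyNA(codes)) stop("invalid CIGAR op")
  sum(cigar$len[CIGAR_CONSUMES_REF[codes]])
}

#' Half-open alignment end of a mapped record
#'
#' `pos0 + reference_span`, with zero-span mapped records (empty CIGAR)
#' treated as spanning one base so they never vanish from window assignment.
#' @param r A `bam_record`.
#' @return Integer half-open end coordinate.
#' @export
bam_end_pos0 <- function(r) {
  if (r$refID < 0L || r$pos0 < 0L)
    stop_with("undefined_coordinate_error",
              "end position undefined for unplaced record '%s'", r$read_name)
  r$pos0 + max(1L, cigar_reference_span(r$cigar))
}

#' 4-bit sequence codec
#'
#' Encodes characters of the 16-letter nibble alphabet two bases per byte
#' (high nibble first); `bam_decode_seq` is the inverse.
#' @param s Character string over `=ACMGRSVTWYHKDBN`.
#' @return `bam_encode_seq`: raw vector of `ceiling(nchar(s)/2)` bytes.
#' @export
bam_encode_seq <- function(s) {
  if (nchar(s) == 0L) return(raw(0))
  nib <- match(strsplit(s, "")[[1]], SEQ_NT16) - 1L
  if (anyNA(nib))
    stop_with("bam_alphabet_error", "sequence contains characters outside =ACMGRSVTWYHKDBN")
  if (length(nib) %% 2L == 1L) nib <- c(nib, 0L)
  hi <- nib[seq(1L, length(nib), by = 2L)]
  lo <- nib[seq(2L, length(nib), by = 2L)]
  as.raw(hi * 16L + lo)
}

#' @rdname bam_encode_seq
#' @param packed Raw vector of packed nibbles.
#' @param l_seq Number of bases encoded.
#' @export
bam_decode_seq <- function(packed, l_seq) {
  if (l_seq == 0L) return("")
  v <- as.integer(packed)
  hi <- v %/% 16L; lo <- v %% 16L
  nib <- as.vector(rbind(hi, lo))[seq_len(l_seq)]
  paste(SEQ_NT16[nib + 1L], collapse = "")
}

#' Serialise one alignment record
#'
#' Standard binary layout; the `bin` field is recomputed from the record's
#' coordinates rather than stored, so written files are always internally
#' consistent for indexing.
#' @param r A `bam_record`.
#' @param header The `bam_header` the record belongs to.
#' @return Raw vector of `block_size + 4` bytes.
#' @export
bam_write_record <- function(r, header) {
  if (nchar(r$read_name) > 254L)
    stop_with("bam_size_error", "read name longer than 254 characters")
  if (!is.null(r$qual) && length(r$qual) != nchar(r$seq))
    stop_with("bam_consistency_error", "qual length must equal seq length")
  if (r$refID >= n_refs(header))
    stop_with("bam_invalid_record_error", "refID %d out of range", r$refID)
  l_seq <- nchar(r$seq)
  name <- c(charToRaw(r$read_name), as.raw(0))
  ncig <- length(r$cigar$op)
  codes <- if (ncig) match(r$cigar$op, CIGAR_OPS) - 1L else integer(0)
  if (anyNA(codes)) stop("invalid CIGAR op")
  cig <- if (ncig) {
    words <- as.numeric(r$cigar$len) * 16 + codes
    do.call(c, lapply(words, wr_u32d))
  } else raw(0)
  bin <- if (r$pos0 >= 0L) reg2bin(r$pos0, bam_end_pos0(r)) else 4680L
  qual <- if (is.null(r$qual)) rep(255L, l_seq) else r$qual
  body <- c(wr_i32(r$refID), wr_i32(r$pos0),
            wr_u8(length(name)), wr_u8(r$mapq), wr_u16(bin),
            wr_u16(ncig), wr_u16(r$flag), wr_i32(l_seq),
            wr_i32(r$next_refID), wr_i32(r$next_pos0), wr_i32(r$tlen),
            name, cig, bam_encode_seq(r$seq), as.raw(qual), r$tags)
  c(wr_i32(length(body)), body)
}

#' Parse one alignment record from a decompressed buffer
#'
#' @param buf Raw vector holding the full record.
#' @param offset 0-based offset of the record's block_size field.
#' @param header The `bam_header` of the stream.
#' @return List with `record` (a `bam_record`) and `bytes_consumed`
#'   (`block_size + 4`).
#' @export
bam_parse_record <- function(buf, offset = 0, header) {
  if (offset + 36L > length(buf))
    stop_with("bam_invalid_record_error",
              "buffer truncated at offset %.0f (need fixed fields)", offset)
  block_size <- rd_i32(buf, offset)
  if (block_size < 32L || offset + 4L + block_size > length(buf))
    stop_with("bam_invalid_record_error",
              "record at offset %.0f truncated or block_size invalid", offset)
  o <- offset + 4L
  refID <- rd_i32(buf, o)
  pos0 <- rd_i32(buf, o + 4L)
  if (refID >= n_refs(header))
    stop_with("bam_invalid_record_error", "refID %d exceeds reference count", refID)
  l_read_name <- rd_u8(buf, o + 8L)
  mapq <- rd_u8(buf, o + 9L)
  ncig <- rd_u16(buf, o + 12L)
  flag <- rd_u16(buf, o + 14L)
  l_seq <- rd_i32(buf, o + 16L)
  next_refID <- rd_i32(buf, o + 20L)
  next_pos0 <- rd_i32(buf, o + 24L)
  tlen <- rd_i32(buf, o + 28L)
  need <- 32L + l_read_name + 4L * ncig + ceiling(l_seq / 2) + l_seq
  if (need > block_size)
    stop_with("bam_invalid_record_error",
              "record at offset %.0f: field lengths exceed block_size", offset)
  p <- o + 32L
  read_name <- rawToChar(buf[(p + 1L):(p + l_read_name - 1L)])
  p <- p + l_read_name
  if (ncig > 0L) {
    words <- vapply(seq_len(ncig) - 1L, function(k) rd_u32d(buf, p + 4L * k),
                    numeric(1))
    cigar <- list(op = CIGAR_OPS[(words %% 16) + 1L],
                  len = as.integer(words %/% 16))
  } else cigar <- list(op = character(0), len = integer(0))
  p <- p + 4L * ncig
  nsb <- as.integer(ceiling(l_seq / 2))
  seq <- if (l_seq > 0L) bam_decode_seq(buf[(p + 1L):(p + nsb)], l_seq) else ""
  p <- p + nsb
  qual <- if (l_seq > 0L) as.integer(buf[(p + 1L):(p + l_seq)]) else integer(0)
  p <- p + l_seq
  tag_len <- offset + 4L + block_size - p
  tags <- if (tag_len > 0L) buf[(p + 1L):(p + tag_len)] else raw(0)
  rec <- structure(list(refID = refID, pos0 = pos0, mapq = mapq,
                        flag = flag, read_name = read_name, cigar = cigar,
                        seq = seq,
                        qual = if (l_seq > 0L) qual else NULL,
                        next_refID = next_refID, next_pos0 = next_pos0,
                        tlen = tlen, tags = tags),
                   class = "bam_record")
  list(record = rec, bytes_consumed = block_size + 4L)
}

#' Parse all records in a decompressed buffer
#'
#' Chains `bam_parse_record` from `offset` to the end of `buf`; the buffer
#' must end exactly at a record boundary.
#' @param buf Raw vector of concatenated records.
#' @param header The `bam_header`.
#' @param offset 0-based starting offset.
#' @param with_offsets If TRUE, attach the 0-based in-buffer start offset of
#'   each record as attribute `offsets`.
#' @return List of `bam_record`s.
#' @export
bam_parse_records <- function(buf, header, offset = 0, with_offsets = FALSE) {
  recs <- list(); offs <- numeric(0); i <- 1L
  o <- as.numeric(offset)
  n <- length(buf)
  while (o < n) {
    pr <- bam_parse_record(buf, o, header)
    recs[[i]] <- pr$record
    if (with_offsets) offs[i] <- o
    o <- o + pr$bytes_consumed
    i <- i + 1L
  }
  if (with_offsets) attr(recs, "offsets") <- offs
  recs
}

# Fast path: extract just the fields flagstat and window assignment need
# from a buffer of concatenated records. Returns a data.frame.
bam_scan_fixed <- function(buf, header, offset = 0) {
  n <- length(buf)
  offs <- numeric(0); i <- 1L
  o <- as.numeric(offset)
  while (o + 4L <= n) {
    bs <- rd_i32(buf, o)
    if (bs < 32L || o + 4L + bs > n)
      stop_with("bam_invalid_record_error",
                "record at offset %.0f truncated or block_size invalid", o)
    offs[i] <- o; i <- i + 1L
    o <- o + bs + 4L
  }
  if (o != n)
    stop_with("bam_invalid_record_error", "trailing bytes after last record")
  offs <- offs
  data.frame(
    offset = offs,
    refID = rd_i32_vec(buf, offs + 4L),
    pos0 = rd_i32_vec(buf, offs + 8L),
    mapq = rd_u8_vec(buf, offs + 13L),
    flag = rd_u16_vec(buf, offs + 18L),
    next_refID = rd_i32_vec(buf, offs + 24L)
  )
}

rd_u8_vec <- function(buf, offs) as.integer(buf[offs + 1L])
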