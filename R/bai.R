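# BAI index: hierarchical bins of chunk intervals plus the 16-kb linear
# ("fixed-bin") index whose per-window start offsets drive parallel
# partitioning. Virtual offsets are carried as packed doubles throughout.

BAI_MAGIC <- as.raw(c(0x42, 0x41, 0x49, 0x01)) # "BAI\1"
LINEAR_WINDOW <- 16384L
PSEUDO_BIN <- 37450L

#' Smallest BAI bin fully containing an interval
#'
#' Standard 5-level binning of [0, 2^29).
#' @param beg0 0-based inclusive start.
#' @param end0 0-based half-open end, `beg0 < end0 <= 2^29`.
#' @return Integer bin id.
#' @export
reg2bin <- function(beg0, end0) {
  if (beg0 < 0 || end0 <= beg0 || end0 > 2^29)
    stop_with("bai_range_error", "interval [%.0f,%.0f) out of range", beg0, end0)
  end <- end0 - 1
  if (beg0 %/% 2^14 == end %/% 2^14) return(as.integer(4681 + beg0 %/% 2^14))
  if (beg0 %/% 2^17 == end %/% 2^17) return(as.integer(585 + beg0 %/% 2^17))
  if (beg0 %/% 2^20 == end %/% 2^20) return(as.integer(73 + beg0 %/% 2^20))
  if (beg0 %/% 2^23 == end %/% 2^23) return(as.integer(9 + beg0 %/% 2^23))
  if (beg0 %/% 2^26 == end %/% 2^26) return(as.integer(1 + beg0 %/% 2^26))
  0L
}

# All bins that may contain records overlapping [beg0, end0)
reg2bins <- function(beg0, end0) {
  end <- end0 - 1
  c(0L,
    (1L + beg0 %/% 2^26):(1L + end %/% 2^26),
    (9L + beg0 %/% 2^23):(9L + end %/% 2^23),
    (73L + beg0 %/% 2^20):(73L + end %/% 2^20),
    (585L + beg0 %/% 2^17):(585L + end %/% 2^17),
    (4681L + beg0 %/% 2^14):(4681L + end %/% 2^14))
}

empty_ref_index <- function() {
  list(bins = list(), linear = numeric(0),
       stats = c(off_beg = NA_real_, off_end = NA_real_,
                 n_mapped = 0, n_unmapped = 0))
}

#' Build a BAI index from records in file order
#'
#' @param info Data frame with one row per record in file order: `refID`,
#'   `pos0`, `end0` (half-open alignment end; ignored for refID -1), `vbeg`
#'   and `vend` (packed virtual offsets of the record's start and of the
#'   next record's start).
#' @param header The `bam_header` of the file.
#' @return An object of class `bai_index`. Records with refID -1 are not
#'   indexed (only counted in `n_no_coor`); they remain reachable through
#'   the boundary scanner.
#' @export
build_bai <- function(info, header) {
  nref <- n_refs(header)
  placed <- info[info$refID >= 0L, , drop = FALSE]
  if (nrow(placed) > 1L) {
    dr <- diff(placed$refID)
    dp <- diff(placed$pos0)
    if (any(dr < 0) || any(dp[dr == 0] < 0))
      stop_with("bai_unsorted_error",
                "records are not coordinate-sorted (refID, then pos0)")
  }
  refs <- replicate(nref, empty_ref_index(), simplify = FALSE)
  for (r in seq_len(nref) - 1L) {
    sub <- placed[placed$refID == r, , drop = FALSE]
    if (nrow(sub) == 0L) next
    ri <- empty_ref_index()
    nwin <- (max(sub$end0) - 1L) %/% LINEAR_WINDOW + 1L
    linear <- rep(NA_real_, nwin)
    bins <- new.env(parent = emptyenv())
    for (k in seq_len(nrow(sub))) {
      b <- as.character(reg2bin(sub$pos0[k], sub$end0[k]))
      ch <- if (exists(b, bins)) get(b, bins) else NULL
      if (!is.null(ch) && ch[nrow(ch), 2L] == sub$vbeg[k]) {
        ch[nrow(ch), 2L] <- sub$vend[k]
      } else {
        ch <- rbind(ch, c(sub$vbeg[k], sub$vend[k]))
      }
      assign(b, ch, bins)
      w <- (sub$pos0[k] %/% LINEAR_WINDOW):((sub$end0[k] - 1L) %/% LINEAR_WINDOW)
      upd <- w + 1L
      linear[upd] <- pmin(linear[upd], sub$vbeg[k], na.rm = TRUE)
    }
    bl <- as.list(bins)
    ri$bins <- bl[order(as.numeric(names(bl)))]
    ri$linear <- linear
    unm <- bitwAnd(if ("flag" %in% names(sub)) sub$flag else integer(nrow(sub)),
                   FLAGS[["UNMAP"]]) != 0L
    ri$stats <- c(off_beg = min(sub$vbeg), off_end = max(sub$vend),
                  n_mapped = sum(!unm), n_unmapped = sum(unm))
    refs[[r + 1L]] <- ri
  }
  structure(list(refs = refs, n_no_coor = sum(info$refID < 0L)),
            class = "bai_index")
}

#' @method print bai_index
#' @export
print.bai_index <- function(x, ...) {
  nb <- vapply(x$refs, function(r) length(r$bins), integer(1))
  cat(sprintf("BAI index: %d reference(s), %d bin(s), n_no_coor=%.0f\n",
              length(x$refs), sum(nb), x$n_no_coor))
  invisible(x)
}

# fill linear-index gaps: empty windows take the next non-empty window's
# offset; trailing gaps take the last non-empty value (0 if none)
fill_linear <- function(linear) {
  if (length(linear) == 0L) return(linear)
  filled <- rev(cummin_na(rev(linear)))
  last <- max(c(0, linear[!is.na(linear)]))
  filled[is.na(filled)] <- last
  filled
}

cummin_na <- function(x) {
  out <- x; cur <- NA_real_
  for (i in seq_along(x)) {
    if (!is.na(x[i])) cur <- if (is.na(cur)) x[i] else min(cur, x[i])
    else out[i] <- cur
  }
  out
}

#' Write a BAI index to a file
#'
#' Emits the standard layout including the 37450 pseudo-bin carrying
#' mapped/unmapped counts per reference and the trailing n_no_coor count.
#' @param index A `bai_index`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_bai <- function(index, path) {
  parts <- list(BAI_MAGIC, wr_i32(length(index$refs)))
  for (ri in index$refs) {
    bins <- ri$bins
    has_stats <- !is.na(ri$stats[["off_beg"]])
    nbin <- length(bins) + as.integer(has_stats)
    parts <- c(parts, list(wr_i32(nbin)))
    for (b in names(bins)[order(as.numeric(names(bins)))]) {
      ch <- bins[[b]]
      parts <- c(parts, list(wr_u32d(as.numeric(b)), wr_i32(nrow(ch))))
      for (k in seq_len(nrow(ch)))
        parts <- c(parts, list(wr_u64d(ch[k, 1L]), wr_u64d(ch[k, 2L])))
    }
    if (has_stats) {
      parts <- c(parts, list(wr_u32d(PSEUDO_BIN), wr_i32(2L),
                             wr_u64d(ri$stats[["off_beg"]]),
                             wr_u64d(ri$stats[["off_end"]]),
                             wr_u64d(ri$stats[["n_mapped"]]),
                             wr_u64d(ri$stats[["n_unmapped"]])))
    }
    lin <- fill_linear(ri$linear)
    parts <- c(parts, list(wr_i32(length(lin))))
    if (length(lin))
      parts <- c(parts, lapply(lin, wr_u64d))
  }
  parts <- c(parts, list(wr_u64d(index$n_no_coor)))
  writeBin(do.call(c, parts), path)
  invisible(path)
}

#' Read a BAI index file
#'
#' The 37450 pseudo-bin, when present, is stored as per-reference metadata
#' and never participates in queries. Linear arrays read from disk are
#' treated as gap-filled (window emptiness is not recoverable from the
#' format).
#' @param path Path to a `.bai` file, or a raw vector.
#' @return A `bai_index`.
#' @export
read_bai <- function(path) {
  buf <- src_bytes(path)
  if (length(buf) < 8L || any(buf[1:4] != BAI_MAGIC))
    stop_with("not_a_bai_error", "file does not begin with the BAI magic")
  need <- function(k, o) if (o + k > length(buf))
    stop_with("bai_truncation_error", "BAI structure truncated at offset %.0f", o)
  o <- 4L
  nref <- rd_i32(buf, o); o <- o + 4L
  refs <- vector("list", nref)
  for (r in seq_len(nref)) {
    ri <- empty_ref_index()
    need(4L, o); nbin <- rd_i32(buf, o); o <- o + 4L
    bins <- list()
    for (j in seq_len(nbin)) {
      need(8L, o)
      bin_id <- rd_u32d(buf, o); nch <- rd_i32(buf, o + 4L); o <- o + 8L
      need(16L * nch, o)
      ch <- matrix(0, nrow = nch, ncol = 2L)
      for (k in seq_len(nch)) {
        ch[k, 1L] <- rd_u64d(buf, o); ch[k, 2L] <- rd_u64d(buf, o + 8L)
        o <- o + 16L
      }
      if (bin_id == PSEUDO_BIN) {
        if (nch >= 2L)
          ri$stats <- c(off_beg = ch[1L, 1L], off_end = ch[1L, 2L],
                        n_mapped = ch[2L, 1L], n_unmapped = ch[2L, 2L])
      } else {
        bins[[as.character(bin_id)]] <- ch
      }
    }
    ri$bins <- bins
    need(4L, o); nintv <- rd_i32(buf, o); o <- o + 4L
    need(8L * nintv, o)
    lin <- numeric(nintv)
    for (k in seq_len(nintv)) { lin[k] <- rd_u64d(buf, o); o <- o + 8L }
    ri$linear <- lin
    refs[[r]] <- ri
  }
  n_no_coor <- if (o + 8L <= length(buf)) rd_u64d(buf, o) else 0
  structure(list(refs = refs, n_no_coor = n_no_coor), class = "bai_index")
}

#' Per-window start offsets from the linear index
#'
#' One entry per non-empty 16-kb window of a reference; offsets are
#' non-decreasing. For indices read from disk, where gap-filling has erased
#' emptiness, runs of equal offsets collapse to their last window.
#' @param index A `bai_index`.
#' @param ref 0-based reference index.
#' @return Data frame with `window` (0-based window index) and `voffset`
#'   (packed virtual offset).
#' @export
window_start_offsets <- function(index, ref) {
  ri <- index$refs[[ref + 1L]]
  lin <- ri$linear
  if (length(lin) == 0L)
    return(data.frame(window = integer(0), voffset = numeric(0)))
  if (anyNA(lin)) {
    keep <- which(!is.na(lin))
  } else {
    keep <- which(c(diff(lin) != 0, TRUE))
  }
  data.frame(window = keep - 1L, voffset = lin[keep])
}

#' Chunks of a region query
#'
#' Candidate chunks from all bins overlapping `[beg0, end0)`, pruned by the
#' linear-index lower bound, sorted and merged when overlapping or adjacent.
#' Reading the returned chunks and filtering by overlap yields exactly the
#' records overlapping the region.
#' @param index A `bai_index`.
#' @param ref 0-based reference index.
#' @param beg0,end0 0-based half-open region.
#' @return Matrix with columns `vbeg`, `vend` (packed virtual offsets).
#' @export
query_chunks <- function(index, ref, beg0, end0) {
  if (beg0 < 0 || end0 <= beg0)
    stop_with("bai_range_error", "invalid region [%.0f,%.0f)", beg0, end0)
  emptym <- matrix(numeric(0), ncol = 2L,
                   dimnames = list(NULL, c("vbeg", "vend")))
  if (ref < 0L || ref >= length(index$refs)) return(emptym)
  ri <- index$refs[[ref + 1L]]
  if (length(ri$bins) == 0L) return(emptym)
  cand <- reg2bins(beg0, min(end0, 2^29))
  chs <- ri$bins[as.character(cand)]
  chs <- chs[!vapply(chs, is.null, logical(1))]
  if (length(chs) == 0L) return(emptym)
  m <- do.call(rbind, chs)
  lin <- fill_linear(ri$linear)
  w <- beg0 %/% LINEAR_WINDOW + 1L
  min_off <- if (w <= length(lin) && !is.na(lin[w])) lin[w] else
    if (length(lin) && w > length(lin)) lin[length(lin)] else 0
  m <- m[m[, 2L] > min_off, , drop = FALSE]
  if (nrow(m) == 0L) return(emptym)
  m[, 1L] <- pmax(m[, 1L], min_off)
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  out <- matrix(0, nrow = 0L, ncol = 2L)
  cur <- m[1L, ]
  for (k in seq_len(nrow(m))[-1L]) {
    if (m[k, 1L] <= cur[2L]) cur[2L] <- max(cur[2L], m[k, 2L])
    else { out <- rbind(out, cur); cur <- m[k, ] }
  }
  out <- rbind(out, cur)
  colnames(out) <- c("vbeg", "vend")
  out
}

#' Records overlapping a region, via the index
#'
#' @param src BAM file image or path.
#' @param index A `bai_index`.
#' @param header The file's `bam_header`.
#' @param ref 0-based reference index.
#' @param beg0,end0 0-based half-open region.
#' @return List of `bam_record`s overlapping the region, in file order.
#' @export
bai_query_records <- function(src, index, header, ref, beg0, end0) {
  ch <- query_chunks(index, ref, beg0, end0)
  out <- list()
  for (k in seq_len(nrow(ch))) {
    buf <- bgzf_read_range(src, ch[k, 1L], ch[k, 2L])
    recs <- bam_parse_records(buf, header)
    keep <- vapply(recs, function(r) {
      r$refID == ref && r$pos0 < end0 && r$pos0 >= 0 &&
        r$pos0 + max(1L, cigar_reference_span(r$cigar)) > beg0
    }, logical(1))
    out <- c(out, recs[keep])
  }
  out
}

#' Compressed bytes spanned by a region
#'
#' Sum over the region's merged chunks of the compressed-offset distance
#' `coffset(vend) - coffset(vbeg)`: a monotone estimate of the compressed
#' data a job covering the region must read, used for job sizing.
#' @inheritParams query_chunks
#' @return Non-negative number of compressed bytes.
#' @export
span_compressed_bytes <- function(index, ref, beg0, end0) {
  ch <- query_chunks(index, ref, beg0, end0)
  if (nrow(ch) == 0L) return(0)
  sum(voff_unpack(ch[, 2L])$coffset - voff_unpack(ch[, 1L])$coffset)
}
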