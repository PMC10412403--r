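# Windowed, mergeable flagstat: per-window flag counters under samtools
# category semantics, gathered by plain summation, formatted as the classic
# "N1 + N2 <category>" report.

FLAGSTAT_FIELDS <- c("total", "secondary", "supplementary", "duplicates",
                     "mapped", "paired_in_sequencing", "read1", "read2",
                     "properly_paired", "with_mate_mapped", "singletons",
                     "mate_diff_ref", "mate_diff_ref_mapq_ge5")

#' Empty flag-statistics accumulator
#'
#' Thirteen integer counters, kept separately for QC-pass and QC-fail
#' records (split on the QCFAIL bit). Merging accumulators is componentwise
#' addition: commutative, associative, with this zero as identity.
#' @return An object of class `flag_counts`: a 2 x 13 numeric matrix with
#'   rows `pass`, `fail`.
#' @export
flag_counts <- function() {
  m <- matrix(0, nrow = 2L, ncol = length(FLAGSTAT_FIELDS),
              dimnames = list(c("pass", "fail"), FLAGSTAT_FIELDS))
  structure(m, class = c("flag_counts", "matrix", "array"))
}

#' Merge two accumulators
#'
#' @param a,b `flag_counts` objects.
#' @return Their componentwise sum.
#' @export
merge_counts <- function(a, b) {
  out <- unclass(a) + unclass(b)
  structure(out, class = c("flag_counts", "matrix", "array"))
}

# Vectorised tally of many records. Mirrors samtools flagstat semantics:
# mapped excludes UNMAP; secondary/supplementary records are excluded from
# every pairing-related counter; properly paired requires
# PAIRED & PROPER_PAIR & !UNMAP; mate-diff-ref requires both ends mapped.
tally_flags <- function(flag, refID, next_refID, mapq) {
  f <- flag_counts()
  for (side in 1:2) {
    sel <- if (side == 1L) !has_flag(flag, FLAGS[["QCFAIL"]])
           else has_flag(flag, FLAGS[["QCFAIL"]])
    fl <- flag[sel]; ri <- refID[sel]; nri <- next_refID[sel]; mq <- mapq[sel]
    sec <- has_flag(fl, FLAGS[["SECONDARY"]])
    sup <- has_flag(fl, FLAGS[["SUPPLEMENTARY"]])
    prim <- !sec & !sup
    unmap <- has_flag(fl, FLAGS[["UNMAP"]])
    munmap <- has_flag(fl, FLAGS[["MUNMAP"]])
    paired <- has_flag(fl, FLAGS[["PAIRED"]]) & prim
    both <- paired & !unmap & !munmap
    diffref <- both & nri != ri & nri >= 0L & ri >= 0L
    f[side, ] <- c(
      total = length(fl),
      secondary = sum(sec),
      supplementary = sum(sup),
      duplicates = sum(has_flag(fl, FLAGS[["DUP"]])),
      mapped = sum(!unmap),
      paired_in_sequencing = sum(paired),
      read1 = sum(paired & has_flag(fl, FLAGS[["READ1"]])),
      read2 = sum(paired & has_flag(fl, FLAGS[["READ2"]])),
      properly_paired = sum(paired & has_flag(fl, FLAGS[["PROPER_PAIR"]]) & !unmap),
      with_mate_mapped = sum(both),
      singletons = sum(paired & !unmap & munmap),
      mate_diff_ref = sum(diffref),
      mate_diff_ref_mapq_ge5 = sum(diffref & mq >= 5L))
  }
  f
}

#' Count one record into an accumulator
#'
#' @param c A `flag_counts`.
#' @param r A `bam_record`.
#' @return The updated `flag_counts`.
#' @export
count_record <- function(c, r) {
  merge_counts(c, tally_flags(r$flag, r$refID, r$next_refID, r$mapq))
}

#' Flag statistics of a whole BAM, computed in parallel windows
#'
#' With an index, per-reference interval jobs count records whose alignment
#' start falls inside them (one count per record, boundary reads in the
#' earlier window) and the unplaced tail is covered by scanner segments;
#' without one, the whole file is partitioned by the boundary scanner. The
#' result is identical for every `n_threads`.
#'
#' @param bam Path to a BAM file (or raw file image).
#' @param n_threads Worker count.
#' @param use_index Use `<bam>.bai` when present; scanner fallback
#'   otherwise.
#' @param index Optional pre-loaded `bai_index`.
#' @return A `flag_counts`.
#' @export
flagstat <- function(bam, n_threads = 1L, use_index = TRUE, index = NULL) {
  src <- src_bytes(bam)
  head_inf <- inflate_forward(src, 0, 2^20)
  hp <- bam_read_header(head_inf$payload)
  header <- hp$header
  if (use_index && is.null(index) && is.character(bam)) {
    bai_path <- paste0(bam, ".bai")
    if (!file.exists(bai_path))
      bai_path <- sub("\\.bam$", ".bai", bam)
    if (file.exists(bai_path)) index <- read_bai(bai_path)
  }
  n_jobs <- max(1L, 4L * n_threads)
  if (use_index && !is.null(index)) {
    windows <- make_windows(header)
    groups <- group_windows(windows, n_jobs)
    jobs <- lapply(seq_along(groups), function(i)
      list(ordinal = i - 1L, kind = "windows", windows = groups[[i]]))
    # unplaced tail: records after the last indexed chunk (first record
    # when nothing is indexed, e.g. an all-unplaced file)
    first_v <- payload_offset_to_voffset(hp$bytes_consumed,
                                         head_inf$coffsets, head_inf$usizes)
    tail_v <- max(c(first_v, unlist(lapply(index$refs, function(ri)
      unlist(lapply(ri$bins, function(ch) ch[, 2L]))))))
    jobs <- c(jobs, list(list(ordinal = length(jobs), kind = "tail",
                              from_v = tail_v)))
    worker <- function(job) {
      if (job$kind == "windows") {
        w <- job$windows
        f <- flag_counts()
        for (ref in unique(w$ref)) {
          sub <- w[w$ref == ref, , drop = FALSE]
          beg0 <- min(sub$beg0); end0 <- max(sub$end0)
          ch <- query_chunks(index, ref, beg0, end0)
          for (k in seq_len(nrow(ch))) {
            buf <- bgzf_read_range(src, ch[k, 1L], ch[k, 2L])
            fx <- bam_scan_fixed(buf, header)
            # start-based assignment: count only records starting in span
            fx <- fx[fx$refID == ref & fx$pos0 >= beg0 & fx$pos0 < end0, ]
            if (nrow(fx))
              f <- merge_counts(f, tally_flags(fx$flag, fx$refID,
                                               fx$next_refID, fx$mapq))
          }
        }
        f
      } else {
        tail_flagstat(src, header, job$from_v)
      }
    }
    run_scatter_gather(jobs, worker, merge_counts, n_threads,
                       init = flag_counts())
  } else {
    hits <- scan_start_points(src, n_jobs, header)
    bounds <- c(hits$voffset, NA)
    jobs <- lapply(seq_len(nrow(hits)), function(i)
      list(ordinal = i - 1L, v_beg = bounds[i], v_end = bounds[i + 1L]))
    worker <- function(job) {
      recs <- if (is.na(job$v_end))
        parse_segment(src, job$v_beg, NULL, header)
      else parse_segment(src, job$v_beg, job$v_end, header)
      if (length(recs) == 0L) return(flag_counts())
      tally_flags(vapply(recs, `[[`, integer(1), "flag"),
                  vapply(recs, `[[`, integer(1), "refID"),
                  vapply(recs, `[[`, integer(1), "next_refID"),
                  vapply(recs, `[[`, integer(1), "mapq"))
    }
    run_scatter_gather(jobs, worker, merge_counts, n_threads,
                       init = flag_counts())
  }
}

# tally the unplaced (refID -1) records stored after the last indexed chunk
tail_flagstat <- function(src, header, from_v) {
  if (is.na(from_v)) return(flag_counts())
  u <- voff_unpack(from_v)
  total <- src_size(src)
  if (u$coffset >= total) return(flag_counts())
  inf <- suppressWarnings(bgzf_decompress(src, u$coffset))
  buf <- inf$payload
  if (u$uoffset > 0) buf <- buf[-seq_len(u$uoffset)]
  if (length(buf) == 0L) return(flag_counts())
  recs <- bam_parse_records(buf, header)
  keep <- vapply(recs, function(r) r$refID < 0L, logical(1))
  recs <- recs[keep]
  if (length(recs) == 0L) return(flag_counts())
  tally_flags(vapply(recs, `[[`, integer(1), "flag"),
              vapply(recs, `[[`, integer(1), "refID"),
              vapply(recs, `[[`, integer(1), "next_refID"),
              vapply(recs, `[[`, integer(1), "mapq"))
}

#' Sequential single-pass flag statistics
#'
#' Reference implementation used for parity checks: one thread, one linear
#' parse of the whole file.
#' @param bam Path or raw image.
#' @return A `flag_counts`.
#' @export
flagstat_sequential <- function(bam) {
  src <- src_bytes(bam)
  inf <- suppressWarnings(bgzf_decompress(src))
  hp <- bam_read_header(inf$payload)
  fx <- bam_scan_fixed(inf$payload, hp$header, hp$bytes_consumed)
  tally_flags(fx$flag, fx$refID, fx$next_refID, fx$mapq)
}

pctfmt <- function(num, den) {
  ifelse(den == 0, "N/A", sprintf("%.2f%%", 100 * num / den))
}

#' Format flag statistics as the classic report
#'
#' One "N1 + N2 <category>" line per category in fixed order, with
#' percentage annotations for mapped, properly paired and singletons
#' ("N/A" when the denominator is zero).
#' @param c A `flag_counts`.
#' @return A single character string (lines joined by newlines).
#' @export
format_flagstat <- function(c) {
  p <- c["pass", ]; f <- c["fail", ]
  line <- function(field, label, extra = "") {
    sprintf("%.0f + %.0f %s%s", p[[field]], f[[field]], label, extra)
  }
  pct2 <- function(field, den_field) {
    sprintf(" (%s : %s)", pctfmt(p[[field]], p[[den_field]]),
            pctfmt(f[[field]], f[[den_field]]))
  }
  paste(c(
    line("total", "in total (QC-passed reads + QC-failed reads)"),
    line("secondary", "secondary"),
    line("supplementary", "supplementary"),
    line("duplicates", "duplicates"),
    line("mapped", "mapped", pct2("mapped", "total")),
    line("paired_in_sequencing", "paired in sequencing"),
    line("read1", "read1"),
    line("read2", "read2"),
    line("properly_paired", "properly paired",
         pct2("properly_paired", "paired_in_sequencing")),
    line("with_mate_mapped", "with itself and mate mapped"),
    line("singletons", "singletons",
         pct2("singletons", "paired_in_sequencing")),
    line("mate_diff_ref", "with mate mapped to a different chr"),
    line("mate_diff_ref_mapq_ge5",
         "with mate mapped to a different chr (mapQ>=5)")),
    collapse = "\n")
}

#' @method print flag_counts
#' @export
print.flag_counts <- function(x, ...) {
  cat(format_flagstat(x), "\n")
  invisible(x)
}
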