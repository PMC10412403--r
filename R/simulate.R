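# Deterministic paired-end read simulator. Emits a coordinate-sorted (or
# deliberately unsorted) BAM, its BAI, a VCF of injected variant sites, and
# exhaustive ground truth recorded during generation: block boundaries,
# per-record virtual offsets, flag tallies and per-site allele counts. The
# truth is the oracle for every other module and is never re-derived from
# the emitted bytes.
#
# There is no reference FASTA: the reference is implicit and deterministic,
# base_at(ref, pos) = ACGT[(3 pos + 7 ref) mod 4]. Variant sites replace it
# with an alternate base in a configurable fraction of overlapping reads.

SIM_BASES <- c("A", "C", "G", "T")

sim_ref_base <- function(ref_i, pos0) {
  SIM_BASES[((3 * pos0 + 7 * ref_i) %% 4) + 1L]
}

#' Simulation configuration
#'
#' Defaults emulate a small multi-chromosome shotgun experiment: three
#' references totalling 2.4 Mb, 25000 read pairs of 100 bp (about 2x
#' coverage), fragment sizes 350 +/- 50, 0.2% base errors, and small
#' fractions of duplicate, QC-fail, secondary and unmapped reads so every
#' flag category is exercised. Base qualities come from a two-level
#' alphabet (high 35, low 12) so quality-threshold tests have exact
#' expected effects.
#'
#' @param seed Integer seed; the same seed yields byte-identical output.
#' @param references Data frame with `name`, `length`.
#' @param n_read_pairs Number of fragments.
#' @param read_len Read length in bases.
#' @param fragment_mean,fragment_sd Fragment-size distribution.
#' @param base_error_rate Per-base substitution error probability.
#' @param dup_fraction,unmapped_fraction,secondary_fraction,qcfail_fraction
#'   Per-pair probabilities of the corresponding flag treatments.
#' @param variant_sites Data frame with `chrom`, `pos1`, `alt_fraction`
#'   (ref/alt bases are derived from the implicit reference), or NULL.
#' @param sorted Emit coordinate-sorted output with a BAI (TRUE) or keep
#'   generation order with no index (FALSE).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       references = data.frame(
                         name = c("chr1", "chr2", "chr3"),
                         length = c(1000000L, 800000L, 600000L)),
                       n_read_pairs = 25000L, read_len = 100L,
                       fragment_mean = 350, fragment_sd = 50,
                       base_error_rate = 0.002, dup_fraction = 0.05,
                       unmapped_fraction = 0.02, secondary_fraction = 0.02,
                       qcfail_fraction = 0.01, variant_sites = NULL,
                       sorted = TRUE) {
  probs <- c(base_error_rate, dup_fraction, unmapped_fraction,
             secondary_fraction, qcfail_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  if (!is.null(variant_sites)) {
    ok <- variant_sites$pos1 >= 1 &
      variant_sites$pos1 <= references$length[
        match(variant_sites$chrom, references$name)]
    if (anyNA(ok) || !all(ok))
      stop_with("sim_config_error", "variant site outside its reference")
    if (any(variant_sites$alt_fraction < 0 | variant_sites$alt_fraction > 1))
      stop("alt_fraction must lie in [0,1]")
  }
  structure(list(seed = as.integer(seed), references = references,
                 n_read_pairs = as.integer(n_read_pairs),
                 read_len = as.integer(read_len),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 base_error_rate = base_error_rate,
                 dup_fraction = dup_fraction,
                 unmapped_fraction = unmapped_fraction,
                 secondary_fraction = secondary_fraction,
                 qcfail_fraction = qcfail_fraction,
                 variant_sites = variant_sites, sorted = sorted),
            class = "sim_config")
}

# one simulated read: returns a bam_record-shaped list plus bookkeeping
sim_make_cigar <- function(read_len, style) {
  switch(style,
         m = list(op = "M", len = read_len),
         s = list(op = c("S", "M"), len = c(5L, read_len - 5L)),
         d = list(op = c("M", "D", "M"),
                  len = c(read_len %/% 2L, 3L, read_len - read_len %/% 2L)),
         i = list(op = c("M", "I", "M"),
                  len = c(read_len %/% 2L, 2L,
                          read_len - 2L - read_len %/% 2L)))
}

# reference positions consumed by each query base (NA for I/S), and query
# indices covering each reference position
sim_aligned_ref_pos <- function(cigar, pos0) {
  refp <- integer(0); qidx <- integer(0)
  refc <- pos0; qc <- 0L
  for (i in seq_along(cigar$op)) {
    op <- cigar$op[i]; len <- cigar$len[i]
    if (op %in% c("M", "=", "X")) {
      refp <- c(refp, refc:(refc + len - 1L))
      qidx <- c(qidx, (qc + 1L):(qc + len))
      refc <- refc + len; qc <- qc + len
    } else if (op %in% c("D", "N")) {
      refc <- refc + len
    } else if (op %in% c("I", "S")) {
      qc <- qc + len
    }
  }
  list(refp = refp, qidx = qidx)
}

#' Simulate a BAM (+BAI, +VCF) with exhaustive ground truth
#'
#' @param cfg A `sim_config`.
#' @return List with `bam` (raw file image), `bai` (raw, NULL when
#'   unsorted), `vcf` (character lines), `truth` (list: `block_boundaries`,
#'   `record_voffsets`, `flag_tallies`, `site_allele_counts`, `records`),
#'   and `header` (the `bam_header`).
#' @export
simulate_bam <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed, kind = "Mersenne-Twister")
  refs <- cfg$references
  nref <- nrow(refs)
  rl <- cfg$read_len
  header <- bam_header(refs, text = paste0(
    "@HD\tVN:1.6\tSO:", if (cfg$sorted) "coordinate" else "unsorted", "\n",
    paste0("@SQ\tSN:", refs$name, "\tLN:", refs$length, "\n", collapse = "")))

  vs <- cfg$variant_sites
  if (!is.null(vs)) {
    vs$refid <- match(vs$chrom, refs$name) - 1L
    vs$pos0 <- vs$pos1 - 1L
    vs$ref <- sim_ref_base(vs$refid, vs$pos0)
    vs$alt <- vapply(seq_len(nrow(vs)), function(i) {
      alts <- setdiff(SIM_BASES, vs$ref[i])
      alts[1L + (vs$pos0[i] %% 3L)]
    }, character(1))
  }

  np <- cfg$n_read_pairs
  recs <- list(); ri <- 1L
  truth_counts <- if (!is.null(vs))
    matrix(0L, nrow = nrow(vs), ncol = 4L,
           dimnames = list(NULL, c("R", "A", "E", "D"))) else NULL

  if (np > 0L) {
    ref_i <- sample.int(nref, np, replace = TRUE, prob = refs$length)
    frag <- pmax(rl + 10L, as.integer(round(stats::rnorm(np, cfg$fragment_mean,
                                                         cfg$fragment_sd))))
    frag <- pmin(frag, as.integer(refs$length[ref_i]))
    start0 <- vapply(seq_len(np), function(i)
      sample.int(refs$length[ref_i[i]] - frag[i] + 1L, 1L) - 1L, integer(1))
    is_dup <- stats::runif(np) < cfg$dup_fraction
    is_qcfail <- stats::runif(np) < cfg$qcfail_fraction
    u <- stats::runif(np)
    pair_kind <- ifelse(u < cfg$unmapped_fraction / 2, "unplaced",
                 ifelse(u < cfg$unmapped_fraction, "singleton", "mapped"))
    has_secondary <- stats::runif(np) < cfg$secondary_fraction
    cig_style <- sample(c("m", "s", "d", "i"), np, replace = TRUE,
                        prob = c(0.85, 0.07, 0.05, 0.03))
    proper <- abs(frag - cfg$fragment_mean) <= 4 * cfg$fragment_sd

    for (i in seq_len(np)) {
      qname <- sprintf("sim%06d", i)
      base_flag <- FLAGS[["PAIRED"]] +
        (if (is_dup[i]) FLAGS[["DUP"]] else 0L) +
        (if (is_qcfail[i]) FLAGS[["QCFAIL"]] else 0L)
      if (pair_kind[i] == "unplaced") {
        for (mate in 1:2) {
          fl <- base_flag + FLAGS[["UNMAP"]] + FLAGS[["MUNMAP"]] +
            (if (mate == 1L) FLAGS[["READ1"]] else FLAGS[["READ2"]])
          sq <- paste(sample(SIM_BASES, rl, replace = TRUE), collapse = "")
          recs[[ri]] <- list(refID = -1L, pos0 = -1L, mapq = 0L, flag = fl,
                             read_name = qname,
                             cigar = list(op = character(0), len = integer(0)),
                             seq = sq, qual = sim_quals(rl),
                             next_refID = -1L, next_pos0 = -1L, tlen = 0L,
                             end0 = NA_integer_)
          ri <- ri + 1L
        }
        next
      }
      r <- ref_i[i] - 1L
      p1 <- start0[i]
      p2 <- start0[i] + frag[i] - rl
      singleton <- pair_kind[i] == "singleton"
      pp <- proper[i] && !singleton
      for (mate in 1:2) {
        this_unmapped <- singleton && mate == 2L
        pos <- if (mate == 1L) p1 else p2
        if (this_unmapped) pos <- p1    # unmapped mate placed at its mate
        cig <- if (this_unmapped) list(op = character(0), len = integer(0))
               else sim_make_cigar(rl, if (mate == 1L) cig_style[i] else "m")
        fl <- base_flag +
          (if (mate == 1L) FLAGS[["READ1"]] else FLAGS[["READ2"]]) +
          (if (pp) FLAGS[["PROPER_PAIR"]] else 0L)
        if (this_unmapped) {
          fl <- fl + FLAGS[["UNMAP"]]
        } else {
          if (mate == 2L) fl <- fl + FLAGS[["REVERSE"]]
          if (mate == 1L && !singleton) fl <- fl + FLAGS[["MREVERSE"]]
          if (singleton && mate == 1L) fl <- fl + FLAGS[["MUNMAP"]]
        }
        gen <- sim_read_seq(r, pos, cig, rl, vs, cfg$base_error_rate)
        mapq <- if (this_unmapped) 0L else 20L + (i %% 40L)
        recs[[ri]] <- list(refID = r, pos0 = pos, mapq = mapq, flag = fl,
                           read_name = qname, cigar = cig, seq = gen$seq,
                           qual = gen$qual,
                           next_refID = r,
                           next_pos0 = if (mate == 1L) p2 else p1,
                           tlen = if (this_unmapped) 0L else
                             (if (mate == 1L) frag[i] else -frag[i]),
                           end0 = if (this_unmapped) pos + 1L else
                             pos + cigar_reference_span(cig))
        ri <- ri + 1L
      }
      if (has_secondary[i]) {
        spos <- (p1 + 1237L) %% (refs$length[ref_i[i]] - rl)
        cig <- sim_make_cigar(rl, "m")
        gen <- sim_read_seq(r, spos, cig, rl, vs, cfg$base_error_rate)
        fl <- base_flag + FLAGS[["READ1"]] + FLAGS[["SECONDARY"]]
        recs[[ri]] <- list(refID = r, pos0 = spos, mapq = 0L, flag = fl,
                           read_name = qname, cigar = cig, seq = gen$seq,
                           qual = gen$qual, next_refID = r, next_pos0 = p2,
                           tlen = 0L, end0 = spos + cigar_reference_span(cig))
        ri <- ri + 1L
      }
    }
  }

  # order: coordinate sort for placed records, unplaced at the end
  refid_v <- vapply(recs, `[[`, integer(1), "refID")
  pos_v <- vapply(recs, `[[`, integer(1), "pos0")
  if (cfg$sorted && length(recs)) {
    placed <- which(refid_v >= 0L)
    unplaced <- which(refid_v < 0L)
    ord <- c(placed[order(refid_v[placed], pos_v[placed])], unplaced)
    recs <- recs[ord]
  }

  # truth allele counts at generation time (default exclusion mask, zero
  # quality thresholds, unlimited depth)
  if (!is.null(vs) && length(recs)) {
    excl <- 0x704L
    for (k in seq_along(recs)) {
      rec <- recs[[k]]
      if (rec$refID < 0L || bitwAnd(rec$flag, excl) != 0L) next
      hits <- which(vs$refid == rec$refID & vs$pos0 >= rec$pos0 &
                    vs$pos0 < rec$end0)
      for (h in hits) {
        al <- sim_aligned_ref_pos(rec$cigar, rec$pos0)
        j <- match(vs$pos0[h], al$refp)
        if (is.na(j)) {
          # site inside a deletion (or skip): D only for deletions
          if (site_in_deletion(rec$cigar, rec$pos0, vs$pos0[h]))
            truth_counts[h, "D"] <- truth_counts[h, "D"] + 1L
        } else {
          b <- substr(rec$seq, al$qidx[j], al$qidx[j])
          cls <- if (b == vs$ref[h]) "R" else if (b == vs$alt[h]) "A" else "E"
          truth_counts[h, cls] <- truth_counts[h, cls] + 1L
        }
      }
    }
  }

  # independent flag tally (generator-side definitions, not count_record)
  truth_tallies <- sim_flag_tally(recs)

  # serialise
  hdr_bytes <- bam_write_header(header)
  rec_bytes <- lapply(recs, function(rec)
    bam_write_record(do.call(bam_record, rec[setdiff(names(rec), "end0")]),
                     header))
  stream <- c(list(hdr_bytes), rec_bytes)
  payload <- do.call(c, stream)
  comp <- bgzf_compress(payload)
  # fixed 65280-byte chunking makes uncompressed offset -> voffset trivial
  rec_lens <- vapply(rec_bytes, length, numeric(1))
  rec_u <- length(hdr_bytes) + cumsum(c(0, rec_lens))[seq_along(recs)]
  blk_of <- function(u) voff_pack(comp$block_coffsets[u %/% 65280 + 1L],
                                  u %% 65280)
  rec_v <- if (length(recs)) vapply(rec_u, blk_of, numeric(1)) else numeric(0)
  eof_coff <- comp$block_coffsets[length(comp$block_coffsets)]
  rec_vend <- c(rec_v[-1L], if (length(recs)) voff_pack(eof_coff, 0))

  rec_df <- if (length(recs)) data.frame(
    refID = vapply(recs, `[[`, integer(1), "refID"),
    pos0 = vapply(recs, `[[`, integer(1), "pos0"),
    end0 = vapply(recs, function(r) {
      if (r$refID < 0L) -1L else as.integer(r$end0)
    }, integer(1)),
    flag = vapply(recs, `[[`, integer(1), "flag"),
    mapq = vapply(recs, `[[`, integer(1), "mapq"),
    next_refID = vapply(recs, `[[`, integer(1), "next_refID"),
    read_name = vapply(recs, `[[`, character(1), "read_name"),
    vbeg = rec_v, vend = rec_vend, stringsAsFactors = FALSE)
  else data.frame(refID = integer(0), pos0 = integer(0), end0 = integer(0),
                  flag = integer(0), mapq = integer(0),
                  next_refID = integer(0), read_name = character(0),
                  vbeg = numeric(0), vend = numeric(0))

  bai_bytes <- NULL
  if (cfg$sorted) {
    idx <- build_bai(rec_df, header)
    tf <- tempfile(); on.exit(unlink(tf), add = TRUE)
    write_bai(idx, tf)
    bai_bytes <- readBin(tf, raw(), file.size(tf))
  }

  vcf <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", refs$name, ",length=", refs$length, ">"),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (!is.null(vs))
    vcf <- c(vcf, sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                          vs$chrom, vs$pos1, vs$ref, vs$alt))

  sac <- if (!is.null(vs))
    cbind(vs[, c("chrom", "pos1", "ref", "alt", "alt_fraction")],
          as.data.frame(truth_counts)) else NULL

  list(bam = comp$bytes, bai = bai_bytes, vcf = vcf,
       header = header,
       truth = list(block_boundaries = comp$block_coffsets,
                    record_voffsets = rec_v,
                    flag_tallies = truth_tallies,
                    site_allele_counts = sac,
                    records = rec_df))
}

site_in_deletion <- function(cigar, pos0, site0) {
  refc <- pos0
  for (i in seq_along(cigar$op)) {
    op <- cigar$op[i]; len <- cigar$len[i]
    if (op %in% c("M", "=", "X", "N")) refc <- refc + len
    else if (op == "D") {
      if (site0 >= refc && site0 < refc + len) return(TRUE)
      refc <- refc + len
    }
  }
  FALSE
}

# two-level quality alphabet: mostly high (35), some low (12)
sim_quals <- function(n) {
  ifelse(stats::runif(n) < 0.9, 35L, 12L)
}

# sequence of one read: implicit reference over aligned positions, variant
# alleles injected per site fraction, random bases for I/S, then base errors
sim_read_seq <- function(ref_i, pos0, cigar, read_len, vs, err_rate) {
  if (length(cigar$op) == 0L) {
    return(list(seq = paste(sample(SIM_BASES, read_len, replace = TRUE),
                            collapse = ""),
                qual = sim_quals(read_len)))
  }
  al <- sim_aligned_ref_pos(cigar, pos0)
  bases <- sample(SIM_BASES, read_len, replace = TRUE)  # I/S filler
  bases[al$qidx] <- sim_ref_base(ref_i, al$refp)
  if (!is.null(vs)) {
    hit <- which(vs$refid == ref_i & vs$pos0 %in% al$refp)
    for (h in hit) {
      if (stats::runif(1) < vs$alt_fraction[h]) {
        j <- match(vs$pos0[h], al$refp)
        bases[al$qidx[j]] <- vs$alt[h]
      }
    }
  }
  err <- which(stats::runif(read_len) < err_rate)
  for (e in err) {
    bases[e] <- sample(setdiff(SIM_BASES, bases[e]), 1L)
  }
  list(seq = paste(bases, collapse = ""), qual = sim_quals(read_len))
}

# generator-side flag tally, written independently of the flagstat module
sim_flag_tally <- function(recs) {
  f <- flag_counts()
  if (length(recs) == 0L) return(f)
  flag <- vapply(recs, `[[`, integer(1), "flag")
  refID <- vapply(recs, `[[`, integer(1), "refID")
  nref <- vapply(recs, `[[`, integer(1), "next_refID")
  mapq <- vapply(recs, `[[`, integer(1), "mapq")
  F <- c(PAIRED = 1L, PROPER = 2L, UNMAP = 4L, MUNMAP = 8L, READ1 = 64L,
         READ2 = 128L, SEC = 256L, QCFAIL = 512L, DUP = 1024L, SUPP = 2048L)
  for (qc in c(FALSE, TRUE)) {
    side <- if (qc) "fail" else "pass"
    s <- (bitwAnd(flag, F[["QCFAIL"]]) != 0L) == qc
    fl <- flag[s]; rid <- refID[s]; nrid <- nref[s]; mq <- mapq[s]
    bit <- function(b) bitwAnd(fl, b) != 0L
    primary <- !bit(F[["SEC"]]) & !bit(F[["SUPP"]])
    f[side, "total"] <- sum(s)
    f[side, "secondary"] <- sum(bit(F[["SEC"]]))
    f[side, "supplementary"] <- sum(bit(F[["SUPP"]]))
    f[side, "duplicates"] <- sum(bit(F[["DUP"]]))
    f[side, "mapped"] <- sum(!bit(F[["UNMAP"]]))
    pr <- bit(F[["PAIRED"]]) & primary
    f[side, "paired_in_sequencing"] <- sum(pr)
    f[side, "read1"] <- sum(pr & bit(F[["READ1"]]))
    f[side, "read2"] <- sum(pr & bit(F[["READ2"]]))
    f[side, "properly_paired"] <- sum(pr & bit(F[["PROPER"]]) & !bit(F[["UNMAP"]]))
    both <- pr & !bit(F[["UNMAP"]]) & !bit(F[["MUNMAP"]])
    f[side, "with_mate_mapped"] <- sum(both)
    f[side, "singletons"] <- sum(pr & !bit(F[["UNMAP"]]) & bit(F[["MUNMAP"]]))
    dc <- both & nrid != rid & nrid >= 0L & rid >= 0L
    f[side, "mate_diff_ref"] <- sum(dc)
    f[side, "mate_diff_ref_mapq_ge5"] <- sum(dc & mq >= 5L)
  }
  f
}

#' Corrupt random bytes of a BAM image
#'
#' Overwrites `n_corruptions` random bytes outside the header block(s) with
#' different random values, for scanner-robustness testing.
#' @param bam Raw BAM file image.
#' @param n_corruptions Number of bytes to corrupt.
#' @param seed Seed for the corruption positions.
#' @return List with `bam` (corrupted copy) and `offsets` (0-based corrupted
#'   byte offsets).
#' @export
corrupt_bam <- function(bam, n_corruptions, seed = 1L) {
  stopifnot(is.raw(bam), n_corruptions >= 0L)
  if (n_corruptions == 0L) return(list(bam = bam, offsets = numeric(0)))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister")
  first <- bgzf_read_block(bam, 0)
  lo <- first$csize + 1        # never touch the header block
  hi <- length(bam) - 28L      # nor the EOF marker
  offs <- sort(sample(lo:hi, min(n_corruptions, hi - lo + 1L))) - 1
  for (o in offs) {
    old <- bam[o + 1L]
    repeat {
      nb <- as.raw(sample.int(256L, 1L) - 1L)
      if (nb != old) break
    }
    bam[o + 1L] <- nb
  }
  list(bam = bam, offsets = offs)
}

#' Write a simulation to disk
#'
#' @param sim Result of [simulate_bam()].
#' @param prefix Output path prefix; writes `<prefix>.bam`,
#'   `<prefix>.bam.bai` (when sorted), `<prefix>.vcf`.
#' @return Invisibly, the BAM path.
#' @export
write_simulation <- function(sim, prefix) {
  bam_path <- paste0(prefix, ".bam")
  writeBin(sim$bam, bam_path)
  if (!is.null(sim$bai)) writeBin(sim$bai, paste0(prefix, ".bam.bai"))
  writeLines(sim$vcf, paste0(prefix, ".vcf"))
  invisible(bam_path)
}
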