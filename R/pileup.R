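# Multi-sample pileup at VCF-listed SNP sites: per-site, per-sample
# R/A/E/D counts (reads supporting the reference base, the alternate base,
# another substitution, or a deletion spanning the site), with a depth cap
# built into the per-site structure: every read is considered in file order
# and counting simply stops once the cap is reached.

#' Pileup filtering and limit parameters
#'
#' @param min_map_quality Minimum mapping quality; reads below contribute
#'   nothing.
#' @param min_base_quality Minimum base quality; an aligned base below the
#'   threshold contributes nothing (value 255 means "missing" and passes
#'   any threshold; deletions carry no base quality and are never filtered
#'   here).
#' @param max_depth Per-site, per-sample cap on R+A+E+D; 0 means unlimited.
#'   Reads are admitted in file order until the cap is reached.
#' @param exclude_flag_mask Records with any of these flag bits set
#'   contribute nothing; default UNMAP|SECONDARY|QCFAIL|DUP.
#' @param min_total_depth Row filter: emit a site only when the summed
#'   depth across samples reaches this value.
#' @return An object of class `pileup_config`.
#' @export
pileup_config <- function(min_map_quality = 0L, min_base_quality = 0L,
                          max_depth = 0L,
                          exclude_flag_mask = 0x704L,
                          min_total_depth = 0L) {
  stopifnot(min_map_quality >= 0L, min_base_quality >= 0L, max_depth >= 0L,
            min_total_depth >= 0L, exclude_flag_mask >= 0L,
            exclude_flag_mask < 65536L)
  structure(list(min_map_quality = as.integer(min_map_quality),
                 min_base_quality = as.integer(min_base_quality),
                 max_depth = as.integer(max_depth),
                 exclude_flag_mask = as.integer(exclude_flag_mask),
                 min_total_depth = as.integer(min_total_depth)),
            class = "pileup_config")
}

#' Read candidate SNP sites from a VCF
#'
#' Keeps bi-allelic SNP rows (single-base REF and ALT, both in ACGT) in
#' file order. Indels, multi-base, symbolic and multi-allelic ALT rows are
#' skipped with a logged count. Duplicate (chrom, pos) rows are all
#' retained, and a later duplicate is processed normally even when the
#' first occurrence was not a bi-allelic SNP.
#'
#' @param vcf_path Path to a VCF (plain or gzip-compressed).
#' @return Data frame of class `snp_sites` with `chrom`, `pos1` (1-based),
#'   `ref`, `alt`.
#' @export
read_sites <- function(vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L)
    stop_with("vcf_input_error", "VCF has no data lines: %s", vcf_path)
  ref <- toupper(fix[, "REF"]); alt <- toupper(fix[, "ALT"])
  snp <- !is.na(ref) & !is.na(alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  n_skipped <- sum(!snp)
  if (n_skipped > 0L)
    message(sprintf("read_sites: skipped %d non-SNP row(s)", n_skipped))
  out <- data.frame(chrom = fix[snp, "CHROM"],
                    pos1 = as.integer(fix[snp, "POS"]),
                    ref = ref[snp], alt = alt[snp],
                    stringsAsFactors = FALSE)
  class(out) <- c("snp_sites", class(out))
  out
}

# What does record r contribute at 0-based reference position site0?
# Returns list(type = "base"|"del"|"none", base, qual).
read_base_at <- function(r, site0) {
  refc <- r$pos0
  qryc <- 0L
  ops <- r$cigar$op; lens <- r$cigar$len
  for (i in seq_along(ops)) {
    op <- ops[i]; len <- lens[i]
    if (op %in% c("M", "=", "X")) {
      if (site0 >= refc && site0 < refc + len) {
        qi <- qryc + (site0 - refc) + 1L
        return(list(type = "base",
                    base = substr(r$seq, qi, qi),
                    qual = if (is.null(r$qual)) 255L else r$qual[qi]))
      }
      refc <- refc + len; qryc <- qryc + len
    } else if (op == "D") {
      if (site0 >= refc && site0 < refc + len)
        return(list(type = "del", base = NA_character_, qual = NA_integer_))
      refc <- refc + len
    } else if (op == "N") {
      if (site0 >= refc && site0 < refc + len)
        return(list(type = "none", base = NA_character_, qual = NA_integer_))
      refc <- refc + len
    } else if (op %in% c("I", "S")) {
      qryc <- qryc + len
    } # H, P consume nothing
  }
  list(type = "none", base = NA_character_, qual = NA_integer_)
}

#' Allele counts of one sample at one site
#'
#' Each passing read contributes exactly one of R/A/E/D; reads matching the
#' exclusion mask or below the mapping-quality threshold contribute
#' nothing, as do aligned bases below the base-quality threshold and
#' reference skips. When `max_depth > 0`, contributions stop once
#' R+A+E+D reaches the cap, in the order the records are given (file
#' order).
#'
#' @param records List of `bam_record`s of one sample overlapping the site.
#' @param site One-row data frame (or list) with `ref`, `alt` and either
#'   `pos1` (1-based) or `pos0`.
#' @param config A `pileup_config`.
#' @return Named integer vector `c(R, A, E, D)`.
#' @export
pileup_site <- function(records, site, config = pileup_config()) {
  site0 <- if (!is.null(site$pos0)) site$pos0 else site$pos1 - 1L
  counts <- c(R = 0L, A = 0L, E = 0L, D = 0L)
  cap <- config$max_depth
  for (r in records) {
    if (cap > 0L && sum(counts) >= cap) break
    if (bitwAnd(r$flag, config$exclude_flag_mask) != 0L) next
    if (r$mapq < config$min_map_quality) next
    hit <- read_base_at(r, site0)
    if (hit$type == "del") {
      counts[["D"]] <- counts[["D"]] + 1L
    } else if (hit$type == "base") {
      if (hit$qual != 255L && hit$qual < config$min_base_quality) next
      cls <- if (hit$base == site$ref) "R"
             else if (hit$base == site$alt) "A" else "E"
      counts[[cls]] <- counts[[cls]] + 1L
    }
  }
  counts
}

#' Multi-sample SNP pileup over VCF sites
#'
#' Iterates over the VCF sites in file order; for each site, pulls the
#' reads overlapping the position from every BAM and extracts per-sample
#' R/A/E/D counts. Work is partitioned over groups of consecutive sites
#' sized by the compressed data they span (via the first sample's index);
#' the output is invariant to `n_threads`.
#'
#' @param vcf Path to the VCF of candidate sites, or an `snp_sites` data
#'   frame.
#' @param bam_paths Character vector of coordinate-sorted, indexed BAMs
#'   (`.bai` expected alongside).
#' @param config A `pileup_config`.
#' @param n_threads Worker count.
#' @return Data frame of class `snp_pileup_table`: `Chromosome`,
#'   `Position` (1-based), `Ref`, `Alt`, then `File<k>R/A/E/D` per sample.
#' @export
snp_pileup <- function(vcf, bam_paths, config = pileup_config(),
                       n_threads = 1L) {
  sites <- if (is.character(vcf)) read_sites(vcf) else vcf
  nb <- length(bam_paths)
  stopifnot(nb >= 1L)
  samples <- lapply(bam_paths, function(p) {
    src <- src_bytes(p)
    inf <- inflate_forward(src, 0, 2^20)
    hp <- bam_read_header(inf$payload)
    bai_path <- paste0(p, ".bai")
    if (!file.exists(bai_path)) bai_path <- sub("\\.bam$", ".bai", p)
    if (!file.exists(bai_path))
      stop_with("bai_missing_error", "no BAI index for %s", p)
    list(src = src, header = hp$header, index = read_bai(bai_path))
  })
  header1 <- samples[[1L]]$header
  for (mc in unique(sites$chrom)) {
    if (!all(vapply(samples, function(s)
      mc %in% s$header$references$name, logical(1))))
      warning(sprintf("chromosome %s absent from at least one BAM header; emitting zero counts there", mc))
  }
  jobs <- partition_sites(sites, samples[[1L]]$index, header1,
                          max(1L, 4L * n_threads))
  worker <- function(job) {
    rows <- job$site_rows
    sub <- sites[rows, , drop = FALSE]
    m <- matrix(0L, nrow = length(rows), ncol = 4L * nb)
    for (k in seq_len(nb)) {
      s <- samples[[k]]
      refid <- match(sub$chrom, s$header$references$name) - 1L
      for (ref in unique(refid[!is.na(refid)])) {
        idx <- which(refid == ref)
        lo <- min(sub$pos1[idx]) - 1L
        hi <- max(sub$pos1[idx])
        recs <- bai_query_records(s$src, s$index, s$header, ref, lo, hi)
        if (length(recs) == 0L) next
        starts <- vapply(recs, `[[`, integer(1), "pos0")
        ends <- vapply(recs, function(r)
          r$pos0 + max(1L, cigar_reference_span(r$cigar)), integer(1))
        for (j in idx) {
          s0 <- sub$pos1[j] - 1L
          ov <- which(starts <= s0 & ends > s0)
          cnt <- pileup_site(recs[ov], list(pos0 = s0, ref = sub$ref[j],
                                            alt = sub$alt[j]), config)
          m[j, (4L * (k - 1L) + 1L):(4L * k)] <- cnt
        }
      }
    }
    cbind(data.frame(Chromosome = sub$chrom, Position = sub$pos1,
                     Ref = sub$ref, Alt = sub$alt,
                     stringsAsFactors = FALSE),
          as.data.frame(m))
  }
  merged <- run_scatter_gather(jobs, worker, rbind, n_threads,
                               init = NULL)
  if (is.null(merged)) {
    merged <- cbind(data.frame(Chromosome = character(0),
                               Position = integer(0), Ref = character(0),
                               Alt = character(0)),
                    as.data.frame(matrix(integer(0), ncol = 4L * nb)))
  }
  cn <- as.vector(t(outer(seq_len(nb), c("R", "A", "E", "D"),
                          function(i, s) paste0("File", i, s))))
  names(merged) <- c("Chromosome", "Position", "Ref", "Alt", cn)
  if (config$min_total_depth > 0L && nrow(merged) > 0L) {
    depth <- rowSums(merged[, cn, drop = FALSE])
    merged <- merged[depth >= config$min_total_depth, , drop = FALSE]
    rownames(merged) <- NULL
  }
  class(merged) <- c("snp_pileup_table", class(merged))
  merged
}

#' Write a pileup table as FACETS-style CSV
#'
#' Header `Chromosome,Position,Ref,Alt,File1R,File1A,File1E,File1D,...`
#' with one R/A/E/D quartet per input BAM in argument order; positions are
#' 1-based; row order is site order.
#' @param table An `snp_pileup_table`.
#' @param out_path Output path.
#' @return Invisibly, the path.
#' @export
write_pileup_csv <- function(table, out_path) {
  con <- tryCatch(file(out_path, "wb"),
                  error = function(e) stop_with("pileup_output_error",
                                                "cannot write %s", out_path))
  on.exit(close(con))
  lines <- paste(names(table), collapse = ",")
  if (nrow(table) > 0L) {
    body <- do.call(paste, c(unname(as.list(table)), sep = ","))
    lines <- c(lines, body)
  }
  writeLines(lines, con)
  invisible(out_path)
}

#' Read back a pileup CSV
#'
#' @param path CSV written by [write_pileup_csv()].
#' @return An `snp_pileup_table`.
#' @export
read_pileup_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA)
  df$Chromosome <- as.character(df$Chromosome)
  class(df) <- c("snp_pileup_table", class(df))
  df
}
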