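# Multi-sample SNP pileup: site parsing, per-read classification, depth
# semantics, CSV output

write_vcf <- function(lines) {
  tf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", lines), tf)
  tf
}

test_that("read_sites keeps bi-allelic SNPs and skips everything else", {
  tf <- write_vcf(c("chr1\t100\t.\tA\tC\t.\t.\t.",
                    "chr1\t200\t.\tA\tAT\t.\t.\t.",
                    "chr1\t300\t.\tAT\tA\t.\t.\t.",
                    "chr1\t400\t.\tG\tT,C\t.\t.\t.",
                    "chr1\t500\t.\tC\t<DEL>\t.\t.\t."))
  expect_message(s <- read_sites(tf), "skipped 4")
  expect_identical(nrow(s), 1L)
  expect_identical(s$pos1, 100L)
  expect_identical(s$ref, "A")
  expect_identical(s$alt, "C")
})

test_that("duplicate coordinates are all retained; a later duplicate works even when the first is not a SNP", {
  tf <- write_vcf(c("chr1\t100\t.\tC\t<DEL>\t.\t.\t.",
                    "chr1\t100\t.\tA\tG\t.\t.\t.",
                    "chr1\t250\t.\tG\tT\t.\t.\t.",
                    "chr1\t250\t.\tG\tC\t.\t.\t."))
  s <- suppressMessages(read_sites(tf))
  expect_identical(s$pos1, c(100L, 250L, 250L))
  expect_identical(s$alt, c("G", "T", "C"))
})

test_that("gzip-compressed VCF input is accepted", {
  tf <- write_vcf("chr1\t123\t.\tT\tG\t.\t.\t.")
  gz <- paste0(tf, ".gz")
  con <- gzfile(gz, "wb"); writeLines(readLines(tf), con); close(con)
  s <- read_sites(gz)
  expect_identical(s$pos1, 123L)
})

mk_read <- function(name, pos, cigar, seq, qual = NULL, flag = 0L,
                    mapq = 60L) {
  bam_record(name, flag = flag, refID = 0L, pos0 = pos, mapq = mapq,
             cigar = cigar, seq = seq,
             qual = qual %||% rep(35L, nchar(seq)))
}

test_that("pileup_site classifies aligned bases, deletions and skips correctly", {
  site <- list(pos0 = 110L, ref = "A", alt = "G")
  # aligned reference base
  r1 <- mk_read("r1", 100L, list(op = "M", len = 50L),
                paste(c(rep("C", 10), "A", rep("C", 39)), collapse = ""))
  expect_identical(pileup_site(list(r1), site),
                   c(R = 1L, A = 0L, E = 0L, D = 0L))
  # alternate base
  r2 <- mk_read("r2", 100L, list(op = "M", len = 50L),
                paste(c(rep("C", 10), "G", rep("C", 39)), collapse = ""))
  expect_identical(pileup_site(list(r2), site)[["A"]], 1L)
  # other substitution counts as error
  r3 <- mk_read("r3", 100L, list(op = "M", len = 50L),
                paste(rep("T", 50), collapse = ""))
  expect_identical(pileup_site(list(r3), site)[["E"]], 1L)
  # deletion spanning the site
  r4 <- mk_read("r4", 100L, list(op = c("M", "D", "M"), len = c(5L, 10L, 45L)),
                paste(rep("A", 50), collapse = ""))
  expect_identical(pileup_site(list(r4), site)[["D"]], 1L)
  # reference skip spanning the site contributes nothing
  r5 <- mk_read("r5", 100L, list(op = c("M", "N", "M"), len = c(5L, 10L, 45L)),
                paste(rep("A", 50), collapse = ""))
  expect_identical(sum(pileup_site(list(r5), site)), 0L)
  # soft clip before the aligned part shifts query indexing
  r6 <- mk_read("r6", 108L, list(op = c("S", "M"), len = c(4L, 10L)),
                paste(c(rep("T", 4), "C", "C", "G", rep("C", 7)),
                      collapse = ""))
  expect_identical(pileup_site(list(r6), site)[["A"]], 1L)
})

test_that("pileup_site honours flag mask, mapq, base quality and the 255 convention", {
  site <- list(pos0 = 110L, ref = "A", alt = "G")
  base_seq <- paste(c(rep("C", 10), "A", rep("C", 39)), collapse = "")
  cfg <- pileup_config(min_map_quality = 20L, min_base_quality = 20L)
  # excluded flags contribute nothing
  for (fl in c(0x4L, 0x100L, 0x200L, 0x400L)) {
    r <- mk_read("x", 100L, list(op = "M", len = 50L), base_seq, flag = fl)
    expect_identical(sum(pileup_site(list(r), site, cfg)), 0L,
                     label = sprintf("flag 0x%x", fl))
  }
  # low mapq is dropped
  r <- mk_read("x", 100L, list(op = "M", len = 50L), base_seq, mapq = 19L)
  expect_identical(sum(pileup_site(list(r), site, cfg)), 0L)
  # low base quality at the site is dropped
  ql <- rep(35L, 50); ql[11] <- 10L
  r <- mk_read("x", 100L, list(op = "M", len = 50L), base_seq, qual = ql)
  expect_identical(sum(pileup_site(list(r), site, cfg)), 0L)
  # quality 255 means missing, not low: passes any threshold
  qm <- rep(255L, 50)
  r <- mk_read("x", 100L, list(op = "M", len = 50L), base_seq, qual = qm)
  expect_identical(pileup_site(list(r), site, cfg)[["R"]], 1L)
})

test_that("depth cap admits reads in file order until R+A+E+D reaches the cap", {
  site <- list(pos0 = 110L, ref = "A", alt = "G")
  reads <- list(
    mk_read("a", 100L, list(op = "M", len = 50L),
            paste(c(rep("C", 10), "A", rep("C", 39)), collapse = "")),
    mk_read("b", 100L, list(op = "M", len = 50L),
            paste(c(rep("C", 10), "G", rep("C", 39)), collapse = "")),
    mk_read("c", 100L, list(op = "M", len = 50L),
            paste(c(rep("C", 10), "G", rep("C", 39)), collapse = "")))
  cfg2 <- pileup_config(max_depth = 2L)
  got <- pileup_site(reads, site, cfg2)
  expect_identical(sum(got), 2L)
  # first two in file order: one R then one A
  expect_identical(got, c(R = 1L, A = 1L, E = 0L, D = 0L))
  expect_identical(sum(pileup_site(reads, site, pileup_config())), 3L)
})

test_that("fixture pileup equals recorded truth and a brute-force CIGAR-walking oracle", {
  sim <- fixture("small")
  tab <- snp_pileup(sim$vcf_path, sim$bam_path)
  truth <- sim$truth$site_allele_counts
  expect_identical(nrow(tab), nrow(truth))
  expect_identical(tab$Position, truth$pos1)
  expect_identical(unname(as.matrix(tab[, c("File1R", "File1A", "File1E",
                                            "File1D")])),
                   unname(as.matrix(truth[, c("R", "A", "E", "D")])))

  # independent oracle: walk every record's CIGAR against every site
  sp <- cached_parse("small")
  oracle <- brute_pileup_counts(sp$records, sim$header, truth)
  expect_identical(unname(as.matrix(tab[, c("File1R", "File1A", "File1E",
                                            "File1D")])), unname(oracle))
})

test_that("raising thresholds never raises counts; max_depth caps sums", {
  sim <- fixture("small")
  base <- snp_pileup(sim$vcf_path, sim$bam_path)
  qcfg <- pileup_config(min_base_quality = 20L, min_map_quality = 30L)
  filt <- snp_pileup(sim$vcf_path, sim$bam_path, qcfg)
  cols <- c("File1R", "File1A", "File1E", "File1D")
  expect_true(all(as.matrix(filt[, cols]) <= as.matrix(base[, cols])))
  capped <- snp_pileup(sim$vcf_path, sim$bam_path,
                       pileup_config(max_depth = 3L))
  expect_true(all(rowSums(capped[, cols]) <= 3L))
  # cap equals uncapped wherever depth was already below it
  low <- rowSums(base[, cols]) <= 3L
  expect_identical(as.matrix(capped[low, cols]), as.matrix(base[low, cols]))
})

test_that("multi-sample output keeps argument order and handles missing chromosomes", {
  sim <- fixture("small")
  tf <- write_vcf(c("chr1\t5000\t.\tA\tG\t.\t.\t.",
                    "chrZ\t100\t.\tA\tG\t.\t.\t."))
  suppressMessages(expect_warning(
    tab <- snp_pileup(tf, c(sim$bam_path, sim$bam_path)), "chrZ"))
  expect_identical(names(tab)[5:12],
                   c("File1R", "File1A", "File1E", "File1D",
                     "File2R", "File2A", "File2E", "File2D"))
  # identical input BAMs give identical per-sample counts
  expect_identical(unname(as.matrix(tab[, 5:8])),
                   unname(as.matrix(tab[, 9:12])))
  # unknown chromosome row present, with zero counts
  expect_identical(nrow(tab), 2L)
  expect_identical(sum(as.matrix(tab[tab$Chromosome == "chrZ", 5:12])), 0L)
})

test_that("row filter, threads and CSV round-trip keep the table stable", {
  sim <- fixture("small")
  t1 <- snp_pileup(sim$vcf_path, sim$bam_path, n_threads = 1L)
  t8 <- snp_pileup(sim$vcf_path, sim$bam_path, n_threads = 8L)
  expect_identical(t1, t8)
  p1 <- tempfile(fileext = ".csv"); p8 <- tempfile(fileext = ".csv")
  write_pileup_csv(t1, p1); write_pileup_csv(t8, p8)
  expect_identical(readBin(p1, raw(), file.size(p1)),
                   readBin(p8, raw(), file.size(p8)))
  expect_identical(readLines(p1)[1],
                   "Chromosome,Position,Ref,Alt,File1R,File1A,File1E,File1D")
  back <- read_pileup_csv(p1)
  expect_equal(as.data.frame(back), as.data.frame(t1))

  # min_total_depth drops shallow rows
  dmin <- snp_pileup(sim$vcf_path, sim$bam_path,
                     pileup_config(min_total_depth = 3L))
  cols <- c("File1R", "File1A", "File1E", "File1D")
  expect_true(all(rowSums(dmin[, cols]) >= 3L))
  kept <- rowSums(t1[, cols]) >= 3L
  expect_identical(dmin$Position, t1$Position[kept])

  # empty table still writes a header-only CSV
  t0 <- t1[0, ]
  p0 <- tempfile(fileext = ".csv")
  write_pileup_csv(t0, p0)
  expect_identical(length(readLines(p0)), 1L)
})

test_that("injected allele fractions are recovered within binomial error at depth", {
  sim <- fixture("deep")
  tab <- snp_pileup(sim$vcf_path, sim$bam_path)
  truth <- sim$truth$site_allele_counts
  expect_identical(tab$Position, truth$pos1)
  depth <- tab$File1R + tab$File1A
  expect_true(all(depth >= 500))
  for (i in seq_len(nrow(tab))) {
    p <- truth$alt_fraction[i]
    vaf <- tab$File1A[i] / depth[i]
    ci <- stats::qbinom(c(0.005, 0.995), depth[i], p) / depth[i]
    # base errors can nudge either count slightly beyond the exact interval
    tol <- 0.01
    expect_gte(vaf, ci[1] - tol)
    expect_lte(vaf, ci[2] + tol)
  }
})
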