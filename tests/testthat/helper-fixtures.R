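# Shared fixtures, built once per test run and cached. Everything is
# generated in code; nothing is stored on disk in the repository.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name) {
  if (!exists(name, .fixture_cache)) {
    assign(name, switch(
      name,
      # small coordinate-sorted multi-reference BAM with variants
      small = {
        sites <- data.frame(
          chrom = rep(c("chr1", "chr2"), c(20, 10)),
          pos1 = c(seq(2500, 97500, length.out = 20),
                   seq(3000, 57000, length.out = 10)),
          alt_fraction = rep(c(0, 0.25, 0.5, 1), length.out = 30))
        sites$pos1 <- as.integer(round(sites$pos1))
        sim <- simulate_bam(sim_config(
          seed = 42L, n_read_pairs = 2000L,
          references = data.frame(name = c("chr1", "chr2", "chr3"),
                                  length = c(100000L, 60000L, 40000L)),
          variant_sites = sites))
        fixture_on_disk(sim)
      },
      # same scale but unsorted and unindexed
      unsorted = {
        sim <- simulate_bam(sim_config(
          seed = 43L, n_read_pairs = 1500L,
          references = data.frame(name = c("chr1", "chr2"),
                                  length = c(100000L, 60000L)),
          sorted = FALSE))
        fixture_on_disk(sim)
      },
      # acceptance-scale fixture: >= 50k records on 3 references,
      # >= 100 variant sites
      big = {
        sites <- data.frame(
          chrom = rep(c("chr1", "chr2", "chr3"), c(50, 40, 30)),
          pos1 = c(seq(5000, 990000, length.out = 50),
                   seq(5000, 790000, length.out = 40),
                   seq(5000, 590000, length.out = 30)),
          alt_fraction = rep(c(0, 0.25, 0.5, 1), length.out = 120))
        sites$pos1 <- as.integer(round(sites$pos1))
        sim <- simulate_bam(sim_config(seed = 101L, variant_sites = sites))
        fixture_on_disk(sim)
      },
      # deep coverage on a short reference for allele-fraction recovery
      deep = {
        sim <- simulate_bam(sim_config(
          seed = 7L, n_read_pairs = 7000L,
          references = data.frame(name = "chrD", length = 2000L),
          fragment_mean = 300, fragment_sd = 30,
          dup_fraction = 0, unmapped_fraction = 0,
          secondary_fraction = 0, qcfail_fraction = 0,
          variant_sites = data.frame(chrom = "chrD",
                                     pos1 = c(400L, 800L, 1200L, 1600L),
                                     alt_fraction = c(0, 0.25, 0.5, 1))))
        fixture_on_disk(sim)
      },
      stop("unknown fixture ", name)), .fixture_cache)
  }
  get(name, .fixture_cache)
}

fixture_on_disk <- function(sim) {
  dir <- tempfile("fx")
  dir.create(dir)
  prefix <- file.path(dir, "sim")
  write_simulation(sim, prefix)
  sim$bam_path <- paste0(prefix, ".bam")
  sim$bai_path <- paste0(prefix, ".bam.bai")
  sim$vcf_path <- paste0(prefix, ".vcf")
  sim$index <- if (!is.null(sim$bai)) read_bai(sim$bai_path) else NULL
  sim
}

# a sequential whole-file parse (records + packed start voffsets),
# independent of index and scanner machinery
sequential_parse <- function(sim) {
  inf <- suppressWarnings(bgzf_decompress(sim$bam))
  hp <- bam_read_header(inf$payload)
  recs <- bam_parse_records(inf$payload, hp$header, hp$bytes_consumed,
                            with_offsets = TRUE)
  cum <- cumsum(c(0, inf$block_usizes))
  offs <- attr(recs, "offsets")
  v <- vapply(offs, function(u) {
    i <- findInterval(u, cum)
    voff_pack(inf$block_coffsets[i], u - cum[i])
  }, numeric(1))
  list(records = recs, voffsets = v, header = hp$header)
}

# stable identity of a record for multiset comparisons
rec_key <- function(recs) {
  sort(vapply(recs, function(r)
    paste(r$read_name, r$flag, r$refID, r$pos0, sep = "/"), character(1)))
}

# random valid bam_record generator for round-trip property tests
random_record <- function(header, rng_i) {
  nref <- nrow(header$references)
  mapped <- rng_i %% 5L != 0L
  l_seq <- sample(0:80, 1L)
  seq <- if (l_seq > 0)
    paste(sample(strsplit("=ACMGRSVTWYHKDBN", "")[[1]], l_seq,
                 replace = TRUE), collapse = "") else ""
  cigar <- if (mapped && l_seq > 0L) {
    n_m <- max(1L, l_seq - 10L)
    extra <- l_seq - n_m
    if (extra > 0L && runif(1) < 0.5)
      list(op = c("S", "M", "I"), len = c(5L, n_m, extra - 5L + 10L))
    else list(op = "M", len = l_seq)
  } else NULL
  if (!is.null(cigar)) {
    # keep query-consuming lengths consistent with l_seq
    qcons <- sum(cigar$len[cigar$op %in% c("M", "I", "S", "=", "X")])
    if (qcons != l_seq) cigar <- list(op = "M", len = l_seq)
  }
  refID <- if (mapped) sample(nref, 1L) - 1L else -1L
  pos0 <- if (mapped)
    sample.int(header$references$length[refID + 1L] - 200L, 1L) - 1L else -1L
  bam_record(
    read_name = sprintf("r%06d", rng_i),
    flag = sample(0:4095, 1L),
    refID = refID, pos0 = pos0,
    mapq = sample(0:254, 1L),
    cigar = cigar, seq = seq,
    qual = if (l_seq > 0 && runif(1) < 0.8) sample(0:93, l_seq, replace = TRUE)
           else NULL,
    next_refID = sample(c(-1L, 0L), 1L),
    next_pos0 = -1L, tlen = sample(-500:500, 1L),
    tags = if (runif(1) < 0.3) as.raw(sample(0:255, 8, replace = TRUE))
           else raw(0))
}

test_header <- function() {
  bam_header(data.frame(name = c("tchr1", "tchr2"),
                        length = c(50000L, 30000L)))
}
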