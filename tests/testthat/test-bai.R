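# BAI construction, serialisation and region queries

# independent binning oracle: walk levels from deepest to root using shifts
reg2bin_oracle <- function(beg, end0) {
  end <- end0 - 1L
  shifts <- c(14L, 17L, 20L, 23L, 26L)
  offsets <- c(4681L, 585L, 73L, 9L, 1L)
  for (k in seq_along(shifts)) {
    if (bitwShiftR(beg, shifts[k]) == bitwShiftR(end, shifts[k]))
      return(offsets[k] + bitwShiftR(beg, shifts[k]))
  }
  0L
}

test_that("reg2bin agrees with the level-walk oracle and handles bounds", {
  expect_identical(reg2bin(0, 16384), 4681L)
  expect_identical(reg2bin(0, 2^29), 0L)
  set.seed(20)
  beg <- sample(0:(2^20 - 2), 10000, replace = TRUE)
  len <- sample(1:200000, 10000, replace = TRUE)
  end <- pmin(beg + len, 2^20)
  got <- mapply(reg2bin, beg, end)
  want <- mapply(reg2bin_oracle, beg, end)
  expect_identical(got, want)
  expect_error(reg2bin(-1, 5), class = "bai_range_error")
  expect_error(reg2bin(10, 10), class = "bai_range_error")
  expect_error(reg2bin(0, 2^29 + 1), class = "bai_range_error")
})

test_that("build_bai records linear-index window starts and rejects unsorted input", {
  h <- test_header()
  # empty input
  idx0 <- build_bai(data.frame(refID = integer(0), pos0 = integer(0),
                               end0 = integer(0), vbeg = numeric(0),
                               vend = numeric(0)), h)
  expect_identical(idx0$n_no_coor, 0L)
  expect_length(window_start_offsets(idx0, 0)$window, 0L)

  # single record at pos 20000 -> window 1
  v <- voff_pack(100, 7)
  idx1 <- build_bai(data.frame(refID = 0L, pos0 = 20000L, end0 = 20100L,
                               vbeg = v, vend = voff_pack(200, 0)), h)
  ws <- window_start_offsets(idx1, 0)
  expect_identical(ws$window, 1L)
  expect_identical(ws$voffset, v)

  # unsorted input is rejected
  expect_error(build_bai(data.frame(refID = c(0L, 0L), pos0 = c(500L, 100L),
                                    end0 = c(600L, 200L),
                                    vbeg = c(0, 100), vend = c(100, 200)), h),
               class = "bai_unsorted_error")
})

test_that("window start offsets are reported only for occupied windows, non-decreasing", {
  sim <- fixture("small")
  idx <- build_bai(sim$truth$records, sim$header)
  for (ref in 0:2) {
    ws <- window_start_offsets(idx, ref)
    expect_true(all(diff(ws$voffset) >= 0))
    # windows listed are exactly those overlapped by >= 1 record
    tr <- sim$truth$records
    tr <- tr[tr$refID == ref, ]
    occ <- sort(unique(unlist(mapply(
      function(p, e) (p %/% 16384L):((e - 1L) %/% 16384L),
      tr$pos0, tr$end0, SIMPLIFY = FALSE))))
    expect_identical(ws$window, as.integer(occ))
  }
})

test_that("BAI write/read round-trip preserves bins, chunks and gap-filled linear arrays", {
  sim <- fixture("small")
  idx <- build_bai(sim$truth$records, sim$header)
  tf <- tempfile(fileext = ".bai")
  on.exit(unlink(tf))
  write_bai(idx, tf)
  back <- read_bai(tf)
  expect_error(read_bai(sim$bam_path), class = "not_a_bai_error")
  expect_identical(length(back$refs), length(idx$refs))
  expect_identical(back$n_no_coor, as.numeric(idx$n_no_coor))
  for (r in seq_along(idx$refs)) {
    a <- idx$refs[[r]]; b <- back$refs[[r]]
    expect_identical(names(b$bins), names(a$bins))
    for (bn in names(a$bins))
      expect_equal(unname(b$bins[[bn]]), unname(a$bins[[bn]]))
    expect_identical(b$linear, fill_linear(a$linear))
    expect_identical(unname(b$stats), unname(as.numeric(a$stats)))
  }
  # query equivalence on random regions
  set.seed(21)
  for (i in 1:100) {
    ref <- sample(0:2, 1)
    len <- sim$header$references$length[ref + 1]
    beg <- sample.int(len - 1L, 1L) - 1L
    end <- min(len, beg + sample.int(30000L, 1L))
    expect_identical(query_chunks(back, ref, beg, end),
                     query_chunks(idx, ref, beg, end))
  }
})

test_that("indexed region queries equal the brute-force full scan", {
  sim <- fixture("small")
  idx <- sim$index
  truth <- sim$truth$records
  set.seed(22)
  for (i in 1:200) {
    ref <- sample(0:2, 1)
    len <- sim$header$references$length[ref + 1]
    beg <- sample.int(len - 1L, 1L) - 1L
    end <- min(len, beg + sample.int(40000L, 1L))
    got <- bai_query_records(sim$bam, idx, sim$header, ref, beg, end)
    exp_rows <- truth[truth$refID == ref & truth$pos0 < end &
                      truth$end0 > beg, ]
    expect_identical(rec_key(got),
                     sort(paste(exp_rows$read_name, exp_rows$flag,
                                exp_rows$refID, exp_rows$pos0, sep = "/")),
                     label = sprintf("region %d:%d-%d", ref, beg, end))
  }
  # a region in a gap yields no records
  gap <- bai_query_records(sim$bam, idx, sim$header, 2L, 39990L, 40000L)
  expect_true(length(gap) == 0 ||
              all(vapply(gap, function(r) r$pos0 < 40000, logical(1))))
})

test_that("an index produced by an independent indexer answers queries identically", {
  skip_if_not_installed("Rsamtools")
  sim <- fixture("small")
  ext_path <- Rsamtools::indexBam(sim$bam_path)
  ext <- read_bai(ext_path)
  idx <- sim$index
  # pseudo-bin metadata must round through without affecting queries
  expect_identical(ext$n_no_coor, as.numeric(sim$truth$flag_tallies["pass", "total"] +
                                             sim$truth$flag_tallies["fail", "total"] -
                                             sum(sim$truth$records$refID >= 0)))
  set.seed(23)
  for (i in 1:100) {
    ref <- sample(0:2, 1)
    len <- sim$header$references$length[ref + 1]
    beg <- sample.int(len - 1L, 1L) - 1L
    end <- min(len, beg + sample.int(40000L, 1L))
    ours <- bai_query_records(sim$bam, idx, sim$header, ref, beg, end)
    theirs <- bai_query_records(sim$bam, ext, sim$header, ref, beg, end)
    expect_identical(rec_key(ours), rec_key(theirs))
  }
})

test_that("span estimates are zero on empty regions, monotone and subadditive", {
  sim <- fixture("small")
  idx <- sim$index
  len <- sim$header$references$length[1]
  whole <- span_compressed_bytes(idx, 0, 0, len)
  half1 <- span_compressed_bytes(idx, 0, 0, len %/% 2)
  half2 <- span_compressed_bytes(idx, 0, len %/% 2, len)
  expect_lte(whole, half1 + half2)
  expect_gte(whole, half1)
  expect_gte(whole, half2)
  expect_gt(whole, 0)
  # empty reference
  empty_ref <- build_bai(data.frame(refID = integer(0), pos0 = integer(0),
                                    end0 = integer(0), vbeg = numeric(0),
                                    vend = numeric(0)), sim$header)
  expect_identical(span_compressed_bytes(empty_ref, 0, 0, 1000), 0)
  set.seed(24)
  for (i in 1:20) {
    beg <- sample.int(len - 20000L, 1L) - 1L
    inner <- span_compressed_bytes(idx, 0, beg + 2000, beg + 10000)
    outer <- span_compressed_bytes(idx, 0, beg, beg + 20000)
    expect_gte(outer, inner)
  }
})
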