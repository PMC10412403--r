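# Independent oracles shared by module and acceptance tests.

.parse_cache <- new.env(parent = emptyenv())

# memoised sequential whole-file parse of a named fixture
cached_parse <- function(name) {
  key <- paste0("parse_", name)
  if (!exists(key, .parse_cache))
    assign(key, sequential_parse(fixture(name)), .parse_cache)
  get(key, .parse_cache)
}

# brute-force per-site allele counting: walks every record's CIGAR
# independently of the pileup engine (zero thresholds, default flag mask)
brute_pileup_counts <- function(records, header, sites) {
  t(vapply(seq_len(nrow(sites)), function(i) {
    ref <- match(sites$chrom[i], header$references$name) - 1L
    s0 <- sites$pos1[i] - 1L
    cnt <- c(R = 0L, A = 0L, E = 0L, D = 0L)
    for (r in records) {
      if (is.na(ref) || r$refID != ref || bitwAnd(r$flag, 0x704L) != 0L) next
      if (r$pos0 > s0) next
      refc <- r$pos0; qc <- 0L; hit <- NULL
      for (k in seq_along(r$cigar$op)) {
        op <- r$cigar$op[k]; ln <- r$cigar$len[k]
        if (op %in% c("M", "=", "X")) {
          if (s0 >= refc && s0 < refc + ln)
            hit <- substr(r$seq, qc + s0 - refc + 1L, qc + s0 - refc + 1L)
          refc <- refc + ln; qc <- qc + ln
        } else if (op == "D") {
          if (s0 >= refc && s0 < refc + ln) hit <- "DEL"
          refc <- refc + ln
        } else if (op == "N") refc <- refc + ln
        else if (op %in% c("I", "S")) qc <- qc + ln
      }
      if (is.null(hit)) next
      key <- if (hit == "DEL") "D" else if (hit == sites$ref[i]) "R"
             else if (hit == sites$alt[i]) "A" else "E"
      cnt[key] <- cnt[key] + 1L
    }
    cnt
  }, integer(4)))
}
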