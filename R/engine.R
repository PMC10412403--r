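# Deterministic scatter/gather: genomic windows from the linear index,
# jobs sized by spanned compressed bytes, a worker pool, and a merge that
# always folds results in job-ordinal order — so output is bit-identical
# for any worker count.

#' Tile every reference into fixed-size windows
#'
#' @param header A `bam_header`.
#' @param window_size Window width in bases; 16384 matches the BAI linear
#'   index.
#' @return Data frame with `ref` (0-based), `beg0`, `end0`, tiling each
#'   reference disjointly in genome order.
#' @export
make_windows <- function(header, window_size = 16384L) {
  stopifnot(window_size >= 1L)
  refs <- header$references
  out <- vector("list", nrow(refs))
  for (i in seq_len(nrow(refs))) {
    len <- refs$length[i]
    beg <- seq(0, len - 1, by = window_size)
    out[[i]] <- data.frame(ref = i - 1L, beg0 = beg,
                           end0 = pmin(beg + window_size, len))
  }
  if (length(out) == 0L)
    return(data.frame(ref = integer(0), beg0 = numeric(0), end0 = numeric(0)))
  do.call(rbind, out)
}

#' Records assigned to one window
#'
#' Start-based assignment: a record belongs to the window containing its
#' alignment start, so boundary-overlapping reads land in the earlier
#' window exactly once.
#' @param src BAM file image or path.
#' @param index A `bai_index`.
#' @param header The file's `bam_header`.
#' @param w One-row data frame (or list) with `ref`, `beg0`, `end0`.
#' @return List of `bam_record`s with `pos0` in `[beg0, end0)`, file order.
#' @export
records_in_window <- function(src, index, header, w) {
  ch <- query_chunks(index, w$ref, w$beg0, w$end0)
  out <- list()
  for (k in seq_len(nrow(ch))) {
    buf <- bgzf_read_range(src, ch[k, 1L], ch[k, 2L])
    recs <- bam_parse_records(buf, header)
    keep <- vapply(recs, function(r)
      r$refID == w$ref && r$pos0 >= w$beg0 && r$pos0 < w$end0, logical(1))
    out <- c(out, recs[keep])
  }
  out
}

#' Group consecutive VCF sites into data-balanced jobs
#'
#' Greedy accumulation of consecutive sites until a job's estimated
#' compressed span reaches `total/n_jobs`; jobs cover all sites, in genome
#' order, with ordinals from 0.
#' @param sites Data frame of sites (`chrom`, `pos1`), sorted by genome
#'   position.
#' @param index A `bai_index` used for span estimates.
#' @param header The `bam_header` naming the references.
#' @param n_jobs Target number of jobs.
#' @return List of jobs; each has `ordinal`, `site_rows` (row indices into
#'   `sites`), `data_estimate` (compressed bytes).
#' @export
partition_sites <- function(sites, index, header, n_jobs) {
  stopifnot(n_jobs >= 1L)
  n <- nrow(sites)
  if (n == 0L) return(list())
  refid <- match(sites$chrom, header$references$name) - 1L
  est <- numeric(n)
  key <- paste0(refid, ":", (sites$pos1 - 1L) %/% LINEAR_WINDOW)
  uk <- !duplicated(key)
  wk <- new.env(parent = emptyenv())
  for (i in which(uk)) {
    if (is.na(refid[i])) { assign(key[i], 0, wk); next }
    wbeg <- ((sites$pos1[i] - 1L) %/% LINEAR_WINDOW) * LINEAR_WINDOW
    reflen <- header$references$length[refid[i] + 1L]
    assign(key[i], span_compressed_bytes(index, refid[i], wbeg,
                                         min(wbeg + LINEAR_WINDOW, reflen)),
           wk)
  }
  est <- vapply(key, function(k) get(k, wk), numeric(1), USE.NAMES = FALSE)
  target <- sum(est) / n_jobs
  jobs <- list(); start <- 1L; acc <- 0; ord <- 0L
  for (i in seq_len(n)) {
    acc <- acc + est[i]
    jobs_left <- n_jobs - ord - 1L
    if ((acc >= target && jobs_left > 0L && (n - i) >= jobs_left) || i == n) {
      jobs[[ord + 1L]] <- list(ordinal = ord, site_rows = start:i,
                               data_estimate = acc)
      ord <- ord + 1L; start <- i + 1L; acc <- 0
    }
  }
  jobs
}

#' Run jobs concurrently and merge in ordinal order
#'
#' `worker` must be a pure function of its job; `merge` must be associative.
#' The result equals the sequential fold of `merge` over
#' `worker(job_0) ... worker(job_k)` for every worker count — worker
#' completion order never matters.
#'
#' @param jobs List of jobs (any payload).
#' @param worker Function of one job.
#' @param merge Binary merge function.
#' @param n_workers Number of concurrent workers (forked processes when
#'   > 1 and the platform supports it).
#' @param init Identity element returned for zero jobs and used to seed the
#'   fold.
#' @return The merged result.
#' @export
run_scatter_gather <- function(jobs, worker, merge, n_workers = 1L,
                               init = NULL) {
  if (length(jobs) == 0L) return(init)
  wrapped <- function(job) {
    tryCatch(list(ok = TRUE, value = worker(job)),
             error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
  }
  n_workers <- max(1L, min(n_workers, length(jobs)))
  results <- if (n_workers == 1L || .Platform$OS.type == "windows") {
    lapply(jobs, wrapped)
  } else {
    parallel::mclapply(jobs, wrapped, mc.cores = n_workers,
                       mc.preschedule = TRUE)
  }
  for (i in seq_along(results)) {
    r <- results[[i]]
    if (!is.list(r) || is.null(r$ok))
      stop_with("worker_error", "worker for job ordinal %d crashed", i - 1L)
    if (!r$ok)
      stop_with("worker_error", "worker failed on job ordinal %d: %s",
                i - 1L, r$msg)
  }
  values <- lapply(results, `[[`, "value")
  if (is.null(init)) Reduce(merge, values)
  else Reduce(merge, values, init)
}

#' Group contiguous windows into jobs
#'
#' Windowed pipelines aim for about `4 * n_workers` jobs (load balancing
#' without oversubscription); per-window semantics are preserved because
#' window contents are merged in genome order inside each job.
#' @param windows Data frame from [make_windows()].
#' @param n_jobs Number of contiguous groups to form.
#' @return List of data frames, one per job, in genome order.
#' @export
group_windows <- function(windows, n_jobs) {
  n <- nrow(windows)
  if (n == 0L) return(list())
  n_jobs <- max(1L, min(n_jobs, n))
  cut_id <- ceiling(seq_len(n) / (n / n_jobs))
  unname(split(windows, cut_id))
}
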