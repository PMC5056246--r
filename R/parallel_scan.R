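#' Configuration for the master-worker scan
#'
#' @param n_processes total process count p >= 2: one master (rank 0) doing
#'   housekeeping only, plus p - 1 workers performing the scan.
#' @param params an [rse_params()].
#' @param cutoff Z-score cutoff for the verdict.
#' @param z_mode Z standardization mode, see [compute_z_scores()].
#' @param backend `"pool"` (process pool: fork cluster on unix, PSOCK
#'   elsewhere) or `"inproc"` (the same chunk protocol executed
#'   sequentially in-process; used for tests and as automatic fallback).
#' @param worker_delays optional numeric vector (seconds), one per worker
#'   rank: an artificial delay added before each worker replies, used to
#'   test that the result is independent of completion order.
#' @return A list of class `parallel_config`.
#' @export
parallel_config <- function(n_processes, params = rse_params(), cutoff = 8,
                            z_mode = c("robust", "moment"),
                            backend = c("pool", "inproc"),
                            worker_delays = NULL) {
  n_processes <- as.integer(n_processes)
  if (is.na(n_processes) || n_processes < 2L)
    stop("`n_processes` must be >= 2 (1 master + >= 1 worker)", call. = FALSE)
  assert_params(params)
  z_mode <- match.arg(z_mode)
  backend <- match.arg(backend)
  if (!is.null(worker_delays)) {
    worker_delays <- as.numeric(worker_delays)
    if (length(worker_delays) != n_processes - 1L || any(worker_delays < 0))
      stop("`worker_delays` must give one nonnegative delay per worker",
           call. = FALSE)
  }
  structure(list(n_processes = n_processes, params = params, cutoff = cutoff,
                 z_mode = z_mode, backend = backend,
                 worker_delays = worker_delays),
            class = "parallel_config")
}

#' Partition scan offsets into contiguous per-worker chunks
#'
#' The p - 1 workers receive contiguous chunks in rank order, each of size
#' `floor(n_offsets / (p - 1))`; the remainder is appended to the last
#' rank's chunk, so the last worker is loaded with the little extra work.
#' If there are more workers than offsets the excess (leading) ranks
#' receive empty chunks.
#'
#' @param n_offsets number of offsets to scan (N - 3), >= 1.
#' @param n_processes total process count p >= 2.
#' @return Data frame with columns `worker_rank`, `offset_start`,
#'   `offset_end` (inclusive; `offset_end < offset_start` marks an empty
#'   chunk) and `n_offsets`.
#' @export
partition_offsets <- function(n_offsets, n_processes) {
  n_offsets <- as.integer(n_offsets)
  n_processes <- as.integer(n_processes)
  if (is.na(n_offsets) || n_offsets < 1L)
    stop("`n_offsets` must be >= 1", call. = FALSE)
  if (is.na(n_processes) || n_processes < 2L)
    stop("`n_processes` must be >= 2", call. = FALSE)
  workers <- n_processes - 1L
  sizes <- rep.int(n_offsets %/% workers, workers)
  sizes[workers] <- sizes[workers] + n_offsets %% workers
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  # plain-list data.frame construction: this runs once per worker sweep in
  # exhaustive partition checks, so keep it allocation-light
  structure(list(worker_rank = seq_len(workers),
                 offset_start = starts,
                 offset_end = as.integer(ends),
                 n_offsets = sizes),
            class = "data.frame", row.names = c(NA, -workers))
}

# One worker's job: scan a contiguous offset chunk and report its duration.
# The optional delay (completion-order testing) is added after the scan is
# timed, so it perturbs completion order but not the reported computation
# time.
scan_chunk <- function(structure, offsets, params, delay = 0) {
  t0 <- proc.time()[["elapsed"]]
  results <- if (length(offsets)) alignment_scan(structure, offsets, params)
             else list()
  duration <- proc.time()[["elapsed"]] - t0
  if (delay > 0) Sys.sleep(delay)
  list(results = results, duration = duration,
       wall = proc.time()[["elapsed"]] - t0)
}

make_worker_pool <- function(n_workers) {
  if (.Platform$OS.type == "unix") {
    parallel::makeForkCluster(n_workers)
  } else {
    cl <- parallel::makePSOCKcluster(n_workers)
    parallel::clusterCall(cl, function(lp) { .libPaths(lp); invisible(NULL) },
                          .libPaths())
    cl
  }
}

#' Master-worker parallel alignment scan
#'
#' Rank 0 (this process) performs housekeeping only: it partitions the
#' offsets `1..N-3` into contiguous chunks ([partition_offsets()]),
#' dispatches the structure and one chunk to every worker, blocks until
#' every worker has replied, concatenates the per-offset results in offset
#' order and then computes Z-scores, best offset, axis and verdict through
#' exactly the same final aggregation as the serial [detect_symmetry()].
#' The returned scan result is therefore identical to the serial one for
#' any process count.
#'
#' If the process pool cannot be created the scan falls back to the
#' in-process backend with a warning; the result is still valid. A failing
#' worker raises an error naming its rank and chunk.
#'
#' @param structure a [protein_structure()] with at least 5 residues.
#' @param config a [parallel_config()].
#' @return List with `result` (a `scan_result`), `timing` (a list of class
#'   `timing_report`: `t_parallel`, `communication_s`, `computation_s`,
#'   `postprocessing_s`, `n_processes`, `backend`) and `chunks` (the
#'   partition used).
#' @export
run_parallel <- function(structure, config) {
  assert_structure(structure)
  if (!inherits(config, "parallel_config"))
    stop("`config` must be a `parallel_config`", call. = FALSE)
  n <- n_residues(structure)
  if (n < 5L)
    stop("need N >= 5 (at least 2 offsets) to scan", call. = FALSE)

  t_total0 <- proc.time()[["elapsed"]]
  chunks <- partition_offsets(n - 3L, config$n_processes)
  delays <- config$worker_delays
  if (is.null(delays)) delays <- rep(0, nrow(chunks))
  jobs <- lapply(seq_len(nrow(chunks)), function(w) {
    offs <- if (chunks$n_offsets[w] > 0L)
      seq.int(chunks$offset_start[w], chunks$offset_end[w]) else integer(0)
    list(rank = chunks$worker_rank[w], offsets = offs, delay = delays[w])
  })

  backend_used <- config$backend
  cl <- NULL
  if (config$backend == "pool") {
    cl <- tryCatch(make_worker_pool(nrow(chunks)), error = function(e) NULL)
    if (is.null(cl)) {
      warning("worker pool unavailable; falling back to in-process scan",
              call. = FALSE)
      backend_used <- "inproc"
    } else {
      on.exit(parallel::stopCluster(cl), add = TRUE)
    }
  }

  worker_fn <- function(job, structure, params) {
    tryCatch(
      c(scan_chunk(structure, job$offsets, params, job$delay),
        list(rank = job$rank, ok = TRUE)),
      error = function(e) list(rank = job$rank, ok = FALSE,
                               message = conditionMessage(e))
    )
  }

  t_comm0 <- proc.time()[["elapsed"]]
  replies <- if (!is.null(cl)) {
    parallel::clusterApply(cl, jobs, worker_fn, structure = structure,
                           params = config$params)
  } else {
    lapply(jobs, worker_fn, structure = structure, params = config$params)
  }
  gather_s <- proc.time()[["elapsed"]] - t_comm0

  for (r in replies) {
    if (!isTRUE(r$ok)) {
      j <- jobs[[r$rank]]
      stop(sprintf("worker rank %d failed on offsets %s..%s: %s", r$rank,
                   if (length(j$offsets)) min(j$offsets) else "-",
                   if (length(j$offsets)) max(j$offsets) else "-",
                   r$message), call. = FALSE)
    }
  }

  durations <- vapply(replies, function(r) r$duration, numeric(1))
  walls <- vapply(replies, function(r) r$wall, numeric(1))
  # communication = master-side dispatch+gather time not accounted for by
  # worker wall time (max wall for concurrent workers, sum when sequential)
  busy <- if (!is.null(cl)) max(walls, 0) else sum(walls)
  communication_s <- max(0, gather_s - busy)

  t_post0 <- proc.time()[["elapsed"]]
  alignments <- do.call(c, lapply(replies, function(r) r$results))
  offsets <- seq_len(n - 3L)
  result <- finalize_scan(structure, offsets, alignments, config$cutoff,
                          config$z_mode)
  postprocessing_s <- proc.time()[["elapsed"]] - t_post0

  timing <- structure(
    list(t_parallel = proc.time()[["elapsed"]] - t_total0,
         communication_s = communication_s,
         computation_s = max(durations, 0),
         postprocessing_s = postprocessing_s,
         n_processes = config$n_processes,
         backend = backend_used),
    class = "timing_report"
  )
  list(result = result, timing = timing, chunks = chunks)
}

#' Measure parallel speedup against the serial scan
#'
#' Runs the serial scan (wall time T1) and the parallel scan (wall time Tp)
#' on the same input, verifies that the two produce identical scores and
#' verdict, and reports the speedup S = T1 / Tp together with the ideal
#' speedup p - 1 (only the p - 1 workers compute) and the parallel
#' efficiency S / (p - 1). Efficiency above 1 is flagged as timing noise.
#'
#' @param structure a [protein_structure()].
#' @param config a [parallel_config()].
#' @return A list of class `timing_report` with fields `t_serial`,
#'   `t_parallel`, `communication_s`, `computation_s`, `postprocessing_s`,
#'   `speedup`, `ideal_speedup`, `efficiency`, `efficiency_noise`,
#'   `results_identical`, `n_processes`, `backend`.
#' @export
measure_speedup <- function(structure, config) {
  t0 <- proc.time()[["elapsed"]]
  serial <- detect_symmetry(structure, config$params, config$cutoff,
                            config$z_mode)
  t_serial <- proc.time()[["elapsed"]] - t0

  par <- run_parallel(structure, config)
  timing <- par$timing

  identical_results <-
    identical(serial$t_scores, par$result$t_scores) &&
    identical(serial$z_scores, par$result$z_scores) &&
    identical(serial$best_offset, par$result$best_offset) &&
    identical(serial$is_symmetric, par$result$is_symmetric)
  if (!identical_results)
    warning("serial and parallel scans disagree; timings reported anyway",
            call. = FALSE)

  speedup <- t_serial / timing$t_parallel
  ideal <- config$n_processes - 1L
  structure(
    c(list(t_serial = t_serial), unclass(timing),
      list(speedup = speedup,
           ideal_speedup = ideal,
           efficiency = speedup / ideal,
           efficiency_noise = speedup / ideal > 1,
           results_identical = identical_results)),
    class = "timing_report"
  )
}

#' @export
print.timing_report <- function(x, ...) {
  cat("<timing_report>\n")
  if (!is.null(x$t_serial))
    cat(sprintf("  serial T1       : %.3f s\n", x$t_serial))
  cat(sprintf("  parallel Tp     : %.3f s (%d processes, %s backend)\n",
              x$t_parallel, x$n_processes, x$backend))
  cat(sprintf("  communication   : %.3f s\n", x$communication_s))
  cat(sprintf("  computation     : %.3f s (max over workers)\n",
              x$computation_s))
  cat(sprintf("  postprocessing  : %.3f s\n", x$postprocessing_s))
  if (!is.null(x$speedup))
    cat(sprintf("  speedup S=T1/Tp : %.2f (ideal %d, efficiency %.2f%s)\n",
                x$speedup, x$ideal_speedup, x$efficiency,
                if (isTRUE(x$efficiency_noise)) ", timing noise" else ""))
  invisible(x)
}
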