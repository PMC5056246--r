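test_that("offset partition is a contiguous disjoint cover, remainder last", {
  # forced arithmetic: 506 offsets over 99 workers = 98 x 5 + (5 + 11)
  ch <- partition_offsets(506, 100)
  expect_equal(nrow(ch), 99L)
  expect_equal(ch$n_offsets, c(rep(5L, 98), 16L))
  expect_equal(ch$offset_start[1], 1L)
  expect_equal(ch$offset_end[99], 506L)

  # one worker takes everything
  one <- partition_offsets(57, 2)
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$offset_start, one$offset_end), c(1L, 57L))

  # more workers than offsets: leading ranks go empty
  few <- partition_offsets(3, 6)
  expect_equal(few$n_offsets, c(0L, 0L, 0L, 0L, 3L))

  expect_error(partition_offsets(0, 4), ">= 1")
  expect_error(partition_offsets(10, 1), ">= 2")
})

test_that("partition invariants hold across a broad size/process sweep", {
  bad <- 0L
  for (n in c(1:64, 100, 333, 509, 1000)) {
    for (p in 2:33) {
      ch <- partition_offsets(n, p)
      sizes <- ch$n_offsets
      covered <- sizes > 0L
      ok <- nrow(ch) == p - 1L &&
        sum(sizes) == n &&
        all(sizes[-length(sizes)] == n %/% (p - 1L)) &&
        all(ch$offset_end - ch$offset_start + 1L == sizes | sizes == 0L) &&
        (!any(covered) ||
           all(ch$offset_start[covered][1] == 1L &
                 utils::tail(ch$offset_end[covered], 1) == n))
      if (!ok) bad <- bad + 1L
    }
  }
  expect_equal(bad, 0L)
})

test_that("parallel scan reproduces the serial scan exactly", {
  s <- make_cn_structure(cn_spec(4, 6, radius = 10, noise_sd = 0, seed = 1))
  serial <- detect_symmetry(s)
  for (p in c(2, 4, 8)) {
    par <- run_parallel(s, parallel_config(p))
    expect_same_scan(serial, par$result)
    expect_equal(nrow(par$chunks), p - 1L)
  }
})

test_that("in-process backend follows the same chunk protocol and result", {
  s <- make_random_coil(24, seed = 4)
  serial <- detect_symmetry(s)
  par <- run_parallel(s, parallel_config(5, backend = "inproc"))
  expect_same_scan(serial, par$result)
  expect_identical(par$timing$backend, "inproc")
  expect_length(par$result$t_scores, 21L)
})

test_that("reassembly preserves offset order for uneven chunking", {
  # 57 offsets over 8 workers: 7 x 7 + (7 + 1)
  s <- make_random_coil(60, seed = 11)
  par <- run_parallel(s, parallel_config(9, backend = "inproc"))
  expect_equal(par$chunks$n_offsets, c(rep(7L, 7), 8L))
  expect_length(par$result$t_scores, 57L)
  serial <- detect_symmetry(s)
  expect_same_scan(serial, par$result)
})

test_that("result does not depend on worker completion order", {
  s <- make_cn_structure(cn_spec(3, 8, radius = 10, noise_sd = 0.2, seed = 9))
  base <- run_parallel(s, parallel_config(4))
  # force the first worker to finish last and vice versa
  delayed <- run_parallel(s, parallel_config(4, worker_delays = c(0.6, 0.3, 0)))
  expect_same_scan(base$result, delayed$result)
})

test_that("timing report fields are well-formed", {
  s <- make_random_coil(40, seed = 6)
  par <- run_parallel(s, parallel_config(3))
  tm <- par$timing
  expect_gte(tm$communication_s, 0)
  expect_gte(tm$computation_s, 0)
  expect_gte(tm$postprocessing_s, 0)
  expect_gte(tm$t_parallel, 0)

  rep <- measure_speedup(s, parallel_config(3, backend = "inproc"))
  expect_true(rep$results_identical)
  expect_equal(rep$speedup, rep$t_serial / rep$t_parallel, tolerance = 1e-9)
  expect_equal(rep$ideal_speedup, 2L)
  expect_equal(rep$efficiency, rep$speedup / 2, tolerance = 1e-9)
})

test_that("postprocessing is minor relative to computation on large inputs", {
  s <- make_random_coil(200, seed = 12)
  par <- run_parallel(s, parallel_config(3, backend = "inproc"))
  expect_lt(par$timing$postprocessing_s, par$timing$computation_s)
})

test_that("worker failures are reported with rank and chunk", {
  s <- make_random_coil(20, seed = 1)
  cfg <- parallel_config(3, backend = "inproc")
  # sabotage one chunk by injecting an invalid offset through the chunk API
  expect_error(
    parasymd:::scan_chunk(s, offsets = 99, params = rse_params()),
    "1..N-3")
  bad <- structure(list(n_processes = 3L, params = "not params", cutoff = 8,
                        z_mode = "robust", backend = "inproc",
                        worker_delays = NULL), class = "parallel_config")
  expect_error(run_parallel(s, bad), "rank")
})

test_that("configuration validation", {
  expect_error(parallel_config(1), ">= 2")
  expect_error(parallel_config(4, worker_delays = c(1, 2)), "per worker")
})
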