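test_that("seed correspondence enumerates the overlap of the shift", {
  p3 <- initial_correspondence(10, 3)
  expect_equal(p3, cbind(i = 1:7, j = 4:10), ignore_attr = TRUE)
  p7 <- initial_correspondence(10, 7)
  expect_equal(p7, cbind(i = 1:3, j = 8:10), ignore_attr = TRUE)
  for (k in 1:7) expect_equal(nrow(initial_correspondence(10, k)), 10 - k)
  expect_error(initial_correspondence(10, 8), "1..N-3")
  expect_error(initial_correspondence(10, 0), "1..N-3")
})

test_that("scan emits one result per offset and offsets are independent", {
  s <- make_random_coil(10, seed = 3)
  full <- alignment_scan(s, 1:7)
  expect_length(full, 7L)
  solo <- alignment_scan(s, 3)
  expect_identical(solo[[1]], full[[3]])
  shuffled <- alignment_scan(s, c(5, 2, 7))
  expect_identical(shuffled[[1]], full[[5]])
  expect_identical(shuffled[[3]], full[[7]])
  expect_error(alignment_scan(s, integer(0)), "non-empty")
  expect_error(alignment_scan(s, 8), "1..N-3")
})

test_that("scan T-score maxima sit at repeat-unit multiples for a C4", {
  s <- make_cn_structure(cn_spec(4, 6, radius = 10, noise_sd = 0, seed = 1))
  res <- detect_symmetry(s)
  t <- res$t_scores
  expect_true(which.max(t) %in% c(6, 12, 18))
  expect_gt(t[6], t[7])
  expect_equal(t[6], 18, tolerance = 1e-6)
  expect_gt(t[6], t[12]) # larger overlap at the finer repeat
})

test_that("Z standardization: robust scale, moment fallback, invariances", {
  expect_equal(compute_z_scores(rep(5, 9)), rep(0, 9))

  # MAD of a constant background with one outlier is zero -> moment fallback
  t <- c(rep(1, 8), 10)
  expect_equal(stats::mad(t), 0)
  z <- compute_z_scores(t)
  expect_equal(z[9], (10 - mean(t)) / stats::sd(t))
  expect_equal(z[9], (10 - 2) / 3, tolerance = 1e-12)
  expect_equal(z, compute_z_scores(t, z_mode = "moment"))

  set.seed(31)
  t2 <- rnorm(25, 10, 2)
  expect_equal(compute_z_scores(t2),
               (t2 - median(t2)) / stats::mad(t2), tolerance = 1e-12)
  # location invariance
  expect_equal(compute_z_scores(t2 + 100), compute_z_scores(t2),
               tolerance = 1e-9)
  expect_equal(compute_z_scores(t2 + 100, "moment"),
               compute_z_scores(t2, "moment"), tolerance = 1e-9)
  expect_error(compute_z_scores(1), "at least 2")
})

test_that("screw-axis decomposition handles canonical cases", {
  id <- extract_symmetry_axis(identity_transform())
  expect_equal(id$angle_deg, 0)
  expect_true(id$degenerate)

  tr <- axis_to_transform(c(0, 0, 1), angle_deg = 90, pitch = 2)
  ax <- extract_symmetry_axis(tr)
  expect_equal(ax$angle_deg, 90, tolerance = 1e-9)
  expect_equal(abs(ax$direction[3]), 1, tolerance = 1e-9)
  expect_equal(ax$pitch * sign(ax$direction[3]), 2, tolerance = 1e-9)
  expect_equal(ax$point[1:2], c(0, 0), tolerance = 1e-9)
  expect_false(ax$degenerate)

  # half-turn: antisymmetric part vanishes, axis still recovered
  half <- extract_symmetry_axis(axis_to_transform(c(1, 1, 0), angle_deg = 180))
  expect_equal(half$angle_deg, 180, tolerance = 1e-6)
  expect_equal(axis_angle_to(half$direction, c(1, 1, 0)), 0, tolerance = 1e-4)
})

test_that("random screws round-trip through the decomposition", {
  set.seed(32)
  worst <- 0
  for (q in 1:200) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    p <- rnorm(3, sd = 10); p <- p - sum(p * u) * u # on-axis representative
    ang <- runif(1, 5, 175)
    pitch <- runif(1, -5, 5)
    tr <- axis_to_transform(u, p, ang, pitch)
    ax <- extract_symmetry_axis(tr)
    worst <- max(worst,
                 max(abs(ax$direction - u)),
                 max(abs(ax$point - p)),
                 abs(ax$angle_deg - ang),
                 abs(ax$pitch - pitch))
    back <- axis_to_transform(ax$direction, ax$point, ax$angle_deg, ax$pitch)
    worst <- max(worst, max(abs(back$rotation - tr$rotation)),
                 max(abs(back$translation - tr$translation)))
  }
  expect_lt(worst, 1e-6)
})

test_that("improper rotations are rejected by the axis decomposition", {
  expect_error(extract_symmetry_axis(list(rotation = diag(c(1, 1, -1)),
                                          translation = rep(0, 3))),
               "transformation")
  expect_error(transformation(diag(c(1, 1, -1))), "proper")
})

test_that("verdict, axis and angle are recovered for Cn positive controls", {
  s <- make_cn_structure(cn_spec(4, 15, radius = 12, noise_sd = 0, seed = 1))
  res <- detect_symmetry(s, cutoff = 8)
  expect_true(res$is_symmetric)
  expect_equal(res$best_offset %% 15, 0)
  expect_lt(abs(res$axis$angle_deg - 90), 1)
  expect_lt(axis_angle_to(res$axis$direction, c(0, 0, 1)), 1)
  # the axis passes near the generation axis (the z axis through origin)
  expect_lt(sqrt(sum(res$axis$point[1:2]^2)), 1)

  # cutoff is configurable (8 default, 10 the stricter convention)
  expect_equal(formals(detect_symmetry)$cutoff, 8)
  res10 <- detect_symmetry(s, cutoff = 10)
  expect_identical(res10$t_scores, res$t_scores)
  expect_identical(res10$is_symmetric, max(res$z_scores) >= 10)
})

test_that("random coil is not called symmetric", {
  res <- detect_symmetry(make_random_coil(60, seed = 7), cutoff = 8)
  expect_false(res$is_symmetric)
  expect_length(res$t_scores, 57L)
})

test_that("verdict is monotone in the cutoff", {
  res <- detect_symmetry(make_random_coil(40, seed = 2))
  zmax <- max(res$z_scores)
  for (cut in c(0, 2, 8, 10, 50)) {
    r <- detect_symmetry(make_random_coil(40, seed = 2), cutoff = cut)
    expect_identical(r$is_symmetric, zmax >= cut)
  }
})

test_that("whole-scan output is invariant under a global rigid motion", {
  s <- make_cn_structure(cn_spec(3, 12, radius = 12, noise_sd = 0.3, seed = 2))
  g <- random_rigid_transform(seed = 7)
  a <- detect_symmetry(s)
  b <- detect_symmetry(transform_structure(s, g))
  expect_equal(a$t_scores, b$t_scores, tolerance = 1e-6)
  expect_identical(a$is_symmetric, b$is_symmetric)
  expect_identical(a$best_offset, b$best_offset)
  # the recovered axis moves with the structure
  expect_lt(axis_angle_to(b$axis$direction,
                          as.numeric(g$rotation %*% a$axis$direction)), 0.1)
})

test_that("structures below the minimum scan size are rejected", {
  tiny <- protein_structure(matrix(rnorm(12), ncol = 3))
  expect_error(detect_symmetry(tiny), "N >= 5")
})
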