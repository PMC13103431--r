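test_that("component bases have the expected boundary behaviour", {
  p <- ref_protocol()
  b <- component_bases(p)
  # no activation before light onset
  expect_equal(b$qE[1], 0)
  expect_equal(b$qT[1], 0)
  expect_equal(b$qI[1], 0)
  # photoinhibition is frozen in the dark: last value equals the light-end value
  expect_equal(b$qI[91], b$qI[46])
  expect_true(all(b$qI >= 0 & b$qI <= 1))
  expect_true(all(b$qE >= 0 & b$qE <= 1))
  expect_true(all(b$qT >= 0 & b$qT <= 1))
})

test_that("qI basis is non-decreasing; qT rises in light and relaxes in dark", {
  b <- component_bases(ref_protocol())
  expect_true(all(diff(b$qI) >= -1e-12))
  light <- 1:45   # pulses strictly inside the light phase
  dark <- 46:91
  expect_true(all(diff(b$qT[light]) >= -1e-12))
  expect_true(all(diff(b$qT[dark]) <= 1e-12))
})

test_that("qE basis shows an interior transitory maximum matching the dense-grid oracle", {
  p <- ref_protocol()
  b <- component_basis(p, "qE")
  i_max <- which.max(b)
  expect_gt(i_max, 1)
  expect_lt(i_max, 46)   # maximum within the light phase, not at its end
  oracle <- qe_dense_oracle()
  # basis values at pulse times agree with the closed forms
  pt <- pulse_times(p)
  expect_equal(b, oracle$values[match(pt, oracle$times)], tolerance = 1e-12)
  # the pulse-grid argmax brackets the dense-grid argmax within one period
  t_dense <- oracle$times[which.max(oracle$values)]
  expect_lt(abs(pt[i_max] - t_dense), 20)
})

test_that("noise-free traces are exactly the stated linear combination", {
  p <- ref_protocol()
  b <- component_bases(p)
  cp <- cell_params(F0 = 700, A_qE = 0.4, A_qT = 0.25, A_qI = 0.1)
  tr <- simulate_trace(cp, p, b)
  manual <- 700 * (1 - 0.4 * b$qE + 0.25 * b$qT - 0.1 * b$qI)
  expect_equal(tr, manual, tolerance = 1e-15)
  # single-component linearity: trace/F0 - 1 = A * basis
  cp2 <- cell_params(F0 = 1, A_qT = 0.3)
  expect_equal(simulate_trace(cp2, p, b) - 1, 0.3 * b$qT, tolerance = 1e-15)
  # null cell gives a flat trace
  expect_equal(simulate_trace(cell_params(F0 = 5), p, b), rep(5, 91))
})

test_that("amplitude combinations that kill Fm' are rejected", {
  p <- ref_protocol()
  b <- component_bases(p)
  expect_error(simulate_trace(cell_params(A_qE = 1.4), p, b), "amplitudes")
  expect_error(simulate_trace(cell_params(A_qE = 0.8, A_qI = 0.5), p, b),
               "amplitudes")
})

test_that("noisy traces are reproducible given a seed", {
  p <- ref_protocol()
  b <- component_bases(p)
  cp <- cell_params(A_qT = 0.3, noise_sigma = 0.02)
  t1 <- simulate_trace(cp, p, b, seed = 5)
  t2 <- simulate_trace(cp, p, b, seed = 5)
  expect_identical(t1, t2)
  expect_false(identical(t1, simulate_trace(cp, p, b, seed = 6)))
  expect_true(all(t1 > 0))
})

test_that("simulated populations are deterministic and carry ground truth", {
  p <- ref_protocol()
  spec <- population_spec("pop_qt", n_cells = 25, seed = 3)
  a <- simulate_population(spec, p)
  b2 <- simulate_population(spec, p)
  expect_identical(a$traces, b2$traces)
  expect_identical(a$ground_truth, b2$ground_truth)
  expect_equal(nrow(a$ground_truth), 25)
  expect_equal(nrow(a$traces), 25 * 91)
  expect_true(all(a$traces$fm_value > 0))
  # single-component population: other amplitudes exactly zero
  expect_true(all(a$ground_truth$A_qE == 0))
  expect_true(all(a$ground_truth$A_qI == 0))
  expect_true(all(a$ground_truth$A_qT > 0))
  # null population: all amplitudes zero
  z <- simulate_population(population_spec("pop_0", n_cells = 10, seed = 4), p)
  expect_true(all(z$ground_truth[, c("A_qE", "A_qT", "A_qI")] == 0))
})

test_that("log-normal amplitude dispersion reproduces the requested CV", {
  p <- ref_protocol()
  in_range <- vapply(1:20, function(s) {
    spec <- population_spec("pop_qt", n_cells = 200, seed = 100 + s)
    gt <- simulate_population(spec, p)$ground_truth
    cv <- stats::sd(gt$A_qT) / mean(gt$A_qT)
    cv >= 0.15 && cv <= 0.25
  }, logical(1))
  expect_gte(sum(in_range), 19)
})

test_that("repeat pairs share ground truth and differ only in noise", {
  p <- ref_protocol()
  spec <- population_spec("pop_qt", n_cells = 30, seed = 9)
  pair <- simulate_repeat_pair(spec, p)
  expect_identical(pair[[1]]$ground_truth, pair[[2]]$ground_truth)
  expect_false(identical(trace_matrix(pair[[1]]), trace_matrix(pair[[2]])))
  expect_equal(pair[[1]]$repeat_index, 1L)
  expect_equal(pair[[2]]$repeat_index, 2L)
  # zero noise: repeats coincide exactly
  spec0 <- population_spec("pop_qt", n_cells = 10, seed = 9, noise_sigma = 0)
  pair0 <- simulate_repeat_pair(spec0, p)
  expect_identical(trace_matrix(pair0[[1]]), trace_matrix(pair0[[2]]))
})

test_that("trace_matrix round-trips the long format", {
  p <- ref_protocol()
  ts <- simulate_population(population_spec("pop_qe", n_cells = 8, seed = 2), p)
  m <- trace_matrix(ts)
  expect_equal(dim(m), c(8, 91))
  expect_equal(rownames(m), ts$ground_truth$cell_id)
  one <- ts$traces[ts$traces$cell_id == rownames(m)[3], ]
  expect_equal(m[3, ], one$fm_value)
})

test_that("simulated movies plant disks consistent with their mask and traces", {
  p <- ref_protocol()
  spec <- population_spec("pop_qt", n_cells = 12, seed = 21, noise_sigma = 0)
  mv <- simulate_movie(spec, p, height = 128, width = 128, cell_radius_px = 5)
  expect_equal(dim(mv$frames), c(128, 128, 91))
  expect_equal(length(unique(mv$mask[mv$mask > 0])), 12)
  expect_identical(mv$timestamps, pulse_times(p))
  planted <- trace_matrix(mv$trace_set)
  for (lab in c(1, 7, 12)) {
    px <- mv$mask == lab
    means <- vapply(1:91, function(k) mean(mv$frames[, , k][px]), numeric(1))
    expect_gt(stats::cor(means, planted[lab, ]), 0.99)
  }
  # single cell: one connected foreground component
  mv1 <- simulate_movie(population_spec("pop_0", n_cells = 1, seed = 5),
                        p, height = 64, width = 64, cell_radius_px = 4)
  expect_equal(length(unique(mv1$mask[mv1$mask > 0])), 1)
})

test_that("impossible disk packings are rejected", {
  p <- ref_protocol()
  spec <- population_spec("pop_0", n_cells = 50, seed = 1)
  expect_error(simulate_movie(spec, p, height = 32, width = 32,
                              cell_radius_px = 6), "cannot place")
})
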