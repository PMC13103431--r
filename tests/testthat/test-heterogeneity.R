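test_that("repeat-distance matrix matches hand computation and brute force", {
  A <- rbind(c(0, 0, 0), c(1, 0, 0))
  B <- rbind(c(0, 0, 0), c(1, 0, 0))
  rd <- repeat_distance_matrix(A, B)
  expect_equal(rd$D, rbind(c(0, 1), c(1, 0)))
  expect_equal(rd$D_ii, c(0, 0))
  set.seed(9)
  A2 <- matrix(rnorm(50 * 3), 50, 3)
  B2 <- A2 + matrix(rnorm(50 * 3, sd = 0.1), 50, 3)
  rd2 <- repeat_distance_matrix(A2, B2)
  expect_equal(rd2$D, brute_force_distance_matrix(A2, B2), tolerance = 1e-12)
  expect_length(rd2$D_ij, 50 * 49)
  expect_true(all(rd2$D >= 0))
  expect_error(repeat_distance_matrix(A2, B2[1:10, ]), "same cells")
})

test_that("identical repeats give a zero diagonal", {
  set.seed(10)
  A <- matrix(rnorm(30 * 3), 30, 3)
  rd <- repeat_distance_matrix(A, A)
  expect_equal(rd$D_ii, rep(0, 30))
})

test_that("the variance test behaves on null, scaled and separated samples", {
  set.seed(11)
  x <- rnorm(100)
  same <- variance_difference_test(x, x)
  expect_lt(same$statistic, 1e-10)
  expect_gt(same$p_value, 0.99)
  # detection power: sd 1 vs sd 3
  a <- rnorm(200); b <- rnorm(200, sd = 3)
  expect_lt(variance_difference_test(a, b)$p_value, 0.001)
  # scale invariance of the Levene statistic
  t1 <- variance_difference_test(a, b)
  t2 <- variance_difference_test(10 * a, 10 * b)
  expect_equal(t1$statistic, t2$statistic, tolerance = 1e-10)
  # F-test variant
  tf <- variance_difference_test(a, b, method = "f")
  expect_lt(tf$p_value, 0.001)
  expect_error(variance_difference_test(1:2, 1:5), "at least 3")
  expect_error(variance_difference_test(rep(1, 5), rep(2, 5)), "constant")
})

test_that("variation coefficient is SD over mean and scale-invariant", {
  sc <- tibble::tibble(qT_score = c(2, 4, 6), qE_score = 1, qI_score = 1)
  expect_equal(variation_coefficient(sc, "qT"), stats::sd(c(2, 4, 6)) / 4)
  expect_equal(variation_coefficient(dplyr::mutate(sc, qT_score = qT_score * 5), "qT"),
               variation_coefficient(sc, "qT"), tolerance = 1e-12)
  expect_equal(variation_coefficient(tibble::tibble(qT_score = rep(3, 5)), "qT"), 0)
  expect_error(variation_coefficient(tibble::tibble(qT_score = c(-2, 0, 2)), "qT"),
               "undefined|positive")
})

test_that("generator CV propagates to the scored qT axis", {
  m <- small_model()
  cvs <- vapply(c(61, 62, 63), function(s) {
    ts <- simulate_population(population_spec("pop_qt", n_cells = 150, seed = s),
                              ref_protocol())
    variation_coefficient(score_traces(ts, m), "qT")
  }, numeric(1))
  expect_true(all(cvs >= 0.13 & cvs <= 0.27))
})

test_that("grid traces partition points and gate on the occupancy minimum", {
  pts <- rbind(matrix(0.5, 4, 2),            # 4 identical points in one box
               matrix(c(0.1, 0.9), 1, 2))    # a lone point elsewhere
  traces <- matrix(rep(c(2, 4), each = 5), 5, 2)
  gm <- grid_traces(pts, traces, bounds = c(0, 1, 0, 1), grid_n = 4,
                    min_count = 3)
  expect_equal(sum(gm$count), 5)
  filled <- gm[gm$count == 4, ]
  expect_length(filled$mean_trace[[1]], 2)
  expect_equal(filled$mean_trace[[1]][1], 1)  # display-normalized to the start
  lone <- gm[gm$count == 1, ]
  expect_null(lone$mean_trace[[1]])
  # counts are conserved under permutation
  perm <- sample(5)
  gm2 <- grid_traces(pts[perm, ], traces[perm, ], bounds = c(0, 1, 0, 1),
                     grid_n = 4, min_count = 3)
  expect_equal(sum(gm2$count), 5)
  expect_equal(dplyr::arrange(as.data.frame(gm2[, 1:3]), ix, iy),
               dplyr::arrange(as.data.frame(gm[, 1:3]), ix, iy))
  # empty input gives an empty map
  expect_equal(nrow(grid_traces(matrix(0, 0, 2), matrix(0, 0, 5),
                                bounds = c(0, 1, 0, 1))), 0)
})

test_that("affine trends recover exact lines and reject degenerate clouds", {
  x <- seq(-2, 2, length.out = 30)
  exact <- affine_trend(cbind(x, 2 * x + 1))
  expect_equal(exact$slope, 2, tolerance = 1e-10)
  expect_equal(exact$intercept, 1, tolerance = 1e-10)
  expect_equal(exact$r, 1, tolerance = 1e-12)
  ols <- affine_trend(cbind(x, 2 * x + 1), method = "ols")
  expect_equal(ols$slope, 2, tolerance = 1e-10)
  expect_error(affine_trend(matrix(1, 5, 2)), "degenerate")
  expect_error(affine_trend(cbind(1:2, 1:2)), "at least 3")
})

test_that("an isotropic cloud shows no spurious correlation", {
  set.seed(12)
  pts <- matrix(rnorm(1000), 500, 2)
  tr <- affine_trend(pts)
  expect_lt(abs(tr$r), 0.15)
})

test_that("TLS and OLS differ under symmetric noise as theory predicts", {
  set.seed(13)
  x <- rnorm(400)
  y <- x + rnorm(400, sd = 1)      # equal noise on both axes
  tls <- affine_trend(cbind(x + rnorm(400, sd = 1), y))
  ols <- affine_trend(cbind(x + rnorm(400, sd = 1), y), method = "ols")
  # OLS attenuates toward zero; TLS stays nearer the true unit slope
  expect_gt(tls$slope, ols$slope)
})

test_that("centroid trends handle collinear centroids and order permutations", {
  mk <- function(cx, cy, n = 40) {
    tibble::tibble(qT_score = rnorm(n, cx, 0.01),
                   qE_score = rnorm(n, cy, 0.01), qI_score = 0)
  }
  sets <- list(mk(0, 1), mk(1, 3), mk(2, 5), mk(3, 7))  # centroids on y=2x+1
  ct <- centroid_trend(sets)
  expect_equal(ct$centroid_fit$slope, 2, tolerance = 0.05)
  expect_equal(ct$centroid_fit$r, 1, tolerance = 1e-3)
  ct_perm <- centroid_trend(sets[c(3, 1, 4, 2)])
  expect_equal(ct_perm$centroid_fit$slope, ct$centroid_fit$slope,
               tolerance = 1e-12)
  expect_error(centroid_trend(sets[1:2]), "3 time points")
})

test_that("an HL-activation series with rising qE and falling qT slopes downward", {
  m <- small_model()
  p <- ref_protocol()
  qe_medians <- c(0.15, 0.3, 0.45, 0.6)
  qt_medians <- c(0.35, 0.3, 0.25, 0.2)
  sets <- lapply(1:4, function(i) {
    spec <- population_spec("wt", n_cells = 80,
                            amplitude_median = c(qE = qe_medians[i],
                                                 qT = qt_medians[i], qI = 0),
                            seed = 300 + i)
    score_traces(simulate_population(spec, p), m)
  })
  ct <- centroid_trend(sets)   # (qT, qE) plane
  expect_lt(ct$centroid_fit$slope, 0)
  expect_lt(ct$centroid_fit$r, -0.9)
})

test_that("anticorrelated ground-truth amplitudes surface in the score plane", {
  m <- small_model()
  p <- ref_protocol()
  b <- component_bases(p)
  rs <- vapply(c(71, 72, 73), function(s) {
    withr::with_seed(s, {
      n <- 150
      z <- matrix(rnorm(2 * n), n, 2) %*% chol(matrix(c(1, -0.8, -0.8, 1), 2))
      A_qE <- pmin(0.6 * exp(0.3 * z[, 1]), 1)
      A_qT <- 0.3 * exp(0.2 * z[, 2])
      traces <- t(vapply(seq_len(n), function(i) {
        simulate_trace(cell_params(F0 = 1000, A_qE = A_qE[i], A_qT = A_qT[i],
                                   noise_sigma = 0.02), p, b)
      }, numeric(91)))
      sc <- score_traces(traces, m)
      affine_trend(cbind(sc$qT_score, sc$qE_score))$r
    })
  }, numeric(1))
  # The recovered correlation is attenuated from the planted -0.8 by the
  # qE-into-qT interaction crosstalk of sum-normalized mixtures (a model
  # trained on single-component populations cannot cancel it), but it must
  # stay clearly negative: under independent amplitudes the crosstalk
  # alone would push the score correlation positive.
  expect_true(all(rs < -0.25))
  expect_lte(mean(rs), -0.4)
})
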