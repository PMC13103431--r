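# waveforms used to build exactly-spanned data
make_waveforms <- function(k, T_len = 91) {
  t <- seq(0, 1, length.out = T_len)
  W <- rbind(
    rep(1, T_len),
    exp(-3 * t),
    1 - exp(-5 * t),
    sin(pi * t) + 1.5,
    t^2 + 0.5,
    cos(2 * pi * t) + 2
  )[seq_len(k), , drop = FALSE]
  W / rowSums(W)   # sum-normalized
}

test_that("a dictionary can represent exactly spanned data to machine precision", {
  W <- make_waveforms(4)
  set.seed(1)
  idx <- sample(4, 60, replace = TRUE)
  Y <- W[idx, ]
  d <- fit_dictionary(Y, n_atoms = 6, lambda = 1e-8, seed = 3)
  err <- reconstruction_error(Y, d)
  expect_lt(err$mean, 1e-10)
  # the residual part of the final objective is at the same machine-level
  # floor (the recorded objective also carries the small L1 term)
  X <- encode(Y, d)
  expect_lt(0.5 * sum((Y - X %*% d$atoms)^2), 1e-8)
})

test_that("the fit objective is non-increasing on arbitrary inputs", {
  set.seed(5)
  for (rep in 1:3) {
    Y <- matrix(abs(rnorm(40 * 30)) + 0.1, 40, 30)
    Y <- normalize_sum(Y)
    d <- fit_dictionary(Y, n_atoms = 5, lambda = 1e-5, seed = rep, max_iter = 40)
    expect_true(all(diff(d$fit_history) <= 1e-15))
    expect_equal(sqrt(rowSums(d$atoms^2)), rep(1, 5), tolerance = 1e-9)
  }
})

test_that("encoding an atom recovers a unit code and huge lambda gives zero", {
  W <- make_waveforms(5)
  d <- structure(
    list(atoms = W / sqrt(rowSums(W^2)), lambda = 1e-8, n_atoms = 5,
         seed = 1, fit_history = numeric(0), iterations = 0, converged = TRUE),
    class = "npq_dictionary"
  )
  y <- d$atoms[3, ]
  x <- encode(y, d, lambda = 1e-10)
  recon <- as.vector(x %*% d$atoms)
  expect_equal(recon, y, tolerance = 1e-6)
  expect_equal(0.5 * sum((y - recon)^2), 0, tolerance = 1e-12)
  # lambda at least the max atom correlation shuts every coefficient off
  lam_max <- max(abs(d$atoms %*% y))
  expect_equal(encode(y, d, lambda = lam_max * 1.01), matrix(0, 1, 5))
})

test_that("coordinate-descent codes match the exhaustive active-set oracle", {
  set.seed(11)
  T_len <- 20
  for (rep in 1:5) {
    D <- matrix(rnorm(5 * T_len), 5, T_len)
    D <- D / sqrt(rowSums(D^2))
    dct <- structure(
      list(atoms = D, lambda = 1e-3, n_atoms = 5, seed = 1,
           fit_history = numeric(0), iterations = 0, converged = TRUE),
      class = "npq_dictionary"
    )
    Y <- matrix(rnorm(4 * T_len, sd = 0.5), 4, T_len)
    X <- encode(Y, dct, lambda = 1e-3)
    for (i in 1:4) {
      oracle <- lasso_oracle(Y[i, ], D, 1e-3)
      obj_cd <- 0.5 * sum((Y[i, ] - as.vector(X[i, ] %*% D))^2) +
        1e-3 * sum(abs(X[i, ]))
      expect_lt(abs(obj_cd - oracle$obj), 1e-8)
    }
  }
})

test_that("encoding at lambda ~ 0 equals the least-squares solution", {
  set.seed(13)
  D <- matrix(rnorm(6 * 40), 6, 40)
  D <- D / sqrt(rowSums(D^2))
  dct <- structure(
    list(atoms = D, lambda = 0, n_atoms = 6, seed = 1,
         fit_history = numeric(0), iterations = 0, converged = TRUE),
    class = "npq_dictionary"
  )
  y <- rnorm(40)
  x <- as.vector(encode(y, dct, lambda = 0))
  ls <- as.vector(solve(D %*% t(D), D %*% y))
  expect_equal(x, ls, tolerance = 1e-6)
})

test_that("codes agree with an independent lasso solver", {
  skip_if_not_installed("glmnet")
  set.seed(17)
  D <- matrix(rnorm(5 * 50), 5, 50)
  D <- D / sqrt(rowSums(D^2))
  dct <- structure(
    list(atoms = D, lambda = 5e-3, n_atoms = 5, seed = 1,
         fit_history = numeric(0), iterations = 0, converged = TRUE),
    class = "npq_dictionary"
  )
  y <- rnorm(50, sd = 0.3)
  x <- as.vector(encode(y, dct))
  # glmnet minimizes 1/(2n)||y - Xb||^2 + lam||b||_1
  g <- glmnet::glmnet(t(D), y, lambda = 5e-3 / 50, intercept = FALSE,
                      standardize = FALSE, thresh = 1e-14)
  xg <- as.vector(g$beta)
  obj <- function(b) 0.5 * sum((y - as.vector(b %*% D))^2) + 5e-3 * sum(abs(b))
  expect_lt(abs(obj(x) - obj(xg)), 1e-8)
})

test_that("reconstruction error is zero on perfect fits and order-invariant", {
  W <- make_waveforms(3)
  d <- structure(
    list(atoms = W / sqrt(rowSums(W^2)), lambda = 1e-9, n_atoms = 3,
         seed = 1, fit_history = numeric(0), iterations = 0, converged = TRUE),
    class = "npq_dictionary"
  )
  Y <- d$atoms[c(1, 2, 3, 2), ]
  err <- reconstruction_error(Y, d)
  expect_lt(err$mean, 1e-12)
  Y2 <- Y[c(3, 1, 4, 2), ]
  err2 <- reconstruction_error(Y2, d)
  expect_equal(sort(err$per_trace), sort(err2$per_trace), tolerance = 1e-12)
})

test_that("atom-count selection finds the spanning size", {
  W <- make_waveforms(4)
  set.seed(3)
  mix <- matrix(abs(rnorm(80 * 4)), 80, 4)
  mix <- mix / rowSums(mix)
  Y <- mix %*% W   # rank-4 mixtures
  sel <- select_n_atoms(Y, candidates = c(2, 4, 6), threshold = 1e-8,
                        lambda = 1e-9, seeds = 1:3, max_iter = 60)
  expect_equal(as.integer(sel), 4L)
  errs <- attr(sel, "errors")
  expect_gt(errs[["2"]], 1e-8)
  # an infinite threshold keeps the first candidate
  expect_equal(as.integer(select_n_atoms(Y, c(2, 4), threshold = Inf,
                                         seeds = 1, max_iter = 5)), 2L)
  expect_error(select_n_atoms(Y, integer(0)), "candidate")
})

test_that("mean reconstruction error does not increase with dictionary size", {
  sets <- small_training_sets()
  Y <- normalize_sum(do.call(rbind, lapply(sets, trace_matrix)))
  sub <- balanced_subsample(Y, rep(names(sets), each = nrow(Y) / 4),
                            n_samples = 120, seed = 5)
  errs <- vapply(c(2, 6, 10), function(k) {
    mean(vapply(1:5, function(s) {
      d <- fit_dictionary(sub$traces, n_atoms = k, lambda = 1e-6, seed = s,
                          max_iter = 30)
      reconstruction_error(sub$traces, d)$mean
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("dictionary fitting rejects invalid inputs", {
  expect_error(fit_dictionary(matrix(1, 3, 10), n_atoms = 5), "at least")
  expect_error(fit_dictionary(matrix(c(1, NA), 10, 10)), "finite")
  bad <- matrix(1, 4, 9)
  d <- fit_dictionary(normalize_sum(matrix(runif(100), 10, 10)),
                      n_atoms = 3, seed = 1, max_iter = 5)
  expect_error(encode(bad, d), "match")
})
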