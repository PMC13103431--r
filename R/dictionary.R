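#' Learn a sparse dictionary of elementary trace waveforms
#'
#' Factorizes a set of (sum-normalized) Fm' traces as sparse linear
#' combinations of `n_atoms` learned waveforms by minimizing, over the
#' dictionary `D` (unit-norm atoms) and the coefficients `X`,
#'
#' \deqn{\tfrac12\,\lVert Y - XD\rVert_F^2 + \lambda\,\lVert X\rVert_1,}
#'
#' via alternating optimization: the sparse-coding step solves the lasso
#' per trace by cyclic coordinate descent; the dictionary-update step
#' minimizes the reconstruction term atom by atom on the unit sphere
#' (block coordinate descent with renormalization). Both steps decrease
#' the objective, so the recorded `fit_history` is non-increasing.
#'
#' @param Y Numeric matrix, rows = traces (each typically sum-normalized),
#'   columns = pulses.
#' @param n_atoms Number of dictionary atoms.
#' @param lambda L1 regularization weight (per trace).
#' @param seed Integer seed for the atom initialization (atoms start as
#'   `n_atoms` randomly chosen training traces, unit-normalized).
#' @param max_iter Maximum alternating iterations. Alternating dictionary
#'   learning shows a long flat objective tail; the default stops well
#'   inside it (reconstruction error changes by far less than the
#'   selection threshold beyond this point).
#' @param tol Stop when the relative objective decrease falls below `tol`.
#' @param coding_sweeps Coordinate-descent sweep cap for the coding step
#'   during fitting (each sweep decreases the objective, so an early cap
#'   preserves monotonicity); [encode()] always runs to full convergence.
#' @return An object of class `npq_dictionary`: list with `atoms`
#'   (`n_atoms x T`, unit Euclidean row norms), `lambda`, `n_atoms`,
#'   `seed`, `fit_history` (objective per iteration), `iterations`,
#'   `converged`.
#' @export
fit_dictionary <- function(Y, n_atoms = 10, lambda = 1e-6, seed = 1L,
                           max_iter = 80, tol = 1e-7, coding_sweeps = 200L) {
  stopifnot(is.matrix(Y))
  if (!all(is.finite(Y))) stop("Y must be finite", call. = FALSE)
  n <- nrow(Y)
  if (n < n_atoms) stop("need at least n_atoms traces", call. = FALSE)
  init <- withr::with_seed(seed, sample(n, n_atoms))
  D <- Y[init, , drop = FALSE]
  D <- D / sqrt(rowSums(D^2))
  X <- matrix(0, n, n_atoms)
  history <- numeric(0)
  obj_prev <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    X <- lasso_code(Y, D, lambda, X_init = X, max_sweeps = coding_sweeps)
    X <- lasso_polish(Y, D, lambda, X)
    obj <- dict_objective(Y, D, X, lambda)
    history <- c(history, obj)
    if (is.finite(obj_prev) && (obj_prev - obj) <= tol * max(obj_prev, 1e-300)) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
    D <- update_atoms(Y, D, X)
  }
  structure(
    list(atoms = D, lambda = lambda, n_atoms = n_atoms, seed = seed,
         fit_history = history, iterations = it, converged = converged),
    class = "npq_dictionary"
  )
}

dict_objective <- function(Y, D, X, lambda) {
  0.5 * sum((Y - X %*% D)^2) + lambda * sum(abs(X))
}

# Cyclic coordinate descent for the lasso sparse-coding step, vectorized
# across traces. Convergence is monitored on the objective: with strongly
# correlated atoms the coefficients can drift along near-flat directions
# long after the objective (which is what downstream stages consume) has
# converged, so the stop rule is a relative objective decrease below tol.
lasso_code <- function(Y, D, lambda, X_init = NULL,
                       max_sweeps = 2000L, tol = 1e-10) {
  n <- nrow(Y)
  k <- nrow(D)
  G <- tcrossprod(D)            # k x k atom Gram matrix
  B <- Y %*% t(D)               # n x k correlations with atoms
  yy <- sum(Y^2)
  X <- if (is.null(X_init)) matrix(0, n, k) else X_init
  obj_prev <- Inf
  for (sweep in seq_len(max_sweeps)) {
    for (j in seq_len(k)) {
      r <- B[, j] - X %*% G[, j] + X[, j] * G[j, j]
      X[, j] <- sign(r) * pmax(abs(r) - lambda, 0) / G[j, j]
    }
    obj <- 0.5 * (yy - 2 * sum(X * B) + sum(X * (X %*% G))) + lambda * sum(abs(X))
    if (obj_prev - obj < tol * max(obj, 1e-300)) break
    obj_prev <- obj
  }
  X
}

# Feature-sign active-set polish (Lee et al.-style): starting from the
# coordinate-descent solution, iterate exact KKT solves on the current
# support with sign-consistency line searches and violated-gradient
# activations. On success this lands on the exact lasso minimizer,
# removing the slow coordinate-descent tail on strongly correlated
# dictionaries; the per-row objective never increases.
lasso_polish <- function(Y, D, lambda, X, max_steps = 100L) {
  G <- tcrossprod(D)
  B <- Y %*% t(D)
  for (i in seq_len(nrow(Y))) {
    X[i, ] <- feature_sign_row(B[i, ], G, lambda, X[i, ], max_steps)
  }
  X
}

feature_sign_row <- function(b, G, lambda, x, max_steps) {
  k <- length(b)
  # objective up to the constant 0.5*||y||^2
  obj <- function(z) 0.5 * sum(z * (G %*% z)) - sum(b * z) + lambda * sum(abs(z))
  A <- which(x != 0)
  theta <- sign(x)
  for (step in seq_len(max_steps)) {
    g <- b - as.vector(G %*% x)
    inactive <- setdiff(seq_len(k), A)
    viol <- inactive[abs(g[inactive]) > lambda * (1 + 1e-12) + 1e-15]
    if (length(A) == 0 && length(viol) == 0) return(x)
    if (length(viol) > 0) {
      j <- viol[which.max(abs(g[viol]))]
      A <- c(A, j)
      theta[j] <- sign(g[j])
    }
    xs <- tryCatch(solve(G[A, A, drop = FALSE], b[A] - lambda * theta[A]),
                   error = function(e) NULL)
    if (is.null(xs)) return(x)   # singular subproblem: keep the CD solution
    if (all(sign(xs) == theta[A])) {
      xnew <- numeric(k)
      xnew[A] <- xs
      g2 <- b - as.vector(G %*% xnew)
      rest <- setdiff(seq_len(k), A)
      if (length(rest) == 0 ||
          all(abs(g2[rest]) <= lambda * (1 + 1e-9) + 1e-12)) {
        return(if (obj(xnew) <= obj(x)) xnew else x)
      }
      x <- xnew
      next
    }
    # sign change along the segment: stop at the best zero crossing
    xa <- x[A]
    dir <- xs - xa
    cross <- -xa / dir
    ts <- sort(unique(c(cross[is.finite(cross) & cross > 0 & cross <= 1], 1)))
    best_o <- obj(x)
    best_x <- x
    for (t in ts) {
      cand <- numeric(k)
      cand[A] <- xa + t * dir
      cand[abs(cand) < 1e-15] <- 0
      o <- obj(cand)
      if (o < best_o) {
        best_o <- o
        best_x <- cand
      }
    }
    if (identical(best_x, x)) return(x)
    x <- best_x
    A <- which(x != 0)
    theta <- sign(x)
  }
  x
}

# Block-coordinate dictionary update on the unit sphere: for each atom,
# the optimum of the reconstruction term at fixed codes is the normalized
# residual correlation. Unused atoms (negligible code energy) are kept.
update_atoms <- function(Y, D, X) {
  C <- crossprod(X)         # k x k
  BY <- crossprod(X, Y)     # k x T
  for (j in seq_len(nrow(D))) {
    v <- BY[j, ] - C[j, ] %*% D + C[j, j] * D[j, ]
    nv <- sqrt(sum(v^2))
    if (nv > 1e-12) D[j, ] <- v / nv
  }
  D
}

#' Encode traces against a fixed dictionary
#'
#' Solves the lasso \eqn{\min_x \tfrac12\lVert y - D^\top x\rVert_2^2 +
#' \lambda\lVert x\rVert_1} for every trace at fixed atoms, by coordinate
#' descent run to convergence.
#'
#' @param Y Numeric matrix, rows = traces, or a single numeric trace.
#' @param dictionary An [fit_dictionary()] object.
#' @param lambda L1 weight; defaults to the dictionary's training lambda.
#' @return Numeric code matrix, rows = traces, columns = atoms.
#' @export
encode <- function(Y, dictionary, lambda = dictionary$lambda) {
  stopifnot(inherits(dictionary, "npq_dictionary"))
  if (!is.matrix(Y)) Y <- matrix(Y, nrow = 1)
  if (ncol(Y) != ncol(dictionary$atoms)) {
    stop("trace length ", ncol(Y), " does not match atom length ",
         ncol(dictionary$atoms), call. = FALSE)
  }
  X <- lasso_code(Y, dictionary$atoms, lambda)
  lasso_polish(Y, dictionary$atoms, lambda, X)
}

#' Reconstruction error of encoded traces
#'
#' Per-trace squared Euclidean residual `||y - D'x||^2` on the given
#' (typically sum-normalized) traces, plus its mean over traces.
#'
#' @inheritParams encode
#' @param codes Code matrix from [encode()]; computed if missing.
#' @return List with `per_trace` (numeric vector) and `mean` (scalar).
#' @export
reconstruction_error <- function(Y, dictionary, codes = NULL) {
  if (!is.matrix(Y)) Y <- matrix(Y, nrow = 1)
  if (is.null(codes)) codes <- encode(Y, dictionary)
  resid <- Y - codes %*% dictionary$atoms
  per <- rowSums(resid^2)
  list(per_trace = per, mean = mean(per))
}

#' Select the dictionary size by a reconstruction-error threshold
#'
#' Fits dictionaries of each candidate size over several seeds and returns
#' the smallest size whose seed-averaged mean reconstruction error is at or
#' below the threshold; if none qualifies, the largest candidate is
#' returned with a warning.
#'
#' @inheritParams fit_dictionary
#' @param candidates Increasing integer vector of candidate atom counts.
#' @param threshold Mean reconstruction-error threshold.
#' @param seeds Integer vector of seeds to average over (>= 3 recommended).
#' @return The selected atom count (integer), with attribute `"errors"`
#'   giving the seed-averaged error per candidate.
#' @export
select_n_atoms <- function(Y, candidates, threshold = 2e-4,
                           lambda = 1e-6, seeds = 1:3, max_iter = 80) {
  if (length(candidates) == 0) stop("no candidate sizes given", call. = FALSE)
  stopifnot(!is.unsorted(candidates))
  errs <- vapply(candidates, function(k) {
    mean(vapply(seeds, function(s) {
      d <- fit_dictionary(Y, n_atoms = k, lambda = lambda, seed = s,
                          max_iter = max_iter)
      reconstruction_error(Y, d)$mean
    }, numeric(1)))
  }, numeric(1))
  ok <- which(errs <= threshold)
  sel <- if (length(ok) > 0) candidates[ok[1]] else {
    warning("no candidate reaches the reconstruction-error threshold; ",
            "returning the largest", call. = FALSE)
    candidates[length(candidates)]
  }
  structure(as.integer(sel), errors = stats::setNames(errs, candidates))
}

#' @export
print.npq_dictionary <- function(x, ...) {
  cat("<npq_dictionary>", x$n_atoms, "atoms x", ncol(x$atoms),
      "pulses; lambda =", format(x$lambda), "; iterations =", x$iterations,
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  invisible(x)
}

#' Tidy a fitted dictionary into a long tibble of atom waveforms
#'
#' @param x An `npq_dictionary`.
#' @param ... Unused.
#' @return Tibble with columns `atom`, `pulse_index`, `value`.
#' @export
tidy.npq_dictionary <- function(x, ...) {
  tibble::tibble(
    atom = rep(seq_len(x$n_atoms), each = ncol(x$atoms)),
    pulse_index = rep(seq_len(ncol(x$atoms)), times = x$n_atoms),
    value = as.vector(t(x$atoms))
  )
}

#' One-row fit summary of a dictionary
#'
#' @inheritParams tidy.npq_dictionary
#' @return Tibble with `n_atoms`, `lambda`, `objective`, `iterations`,
#'   `converged`.
#' @export
glance.npq_dictionary <- function(x, ...) {
  tibble::tibble(
    n_atoms = x$n_atoms, lambda = x$lambda,
    objective = x$fit_history[length(x$fit_history)],
    iterations = x$iterations, converged = x$converged
  )
}
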