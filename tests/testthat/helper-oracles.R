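# Independent oracles used to freeze expected values. These deliberately
# share no code with the implementation paths they check.

# Brute-force nearest-neighbour distances via a full double loop.
brute_force_nn <- function(x) {
  n <- nrow(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt(sum((x[i, ] - x[j, ])^2))
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# Brute-force repeat-distance matrix.
brute_force_distance_matrix <- function(A, B) {
  n <- nrow(A)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    D[i, j] <- sqrt(sum((A[i, ] - B[j, ])^2))
  }
  D
}

# Exhaustive active-set lasso oracle: enumerate every support/sign pattern,
# solve the corresponding equality-constrained quadratic program and keep
# the best KKT-consistent solution. Exponential in the atom count - only
# for tiny dictionaries.
lasso_oracle <- function(y, D, lambda) {
  k <- nrow(D)
  G <- D %*% t(D)
  b <- as.vector(D %*% y)
  best <- list(obj = 0.5 * sum(y^2), x = rep(0, k))   # empty support
  signs <- c(-1, 1)
  for (mask in 1:(2^k - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    n_s <- length(S)
    grid <- as.matrix(expand.grid(rep(list(signs), n_s)))
    for (g in seq_len(nrow(grid))) {
      s <- grid[g, ]
      xs <- tryCatch(solve(G[S, S, drop = FALSE], b[S] - lambda * s),
                     error = function(e) NULL)
      if (is.null(xs)) next
      if (any(sign(xs) != s)) next
      x <- rep(0, k)
      x[S] <- xs
      obj <- 0.5 * sum((y - as.vector(t(D) %*% x))^2) + lambda * sum(abs(x))
      if (obj < best$obj) best <- list(obj = obj, x = x)
    }
  }
  best
}

# Dense-grid evaluation of the qE activation over the reference protocol,
# directly from the closed-form light/dark expressions.
qe_dense_oracle <- function(tau_rise = 30, tau_transitory = 300,
                            transitory_fraction = 0.6, tau_relax = 30,
                            dt = 1) {
  t_light <- seq(0, 900 - dt, by = dt)
  e_light <- (1 - exp(-t_light / tau_rise)) *
    (transitory_fraction + (1 - transitory_fraction) * exp(-t_light / tau_transitory))
  e_end <- (1 - exp(-900 / tau_rise)) *
    (transitory_fraction + (1 - transitory_fraction) * exp(-900 / tau_transitory))
  t_dark <- seq(900, 1800, by = dt)
  e_dark <- e_end * exp(-(t_dark - 900) / tau_relax)
  list(times = c(t_light, t_dark), values = c(e_light, e_dark))
}
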