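#' Repeat-distance matrix in the NPQ score space
#'
#' For the same `n` cells scored in two consecutive protocol repeats,
#' `D[i, j]` is the Euclidean distance between cell `i`'s position in the
#' first repeat and cell `j`'s position in the second. The diagonal
#' (same-cell) distances capture measurement noise; the off-diagonal
#' (cell-to-population) distances additionally capture biological
#' heterogeneity, so a diagonal distribution much narrower than the
#' off-diagonal one indicates that the observed cell-to-cell spread is not
#' noise.
#'
#' @param scores_a,scores_b Score tibbles (from [score_traces()]) or
#'   `n x 3` matrices for the two repeats, cells aligned by row (and
#'   checked by `cell_id` when present).
#' @param test Variance-comparison method passed to
#'   [variance_difference_test()].
#' @return List of class `npq_repeat_distance`: `D` (`n x n`), `D_ii`
#'   (diagonal), `D_ij` (off-diagonal values), `sd_ii`, `sd_ij`,
#'   `variance_test` (tibble with `statistic`, `p_value`, `method`).
#' @export
repeat_distance_matrix <- function(scores_a, scores_b, test = "levene") {
  A <- score_coords(scores_a)
  B <- score_coords(scores_b)
  if (!all(dim(A) == dim(B))) stop("repeats must score the same cells", call. = FALSE)
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B))) {
    stop("cell ids differ between repeats; align cells first", call. = FALSE)
  }
  D <- sqrt(pmax(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B), 0))
  # the diagonal is the statistic of interest: compute it exactly from
  # coordinate differences rather than the expanded-square shortcut
  D_ii <- sqrt(rowSums((A - B)^2))
  diag(D) <- D_ii
  D_ij <- D[row(D) != col(D)]
  vt <- tryCatch(variance_difference_test(D_ii, D_ij, method = test),
                 error = function(e) tibble::tibble(
                   statistic = NA_real_, p_value = NA_real_,
                   method = paste0(test, " (degenerate)")))
  structure(
    list(D = D, D_ii = D_ii, D_ij = D_ij,
         sd_ii = stats::sd(D_ii), sd_ij = stats::sd(D_ij),
         variance_test = vt),
    class = "npq_repeat_distance"
  )
}

score_coords <- function(x) {
  if (is.matrix(x)) return(x)
  m <- as.matrix(x[, c("qT_score", "qE_score", "qI_score")])
  if ("cell_id" %in% names(x)) rownames(m) <- x$cell_id
  m
}

#' @export
print.npq_repeat_distance <- function(x, ...) {
  cat("<npq_repeat_distance>", length(x$D_ii), "cells; sd(D_ii) =",
      signif(x$sd_ii, 3), "sd(D_ij) =", signif(x$sd_ij, 3),
      "; ", x$variance_test$method, "p =",
      format.pval(x$variance_test$p_value), "\n")
  invisible(x)
}

#' Test whether two samples have different variances
#'
#' Default is the median-centered Levene (Brown-Forsythe) test, robust to
#' the skewness typical of distance distributions; the classical F test is
#' available as an alternative.
#'
#' @param sample_1,sample_2 Numeric vectors (>= 3 values each).
#' @param method `"levene"` or `"f"`.
#' @return Tibble with `statistic`, `p_value`, `method`.
#' @export
variance_difference_test <- function(sample_1, sample_2,
                                     method = c("levene", "f")) {
  method <- match.arg(method)
  if (length(sample_1) < 3 || length(sample_2) < 3) {
    stop("both samples need at least 3 values", call. = FALSE)
  }
  if (stats::sd(sample_1) == 0 && stats::sd(sample_2) == 0) {
    stop("both samples are constant: variance comparison degenerate",
         call. = FALSE)
  }
  if (method == "levene") {
    vals <- c(sample_1, sample_2)
    grp <- factor(rep(c("a", "b"), c(length(sample_1), length(sample_2))))
    lt <- car::leveneTest(vals, grp, center = stats::median)
    tibble::tibble(statistic = lt[1, "F value"],
                   p_value = lt[1, "Pr(>F)"],
                   method = "levene")
  } else {
    ft <- stats::var.test(sample_1, sample_2)
    tibble::tibble(statistic = unname(ft$statistic),
                   p_value = ft$p.value, method = "f")
  }
}

#' Coefficient of variation of one score axis
#'
#' Standard deviation relative to the mean of the named axis over cells.
#' Undefined (error) when the mean is not positive.
#'
#' @param scores Score tibble from [score_traces()].
#' @param axis One of `"qT"`, `"qE"`, `"qI"` (or the full column name).
#' @return Scalar CV.
#' @export
variation_coefficient <- function(scores, axis) {
  col <- if (axis %in% names(scores)) axis else paste0(axis, "_score")
  if (!col %in% names(scores)) stop("unknown axis: ", axis, call. = FALSE)
  v <- scores[[col]]
  m <- mean(v)
  if (m <= 0) stop("mean of ", col, " is not positive; CV undefined", call. = FALSE)
  stats::sd(v) / m
}

#' Grid-trace map: average trace per cell of a 2D score grid
#'
#' Partitions a rectangle of a 2D score plane into `grid_n x grid_n`
#' half-open boxes (the last row/column edge closed) and, wherever a box
#' holds more than `min_count` cells, stores the average of their
#' display-normalized traces. This renders how the trace waveform morphs
#' along the score axes.
#'
#' @param scores_2d Numeric `n x 2` matrix (or data frame) of the two
#'   score coordinates (x, y).
#' @param display_traces Numeric `n x T` matrix of traces; each is
#'   normalized to its initial value before averaging.
#' @param bounds Length-4 numeric `c(xmin, xmax, ymin, ymax)`; default is
#'   the 1st-99th percentile rectangle of the data.
#' @param grid_n Grid size per side.
#' @param min_count A mean trace is emitted only where the box count
#'   strictly exceeds this.
#' @return Tibble of class `npq_grid_traces` with one row per non-empty
#'   box: `ix`, `iy` (1-based box indices), `count`, `mean_trace`
#'   (list-column; `NULL` where `count <= min_count`), plus attributes
#'   `bounds`, `grid_n`, `min_count`.
#' @export
grid_traces <- function(scores_2d, display_traces, bounds = NULL,
                        grid_n = 8, min_count = 3) {
  S <- as.matrix(scores_2d)
  stopifnot(ncol(S) == 2, nrow(S) == nrow(display_traces))
  if (nrow(S) == 0) {
    out <- tibble::tibble(ix = integer(), iy = integer(), count = integer(),
                          mean_trace = list())
    return(structure(out, bounds = bounds, grid_n = grid_n,
                     min_count = min_count, class = c("npq_grid_traces", class(out))))
  }
  if (is.null(bounds)) {
    qx <- stats::quantile(S[, 1], c(0.01, 0.99), names = FALSE)
    qy <- stats::quantile(S[, 2], c(0.01, 0.99), names = FALSE)
    bounds <- c(qx, qy)
  }
  disp <- normalize_to_initial(as.matrix(display_traces))
  bx <- seq(bounds[1], bounds[2], length.out = grid_n + 1)
  by <- seq(bounds[3], bounds[4], length.out = grid_n + 1)
  ix <- findInterval(S[, 1], bx, rightmost.closed = TRUE)
  iy <- findInterval(S[, 2], by, rightmost.closed = TRUE)
  inb <- ix >= 1 & ix <= grid_n & iy >= 1 & iy <= grid_n
  df <- tibble::tibble(ix = ix[inb], iy = iy[inb],
                       row = which(inb))
  out <- df |>
    dplyr::group_by(.data$ix, .data$iy) |>
    dplyr::summarise(count = dplyr::n(), rows = list(.data$row), .groups = "drop") |>
    dplyr::mutate(mean_trace = purrr::map2(.data$rows, .data$count, function(r, ct) {
      if (ct > min_count) colMeans(disp[r, , drop = FALSE]) else NULL
    })) |>
    dplyr::select(-"rows")
  structure(out, bounds = bounds, grid_n = grid_n, min_count = min_count,
            class = c("npq_grid_traces", class(out)))
}

#' Affine trend of a 2D point cloud
#'
#' Fits a line through a score-plane point cloud. The default is the
#' orthogonal (total least squares) fit — appropriate when both axes carry
#' comparable noise — with ordinary least squares available for
#' comparison. The Pearson correlation and its p-value are reported
#' alongside.
#'
#' @param points_2d Numeric `n x 2` matrix or data frame (`n >= 3`).
#' @param method `"tls"` (orthogonal) or `"ols"`.
#' @return One-row tibble: `slope`, `intercept`, `r`, `p_value`, `n`,
#'   `method`.
#' @export
affine_trend <- function(points_2d, method = c("tls", "ols")) {
  method <- match.arg(method)
  P <- as.matrix(points_2d)
  stopifnot(ncol(P) == 2)
  if (nrow(P) < 3) stop("need at least 3 points", call. = FALSE)
  vx <- stats::var(P[, 1])
  vy <- stats::var(P[, 2])
  if (vx == 0 && vy == 0) stop("degenerate cloud: no variance", call. = FALSE)
  if (method == "tls") {
    v <- eigen(stats::cov(P), symmetric = TRUE)$vectors[, 1]
    if (abs(v[1]) < 1e-12) stop("orthogonal fit is vertical; use ols on swapped axes",
                                call. = FALSE)
    slope <- v[2] / v[1]
  } else {
    slope <- stats::cov(P[, 1], P[, 2]) / vx
  }
  intercept <- mean(P[, 2]) - slope * mean(P[, 1])
  ct <- if (vx > 0 && vy > 0) stats::cor.test(P[, 1], P[, 2]) else
    list(estimate = NA_real_, p.value = NA_real_)
  tibble::tibble(slope = slope, intercept = intercept,
                 r = unname(ct$estimate), p_value = ct$p.value,
                 n = nrow(P), method = method)
}

#' Trend through per-time-point score centroids
#'
#' For a high-light activation series scored at several time points, fits
#' the affine trend through the per-time-point centroids of the
#' `(qT, qE)` plane and reports the angle between that centroid trend and
#' the pooled per-cloud trend — collinearity of the two indicates that the
#' population-level drift and the single-cell correlation share one axis.
#'
#' @param score_sets List (>= 3) of score tibbles, one per time point.
#' @param axes Character pair of score columns, default
#'   `c("qT_score", "qE_score")`.
#' @param method Trend method as in [affine_trend()].
#' @return List of class `npq_centroid_trend`: `centroid_fit` (trend
#'   tibble), `centroids` (tibble), `cloud_fit` (pooled per-cloud trend),
#'   `alignment_angle_deg`.
#' @export
centroid_trend <- function(score_sets, axes = c("qT_score", "qE_score"),
                           method = "tls") {
  if (length(score_sets) < 3) stop("need at least 3 time points", call. = FALSE)
  centroids <- purrr::imap_dfr(score_sets, function(s, i) {
    tibble::tibble(time_point = i,
                   x = mean(s[[axes[1]]]), y = mean(s[[axes[2]]]))
  })
  centroid_fit <- affine_trend(centroids[, c("x", "y")], method = method)
  pooled <- purrr::map_dfr(score_sets, function(s) {
    tibble::tibble(x = s[[axes[1]]], y = s[[axes[2]]])
  })
  cloud_fit <- affine_trend(pooled, method = method)
  ang <- abs(atan(centroid_fit$slope) - atan(cloud_fit$slope)) * 180 / pi
  structure(
    list(centroid_fit = centroid_fit, centroids = centroids,
         cloud_fit = cloud_fit, alignment_angle_deg = ang),
    class = "npq_centroid_trend"
  )
}

#' @export
print.npq_centroid_trend <- function(x, ...) {
  cat("<npq_centroid_trend> centroid slope", signif(x$centroid_fit$slope, 3),
      "| pooled-cloud slope", signif(x$cloud_fit$slope, 3),
      "| angle", signif(x$alignment_angle_deg, 3), "deg\n")
  invisible(x)
}
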