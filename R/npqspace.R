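#' Multiclass linear discriminant projection of dictionary codes
#'
#' Computes the between-class scatter `S_B` (class-size weighted, from
#' class means vs the global mean) and pooled within-class scatter `S_W`,
#' and extracts the top `c - 1` directions of the generalized eigenproblem
#' `S_B v = mu S_W v` by whitening `S_W` (with a small ridge for
#' stability) and an eigendecomposition of the whitened `S_B` — the
#' SVD-based route to multiclass LDA. With the four training classes this
#' yields a projection from the code space to three dimensions.
#'
#' @param codes Numeric matrix, rows = cells, columns = dictionary atoms.
#' @param labels Class label per row (4 classes for the NPQ design).
#' @param ridge Ridge added to `S_W` (times its mean diagonal) before
#'   whitening.
#' @return An object of class `npq_lda`: list with `T_matrix`
#'   (`n_atoms x (c-1)`), `class_means`, `classes`, `S_B`, `S_W`,
#'   `eigenvalues`.
#' @export
fit_lda <- function(codes, labels, ridge = 1e-8) {
  stopifnot(is.matrix(codes), nrow(codes) == length(labels))
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes", call. = FALSE)
  if (any(table(labels) < 2)) stop("each class needs >= 2 samples", call. = FALSE)
  p <- ncol(codes)
  mu <- colMeans(codes)
  S_B <- matrix(0, p, p)
  S_W <- matrix(0, p, p)
  means <- matrix(0, length(classes), p,
                  dimnames = list(classes, colnames(codes)))
  for (cl in classes) {
    Xc <- codes[labels == cl, , drop = FALSE]
    mc <- colMeans(Xc)
    means[cl, ] <- mc
    d <- mc - mu
    S_B <- S_B + nrow(Xc) * tcrossprod(d)
    S_W <- S_W + crossprod(sweep(Xc, 2, mc))
  }
  # whiten S_W, then eigendecompose the whitened between-class scatter
  Sw_r <- S_W + diag(ridge * mean(diag(S_W)) + 1e-300, p)
  ew <- eigen(Sw_r, symmetric = TRUE)
  W <- ew$vectors %*% diag(1 / sqrt(pmax(ew$values, 1e-300))) %*% t(ew$vectors)
  M <- W %*% S_B %*% W
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  k <- length(classes) - 1L
  Tm <- W %*% em$vectors[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(k)) {
    i <- which.max(abs(Tm[, j]))
    if (Tm[i, j] < 0) Tm[, j] <- -Tm[, j]
  }
  structure(
    list(T_matrix = Tm, class_means = means, classes = classes,
         S_B = S_B, S_W = S_W, eigenvalues = em$values[seq_len(k)]),
    class = "npq_lda"
  )
}

#' Project codes through a fitted LDA
#'
#' @param codes Code matrix (rows = cells).
#' @param lda An [fit_lda()] object.
#' @return Matrix `n x (c-1)` of discriminant coordinates.
#' @export
project_lda <- function(codes, lda) {
  stopifnot(inherits(lda, "npq_lda"))
  codes %*% lda$T_matrix
}

#' First principal direction of a class point cloud
#'
#' Returns the unit leading eigenvector of the class covariance. The sign
#' is fixed so that the vector from `reference_point` (typically the
#' centroid of all other classes) to the class centroid has a positive
#' projection on it; with no reference the largest-magnitude component is
#' made positive.
#'
#' @param points Numeric matrix `m x d`, `m >= 2`.
#' @param reference_point Optional length-`d` point anchoring the sign.
#' @param degenerate_tol Relative eigengap below which the direction is
#'   considered undefined (isotropic cloud) and an error is signalled.
#' @return Unit numeric vector of length `d`.
#' @export
class_principal_direction <- function(points, reference_point = NULL,
                                      degenerate_tol = 1e-9) {
  stopifnot(is.matrix(points), nrow(points) >= 2)
  cv <- stats::cov(points)
  if (all(abs(cv) < 1e-300)) stop("zero covariance: degenerate class", call. = FALSE)
  ev <- eigen((cv + t(cv)) / 2, symmetric = TRUE)
  gap <- (ev$values[1] - ev$values[2]) / max(ev$values[1], 1e-300)
  if (gap < degenerate_tol) {
    stop("principal direction undefined: leading eigengap below tolerance",
         call. = FALSE)
  }
  v <- ev$vectors[, 1]
  if (!is.null(reference_point)) {
    s <- sum((colMeans(points) - reference_point) * v)
    if (s < 0) v <- -v
  } else if (v[which.max(abs(v))] < 0) {
    v <- -v
  }
  v
}

#' Axis alignment of the discriminant space onto (qT, qE, qI)
#'
#' Assembles the transfer matrix `R` whose columns are the principal
#' directions of the qT, qE and qI training clouds in the 3D discriminant
#' space, changes basis by `R^{-1}` (an oblique change of basis — the
#' columns are not orthogonalized), and anchors each axis origin using the
#' populations biologically known to lack the component: the qT origin is
#' the mean over pooled qE, qI and null cells; the qE origin the mean over
#' qI cells; the qI origin the mean over pooled qE, qT and null cells.
#'
#' @param projected Matrix `n x 3` of discriminant coordinates.
#' @param labels Per-row class labels containing `"pop_0"`, `"pop_qe"`,
#'   `"pop_qt"`, `"pop_qi"`.
#' @param cond_bound Maximum admissible condition number of `R`.
#' @return An object of class `npq_alignment`: list with `R` (3 x 3),
#'   `R_inv`, `origins` (named length-3 vector, axes `qT`, `qE`, `qI`).
#' @export
build_alignment <- function(projected, labels, cond_bound = 1e3) {
  stopifnot(is.matrix(projected), ncol(projected) == 3)
  labels <- as.character(labels)
  need <- c("pop_0", "pop_qe", "pop_qt", "pop_qi")
  if (!all(need %in% labels)) {
    stop("alignment needs all four training populations", call. = FALSE)
  }
  dir_for <- function(cl) {
    pts <- projected[labels == cl, , drop = FALSE]
    other <- colMeans(projected[labels != cl, , drop = FALSE])
    class_principal_direction(pts, reference_point = other)
  }
  R <- cbind(qT = dir_for("pop_qt"), qE = dir_for("pop_qe"),
             qI = dir_for("pop_qi"))
  cn <- kappa(R, exact = TRUE)
  if (!is.finite(cn) || cn > cond_bound) {
    stop("transfer matrix ill-conditioned (condition number ",
         format(cn, digits = 3), " > ", cond_bound, ")", call. = FALSE)
  }
  R_inv <- solve(R)
  aligned <- projected %*% t(R_inv)
  origins <- c(
    qT = mean(aligned[labels %in% c("pop_qe", "pop_qi", "pop_0"), 1]),
    qE = mean(aligned[labels == "pop_qi", 2]),
    qI = mean(aligned[labels %in% c("pop_qe", "pop_qt", "pop_0"), 3])
  )
  structure(list(R = R, R_inv = R_inv, origins = origins),
            class = "npq_alignment")
}

#' Apply an axis alignment to discriminant coordinates
#'
#' @param projected Matrix `n x 3`.
#' @param alignment An [build_alignment()] object.
#' @return Matrix `n x 3` with columns `qT_score`, `qE_score`, `qI_score`.
#' @export
apply_alignment <- function(projected, alignment) {
  out <- sweep(projected %*% t(alignment$R_inv), 2, alignment$origins)
  colnames(out) <- c("qT_score", "qE_score", "qI_score")
  out
}

#' Train the full NPQ scoring pipeline
#'
#' Composes the training stages: pool the four labelled populations,
#' sum-normalize every trace, drop isolated traces (nearest-neighbour
#' distance above `isolation_d`), learn the sparse dictionary on a
#' balanced random subsample, encode all surviving traces, fit the
#' multiclass LDA on all labelled codes, and anchor the (qT, qE, qI) axes.
#' All randomness derives from `seed` (split deterministically per stage).
#'
#' @param trace_sets List of four `npq_trace_set`s (or a named list of
#'   trace matrices) covering populations `pop_0`, `pop_qe`, `pop_qt`,
#'   `pop_qi`.
#' @param n_atoms,lambda Dictionary size and L1 weight.
#' @param n_samples Balanced subsample size for dictionary training.
#' @param isolation_d Isolation radius on sum-normalized traces.
#' @param seed Master integer seed.
#' @param max_iter Dictionary iteration cap.
#' @return An object of class `npq_model`: list with `dictionary`, `lda`,
#'   `alignment`, `config`, `filter_report`, `training` (tibble of
#'   training-set scores), `class_counts`.
#' @export
train_npq_model <- function(trace_sets, n_atoms = 10, lambda = 1e-6,
                            n_samples = 300, isolation_d = 0.01,
                            seed = 1L, max_iter = 80) {
  mats <- lapply(trace_sets, function(ts) {
    if (inherits(ts, "npq_trace_set")) trace_matrix(ts) else as.matrix(ts)
  })
  labs <- unlist(lapply(seq_along(trace_sets), function(i) {
    ts <- trace_sets[[i]]
    lab <- if (inherits(ts, "npq_trace_set")) ts$label else names(trace_sets)[i]
    rep(lab, nrow(mats[[i]]))
  }))
  Y <- do.call(rbind, mats)
  ids <- rownames(Y) %||% as.character(seq_len(nrow(Y)))
  Yn <- normalize_sum(Y)
  iso <- remove_isolated(Yn, d = isolation_d)
  Yn <- iso$traces
  labs <- labs[iso$keep]
  ids <- ids[iso$keep]
  sub <- balanced_subsample(Yn, labs, n_samples = n_samples,
                            seed = seed * 1000L + 2L)
  dict <- fit_dictionary(sub$traces, n_atoms = n_atoms, lambda = lambda,
                         seed = seed * 1000L + 1L, max_iter = max_iter)
  codes <- encode(Yn, dict)
  lda <- fit_lda(codes, labs)
  proj <- project_lda(codes, lda)
  alignment <- build_alignment(proj, labs)
  aligned <- apply_alignment(proj, alignment)
  training <- tibble::tibble(
    cell_id = ids, population = labs,
    qT_score = aligned[, "qT_score"],
    qE_score = aligned[, "qE_score"],
    qI_score = aligned[, "qI_score"]
  )
  structure(
    list(
      dictionary = dict, lda = lda, alignment = alignment,
      config = list(n_atoms = n_atoms, lambda = lambda,
                    n_samples = n_samples, isolation_d = isolation_d,
                    seed = seed, max_iter = max_iter),
      filter_report = iso$report,
      training = training,
      class_counts = table(labs)
    ),
    class = "npq_model"
  )
}

#' Score traces in the 3D NPQ space
#'
#' Sum-normalizes the traces (idempotent), encodes them against the
#' model's dictionary, projects through the LDA and applies the axis
#' alignment, yielding per-cell `(qT, qE, qI)` scores.
#'
#' @param traces An `npq_trace_set`, a long trace tibble, or a numeric
#'   matrix (rows = cells).
#' @param model An [train_npq_model()] object.
#' @return Tibble with columns `cell_id`, `population` (if known),
#'   `repeat` (if known), `qT_score`, `qE_score`, `qI_score`.
#' @export
score_traces <- function(traces, model) {
  stopifnot(inherits(model, "npq_model"))
  meta <- NULL
  if (inherits(traces, "npq_trace_set")) {
    meta <- dplyr::distinct(traces$traces, .data$cell_id, .data$population,
                            .data$`repeat`)
    mat <- trace_matrix(traces)
  } else if (is.data.frame(traces)) {
    meta <- dplyr::distinct(traces, .data$cell_id,
      population = if ("population" %in% names(traces)) .data$population else NA,
      `repeat` = if ("repeat" %in% names(traces)) .data$`repeat` else NA)
    mat <- trace_matrix(traces)
  } else {
    mat <- as.matrix(traces)
  }
  if (ncol(mat) != ncol(model$dictionary$atoms)) {
    stop("trace length ", ncol(mat), " does not match model (",
         ncol(model$dictionary$atoms), ")", call. = FALSE)
  }
  codes <- encode(normalize_sum(mat), model$dictionary)
  aligned <- apply_alignment(project_lda(codes, model$lda), model$alignment)
  out <- tibble::as_tibble(aligned)
  out$cell_id <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  if (!is.null(meta)) out <- dplyr::left_join(out, meta, by = "cell_id")
  dplyr::relocate(out, "cell_id")
}

#' Nearest-centroid classification in the NPQ score space
#'
#' Assigns each scored cell to the training population with the nearest
#' centroid in `(qT, qE, qI)` coordinates — the simple readout used to
#' check class separation.
#'
#' @param scores Score tibble from [score_traces()].
#' @param model The trained [train_npq_model()].
#' @return `scores` with an added `predicted` column.
#' @export
classify_nearest_centroid <- function(scores, model) {
  cen <- model$training |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(dplyr::across(dplyr::ends_with("_score"), mean),
                     .groups = "drop")
  S <- as.matrix(scores[, c("qT_score", "qE_score", "qI_score")])
  Cm <- as.matrix(cen[, c("qT_score", "qE_score", "qI_score")])
  d2 <- outer(rowSums(S^2), rowSums(Cm^2), "+") - 2 * S %*% t(Cm)
  scores$predicted <- cen$population[apply(d2, 1, which.min)]
  scores
}

#' @export
print.npq_model <- function(x, ...) {
  cat("<npq_model>", x$config$n_atoms, "atoms ->", ncol(x$lda$T_matrix),
      "discriminant axes; trained on", nrow(x$training), "cells (",
      paste(names(x$class_counts), x$class_counts, collapse = ", "), ")\n")
  invisible(x)
}

#' Tidy the training-set scores of a fitted NPQ model
#'
#' @param x An `npq_model`.
#' @param ... Unused.
#' @return The training score tibble (`cell_id`, `population`, per-axis
#'   scores).
#' @export
tidy.npq_model <- function(x, ...) x$training

#' One-row summary of a fitted NPQ model
#'
#' @inheritParams tidy.npq_model
#' @return Tibble with training size, dictionary fit summary, the Fisher
#'   separability (trace of `S_W^{-1} S_B`) and the transfer-matrix
#'   condition number.
#' @export
glance.npq_model <- function(x, ...) {
  sep <- sum(diag(solve(x$lda$S_W + diag(1e-12, ncol(x$lda$S_W)), x$lda$S_B)))
  tibble::tibble(
    n_training = nrow(x$training),
    n_atoms = x$config$n_atoms,
    lambda = x$config$lambda,
    dict_objective = x$dictionary$fit_history[length(x$dictionary$fit_history)],
    fisher_separability = sep,
    R_condition = kappa(x$alignment$R, exact = TRUE),
    seed = x$config$seed
  )
}

#' Save / load a trained NPQ model as JSON
#'
#' All numeric payloads are stored at full double precision so a reloaded
#' model reproduces scores bit-exactly.
#'
#' @param model An `npq_model`.
#' @param path File path.
#' @return `save_npq_model()` returns `path` invisibly; `read_npq_model()`
#'   an `npq_model`.
#' @export
save_npq_model <- function(model, path) {
  stopifnot(inherits(model, "npq_model"))
  obj <- list(
    atoms = model$dictionary$atoms,
    lambda = model$dictionary$lambda,
    dict_seed = model$dictionary$seed,
    T_matrix = model$lda$T_matrix,
    lda_classes = model$lda$classes,
    class_means = model$lda$class_means,
    R = model$alignment$R,
    origins = as.list(model$alignment$origins),
    config = model$config,
    class_counts = as.list(as.integer(model$class_counts)) |>
      stats::setNames(names(model$class_counts)),
    training = model$training
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_npq_model
#' @export
read_npq_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  atoms <- as.matrix(obj$atoms)
  dimnames(atoms) <- NULL
  dict <- structure(
    list(atoms = atoms, lambda = obj$lambda, n_atoms = nrow(atoms),
         seed = obj$dict_seed, fit_history = numeric(0),
         iterations = NA_integer_, converged = NA),
    class = "npq_dictionary"
  )
  Tm <- as.matrix(obj$T_matrix)
  dimnames(Tm) <- NULL
  cm <- as.matrix(obj$class_means)
  dimnames(cm) <- list(obj$lda_classes, NULL)
  lda <- structure(
    list(T_matrix = Tm, class_means = cm, classes = obj$lda_classes,
         S_B = NULL, S_W = NULL, eigenvalues = NULL),
    class = "npq_lda"
  )
  R <- as.matrix(obj$R)
  dimnames(R) <- list(NULL, c("qT", "qE", "qI"))
  alignment <- structure(
    list(R = R, R_inv = solve(R), origins = unlist(obj$origins)),
    class = "npq_alignment"
  )
  structure(
    list(dictionary = dict, lda = lda, alignment = alignment,
         config = obj$config, filter_report = NULL,
         training = tibble::as_tibble(obj$training),
         class_counts = unlist(obj$class_counts)),
    class = "npq_model"
  )
}
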