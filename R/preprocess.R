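#' Discard cells with too small a segmented area
#'
#' Cells whose segmented surface is strictly smaller than `min_area` pixels
#' are removed (the default reproduces the training pipeline's 5-pixel
#' rule: areas of exactly 5 survive).
#'
#' @param cells Tibble of cell records with an `area` column (see
#'   [extract_traces()]).
#' @param min_area Minimum surviving area in pixels.
#' @return List with `cells` (the survivors) and `report` (a
#'   `filter_report` tibble: `n_input`, `n_removed`, `removed_ids`).
#' @export
filter_by_area <- function(cells, min_area = 5) {
  stopifnot("area" %in% names(cells))
  keep <- cells$area >= min_area
  list(
    cells = cells[keep, , drop = FALSE],
    report = filter_report("area", nrow(cells), cells$cell_id[!keep])
  )
}

filter_report <- function(stage, n_input, removed_ids) {
  tibble::tibble(stage = stage, n_input = n_input,
                 n_removed = length(removed_ids),
                 removed_ids = list(removed_ids))
}

#' Remove isolated traces by nearest-neighbour distance
#'
#' A trace is an outlier when all its neighbours lie further than `d` in
#' Euclidean distance — equivalently, when its nearest-neighbour distance
#' (excluding itself) strictly exceeds `d`. Intended to run on
#' sum-normalized traces, for which the default `d = 0.01` is calibrated.
#' Distances are computed exactly (blocked pairwise computation), so the
#' removal set is identical to the brute-force definition; ties at exactly
#' `d` are kept.
#'
#' @param traces Numeric matrix, rows = cells, columns = pulses.
#' @param d Isolation radius.
#' @return List with `traces` (surviving rows), `keep` (logical index into
#'   the input rows), `nn_dist` (per-row nearest-neighbour distance) and
#'   `report` (a `filter_report`).
#' @export
remove_isolated <- function(traces, d = 0.01) {
  stopifnot(is.matrix(traces))
  n <- nrow(traces)
  if (n < 2) stop("isolation is undefined for fewer than 2 traces", call. = FALSE)
  nn <- nearest_neighbor_dist(traces)
  keep <- nn <= d
  ids <- rownames(traces) %||% as.character(seq_len(n))
  list(
    traces = traces[keep, , drop = FALSE],
    keep = keep,
    nn_dist = nn,
    report = filter_report("isolation", n, ids[!keep])
  )
}

# exact nearest-neighbour Euclidean distances, blocked to bound memory
nearest_neighbor_dist <- function(x, block = 512L) {
  n <- nrow(x)
  sq <- rowSums(x^2)
  nn <- rep(Inf, n)
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    # squared distances of block rows to all rows
    d2 <- outer(sq[s:e], sq, "+") - 2 * tcrossprod(x[s:e, , drop = FALSE], x)
    d2[cbind(seq_len(e - s + 1L), s:e)] <- Inf   # exclude self
    nn[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  nn
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a trace to unit sum
#'
#' Divides each trace by its sum so it forms a discrete probability
#' distribution over pulses. Idempotent; invariant to positive rescaling of
#' the input (so the cell's absolute brightness drops out).
#'
#' @param x Numeric vector (one trace) or matrix (rows = traces).
#' @return Same shape as `x`, rows summing to 1.
#' @export
normalize_sum <- function(x) {
  if (is.matrix(x)) {
    s <- rowSums(x)
    if (any(s <= 0)) stop("trace sums must be positive", call. = FALSE)
    x / s
  } else {
    s <- sum(x)
    if (s <= 0) stop("trace sum must be positive", call. = FALSE)
    x / s
  }
}

#' Normalize a trace to its initial value
#'
#' Display normalization: the first pulse value becomes 1. Used for plotted
#' and grid-averaged traces, not for model fitting.
#'
#' @inheritParams normalize_sum
#' @return Same shape as `x`, first entry (or column) equal to 1.
#' @export
normalize_to_initial <- function(x) {
  if (is.matrix(x)) {
    if (any(x[, 1] <= 0)) stop("first trace values must be positive", call. = FALSE)
    x / x[, 1]
  } else {
    if (x[1] <= 0) stop("first trace value must be positive", call. = FALSE)
    x / x[1]
  }
}

#' Balanced random subsample across classes
#'
#' Draws `n_samples` traces in total, split equally over the classes
#' (`n_samples` must be divisible by the number of classes), sampled
#' without replacement within each class. Deterministic given `seed`.
#'
#' @param traces Numeric matrix, rows = cells.
#' @param labels Character/factor vector of class labels, one per row.
#' @param n_samples Total subsample size.
#' @param seed Integer seed.
#' @return List with `traces` (the subsampled matrix), `labels` and `index`
#'   (row indices into the input).
#' @export
balanced_subsample <- function(traces, labels, n_samples = 300, seed = 1L) {
  stopifnot(is.matrix(traces), nrow(traces) == length(labels))
  classes <- sort(unique(as.character(labels)))
  per <- n_samples / length(classes)
  if (per != floor(per)) {
    stop("n_samples must be divisible by the number of classes", call. = FALSE)
  }
  counts <- table(as.character(labels))
  if (any(counts < per)) {
    short <- names(counts)[counts < per]
    stop("class(es) too small for balanced subsample: ",
         paste(short, collapse = ", "), call. = FALSE)
  }
  idx <- withr::with_seed(seed, {
    unlist(lapply(classes, function(cl) {
      sample(which(as.character(labels) == cl), per)
    }))
  })
  list(traces = traces[idx, , drop = FALSE],
       labels = as.character(labels)[idx],
       index = idx)
}
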