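#' Watershed segmentation of a fluorescence frame
#'
#' Segments cells from a single (typically the first) movie frame:
#' foreground pixels are selected by a global threshold (Otsu by default),
#' the Euclidean distance transform of the foreground is computed, and a
#' watershed on the distance map separates touching cells, with basins
#' closer than `min_distance_px` merged. Labels are relabelled to
#' consecutive integers `1..K`; background is 0.
#'
#' The automatic threshold is Otsu's method applied to log-transformed
#' intensities: cell brightness in fluorescence images is approximately
#' log-normally distributed, and a linear-domain Otsu can bisect that wide
#' bright-pixel distribution instead of separating it from the background.
#'
#' @param frame Non-negative numeric matrix (rows x cols).
#' @param min_distance_px Minimum separation (px) between the distance-map
#'   maxima that seed distinct cells.
#' @param threshold Either `"otsu"` or a numeric global threshold; pixels
#'   strictly above it are foreground.
#' @return Integer label matrix of the same size (0 = background). A frame
#'   with empty foreground yields an all-zero mask.
#' @export
segment_watershed <- function(frame, min_distance_px = 5, threshold = "otsu") {
  stopifnot(is.matrix(frame), all(frame >= 0))
  thr <- if (identical(threshold, "otsu")) {
    lf <- log1p(frame)
    rng <- range(lf)
    if (rng[1] == rng[2]) return(matrix(0L, nrow(frame), ncol(frame)))
    scaled <- (lf - rng[1]) / (rng[2] - rng[1])
    lthr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1)) *
      (rng[2] - rng[1]) + rng[1]
    expm1(lthr)
  } else {
    as.numeric(threshold)
  }
  fg <- frame > thr
  if (!any(fg)) return(matrix(0L, nrow(frame), ncol(frame)))
  dm <- EBImage::distmap(EBImage::Image(fg * 1))
  ws <- EBImage::watershed(dm, tolerance = 1, ext = as.integer(min_distance_px))
  labels <- EBImage::imageData(ws)
  relabel_consecutive(matrix(as.integer(labels), nrow(frame), ncol(frame)))
}

# map arbitrary positive labels to consecutive 1..K (order of first value)
relabel_consecutive <- function(mask) {
  u <- sort(unique(mask[mask > 0]))
  if (length(u) == 0) return(mask)
  lut <- integer(max(u))
  lut[u] <- seq_along(u)
  out <- mask
  out[mask > 0] <- lut[mask[mask > 0]]
  out
}

#' Extract per-cell Fm' traces from a movie
#'
#' For every labelled cell and every saturating pulse, the trace value is
#' the mean over the cell's pixels of the mean of all frames whose
#' timestamp falls in the pulse window `[t_pulse, t_pulse + pulse_duration]`.
#'
#' @param movie List with `frames` (array `H x W x n_frames`) and
#'   `timestamps` (seconds per frame), e.g. from [simulate_movie()] or
#'   [read_movie_tiff()].
#' @param mask Integer label matrix `H x W` (0 = background).
#' @param protocol An [npq_protocol()].
#' @return Tibble with one row per cell: `cell_id` (integer label), `area`
#'   (px), `centroid_row`, `centroid_col` (0-based), and a list-column
#'   `trace` (numeric, one value per pulse).
#' @export
extract_traces <- function(movie, mask, protocol) {
  frames <- movie$frames
  stopifnot(length(dim(frames)) == 3,
            all(dim(frames)[1:2] == dim(mask)))
  tms <- movie$timestamps
  pt <- pulse_times(protocol)
  pw <- protocol$pulses$duration
  frame_sets <- lapply(pt, function(t) which(tms >= t & tms <= t + pw))
  if (any(lengths(frame_sets) == 0)) {
    stop("protocol/movie mismatch: a pulse window contains no frame",
         call. = FALSE)
  }
  labels <- sort(unique(mask[mask > 0]))
  if (length(labels) == 0) return(empty_cell_records())
  # mean frame per pulse window, then per-cell pixel means via tabulation
  n_lab <- max(labels)
  idx <- as.integer(mask)
  areas <- tabulate(idx, nbins = n_lab)
  traces <- matrix(0, length(labels), length(pt))
  for (k in seq_along(pt)) {
    fs <- frame_sets[[k]]
    fr <- if (length(fs) == 1) frames[, , fs] else
      apply(frames[, , fs, drop = FALSE], c(1, 2), mean)
    sums <- rowsum(as.vector(fr)[idx > 0], idx[idx > 0])
    traces[, k] <- sums[as.character(labels), 1] / areas[labels]
  }
  rows <- row(mask) - 1L
  cols <- col(mask) - 1L
  cen_r <- rowsum(as.vector(rows)[idx > 0], idx[idx > 0])[as.character(labels), 1] / areas[labels]
  cen_c <- rowsum(as.vector(cols)[idx > 0], idx[idx > 0])[as.character(labels), 1] / areas[labels]
  tibble::tibble(
    cell_id = labels,
    area = areas[labels],
    centroid_row = cen_r,
    centroid_col = cen_c,
    trace = lapply(seq_along(labels), function(i) traces[i, ])
  )
}

empty_cell_records <- function() {
  tibble::tibble(cell_id = integer(), area = integer(),
                 centroid_row = numeric(), centroid_col = numeric(),
                 trace = list())
}

#' Write / read a movie as multi-page TIFF
#'
#' Frames are stored as 32-bit float pages. Frame timestamps travel in a
#' JSON sidecar (`<path>.json`) next to the TIFF.
#'
#' @param movie List with `frames` (array `H x W x n_frames`) and `timestamps`.
#' @param path File path.
#' @return `write_movie_tiff()` returns `path` invisibly; `read_movie_tiff()`
#'   a list with `frames` and `timestamps` (`NULL` when no sidecar exists).
#' @export
write_movie_tiff <- function(movie, path) {
  frames <- movie$frames
  scale <- max(frames, 1e-300)
  pages <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(timestamps = movie$timestamps,
                            intensity_scale = scale),
                       paste0(path, ".json"), digits = I(17))
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".json")
  tms <- NULL
  scale <- 1
  if (file.exists(side)) {
    meta <- jsonlite::fromJSON(side)
    tms <- as.numeric(meta$timestamps)
    if (!is.null(meta$intensity_scale)) scale <- meta$intensity_scale
  }
  frames <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) frames[, , k] <- pages[[k]] * scale
  list(frames = frames, timestamps = tms)
}

#' Write / read a label mask as 16-bit TIFF
#'
#' @param mask Integer label matrix.
#' @param path File path.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}
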