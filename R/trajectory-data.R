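#' Marker trajectory sets
#'
#' A `mocap_traj` holds the time-indexed 3D positions of a set of labelled
#' markers, together with a per-sample validity mask. It is the raw
#' measurement of an optical capture system: `positions[f, m, ]` is the
#' (x, y, z) position in millimetres of marker `m` at frame `f`, and
#' `valid[f, m]` records whether that sample was actually observed.
#' Invalid samples are stored as `NA` and are never interpreted as
#' coordinates anywhere downstream.
#'
#' @param positions numeric array `n_frames x n_markers x 3` (mm). `NA`
#'   entries are treated as missing.
#' @param labels character vector of unique marker names, one per marker
#'   column. Defaults to the second dimnames of `positions`.
#' @param frame_rate sampling rate in Hz (> 0).
#' @param valid optional logical `n_frames x n_markers` mask; defaults to
#'   "all three coordinates finite".
#' @param start_frame frame number of the first sample (1-based).
#'
#' @return An object of class `mocap_traj`: a list with elements
#'   `positions`, `valid`, `labels`, `frame_rate`, `start_frame`.
#' @export
mocap_traj <- function(positions, labels = dimnames(positions)[[2]],
                       frame_rate = 100, valid = NULL, start_frame = 1L) {
  if (length(dim(positions)) != 3L || dim(positions)[3] != 3L) {
    stop("`positions` must be an n_frames x n_markers x 3 array", call. = FALSE)
  }
  n_frames <- dim(positions)[1]
  n_markers <- dim(positions)[2]
  if (n_frames < 1L) stop("trajectory set must contain at least one frame", call. = FALSE)
  if (is.null(labels)) stop("marker labels are required", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != n_markers) {
    stop("length of `labels` must match the marker dimension", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("duplicate marker label: ", labels[duplicated(labels)][1], call. = FALSE)
  }
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0) {
    stop("`frame_rate` must be a single positive number", call. = FALSE)
  }
  if (is.null(valid)) {
    valid <- apply(is.finite(positions), c(1, 2), all)
    dim(valid) <- c(n_frames, n_markers)
  }
  if (!identical(dim(valid), c(n_frames, n_markers))) {
    stop("`valid` must be an n_frames x n_markers logical matrix", call. = FALSE)
  }
  valid <- valid & apply(is.finite(positions), c(1, 2), all)
  # invalid coordinates are never read: blank them out
  for (k in 1:3) positions[, , k][!valid] <- NA_real_
  dimnames(positions) <- list(NULL, labels, c("x", "y", "z"))
  dimnames(valid) <- list(NULL, labels)
  structure(
    list(positions = positions, valid = valid, labels = labels,
         frame_rate = as.numeric(frame_rate),
         start_frame = as.integer(start_frame)),
    class = "mocap_traj"
  )
}

#' @export
print.mocap_traj <- function(x, ...) {
  cat(sprintf("<mocap_traj> %d frames x %d markers @ %g Hz\n",
              n_frames(x), length(x$labels), x$frame_rate))
  cat("markers:", paste(x$labels, collapse = ", "), "\n")
  miss <- sum(!x$valid)
  cat(sprintf("missing samples: %d of %d (%.1f%%)\n",
              miss, length(x$valid), 100 * miss / length(x$valid)))
  invisible(x)
}

#' Number of frames in a trajectory set
#' @param x a [mocap_traj()].
#' @return integer frame count.
#' @export
n_frames <- function(x) dim(x$positions)[1]

#' Frame numbers of a trajectory set
#' @param x a [mocap_traj()].
#' @return integer vector `start_frame, start_frame + 1, ...`.
#' @export
frame_numbers <- function(x) x$start_frame + seq_len(n_frames(x)) - 1L

#' Extract one marker's trajectory as an n x 3 matrix
#' @param x a [mocap_traj()].
#' @param marker marker label.
#' @return numeric `n_frames x 3` matrix (mm); invalid samples are `NA`.
#' @export
marker_xyz <- function(x, marker) {
  if (!marker %in% x$labels) stop("unknown marker label: ", marker, call. = FALSE)
  m <- x$positions[, marker, , drop = FALSE]
  dim(m) <- c(dim(x$positions)[1], 3L)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Convert a trajectory set to a long tibble
#'
#' @param x a [mocap_traj()].
#' @param ... unused.
#' @return tibble with columns `frame`, `time_s`, `marker`, `x`, `y`, `z`,
#'   `valid` (one row per frame per marker).
#' @method as_tibble mocap_traj
#' @export
as_tibble.mocap_traj <- function(x, ...) {
  nf <- n_frames(x)
  nm <- length(x$labels)
  frames <- frame_numbers(x)
  tibble::tibble(
    frame = rep(frames, times = nm),
    time_s = (rep(frames, times = nm) - x$start_frame) / x$frame_rate,
    marker = factor(rep(x$labels, each = nf), levels = x$labels),
    x = as.vector(x$positions[, , 1]),
    y = as.vector(x$positions[, , 2]),
    z = as.vector(x$positions[, , 3]),
    valid = as.vector(x$valid)
  )
}

#' Subset a trajectory set to one marker cluster
#'
#' Extracts the markers of a single rigid cluster (e.g. the four thigh
#' markers) in the requested order. Frames, coordinates and validity masks
#' are carried over untouched.
#'
#' @param set a [mocap_traj()].
#' @param labels marker labels to keep, in the desired order.
#' @return a [mocap_traj()] restricted to `labels`.
#' @export
select_cluster <- function(set, labels) {
  unknown <- setdiff(labels, set$labels)
  if (length(unknown) > 0) {
    stop("unknown marker label: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  mocap_traj(set$positions[, labels, , drop = FALSE], labels = labels,
             frame_rate = set$frame_rate, valid = set$valid[, labels, drop = FALSE],
             start_frame = set$start_frame)
}

#' Plot marker trajectories
#'
#' One panel per coordinate (x, y, z in mm) with one line per marker --
#' the usual pre/post-patch inspection view of a capture.
#'
#' @param object a [mocap_traj()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot mocap_traj
#' @export
autoplot.mocap_traj <- function(object, ...) {
  df <- as_tibble.mocap_traj(object)
  df <- tidyr::pivot_longer(df, cols = c("x", "y", "z"),
                            names_to = "coordinate", values_to = "mm")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$mm,
                                   colour = .data$marker)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~coordinate, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frame", y = "position (mm)")
}
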