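#' Detect occlusion gaps in a trajectory set
#'
#' A gap is a maximal run of invalid samples for one marker, reported with
#' inclusive 1-based frame bounds.
#'
#' @param set a [mocap_traj()].
#' @return tibble with columns `marker`, `start`, `end`, `length`.
#' @export
detect_gaps <- function(set) {
  frames <- frame_numbers(set)
  purrr::map_dfr(seq_along(set$labels), function(j) {
    miss <- !set$valid[, j]
    if (!any(miss)) return(NULL)
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    tibble::tibble(marker = set$labels[j],
                   start = frames[starts[keep]],
                   end = frames[ends[keep]],
                   length = r$lengths[keep])
  })
}

#' Detect single-sample "bounce" spikes
#'
#' A sample is flagged as a bounce when both inter-frame displacements into
#' and out of it exceed `k` times the marker's median inter-frame
#' displacement (over valid consecutive pairs), and the trajectory returns:
#' the direct step from the previous to the next sample is shorter than
#' either detour leg. Flagged samples are invalidated so the repair stages
#' treat them as missing.
#'
#' @param set a [mocap_traj()].
#' @param k threshold multiplier (> 1, default 5).
#' @return list with `set` (spikes invalidated) and `spikes` (tibble
#'   `marker`, `frame`, `displacement` in mm).
#' @export
detect_spikes <- function(set, k = 5) {
  if (k <= 1) stop("`k` must be greater than 1", call. = FALSE)
  nf <- n_frames(set)
  spikes <- tibble::tibble(marker = character(), frame = integer(),
                           displacement = numeric())
  if (nf < 3L) return(list(set = set, spikes = spikes))
  frames <- frame_numbers(set)
  out <- set
  for (j in seq_along(set$labels)) {
    p <- matrix(set$positions[, j, ], ncol = 3)
    v <- set$valid[, j]
    step <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nf, , drop = FALSE])^2))
    pair_ok <- v[-1] & v[-nf]
    if (!any(pair_ok)) next
    med <- stats::median(step[pair_ok])
    cand <- which(v[-c(1, 2)] & v[-c(1, nf)] & v[-c(nf - 1, nf)]) + 1L
    for (i in cand) {
      d_in <- step[i - 1L]; d_out <- step[i]
      d_skip <- sqrt(sum((p[i + 1L, ] - p[i - 1L, ])^2))
      if (d_in > k * med && d_out > k * med && d_skip < d_in && d_skip < d_out) {
        out$valid[i, j] <- FALSE
        out$positions[i, j, ] <- NA_real_
        spikes <- dplyr::bind_rows(spikes, tibble::tibble(
          marker = set$labels[j], frame = frames[i],
          displacement = max(d_in, d_out)))
      }
    }
  }
  list(set = out, spikes = spikes)
}

#' Rigid-body completion of single-marker dropouts in a 4-marker cluster
#'
#' For each frame in which exactly one of the four cluster markers is
#' missing, the nearest frame with all four markers observed (ties broken
#' toward the earlier frame) donates the cluster geometry: the rigid
#' transform fitted on the three shared markers carries the donor's fourth
#' marker into the gap frame. Frames with two or more missing markers are
#' left untouched at this stage.
#'
#' @param cluster a 4-marker [mocap_traj()].
#' @return list with `set` (repaired) and `log` (tibble `frame`, `marker`,
#'   `method`, `donor`).
#' @export
repair_rigid <- function(cluster) {
  if (length(cluster$labels) != 4L) {
    stop("rigid repair operates on a 4-marker cluster", call. = FALSE)
  }
  nf <- n_frames(cluster)
  frames <- frame_numbers(cluster)
  nmiss <- rowSums(!cluster$valid)
  donors <- which(nmiss == 0L)
  targets <- which(nmiss == 1L)
  out <- cluster
  log <- tibble::tibble(frame = integer(), marker = character(),
                        method = character(), donor = integer())
  if (length(donors) == 0L || length(targets) == 0L) {
    return(list(set = out, log = log))
  }
  for (f in targets) {
    d <- donors[order(abs(donors - f), donors)][1]  # nearest, earlier on ties
    j_miss <- which(!cluster$valid[f, ])
    j_ok <- which(cluster$valid[f, ])
    fit <- fit_rigid(cluster$positions[d, j_ok, ], cluster$positions[f, j_ok, ])
    out$positions[f, j_miss, ] <- apply_transform(fit, cluster$positions[d, j_miss, ])
    out$valid[f, j_miss] <- TRUE
    log <- dplyr::bind_rows(log, tibble::tibble(
      frame = frames[f], marker = cluster$labels[j_miss],
      method = "rigid", donor = frames[d]))
  }
  list(set = out, log = log)
}

#' Cubic-spline interpolation of remaining short gaps
#'
#' Each marker coordinate is fitted with a natural cubic spline through all
#' of its valid samples; interior gaps no longer than `max_gap_frames` are
#' filled from the spline. Edge gaps (no valid sample on one side) are
#' never extrapolated.
#'
#' @param set a [mocap_traj()].
#' @param max_gap_frames longest gap (in frames) eligible for spline fill
#'   (default 50, i.e. 0.5 s at 100 Hz).
#' @param exclude_frames frame indices that must never be filled (used by
#'   [patch_pipeline()] to keep discarded frames out of reach).
#' @return list with `set` (repaired) and `log` (tibble `frame`, `marker`,
#'   `method`).
#' @export
repair_spline <- function(set, max_gap_frames = 50, exclude_frames = integer()) {
  nf <- n_frames(set)
  frames <- frame_numbers(set)
  out <- set
  log <- tibble::tibble(frame = integer(), marker = character(),
                        method = character())
  for (j in seq_along(set$labels)) {
    v <- set$valid[, j]
    if (all(v) || sum(v) < 2L) next
    knots <- which(v)
    gaps <- detect_runs(!v)
    fill <- integer()
    for (g in seq_len(nrow(gaps))) {
      s <- gaps$start[g]; e <- gaps$end[g]
      interior <- s > min(knots) && e < max(knots)
      if (interior && (e - s + 1L) <= max_gap_frames) fill <- c(fill, s:e)
    }
    fill <- setdiff(fill, exclude_frames)
    if (length(fill) == 0L) next
    for (k in 1:3) {
      sf <- stats::splinefun(knots, set$positions[knots, j, k], method = "natural")
      out$positions[fill, j, k] <- sf(fill)
    }
    out$valid[fill, j] <- TRUE
    log <- dplyr::bind_rows(log, tibble::tibble(
      frame = frames[fill], marker = set$labels[j], method = "spline"))
  }
  list(set = out, log = log)
}

# maximal TRUE runs of a logical vector, as a tibble of 1-based inclusive
# index bounds
detect_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(start = starts[r$values], end = ends[r$values])
}

#' The Patch Program: full repair pipeline for one 4-marker cluster
#'
#' Stages, in order: spike detection (bounces invalidated), rigid-body
#' completion of single-marker dropouts, then the discard rule -- any frame
#' still missing two or more of the four cluster markers cannot be repaired
#' and all four of its samples are invalidated (masked, never deleted, so
#' frame indexing stays aligned across clusters) -- and finally cubic-spline
#' fill of the remaining short interior single-marker gaps. Discard takes
#' precedence over spline interpolation because a frame lacking two markers
#' has lost its cluster geometry; splining both trajectories through it
#' would fabricate a pose.
#'
#' @param cluster a 4-marker [mocap_traj()].
#' @param spike_k spike threshold multiplier (see [detect_spikes()]).
#' @param max_gap_frames spline gap limit (see [repair_spline()]).
#' @return list with `set` (patched cluster) and `report` (a `gap_report`).
#' @export
patch_pipeline <- function(cluster, spike_k = 5, max_gap_frames = 50) {
  if (length(cluster$labels) != 4L) {
    stop("patch_pipeline operates on a 4-marker cluster", call. = FALSE)
  }
  frames <- frame_numbers(cluster)
  orig_valid <- cluster$valid
  gaps0 <- detect_gaps(cluster)

  sp <- detect_spikes(cluster, k = spike_k)
  pre_valid <- sp$set$valid          # after spike invalidation
  rr <- repair_rigid(sp$set)

  # discard rule: frames still missing >= 2 cluster markers after rigid
  # completion have lost their cluster geometry and cannot be repaired
  discard_f <- which(rowSums(!rr$set$valid) >= 2L)
  discard_log <- tibble::tibble(frame = integer(), marker = character(),
                                method = character())
  mid <- rr$set
  if (length(discard_f) > 0L) {
    discard_log <- tidyr::expand_grid(frame = frames[discard_f],
                                      marker = cluster$labels) |>
      dplyr::mutate(method = "discarded")
    mid$valid[discard_f, ] <- FALSE
    mid$positions[discard_f, , ] <- NA_real_
  }

  rs <- repair_spline(mid, max_gap_frames = max_gap_frames,
                      exclude_frames = discard_f)
  out <- rs$set

  repairs <- dplyr::bind_rows(
    rr$log,
    rs$log |> dplyr::mutate(donor = NA_integer_),
    discard_log |> dplyr::mutate(donor = NA_integer_)
  )
  # every sample ends in exactly one state
  status <- matrix(ifelse(pre_valid, "kept", "missing"),
                   nrow = length(frames), ncol = 4L)
  assign_status <- function(log, what) {
    for (i in seq_len(nrow(log))) {
      status[match(log$frame[i], frames), match(log$marker[i], cluster$labels)] <<- what
    }
  }
  assign_status(rr$log, "rigid")
  assign_status(rs$log, "spline")
  if (length(discard_f) > 0L) status[discard_f, ] <- "discarded"
  counts <- purrr::map_dfr(seq_along(cluster$labels), function(j) {
    tibble::tibble(
      marker = cluster$labels[j],
      total = length(frames),
      kept = sum(status[, j] == "kept"),
      rigid = sum(status[, j] == "rigid"),
      spline = sum(status[, j] == "spline"),
      discarded = sum(status[, j] == "discarded"),
      missing = sum(status[, j] == "missing")
    )
  })
  report <- structure(
    list(gaps = gaps0, spikes = sp$spikes, repairs = repairs, counts = counts,
         frames_discarded = frames[discard_f],
         missing_per_frame = tibble::tibble(frame = frames,
                                            n_missing = rowSums(!orig_valid))),
    class = "gap_report"
  )
  list(set = out, report = report)
}

#' @export
print.gap_report <- function(x, ...) {
  cat("<gap_report>\n")
  cat(sprintf("gaps: %d  spikes: %d  repairs: %d  discarded frames: %d\n",
              nrow(x$gaps), nrow(x$spikes),
              sum(x$repairs$method %in% c("rigid", "spline")),
              length(x$frames_discarded)))
  if (nrow(x$counts) > 0) print(x$counts)
  invisible(x)
}

#' @method glance gap_report
#' @export
glance.gap_report <- function(x, ...) {
  tibble::tibble(
    n_gaps = nrow(x$gaps),
    n_spikes = nrow(x$spikes),
    n_rigid = sum(x$repairs$method == "rigid"),
    n_spline = sum(x$repairs$method == "spline"),
    n_frames_discarded = length(x$frames_discarded)
  )
}

#' Serialize a gap report to JSON text
#' @param report a `gap_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gap_report <- function(report, path) {
  jsonlite::write_json(
    list(gaps = report$gaps, spikes = report$spikes, repairs = report$repairs,
         counts = report$counts, frames_discarded = report$frames_discarded),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
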