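#' Stylus probe model
#'
#' Local coordinates (mm) of the probe's markers in a probe-fixed frame
#' whose origin is the probe tip: posing the probe and registering these
#' local points onto the measured marker positions places the tip at the
#' translation component of the fitted transform.
#'
#' @param local numeric `4 x 3` matrix of marker positions (mm), tip at the
#'   origin.
#' @param labels marker labels (default `P1..P4`).
#' @return object of class `probe_model`.
#' @export
probe_model <- function(local, labels = paste0("P", 1:4)) {
  local <- as_points(local)
  if (nrow(local) != 4L) stop("a probe model has exactly 4 markers", call. = FALSE)
  sv <- svd(sweep(local, 2, colMeans(local)))$d
  if (sv[2] / max(sv[1], 1e-12) < .km_tol$rank) {
    stop("probe markers are collinear; cannot register", call. = FALSE)
  }
  rownames(local) <- labels
  structure(list(local = local, labels = labels), class = "probe_model")
}

#' Read a probe model file
#'
#' Four CSV rows `label,x,y,z` in mm, tip-origin frame.
#'
#' @param path file to read.
#' @return a [probe_model()].
#' @export
read_probe_model <- function(path) {
  if (!file.exists(path)) stop("probe model file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("probe model file needs columns label,x,y,z", call. = FALSE)
  }
  probe_model(as.matrix(df[, c("x", "y", "z")]), labels = as.character(df$label))
}

#' Write a probe model file
#' @param probe a [probe_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_probe_model <- function(probe, path) {
  df <- data.frame(label = probe$labels,
                   x = sprintf("%.17g", probe$local[, 1]),
                   y = sprintf("%.17g", probe$local[, 2]),
                   z = sprintf("%.17g", probe$local[, 3]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Probe-tip position from measured probe markers
#'
#' Registers the probe's local marker geometry onto the measured global
#' positions; the tip (the local origin) maps to the translation of the
#' fitted transform.
#'
#' @param probe a [probe_model()].
#' @param measured `4 x 3` matrix of measured marker positions (mm), in the
#'   same row order as `probe$local`; any `NA` row is an error.
#' @return list with `tip` (length-3, mm), `residual` (registration RMS,
#'   mm) and `transform` (the fitted [rigid_transform()]).
#' @export
probe_tip <- function(probe, measured) {
  measured <- as_points(measured)
  if (nrow(measured) != 4L) stop("expected 4 measured probe markers", call. = FALSE)
  if (anyNA(measured)) {
    stop("cannot calibrate: a probe marker is missing in this frame", call. = FALSE)
  }
  fit <- fit_rigid(probe$local, measured)
  list(tip = fit$t, residual = fit$residual_rms, transform = fit)
}

#' Calibrate one bony landmark into cluster-local coordinates
#'
#' For every usable calibration frame (all four probe markers and all four
#' cluster markers observed), the probe tip gives the landmark's global
#' position and the cluster pose (registration of `reference` onto the
#' observed cluster markers) carries it into cluster-local coordinates.
#' The result is the mean over usable frames; the residual is the RMS
#' spread of the per-frame local positions about that mean.
#'
#' @param probe a [probe_model()].
#' @param probe_traj [mocap_traj()] of the 4 probe markers during the
#'   calibration recording (marker order matching `probe$local`).
#' @param cluster_traj [mocap_traj()] of the 4 cluster markers during the
#'   same recording.
#' @param reference `4 x 3` matrix: the cluster's reference marker
#'   positions (the pose in which local coordinates are expressed).
#' @return list with `local` (length-3 landmark position in cluster-local
#'   mm), `residual` (RMS frame-to-frame spread, mm), `n_frames` (usable
#'   frames), `probe_residual_rms` (mean probe registration RMS, mm).
#' @export
calibrate_landmark <- function(probe, probe_traj, cluster_traj, reference) {
  reference <- as_points(reference)
  nf <- min(n_frames(probe_traj), n_frames(cluster_traj))
  usable <- which(
    rowSums(probe_traj$valid[seq_len(nf), , drop = FALSE]) == 4L &
    rowSums(cluster_traj$valid[seq_len(nf), , drop = FALSE]) == 4L
  )
  if (length(usable) == 0L) {
    stop("landmark calibration failed: no frame has all probe and cluster markers",
         call. = FALSE)
  }
  locals <- matrix(NA_real_, length(usable), 3)
  probe_res <- numeric(length(usable))
  for (i in seq_along(usable)) {
    f <- usable[i]
    tip <- probe_tip(probe, probe_traj$positions[f, , ])
    C <- fit_rigid(reference, cluster_traj$positions[f, , ])
    locals[i, ] <- apply_transform(invert(C), tip$tip)
    probe_res[i] <- tip$residual
  }
  local <- colMeans(locals)
  spread <- sweep(locals, 2, local)
  list(local = local,
       residual = sqrt(mean(rowSums(spread^2))),
       n_frames = length(usable),
       probe_residual_rms = mean(probe_res))
}

#' Cluster template: reference geometry plus local landmarks
#'
#' @param name cluster name (e.g. `"thigh"`).
#' @param labels the cluster's 4 marker labels.
#' @param reference `4 x 3` matrix of reference marker positions (mm).
#' @param landmarks tibble with columns `landmark`, `x`, `y`, `z`
#'   (cluster-local mm) and `residual` (calibration spread, mm).
#' @return object of class `cluster_template`.
#' @export
cluster_template <- function(name, labels, reference, landmarks) {
  reference <- as_points(reference)
  if (nrow(reference) != 4L || length(labels) != 4L) {
    stop("a cluster template has exactly 4 markers", call. = FALSE)
  }
  sv <- svd(sweep(reference, 2, colMeans(reference)))$d
  if (sv[2] / max(sv[1], 1e-12) < .km_tol$rank) {
    stop("cluster reference markers are collinear", call. = FALSE)
  }
  if (!all(is.finite(as.matrix(landmarks[, c("x", "y", "z")])))) {
    stop("landmark local coordinates must be finite", call. = FALSE)
  }
  structure(list(name = name, labels = labels, reference = reference,
                 landmarks = tibble::as_tibble(landmarks)),
            class = "cluster_template")
}

#' @export
print.cluster_template <- function(x, ...) {
  cat(sprintf("<cluster_template> %s (markers: %s)\n", x$name,
              paste(x$labels, collapse = ", ")))
  print(x$landmarks)
  invisible(x)
}

#' Calibrate a cluster's landmarks from per-landmark recordings
#'
#' Runs [calibrate_landmark()] for each landmark recording of one cluster.
#' The cluster's reference marker positions default to the mean observed
#' positions over the usable frames of the first recording (a dedicated
#' reference recording can be supplied instead).
#'
#' @param probe a [probe_model()].
#' @param recordings named list (landmark name -> [mocap_traj()]) of
#'   calibration recordings, each containing the probe markers and the
#'   cluster markers.
#' @param cluster_name name for the template.
#' @param cluster_labels the cluster's 4 marker labels.
#' @param probe_labels the probe's 4 marker labels in the recordings.
#' @param reference optional `4 x 3` reference marker matrix, or a
#'   [mocap_traj()] reference recording to average.
#' @return a [cluster_template()].
#' @export
calibrate_cluster <- function(probe, recordings, cluster_name, cluster_labels,
                              probe_labels = probe$labels, reference = NULL) {
  if (is.null(names(recordings)) || any(!nzchar(names(recordings)))) {
    stop("`recordings` must be a named list (landmark -> recording)", call. = FALSE)
  }
  ref_mat <- resolve_reference(reference, recordings[[1]], cluster_labels)
  rows <- purrr::map(names(recordings), function(lm) {
    rec <- recordings[[lm]]
    cal <- calibrate_landmark(probe,
                              select_cluster(rec, probe_labels),
                              select_cluster(rec, cluster_labels),
                              ref_mat)
    tibble::tibble(landmark = lm, x = cal$local[1], y = cal$local[2],
                   z = cal$local[3], residual = cal$residual,
                   n_frames = cal$n_frames)
  })
  cluster_template(cluster_name, cluster_labels, ref_mat, dplyr::bind_rows(rows))
}

resolve_reference <- function(reference, first_recording, cluster_labels) {
  if (is.null(reference)) reference <- first_recording
  if (inherits(reference, "mocap_traj")) {
    cl <- select_cluster(reference, cluster_labels)
    ok <- rowSums(cl$valid) == 4L
    if (!any(ok)) stop("no usable frame to define cluster reference", call. = FALSE)
    ref <- apply(cl$positions[ok, , , drop = FALSE], c(2, 3), mean)
    return(as_points(ref))
  }
  as_points(reference)
}

#' Reconstruct bony landmarks as virtual markers in a motion recording
#'
#' Per frame, the cluster's reference geometry is registered onto the
#' observed cluster markers (all 4 when available, the 3 valid ones
#' otherwise) and the calibrated local landmark positions are mapped
#' through the fitted pose. Frames with fewer than 3 valid cluster markers
#' yield invalid landmark samples.
#'
#' @param template a [cluster_template()].
#' @param motion [mocap_traj()] containing the cluster's markers.
#' @return a [mocap_traj()] over the landmark names, with an attribute
#'   `registration_residual` (per-frame RMS, mm, `NA` where unresolvable).
#' @export
reconstruct_virtual_markers <- function(template, motion) {
  cl <- select_cluster(motion, template$labels)
  nf <- n_frames(cl)
  lms <- template$landmarks$landmark
  local <- as.matrix(template$landmarks[, c("x", "y", "z")])
  pos <- array(NA_real_, dim = c(nf, length(lms), 3L))
  resid <- rep(NA_real_, nf)
  for (f in seq_len(nf)) {
    ok <- which(cl$valid[f, ])
    if (length(ok) < 3L) next
    fit <- fit_rigid(template$reference[ok, , drop = FALSE],
                     cl$positions[f, ok, ])
    pos[f, , ] <- apply_transform(fit, local)
    resid[f] <- fit$residual_rms
  }
  out <- mocap_traj(pos, labels = lms, frame_rate = cl$frame_rate,
                    start_frame = cl$start_frame)
  attr(out, "registration_residual") <- resid
  out
}
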