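# The seven bony landmarks of the tibiofemoral joint model, and which
# segment cluster each belongs to.
.km_landmarks <- c(
  greater_trochanter         = "thigh",
  medial_femoral_epicondyle  = "thigh",
  lateral_femoral_epicondyle = "thigh",
  medial_tibial_plateau      = "calf",
  lateral_tibial_plateau     = "calf",
  medial_malleolus           = "calf",
  lateral_malleolus          = "calf"
)

#' Read and validate a capture-session configuration
#'
#' A session configuration is a YAML file describing one capture session:
#' sampling rate, body side, the probe model file, the two 4-marker
#' cluster definitions (`thigh`, `calf`), one calibration recording per
#' bony landmark, the motion recording, and patch/angle parameters.
#' Relative file paths are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return a validated session configuration (class `mocap_session`).
#' @export
read_session_config <- function(path) {
  if (!file.exists(path)) stop("session config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  cfg$.dir <- dirname(normalizePath(path))
  validate_session_config(cfg)
}

validate_session_config <- function(cfg) {
  if (is.null(cfg$frame_rate)) cfg$frame_rate <- 100
  if (is.null(cfg$side)) cfg$side <- "right"
  if (is.null(cfg$.dir)) cfg$.dir <- "."
  for (key in c("probe", "clusters", "landmarks", "motion")) {
    if (is.null(cfg[[key]])) stop("session config lacks `", key, "`", call. = FALSE)
  }
  if (is.null(cfg$probe$labels)) cfg$probe$labels <- paste0("P", 1:4)
  for (cl in c("thigh", "calf")) {
    labs <- cfg$clusters[[cl]]$labels
    if (length(labs) != 4L || anyDuplicated(labs)) {
      stop("cluster `", cl, "` must list exactly 4 distinct marker labels",
           call. = FALSE)
    }
  }
  lm_names <- names(cfg$landmarks)
  if (!setequal(lm_names, names(.km_landmarks))) {
    stop("session config must define exactly these 7 landmarks: ",
         paste(names(.km_landmarks), collapse = ", "), call. = FALSE)
  }
  for (lm in lm_names) {
    if (is.null(cfg$landmarks[[lm]]$cluster)) {
      cfg$landmarks[[lm]]$cluster <- unname(.km_landmarks[lm])
    }
  }
  if (is.null(cfg$patch)) cfg$patch <- list()
  if (is.null(cfg$patch$spike_k)) cfg$patch$spike_k <- 5
  if (is.null(cfg$patch$max_gap_frames)) cfg$patch$max_gap_frames <- 50
  if (is.null(cfg$angles)) cfg$angles <- list()
  if (is.null(cfg$angles$flexion_sign)) cfg$angles$flexion_sign <- -1
  if (is.null(cfg$angles$bin_width)) cfg$angles$bin_width <- 2
  class(cfg) <- "mocap_session"
  cfg
}

session_path <- function(cfg, p) {
  if (grepl("^/", p)) p else file.path(cfg$.dir, p)
}

#' Run the full knee-kinematics pipeline on one session
#'
#' Executes the whole chain: read the probe model and calibration
#' recordings, calibrate the seven bony landmarks into cluster-local
#' coordinates, read the motion recording, patch each cluster (spike
#' removal, rigid completion, spline fill, discard rule), reconstruct the
#' landmarks as virtual markers, build femoral and tibial anatomical
#' frames, and extract the joint angles. Deterministic given its inputs.
#'
#' @param session a session config (path to YAML, or the object returned
#'   by [read_session_config()]).
#' @param out_dir optional directory; when given, the per-frame angle CSV,
#'   the flexion-binned CSV, the patched motion CSV and a QC report (JSON)
#'   are written there.
#' @return a `knee_session_result`: list with `angles` (a `knee_angles`
#'   tibble), `binned`, `qc`, `templates`, `patched` (named list of
#'   patched cluster trajectories), `landmarks` (reconstructed virtual
#'   marker trajectories) and `config`.
#' @export
run_main_pipeline <- function(session, out_dir = NULL) {
  cfg <- if (inherits(session, "mocap_session")) session else
    read_session_config(session)

  probe <- stage(cfg, "probe-model", cfg$probe$file,
                 read_probe_model(session_path(cfg, cfg$probe$file)))

  templates <- list()
  for (cl in c("thigh", "calf")) {
    lms <- names(Filter(function(x) identical(x$cluster, cl), cfg$landmarks))
    recordings <- lapply(lms, function(lm) {
      stage(cfg, "calibration", cfg$landmarks[[lm]]$file,
            read_trajectories(session_path(cfg, cfg$landmarks[[lm]]$file),
                              frame_rate = cfg$frame_rate))
    })
    names(recordings) <- lms
    templates[[cl]] <- stage(cfg, "landmark-calibration", cl,
      calibrate_cluster(probe, recordings, cluster_name = cl,
                        cluster_labels = cfg$clusters[[cl]]$labels,
                        probe_labels = cfg$probe$labels))
  }

  motion <- stage(cfg, "motion", cfg$motion$file,
                  read_trajectories(session_path(cfg, cfg$motion$file),
                                    frame_rate = cfg$frame_rate))

  patched <- list(); reports <- list(); lm_traj <- list()
  for (cl in c("thigh", "calf")) {
    cluster <- select_cluster(motion, cfg$clusters[[cl]]$labels)
    pp <- patch_pipeline(cluster, spike_k = cfg$patch$spike_k,
                         max_gap_frames = cfg$patch$max_gap_frames)
    patched[[cl]] <- pp$set
    reports[[cl]] <- pp$report
    lm_traj[[cl]] <- reconstruct_virtual_markers(templates[[cl]], pp$set)
  }

  fem <- femur_frame(marker_xyz(lm_traj$thigh, "greater_trochanter"),
                     marker_xyz(lm_traj$thigh, "medial_femoral_epicondyle"),
                     marker_xyz(lm_traj$thigh, "lateral_femoral_epicondyle"),
                     side = cfg$side)
  tib <- tibia_frame(marker_xyz(lm_traj$calf, "medial_tibial_plateau"),
                     marker_xyz(lm_traj$calf, "lateral_tibial_plateau"),
                     marker_xyz(lm_traj$calf, "medial_malleolus"),
                     marker_xyz(lm_traj$calf, "lateral_malleolus"),
                     side = cfg$side)
  angles <- knee_angles(fem, tib, frame_rate = motion$frame_rate,
                        start_frame = motion$start_frame,
                        flexion_sign = cfg$angles$flexion_sign)
  binned <- if (any(angles$valid)) {
    angles_vs_flexion(angles, bin_width = cfg$angles$bin_width)
  } else tibble::tibble()

  calib_tbl <- purrr::map_dfr(names(templates), function(cl) {
    dplyr::mutate(templates[[cl]]$landmarks, cluster = cl, .before = 1)
  })
  qc <- list(
    calibration = calib_tbl,
    patch = purrr::map(reports, glance.gap_report),
    registration_residual_mm = purrr::map_dbl(lm_traj, function(tr) {
      r <- attr(tr, "registration_residual"); mean(r, na.rm = TRUE)
    }),
    discarded_fraction = purrr::map_dbl(reports, function(rp) {
      length(rp$frames_discarded) / n_frames(motion)
    }),
    warnings = character()
  )
  if (any(calib_tbl$residual > 1)) {
    qc$warnings <- c(qc$warnings, sprintf(
      "landmark calibration residual above 1 mm: %s",
      paste(calib_tbl$landmark[calib_tbl$residual > 1], collapse = ", ")))
  }
  if (any(qc$discarded_fraction > 0.10)) {
    qc$warnings <- c(qc$warnings, sprintf(
      "more than 10%% of frames discarded in cluster: %s",
      paste(names(qc$discarded_fraction)[qc$discarded_fraction > 0.10],
            collapse = ", ")))
  }

  result <- structure(
    list(angles = angles, binned = binned, qc = qc, templates = templates,
         reports = reports, patched = patched, landmarks = lm_traj,
         config = cfg),
    class = "knee_session_result"
  )
  if (!is.null(out_dir)) write_session_result(result, out_dir)
  result
}

stage <- function(cfg, name, file, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s: %s", name, file, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Write the result files of a session run
#'
#' @param result a `knee_session_result`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_session_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ang <- tibble::as_tibble(result$angles)[
    , c("frame", "time_s", "flexion_deg", "abd_add_deg", "int_ext_deg",
        "valid", "gimbal")]
  write_num_csv(ang, file.path(out_dir, "angles.csv"))
  if (nrow(result$binned) > 0) {
    write_num_csv(result$binned, file.path(out_dir, "angles_vs_flexion.csv"))
  }
  for (cl in names(result$patched)) {
    write_trajectories(result$patched[[cl]],
                       file.path(out_dir, paste0("patched_", cl, ".csv")))
    write_gap_report(result$reports[[cl]],
                     file.path(out_dir, paste0("patch_report_", cl, ".json")))
  }
  jsonlite::write_json(result$qc, file.path(out_dir, "qc.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out_dir)
}

# CSV writer with reproducible full-precision doubles
write_num_csv <- function(df, path) {
  df2 <- as.data.frame(lapply(df, function(col) {
    if (is.double(col)) ifelse(is.na(col), "", sprintf("%.17g", col)) else col
  }), check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df2, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.knee_session_result <- function(x, ...) {
  cat("<knee_session_result>\n")
  print(glance.knee_session_result(x))
  invisible(x)
}

#' @method glance knee_session_result
#' @export
glance.knee_session_result <- function(x, ...) {
  a <- dplyr::filter(tibble::as_tibble(x$angles), .data$valid)
  tibble::tibble(
    n_frames = nrow(x$angles),
    n_valid = nrow(a),
    max_flexion_deg = if (nrow(a)) max(a$flexion_deg) else NA_real_,
    abd_add_min_deg = if (nrow(a)) min(a$abd_add_deg) else NA_real_,
    abd_add_max_deg = if (nrow(a)) max(a$abd_add_deg) else NA_real_,
    int_ext_min_deg = if (nrow(a)) min(a$int_ext_deg) else NA_real_,
    int_ext_max_deg = if (nrow(a)) max(a$int_ext_deg) else NA_real_,
    n_repairs = sum(purrr::map_int(x$reports, function(r) {
      sum(r$repairs$method %in% c("rigid", "spline"))
    })),
    n_frames_discarded = sum(purrr::map_int(x$reports, function(r) {
      length(r$frames_discarded)
    })),
    max_calibration_residual_mm = max(x$qc$calibration$residual)
  )
}
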