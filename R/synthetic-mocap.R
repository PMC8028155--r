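#' Default synthetic leg geometry
#'
#' Segment-local positions (mm) of the seven bony landmarks and the two
#' 4-marker surface clusters, approximating an adult right leg: 100 mm
#' epicondyle spacing, 80 mm plateau spacing, 400 mm femur and 380 mm
#' tibia segment lengths. Each segment's local frame is its anatomical
#' frame (origin at the epicondyle/plateau midpoint, X lateral, Y
#' anterior, Z superior), so prescribed joint angles translate directly
#' into relative segment poses.
#'
#' @return list with matrices `femur_landmarks`, `tibia_landmarks`,
#'   `thigh_markers`, `calf_markers` (rows named).
#' @export
default_leg_geometry <- function() {
  femur_landmarks <- rbind(
    greater_trochanter         = c(15, 0, 400),
    medial_femoral_epicondyle  = c(-50, 0, 0),
    lateral_femoral_epicondyle = c(50, 0, 0)
  )
  tibia_landmarks <- rbind(
    medial_tibial_plateau  = c(-40, 0, 0),
    lateral_tibial_plateau = c(40, 0, 0),
    medial_malleolus       = c(-35, 8, -380),
    lateral_malleolus      = c(25, -8, -380)
  )
  thigh_markers <- rbind(
    M5 = c(70, 15, 260),
    M6 = c(78, -20, 190),
    M7 = c(52, 30, 130),
    M8 = c(80, 5, 70)
  )
  calf_markers <- rbind(
    M9  = c(55, 18, -90),
    M10 = c(62, -18, -160),
    M11 = c(40, 28, -230),
    M12 = c(66, 6, -300)
  )
  list(femur_landmarks = femur_landmarks, tibia_landmarks = tibia_landmarks,
       thigh_markers = thigh_markers, calf_markers = calf_markers)
}

#' Default synthetic probe geometry
#'
#' Four markers spaced along and off the probe shaft, in a probe-fixed
#' frame with the tip at the origin.
#'
#' @return a [probe_model()].
#' @export
default_probe_model <- function() {
  probe_model(rbind(c(0, 0, 100), c(20, 0, 160), c(0, 25, 210), c(-15, -10, 260)))
}

#' Ground-truth joint-angle profile of a squat
#'
#' A smooth squat cycle: half-cosine flexion from 0 up to `max_flexion`
#' and back to 0; adduction/abduction that rises to `abd_peak` (abduction)
#' until flexion passes `abd_switch` and then reverses towards adduction
#' at peak flexion; external rotation growing in proportion to flexion up
#' to `ext_rotation_total`. Raw `alpha_deg` is negative in flexion
#' (`flexion_deg = -alpha_deg`).
#'
#' @param frames number of frames (>= 2).
#' @param max_flexion peak knee flexion in degrees (default 100).
#' @param abd_peak peak abduction in degrees (default 5).
#' @param abd_switch flexion angle at which abduction turns to adduction
#'   (default 40 degrees).
#' @param ext_rotation_total external rotation at peak flexion in degrees
#'   (default 30).
#' @return tibble with columns `frame`, `alpha_deg`, `beta_deg`,
#'   `gamma_deg`, `flexion_deg`.
#' @export
squat_profile <- function(frames, max_flexion = 100, abd_peak = 5,
                          abd_switch = 40, ext_rotation_total = 30) {
  if (frames < 2L) stop("a motion profile needs at least 2 frames", call. = FALSE)
  u <- seq(0, 1, length.out = frames)
  flex <- max_flexion * (1 - cos(2 * pi * u)) / 2
  s <- min(abd_switch, max_flexion)
  beta <- numeric(frames)
  if (s > 0) {
    rising <- flex <= s
    beta[rising] <- abd_peak * (1 - cos(pi * flex[rising] / s)) / 2
    if (max_flexion > s) {
      beta[!rising] <- abd_peak * cos(pi * (flex[!rising] - s) / (max_flexion - s))
    }
  }
  gamma <- if (max_flexion > 0) ext_rotation_total * flex / max_flexion else
    numeric(frames)
  tibble::tibble(frame = seq_len(frames), alpha_deg = -flex, beta_deg = beta,
                 gamma_deg = gamma, flexion_deg = flex)
}

#' Inject occlusion gaps and bounce spikes into a trajectory set
#'
#' Gaps invalidate the listed samples; spikes displace single samples by
#' `amplitude` mm in a seeded random direction. Only listed samples are
#' altered; identical seeds yield identical output.
#'
#' @param set a [mocap_traj()].
#' @param gaps data frame with columns `marker`, `start`, `end` (inclusive
#'   frame numbers), or `NULL`.
#' @param spikes data frame with columns `marker`, `frame`, `amplitude`
#'   (mm), or `NULL`.
#' @param seed RNG seed for spike directions.
#' @return the corrupted [mocap_traj()].
#' @export
corrupt <- function(set, gaps = NULL, spikes = NULL, seed = 1) {
  frames <- frame_numbers(set)
  out <- set
  if (!is.null(gaps) && nrow(gaps) > 0) {
    for (i in seq_len(nrow(gaps))) {
      j <- match(gaps$marker[i], set$labels)
      if (is.na(j)) stop("unknown marker in gap spec: ", gaps$marker[i], call. = FALSE)
      idx <- match(gaps$start[i]:gaps$end[i], frames)
      if (anyNA(idx)) stop("gap out of recording bounds: ", gaps$marker[i],
                           " ", gaps$start[i], "-", gaps$end[i], call. = FALSE)
      out$valid[idx, j] <- FALSE
      out$positions[idx, j, ] <- NA_real_
    }
  }
  if (!is.null(spikes) && nrow(spikes) > 0) {
    withr::with_seed(seed, {
      for (i in seq_len(nrow(spikes))) {
        j <- match(spikes$marker[i], set$labels)
        if (is.na(j)) stop("unknown marker in spike spec: ", spikes$marker[i],
                           call. = FALSE)
        f <- match(spikes$frame[i], frames)
        if (is.na(f)) stop("spike frame out of bounds: ", spikes$frame[i],
                           call. = FALSE)
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        out$positions[f, j, ] <- out$positions[f, j, ] + spikes$amplitude[i] * dir
      }
    })
  }
  out
}

#' Generate a complete synthetic capture session
#'
#' Builds a full session on disk: probe model file, one calibration
#' recording per bony landmark (probe posed with its tip on the landmark,
#' segments static in the reference pose), a motion recording of the two
#' 4-marker clusters posed per the ground-truth angle profile, the
#' ground-truth angle CSV (written before any corruption), and a
#' ready-to-run session YAML. Gaussian coordinate noise, occlusion gaps
#' and bounce spikes are applied to the observations only. Identical
#' seeds yield byte-identical bundles.
#'
#' The femur receives a smooth global motion of its own (pelvis drop and
#' pitch during the squat); the tibia is posed relative to it through the
#' same X-Y-Z angle convention the analysis inverts, so the prescribed
#' angles are the exact ground truth of the relative motion.
#'
#' @param out_dir directory for the bundle (created if needed).
#' @param profile ground-truth angle tibble (`alpha_deg`, `beta_deg`,
#'   `gamma_deg` per frame); default `squat_profile(frames)`.
#' @param frames number of motion frames when `profile` is NULL
#'   (default 500).
#' @param frame_rate sampling rate in Hz (default 100).
#' @param noise_sd i.i.d. Gaussian noise sd per coordinate, mm (default 0).
#' @param gaps,spikes corruption specs for the motion recording (see
#'   [corrupt()]).
#' @param seed RNG seed for noise, probe poses and spike directions.
#' @param n_cal_frames frames per calibration recording (default 10).
#' @param geometry see [default_leg_geometry()].
#' @param probe see [default_probe_model()].
#' @return (invisibly) list with `config_path`, `config`, `truth` (the
#'   ground-truth angle tibble) and `paths` of all written files.
#' @export
generate_session <- function(out_dir, profile = NULL, frames = 500,
                             frame_rate = 100, noise_sd = 0, gaps = NULL,
                             spikes = NULL, seed = 1, n_cal_frames = 10,
                             geometry = default_leg_geometry(),
                             probe = default_probe_model()) {
  if (is.null(profile)) profile <- squat_profile(frames)
  frames <- nrow(profile)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  check_gap_blackout(gaps, frames)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  geom <- geometry
  # lab frame: Y vertical; segment Z (superior) maps onto lab +Y
  G0 <- matrix(c(1, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3, byrow = TRUE)
  knee_height <- 500

  flex <- -profile$alpha_deg
  pose_femur <- function(f) {
    pitch <- 0.35 * flex[f] * pi / 180
    E <- matrix(c(1, 0, 0, 0, cos(pitch), -sin(pitch),
                  0, sin(pitch), cos(pitch)), 3, 3, byrow = TRUE)
    list(R = G0 %*% E, t = c(0, knee_height - 0.4 * flex[f], 0))
  }

  withr::with_seed(seed, {
    # --- calibration recordings: static reference pose (frame 1 of profile
    # is not required to be neutral; calibration uses the neutral pose) ---
    A_ref <- list(R = G0, t = c(0, knee_height, 0))
    paths <- list()
    for (lm in names(.km_landmarks)) {
      cl <- .km_landmarks[[lm]]
      lm_local <- if (cl == "thigh") geom$femur_landmarks[lm, ] else
        geom$tibia_landmarks[lm, ]
      g <- as.vector(A_ref$R %*% lm_local) + A_ref$t
      axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
      Q <- axis_angle_matrix(axis, stats::runif(1, 0.2, 1.2))
      probe_global <- probe$local %*% t(Q) + matrix(g, 4, 3, byrow = TRUE)
      mk_local <- if (cl == "thigh") geom$thigh_markers else geom$calf_markers
      mk_global <- mk_local %*% t(A_ref$R) + matrix(A_ref$t, 4, 3, byrow = TRUE)
      pos <- array(NA_real_, dim = c(n_cal_frames, 8, 3))
      for (f in seq_len(n_cal_frames)) {
        pos[f, 1:4, ] <- probe_global
        pos[f, 5:8, ] <- mk_global
      }
      if (noise_sd > 0) pos <- pos + noise_sd * stats::rnorm(length(pos))
      rec <- mocap_traj(pos, labels = c(probe$labels, rownames(mk_local)),
                        frame_rate = frame_rate)
      p <- file.path(out_dir, paste0("cal_", lm, ".csv"))
      write_trajectories(rec, p)
      paths[[paste0("cal_", lm)]] <- p
    }

    # --- motion recording ---
    labels <- c(rownames(geom$thigh_markers), rownames(geom$calf_markers))
    pos <- array(NA_real_, dim = c(frames, 8, 3))
    for (f in seq_len(frames)) {
      A <- pose_femur(f)
      Rrel <- rotation_from_angles(profile$alpha_deg[f], profile$beta_deg[f],
                                   profile$gamma_deg[f])
      B <- A$R %*% Rrel
      pos[f, 1:4, ] <- geom$thigh_markers %*% t(A$R) +
        matrix(A$t, 4, 3, byrow = TRUE)
      pos[f, 5:8, ] <- geom$calf_markers %*% t(B) +
        matrix(A$t, 4, 3, byrow = TRUE)
    }
    if (noise_sd > 0) pos <- pos + noise_sd * stats::rnorm(length(pos))
    motion <- mocap_traj(pos, labels = labels, frame_rate = frame_rate)
    motion <- corrupt(motion, gaps = gaps, spikes = spikes, seed = seed + 1L)
    motion_path <- file.path(out_dir, "motion.csv")
    write_trajectories(motion, motion_path)
    paths$motion <- motion_path
  })

  probe_path <- file.path(out_dir, "probe.csv")
  write_probe_model(probe, probe_path)
  paths$probe <- probe_path

  truth <- dplyr::mutate(profile,
                         time_s = (profile$frame - profile$frame[1]) / frame_rate,
                         .after = "frame")
  truth_path <- file.path(out_dir, "truth_angles.csv")
  write_num_csv(truth, truth_path)
  paths$truth <- truth_path

  cfg <- list(
    frame_rate = frame_rate,
    side = "right",
    probe = list(file = "probe.csv", labels = probe$labels),
    clusters = list(
      thigh = list(labels = rownames(geometry$thigh_markers)),
      calf = list(labels = rownames(geometry$calf_markers))
    ),
    landmarks = purrr::imap(.km_landmarks, function(cl, lm) {
      list(file = paste0("cal_", lm, ".csv"), cluster = cl)
    }),
    motion = list(file = "motion.csv"),
    patch = list(spike_k = 5, max_gap_frames = 50),
    angles = list(flexion_sign = -1, bin_width = 2)
  )
  config_path <- file.path(out_dir, "session.yaml")
  yaml::write_yaml(cfg, config_path)
  paths$config <- config_path

  invisible(list(config_path = config_path,
                 config = validate_session_config(c(cfg, list(.dir = out_dir))),
                 truth = truth, paths = paths))
}

axis_angle_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# warn when a gap spec blinds >= 2 markers of one cluster for every frame
check_gap_blackout <- function(gaps, frames) {
  if (is.null(gaps) || nrow(gaps) == 0) return(invisible())
  full <- gaps$marker[gaps$start <= 1 & gaps$end >= frames]
  clusters <- list(thigh = paste0("M", 5:8), calf = paste0("M", 9:12))
  for (cl in names(clusters)) {
    if (sum(clusters[[cl]] %in% full) >= 2) {
      warning("gap spec blinds >= 2 markers of the ", cl,
              " cluster for the whole recording; all frames would be discarded",
              call. = FALSE)
    }
  }
  invisible()
}
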