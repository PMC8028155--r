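#' Per-frame anatomical segment coordinate systems
#'
#' A `segment_frames` object stores, per frame, an origin (mm) and the
#' three right-handed orthonormal axis directions X, Y, Z in global
#' coordinates.
#'
#' @param origin `n x 3` matrix (mm).
#' @param X,Y,Z `n x 3` matrices of unit axis directions.
#' @param valid logical vector, one entry per frame.
#' @return object of class `segment_frames`.
#' @export
segment_frames <- function(origin, X, Y, Z, valid = rep(TRUE, nrow(origin))) {
  origin <- as_points(origin); X <- as_points(X); Y <- as_points(Y); Z <- as_points(Z)
  ok <- which(valid)
  if (length(ok) > 0) {
    norms <- cbind(rowSums(X[ok, , drop = FALSE]^2),
                   rowSums(Y[ok, , drop = FALSE]^2),
                   rowSums(Z[ok, , drop = FALSE]^2))
    if (max(abs(norms - 1)) > 1e-6) {
      stop("segment axes must be unit vectors", call. = FALSE)
    }
  }
  structure(list(origin = origin, X = X, Y = Y, Z = Z, valid = as.logical(valid)),
            class = "segment_frames")
}

#' @export
print.segment_frames <- function(x, ...) {
  cat(sprintf("<segment_frames> %d frames (%d valid)\n",
              nrow(x$origin), sum(x$valid)))
  invisible(x)
}

# shared axis construction: X along the given direction, v the long-axis
# hint; Y = unit(X x v), Z = X x Y. Exactly orthonormal by construction.
build_frames <- function(origin, x_dir, v_dir, context) {
  n <- nrow(origin)
  X <- unit_rows(x_dir)
  v <- unit_rows(v_dir)
  Yraw <- cross_rows(X, v)
  ynorm <- sqrt(rowSums(Yraw^2))
  valid <- is.finite(ynorm) & ynorm > 1e-8 &
    apply(is.finite(origin), 1, all)
  if (!any(valid) || (n == 1L && !valid[1])) {
    stop("degenerate ", context, " frame: long-axis landmark is collinear ",
         "with the mediolateral axis", call. = FALSE)
  }
  Y <- Yraw / ifelse(ynorm > 0, ynorm, NA_real_)
  Z <- cross_rows(X, Y)
  origin[!valid, ] <- NA_real_
  X[!valid, ] <- NA_real_; Y[!valid, ] <- NA_real_; Z[!valid, ] <- NA_real_
  segment_frames(origin, X, Y, Z, valid)
}

unit_rows <- function(m) {
  m <- as_points(m)
  m / sqrt(rowSums(m^2))
}

cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Femoral anatomical coordinate system
#'
#' Built from the greater trochanter and the two femoral epicondyles: the
#' epicondyle line is the mediolateral X axis (pointing laterally -- from
#' medial to lateral epicondyle on the right side, mirrored on the left),
#' its midpoint is the origin, the cross product of X with the direction
#' from the greater trochanter to the origin gives the anterior Y axis,
#' and Z = X cross Y points superiorly.
#'
#' @param GT,MFE,LFE greater trochanter, medial and lateral femoral
#'   epicondyle positions: length-3 vectors or `n x 3` matrices (mm).
#' @param side `"right"` or `"left"`.
#' @return a [segment_frames()]; frames with missing or degenerate
#'   landmarks are flagged invalid (a single degenerate frame errors).
#' @export
femur_frame <- function(GT, MFE, LFE, side = c("right", "left")) {
  side <- match.arg(side)
  GT <- as_points(GT); MFE <- as_points(MFE); LFE <- as_points(LFE)
  origin <- (MFE + LFE) / 2
  x_dir <- if (side == "right") LFE - MFE else MFE - LFE
  build_frames(origin, x_dir, origin - GT, "femur")
}

#' Tibial anatomical coordinate system
#'
#' The plateau line is the mediolateral X axis (lateral-pointing), its
#' midpoint the origin; the cross product of X with the direction from the
#' origin to the inter-malleolar midpoint gives the anterior Y axis, and
#' Z = X cross Y points superiorly.
#'
#' @param MTP,LTP medial/lateral tibial plateau positions (mm).
#' @param MM,LM medial/lateral malleolus positions (mm).
#' @param side `"right"` or `"left"`.
#' @return a [segment_frames()].
#' @export
tibia_frame <- function(MTP, LTP, MM, LM, side = c("right", "left")) {
  side <- match.arg(side)
  MTP <- as_points(MTP); LTP <- as_points(LTP)
  MM <- as_points(MM); LM <- as_points(LM)
  origin <- (MTP + LTP) / 2
  x_dir <- if (side == "right") LTP - MTP else MTP - LTP
  ankle_mid <- (MM + LM) / 2
  build_frames(origin, x_dir, ankle_mid - origin, "tibia")
}

#' Relative rotation matrix between two segment frames
#'
#' Expresses the tibial axes in the femoral frame: `R = F' T`, where `F`
#' and `T` hold the femur/tibia unit axes as columns.
#'
#' @param femur,tibia [segment_frames()] series of equal length.
#' @return for a single frame pair, a 3x3 rotation matrix; otherwise an
#'   `n x 3 x 3` array with `NA` slices on invalid frames, carrying a
#'   `valid` attribute.
#' @export
relative_rotation <- function(femur, tibia) {
  n <- nrow(femur$origin)
  if (nrow(tibia$origin) != n) {
    stop("femur and tibia series must have equal frame counts", call. = FALSE)
  }
  R <- array(NA_real_, dim = c(n, 3, 3))
  valid <- femur$valid & tibia$valid
  for (f in which(valid)) {
    Fm <- cbind(femur$X[f, ], femur$Y[f, ], femur$Z[f, ])
    Tm <- cbind(tibia$X[f, ], tibia$Y[f, ], tibia$Z[f, ])
    R[f, , ] <- crossprod(Fm, Tm)
  }
  if (n == 1L) {
    out <- matrix(R[1, , ], 3, 3)
    attr(out, "valid") <- valid
    return(out)
  }
  attr(R, "valid") <- valid
  R
}

#' Compose a rotation matrix from X-Y-Z joint angles
#'
#' The convention throughout the package: the relative rotation `R`
#' (tibial axes expressed in the femoral frame) and the joint angles
#' satisfy `t(R) = Rx(alpha) Ry(beta) Rz(gamma)` -- the femoral frame is
#' carried onto the tibial frame by rotating alpha about X, then beta
#' about Y, then gamma about Z.
#'
#' @param alpha,beta,gamma angles in degrees.
#' @return 3x3 rotation matrix `R`.
#' @export
rotation_from_angles <- function(alpha, beta, gamma) {
  a <- alpha * pi / 180; b <- beta * pi / 180; g <- gamma * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rz <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3, 3)
  t(Rx %*% Ry %*% Rz)
}

#' Extract X-Y-Z joint angles from a rotation matrix
#'
#' Two-argument arctangent extraction:
#' `alpha = atan2(-R32, R33)`, `beta = atan2(R31, sqrt(R11^2 + R21^2))`,
#' `gamma = atan2(-R21, R11)`. The `strict_printed` variant replaces the
#' `R21` inside beta's square root with `R12`; it is retained for
#' comparison but is not self-consistent with the X-Y-Z factorization (the
#' round-trip property fails), which is why the `R21` form is the default.
#' At gimbal lock (`|beta| = 90` degrees, `R31 = +/-1`) gamma is set to 0,
#' alpha absorbs the free angle, and the gimbal flag is raised.
#'
#' @param R a 3x3 rotation matrix or an `n x 3 x 3` array of them.
#' @param strict_printed use the `R12` variant of the beta formula.
#' @return tibble with columns `alpha`, `beta`, `gamma` (degrees) and
#'   `gimbal` (logical), one row per input rotation.
#' @export
euler_xyz <- function(R, strict_printed = FALSE) {
  if (is.matrix(R)) {
    Ra <- array(R, dim = c(1, 3, 3))
    Ra[1, , ] <- R
    R <- Ra
  }
  n <- dim(R)[1]
  out <- tibble::tibble(alpha = rep(NA_real_, n), beta = NA_real_,
                        gamma = NA_real_, gimbal = FALSE)
  deg <- 180 / pi
  for (f in seq_len(n)) {
    M <- matrix(R[f, , ], 3, 3)
    if (anyNA(M)) next
    err <- max(abs(crossprod(M) - diag(3)))
    if (err > .km_tol$rotation_in || abs(det(M) - 1) > .km_tol$rotation_in) {
      stop(sprintf("not a rotation matrix (max |R'R - I| = %.2e)", err),
           call. = FALSE)
    }
    r31 <- M[3, 1]
    if (abs(r31) >= 1 - 1e-12) {
      # gimbal lock: beta = +/-90 deg, only alpha -/+ gamma is determined
      out$beta[f] <- deg * asin(max(-1, min(1, r31)))
      out$gamma[f] <- 0
      out$alpha[f] <- deg * if (r31 > 0) atan2(M[1, 2], M[2, 2]) else
        -atan2(M[1, 2], M[2, 2])
      out$gimbal[f] <- TRUE
    } else {
      out$alpha[f] <- deg * atan2(-M[3, 2], M[3, 3])
      hyp <- if (strict_printed) sqrt(M[1, 1]^2 + M[1, 2]^2) else
        sqrt(M[1, 1]^2 + M[2, 1]^2)
      out$beta[f] <- deg * atan2(r31, hyp)
      out$gamma[f] <- deg * atan2(-M[2, 1], M[1, 1])
    }
  }
  out
}

#' Knee joint angles from femur and tibia frame series
#'
#' Per frame, the relative rotation (tibial axes in the femoral frame) is
#' decomposed by the X-Y-Z convention: alpha is flexion/extension (about
#' the mediolateral X axis), beta adduction/abduction (about Y), gamma
#' internal/external rotation (about Z). The clinical `flexion_deg` column
#' applies `flexion_sign` to alpha so knee flexion is positive (with this
#' package's frame conventions, alpha is negative in flexion; the default
#' sign is therefore -1).
#'
#' @param femur,tibia [segment_frames()] series of equal length.
#' @param frame_rate sampling rate in Hz.
#' @param start_frame frame number of the first sample.
#' @param flexion_sign +1 or -1 multiplier applied to alpha for the
#'   clinical flexion column.
#' @param strict_printed see [euler_xyz()].
#' @return a `knee_angles` tibble with columns `frame`, `time_s`,
#'   `alpha_deg`, `beta_deg`, `gamma_deg`, `flexion_deg`, `abd_add_deg`,
#'   `int_ext_deg`, `valid`, `gimbal`.
#' @export
knee_angles <- function(femur, tibia, frame_rate = 100, start_frame = 1L,
                        flexion_sign = -1, strict_printed = FALSE) {
  R <- relative_rotation(femur, tibia)
  if (is.matrix(R)) {
    Ra <- array(NA_real_, dim = c(1, 3, 3)); Ra[1, , ] <- R
    attr(Ra, "valid") <- attr(R, "valid"); R <- Ra
  }
  valid <- attr(R, "valid")
  ang <- euler_xyz(R, strict_printed = strict_printed)
  n <- nrow(ang)
  frames <- start_frame + seq_len(n) - 1L
  out <- tibble::tibble(
    frame = frames,
    time_s = (frames - start_frame) / frame_rate,
    alpha_deg = ang$alpha, beta_deg = ang$beta, gamma_deg = ang$gamma,
    flexion_deg = flexion_sign * ang$alpha,
    abd_add_deg = ang$beta,
    int_ext_deg = ang$gamma,
    valid = valid & !is.na(ang$alpha),
    gimbal = ang$gimbal
  )
  class(out) <- c("knee_angles", class(out))
  attr(out, "frame_rate") <- frame_rate
  out
}

#' Bin joint angles by flexion angle
#'
#' Buckets valid frames by the clinical flexion angle and reports
#' per-bucket mean adduction/abduction and internal/external rotation --
#' the standard "coupled rotations vs flexion" curve.
#'
#' @param angles a `knee_angles` tibble (or any data frame with
#'   `flexion_deg`, `abd_add_deg`, `int_ext_deg`, `valid`).
#' @param bin_width flexion bin width in degrees (> 0, default 2).
#' @return tibble with columns `flexion_deg` (bin centre), `abd_add_deg`,
#'   `int_ext_deg` (bucket means) and `n_frames`, ordered by flexion.
#' @export
angles_vs_flexion <- function(angles, bin_width = 2) {
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("`bin_width` must be a positive number of degrees", call. = FALSE)
  }
  df <- dplyr::filter(tibble::as_tibble(angles), .data$valid)
  if (nrow(df) == 0L) stop("no valid frames to bin", call. = FALSE)
  df |>
    dplyr::mutate(.bin = floor(.data$flexion_deg / bin_width)) |>
    dplyr::group_by(.data$.bin) |>
    dplyr::summarise(
      flexion_deg = (.bin[1] + 0.5) * bin_width,
      abd_add_deg = mean(.data$abd_add_deg),
      int_ext_deg = mean(.data$int_ext_deg),
      n_frames = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$flexion_deg) |>
    dplyr::select(-".bin")
}

#' Plot knee angle time series
#' @param object a `knee_angles` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot knee_angles
#' @export
autoplot.knee_angles <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(.data$valid) |>
    tidyr::pivot_longer(cols = c("flexion_deg", "abd_add_deg", "int_ext_deg"),
                        names_to = "angle", values_to = "deg")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$deg)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~angle, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "angle (deg)")
}

#' Plot coupled rotations against flexion
#' @param angles a `knee_angles` tibble.
#' @param bin_width flexion bin width in degrees.
#' @return a ggplot object.
#' @export
plot_angles_vs_flexion <- function(angles, bin_width = 2) {
  binned <- angles_vs_flexion(angles, bin_width) |>
    tidyr::pivot_longer(cols = c("abd_add_deg", "int_ext_deg"),
                        names_to = "angle", values_to = "deg")
  ggplot2::ggplot(binned, ggplot2::aes(x = .data$flexion_deg, y = .data$deg,
                                       colour = .data$angle)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "flexion (deg)", y = "coupled rotation (deg)")
}
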