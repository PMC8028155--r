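test_that("the femoral frame matches the hand-checkable construction", {
  fr <- femur_frame(GT = c(0, 0, 400), MFE = c(-50, 0, 0), LFE = c(50, 0, 0))
  expect_equal(fr$origin[1, ], c(0, 0, 0))
  expect_equal(fr$X[1, ], c(1, 0, 0))
  expect_equal(fr$Y[1, ], c(0, 1, 0))
  expect_equal(fr$Z[1, ], c(0, 0, 1))
  # translation equivariance
  d <- c(7, 8, 9)
  fr2 <- femur_frame(c(0, 0, 400) + d, c(-50, 0, 0) + d, c(50, 0, 0) + d)
  expect_equal(fr2$origin[1, ], d)
  expect_equal(fr2$X[1, ], fr$X[1, ])
  expect_equal(fr2$Y[1, ], fr$Y[1, ])
  expect_equal(fr2$Z[1, ], fr$Z[1, ])
  # left side mirrors the mediolateral axis
  frl <- femur_frame(c(0, 0, 400), c(-50, 0, 0), c(50, 0, 0), side = "left")
  expect_equal(frl$X[1, ], c(-1, 0, 0))
})

test_that("the tibial frame matches the hand-checkable construction", {
  fr <- tibia_frame(MTP = c(-40, 0, 0), LTP = c(40, 0, 0),
                    MM = c(-30, 0, -380), LM = c(30, 0, -380))
  expect_equal(fr$origin[1, ], c(0, 0, 0))
  expect_equal(fr$X[1, ], c(1, 0, 0))
  expect_equal(fr$Y[1, ], c(0, 1, 0))
  expect_equal(fr$Z[1, ], c(0, 0, 1))
  # malleoli midpoint on the plateau axis: no anterior direction exists
  expect_error(tibia_frame(c(-40, 0, 0), c(40, 0, 0),
                           c(-10, 0, 0), c(30, 0, 0)), "degenerate")
})

test_that("frame construction is equivariant under rigid motions", {
  withr::with_seed(43, {
    GT <- c(15, 3, 400); MFE <- c(-50, -4, 2); LFE <- c(50, 5, -1)
    base <- femur_frame(GT, MFE, LFE)
    for (i in 1:10) {
      Q <- random_rotation(); t <- stats::rnorm(3, sd = 200)
      mv <- function(p) as.vector(Q %*% p) + t
      fr <- femur_frame(mv(GT), mv(MFE), mv(LFE))
      expect_lt(max(abs(fr$origin[1, ] - mv((MFE + LFE) / 2))), 1e-9)
      expect_lt(max(abs(fr$X[1, ] - as.vector(Q %*% base$X[1, ]))), 1e-9)
      expect_lt(max(abs(fr$Y[1, ] - as.vector(Q %*% base$Y[1, ]))), 1e-9)
      expect_lt(max(abs(fr$Z[1, ] - as.vector(Q %*% base$Z[1, ]))), 1e-9)
    }
  })
})

test_that("constructed axes are exactly orthonormal and right-handed", {
  withr::with_seed(47, {
    for (i in 1:20) {
      pts <- matrix(stats::rnorm(9, sd = 100), 3, 3)
      fr <- tryCatch(femur_frame(pts[1, ], pts[2, ], pts[3, ]),
                     error = function(e) NULL)
      if (is.null(fr)) next
      B <- cbind(fr$X[1, ], fr$Y[1, ], fr$Z[1, ])
      expect_lt(max(abs(crossprod(B) - diag(3))), 1e-9)
      expect_equal(det(B), 1, tolerance = 1e-9)
    }
  })
})

test_that("relative rotation is the tibia expressed in the femoral frame", {
  fem <- femur_frame(c(0, 0, 400), c(-50, 0, 0), c(50, 0, 0))
  tib <- tibia_frame(c(-40, 0, 0), c(40, 0, 0), c(-30, 0, -380), c(30, 0, -380))
  R <- relative_rotation(fem, tib)
  expect_equal(matrix(R, 3, 3), diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  # tibia rotated about the femoral X axis by a known angle
  th <- 0.4
  Q <- rot_axis_angle(c(1, 0, 0), th)
  tib2 <- tibia_frame(as.vector(Q %*% c(-40, 0, 0)), as.vector(Q %*% c(40, 0, 0)),
                      as.vector(Q %*% c(-30, 0, -380)), as.vector(Q %*% c(30, 0, -380)))
  R2 <- relative_rotation(fem, tib2)
  expect_lt(max(abs(matrix(R2, 3, 3) - Q)), 1e-12)
  expect_equal(det(matrix(R2, 3, 3)), 1, tolerance = 1e-12)
})

test_that("angle extraction round-trips the X-Y-Z factorization", {
  expect_equal(unlist(euler_xyz(diag(3))[1, 1:3]),
               c(alpha = 0, beta = 0, gamma = 0))
  ang <- euler_xyz(rotation_from_angles(30, 10, -20))
  expect_equal(ang$alpha, 30, tolerance = 1e-9)
  expect_equal(ang$beta, 10, tolerance = 1e-9)
  expect_equal(ang$gamma, -20, tolerance = 1e-9)
  expect_false(ang$gimbal)
  # grid round-trip at 1e-9 degrees
  grid <- expand.grid(a = seq(-80, 80, by = 20), b = seq(-80, 80, by = 20),
                      g = seq(-80, 80, by = 20))
  Rs <- array(NA_real_, dim = c(nrow(grid), 3, 3))
  for (i in seq_len(nrow(grid))) {
    Rs[i, , ] <- rotation_from_angles(grid$a[i], grid$b[i], grid$g[i])
  }
  out <- euler_xyz(Rs)
  expect_lt(max(abs(out$alpha - grid$a)), 1e-9)
  expect_lt(max(abs(out$beta - grid$b)), 1e-9)
  expect_lt(max(abs(out$gamma - grid$g)), 1e-9)
})

test_that("the printed beta variant (R12) breaks the round-trip", {
  ok <- euler_xyz(rotation_from_angles(25, 35, 45))
  bad <- euler_xyz(rotation_from_angles(25, 35, 45), strict_printed = TRUE)
  expect_equal(ok$beta, 35, tolerance = 1e-9)
  expect_gt(abs(bad$beta - 35), 1e-3)
})

test_that("gimbal lock is flagged with gamma conventionally zeroed", {
  R <- rotation_from_angles(20, 90, 0)
  out <- euler_xyz(R)
  expect_true(out$gimbal)
  expect_equal(out$beta, 90, tolerance = 1e-9)
  expect_equal(out$gamma, 0)
  expect_equal(out$alpha, 20, tolerance = 1e-6)
  expect_error(euler_xyz(matrix(c(1, 0, 0, 0, 2, 0, 0, 0, 1), 3, 3)),
               "not a rotation")
})

test_that("knee angles propagate masks and are zero for coincident frames", {
  n <- 5
  GT <- matrix(rep(c(0, 0, 400), each = n), n, 3)
  MFE <- matrix(rep(c(-50, 0, 0), each = n), n, 3)
  LFE <- matrix(rep(c(50, 0, 0), each = n), n, 3)
  fem <- femur_frame(GT, MFE, LFE)
  MTP <- matrix(rep(c(-40, 0, 0), each = n), n, 3)
  LTP <- matrix(rep(c(40, 0, 0), each = n), n, 3)
  MM <- matrix(rep(c(-30, 0, -380), each = n), n, 3)
  LM <- matrix(rep(c(30, 0, -380), each = n), n, 3)
  tib <- tibia_frame(MTP, LTP, MM, LM)
  ang <- knee_angles(fem, tib, frame_rate = 100)
  expect_true(all(ang$valid))
  expect_equal(max(abs(c(ang$alpha_deg, ang$beta_deg, ang$gamma_deg))), 0,
               tolerance = 1e-12)
  expect_equal(ang$flexion_deg, -ang$alpha_deg)
  # one invalid landmark frame invalidates that angle frame only
  GT2 <- GT; GT2[3, ] <- NA_real_
  fem2 <- femur_frame(GT2, MFE, LFE)
  ang2 <- knee_angles(fem2, tib, frame_rate = 100)
  expect_identical(ang2$valid, c(TRUE, TRUE, FALSE, TRUE, TRUE))
})

test_that("relative angles ignore any common rigid motion of both segments", {
  withr::with_seed(53, {
    fem_l <- list(GT = c(15, 0, 400), MFE = c(-50, 0, 0), LFE = c(50, 0, 0))
    tib_l <- list(MTP = c(-40, 0, 0), LTP = c(40, 0, 0),
                  MM = c(-35, 8, -380), LM = c(25, -8, -380))
    Rrel <- rotation_from_angles(-35, 4, 12)
    tib_posed <- lapply(tib_l, function(p) as.vector(Rrel %*% p))
    base <- knee_angles(do.call(femur_frame, fem_l),
                        do.call(tibia_frame, tib_posed))
    for (i in 1:5) {
      Q <- random_rotation(); t <- stats::rnorm(3, sd = 500)
      mv <- function(p) as.vector(Q %*% p) + t
      moved <- knee_angles(do.call(femur_frame, lapply(fem_l, mv)),
                           do.call(tibia_frame, lapply(tib_posed, mv)))
      expect_lt(max(abs(c(moved$alpha_deg - base$alpha_deg,
                          moved$beta_deg - base$beta_deg,
                          moved$gamma_deg - base$gamma_deg))), 1e-9)
    }
    expect_equal(base$alpha_deg, -35, tolerance = 1e-9)
    expect_equal(base$beta_deg, 4, tolerance = 1e-9)
    expect_equal(base$gamma_deg, 12, tolerance = 1e-9)
  })
})

test_that("flexion binning averages within ordered buckets", {
  # constant angles: one bucket holding exactly those values
  ang <- tibble::tibble(flexion_deg = rep(10.4, 8), abd_add_deg = 3,
                        int_ext_deg = -7, valid = TRUE)
  b <- angles_vs_flexion(ang, bin_width = 2)
  expect_equal(nrow(b), 1)
  expect_equal(b$abd_add_deg, 3)
  expect_equal(b$int_ext_deg, -7)
  expect_equal(b$n_frames, 8L)
  # linear coupling: bucket means sit on the line within half a bin
  flex <- seq(0, 60, by = 0.25)
  ang2 <- tibble::tibble(flexion_deg = flex, abd_add_deg = 0.3 * flex,
                         int_ext_deg = -0.1 * flex, valid = TRUE)
  b2 <- angles_vs_flexion(ang2, bin_width = 2)
  expect_true(all(diff(b2$flexion_deg) > 0))
  expect_lte(max(abs(b2$abd_add_deg - 0.3 * b2$flexion_deg)), 0.3 * 1 + 1e-9)
  expect_error(angles_vs_flexion(ang2, bin_width = 0), "positive")
  expect_error(angles_vs_flexion(dplyr::mutate(ang2, valid = FALSE)),
               "no valid frames")
})
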