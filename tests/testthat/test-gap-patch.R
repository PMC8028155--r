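punch_gap <- function(traj, marker, frames) {
  traj$valid[frames, marker] <- FALSE
  traj$positions[frames, marker, ] <- NA_real_
  traj
}

test_that("gap detection reports maximal invalid runs with inclusive bounds", {
  tr <- rigid_cluster_motion(n = 250)
  expect_equal(nrow(detect_gaps(tr)), 0)
  tr2 <- punch_gap(tr, "M2", c(105:150, 152:155, 190:215))
  gaps <- detect_gaps(tr2)
  expect_equal(gaps$marker, rep("M2", 3))
  expect_equal(gaps$start, c(105, 152, 190))
  expect_equal(gaps$end, c(150, 155, 215))
  expect_equal(gaps$length, c(46, 4, 26))
  # gap touching the first frame
  tr3 <- punch_gap(tr, "M1", 1:5)
  expect_equal(detect_gaps(tr3)$start, 1)
})

test_that("the spike detector flags single-frame bounces and only those", {
  # constant trajectory with one 50 mm excursion: both legs are 50 mm,
  # the median displacement is 0, and the detour returns -> flagged
  pos <- array(0, dim = c(60, 1, 3))
  pos[30, 1, ] <- c(50, 0, 0) / sqrt(1)
  tr <- mocap_traj(pos + 100, labels = "A", frame_rate = 100)
  tr$positions[30, 1, 1] <- 150
  out <- detect_spikes(tr, k = 5)
  expect_equal(out$spikes$frame, 30)
  expect_equal(out$spikes$marker, "A")
  expect_false(out$set$valid[30, 1])
  expect_equal(sum(!out$set$valid), 1)

  # smooth sinusoid: every displacement is comparable to the median
  f <- 1:200
  pos <- array(0, dim = c(200, 1, 3))
  pos[, 1, 1] <- 100 * sin(2 * pi * f / 100)
  pos[, 1, 2] <- 500
  tr <- mocap_traj(pos, labels = "A", frame_rate = 100)
  expect_equal(nrow(detect_spikes(tr, k = 5)$spikes), 0)

  # short series: nothing to flag, no error
  short <- mocap_traj(array(1, dim = c(2, 1, 3)), labels = "A")
  expect_equal(nrow(detect_spikes(short, k = 5)$spikes), 0)
  expect_error(detect_spikes(tr, k = 1), "greater than 1")
})

test_that("rigid completion reconstructs single-marker dropouts exactly", {
  tr <- rigid_cluster_motion(n = 100)
  clean <- tr
  tr <- punch_gap(tr, "M2", 10:40)
  out <- repair_rigid(tr)
  expect_true(all(out$set$valid))
  expect_lt(max(abs(out$set$positions - clean$positions)), 1e-9)
  expect_equal(sort(out$log$frame), 10:40)
  expect_true(all(out$log$marker == "M2"))
  # all-complete input: identical output, empty log
  out0 <- repair_rigid(clean)
  expect_identical(out0$set$positions, clean$positions)
  expect_equal(nrow(out0$log), 0)
  # frames with two missing markers are left untouched here
  tr2 <- punch_gap(clean, "M1", 50:55)
  tr2 <- punch_gap(tr2, "M3", 50:55)
  out2 <- repair_rigid(tr2)
  expect_false(any(out2$set$valid[50:55, c("M1", "M3")]))
  expect_equal(nrow(out2$log), 0)
})

test_that("donor frames are the nearest complete frames, earlier on ties", {
  tr <- rigid_cluster_motion(n = 21)
  tr <- punch_gap(tr, "M4", 11)   # frames 10 and 12 equally near
  out <- repair_rigid(tr)
  expect_equal(out$log$donor, 10)
  tr2 <- rigid_cluster_motion(n = 21)
  tr2 <- punch_gap(tr2, "M4", 2:12)  # frame 1 nearer for 2..6, 13 for 8..12
  donors <- repair_rigid(tr2)$log$donor
  expect_equal(donors, c(1, 1, 1, 1, 1, 1, 13, 13, 13, 13, 13))
})

test_that("spline fill is exact on lines, interpolatory, and bounded on sinusoids", {
  # linear trajectory: natural cubic spline reproduces it exactly
  n <- 50
  pos <- array(NA_real_, dim = c(n, 1, 3))
  for (k in 1:3) pos[, 1, k] <- k * 10 + 2 * k * (1:n)
  clean <- mocap_traj(pos, labels = "A")
  gappy <- punch_gap(clean, "A", 20:24)
  out <- repair_spline(gappy)
  expect_true(all(out$set$valid))
  expect_lt(max(abs(out$set$positions - clean$positions)), 1e-9)
  expect_equal(out$log$frame, 20:24)
  # valid samples are never altered
  expect_identical(out$set$positions[-(20:24), 1, ], clean$positions[-(20:24), 1, ])

  # sinusoid with a 10-frame gap: error within the bound of the same
  # natural-spline oracle evaluated against the dense series
  n <- 200
  pos <- array(0, dim = c(n, 1, 3))
  pos[, 1, 1] <- 100 * sin(2 * pi * (1:n) / 100)
  clean <- mocap_traj(pos, labels = "A")
  gap <- 95:104
  gappy <- punch_gap(clean, "A", gap)
  out <- repair_spline(gappy)
  oracle <- stats::splinefun(setdiff(1:n, gap),
                             100 * sin(2 * pi * setdiff(1:n, gap) / 100),
                             method = "natural")
  bound <- max(abs(oracle(gap) - 100 * sin(2 * pi * gap / 100))) + 1e-9
  expect_lte(max(abs(out$set$positions[gap, 1, 1] -
                       clean$positions[gap, 1, 1])), bound)

  # edge gaps are never extrapolated; overlong gaps stay missing
  edge <- punch_gap(clean, "A", 1:5)
  expect_false(any(repair_spline(edge)$set$valid[1:5, 1]))
  long <- punch_gap(clean, "A", 50:120)
  expect_false(any(repair_spline(long, max_gap_frames = 50)$set$valid[50:120, 1]))
})

test_that("the patch pipeline repairs a corrupted squat and reports it", {
  clean <- rigid_cluster_motion(n = 500)
  # dropout patterns with the frame ranges seen in real thigh captures,
  # plus three bounces
  tr <- punch_gap(clean, "M1", 370:400)
  tr <- punch_gap(tr, "M2", c(105:150, 152:155, 190:215))
  spiked <- corrupt(tr, spikes = tibble::tibble(
    marker = c("M3", "M4", "M4"), frame = c(80, 220, 340),
    amplitude = c(60, 55, 70)), seed = 9)
  out <- patch_pipeline(spiked)
  expect_true(all(out$set$valid))
  expect_equal(length(out$report$frames_discarded), 0)
  expect_lt(max(abs(out$set$positions - clean$positions)), 1e-9)
  expect_setequal(unique(out$report$repairs$method), "rigid")
  expect_equal(nrow(out$report$spikes), 3)
  # conservation: every sample in exactly one state
  cnt <- out$report$counts
  expect_true(all(cnt$kept + cnt$rigid + cnt$spline + cnt$discarded +
                    cnt$missing == cnt$total))

  # clean input: zero repairs, identical output
  out0 <- patch_pipeline(clean)
  expect_identical(out0$set$positions, clean$positions)
  expect_equal(sum(out0$report$counts$rigid + out0$report$counts$spline), 0)
})

test_that("simultaneous two-marker dropouts are discarded, never imputed", {
  clean <- rigid_cluster_motion(n = 100)
  tr <- punch_gap(clean, "M1", 50:60)
  tr <- punch_gap(tr, "M2", 50:60)
  out <- patch_pipeline(tr)
  expect_equal(out$report$frames_discarded, 50:60)
  expect_false(any(out$set$valid[50:60, ]))
  expect_true(all(is.na(out$set$positions[50:60, , ])))
  expect_true(all(out$set$valid[-(50:60), ]))
  cnt <- out$report$counts
  expect_equal(sum(cnt$discarded), 11 * 4)
  expect_true(all(cnt$kept + cnt$rigid + cnt$spline + cnt$discarded +
                    cnt$missing == cnt$total))
})

test_that("patching is idempotent and respects valid input samples", {
  clean <- rigid_cluster_motion(n = 200)
  tr <- punch_gap(clean, "M3", 20:45)
  tr <- punch_gap(tr, "M1", 100:110)
  out1 <- patch_pipeline(tr)
  out2 <- patch_pipeline(out1$set)
  expect_equal(sum(out2$report$counts$rigid + out2$report$counts$spline), 0)
  expect_identical(out2$set$positions, out1$set$positions)
  # untouched samples are bit-identical to the input
  mask <- tr$valid
  for (j in 1:4) {
    expect_identical(out1$set$positions[mask[, j], j, ],
                     tr$positions[mask[, j], j, ])
  }
})

test_that("noisy rigid repair stays within five noise standard deviations", {
  withr::with_seed(41, {
    clean <- rigid_cluster_motion(n = 200)
    sd <- 0.2
    noisy <- clean
    noisy$positions <- clean$positions + array(stats::rnorm(200 * 4 * 3, sd = sd),
                                               dim = c(200, 4, 3))
    tr <- punch_gap(noisy, "M2", 60:100)
    out <- repair_rigid(tr)
    err <- sqrt(rowSums((out$set$positions[60:100, 2, ] -
                           clean$positions[60:100, 2, ])^2))
    expect_lt(sqrt(mean(err^2)), 5 * sd)
  })
})
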