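test_that("downsampling decimates integer ratios exactly and is identity at target rate", {
  tr300 <- fixture_trial("HS", n_strides = 2, rate = 300, noise_sd = 0)
  tr150 <- downsample_trial(tr300, 150)
  expect_equal(tr150$rate, 150)
  expect_equal(tr150$n_frames, ceiling(tr300$n_frames / 2))
  expect_equal(get_marker(tr150, "HEE")$positions,
               get_marker(tr300, "HEE")$positions[seq(1, tr300$n_frames, 2), ])
  expect_identical(tr150$events$time_s, tr300$events$time_s)

  same <- fixture_trial("HS", n_strides = 2, rate = 150)
  expect_identical(downsample_trial(same, 150), same)
  expect_error(downsample_trial(same, 300), "exceeds")
})

test_that("downsampling a linear ramp lands exactly on the ramp for any ratio", {
  n <- 100
  pos <- cbind(seq(0, 99, length.out = n), 0, 0)
  mk <- marker_trajectory("HEE", "R", pos, rate = 250)
  tr <- gait_trial("s", "t", list(mk), 250)
  # non-integer ratio 250 -> 150 forces interpolation
  dn <- downsample_trial(tr, 150)
  expect_equal(get_marker(dn, "HEE")$positions[, 1],
               trial_frame_times(dn) * 250, tolerance = 1e-9)
})

test_that("forward-difference velocity matches the difference quotient", {
  expect_equal(compute_velocities(cbind(c(0, 1, 2)), 150),
               cbind(c(150, 150, 150)))
  expect_equal(compute_velocities(matrix(5, 10, 3), 150),
               matrix(0, 10, 3))
  # sine input: output equals the analytic difference quotient, not cos
  rate <- 150
  t <- (0:99) / rate
  s <- sin(2 * pi * 3 * t)
  v <- compute_velocities(cbind(s), rate)
  expected <- (s[2:100] - s[1:99]) * rate
  expect_equal(v[1:99], expected)
  expect_equal(v[100], expected[99])  # last frame padded
  expect_error(compute_velocities(cbind(1), 150), "two frames")
})

test_that("canonicalization aligns progression with +x, mirrors left feet, and is idempotent", {
  # a trial walking in -x after a 180 degree rotation of the lab frame
  tr <- fixture_trial("HS", n_strides = 3, noise_sd = 0)
  flipped <- tr
  for (nm in names(flipped$markers))
    flipped$markers[[nm]]$positions[, 1:2] <-
      -flipped$markers[[nm]]$positions[, 1:2]
  can <- canonicalize_trial(flipped)
  hee <- get_marker(can, "HEE")$positions
  expect_gt(hee[nrow(hee), 1] - hee[1, 1], 1000)

  # mirrored left-foot trial equals the equivalent right-foot trial
  trL <- fixture_trial("FF", n_strides = 3, noise_sd = 0, side = "L")
  trR <- fixture_trial("FF", n_strides = 3, noise_sd = 0, side = "R")
  cl <- canonicalize_trial(trL); cr <- canonicalize_trial(trR)
  expect_equal(get_marker(cl, "TOE")$positions,
               get_marker(cr, "TOE")$positions, tolerance = 1e-6)

  expect_identical(canonicalize_trial(can), can)

  # standing still is rejected
  still <- tr
  for (nm in names(still$markers))
    still$markers[[nm]]$positions[, 1] <- 0
  expect_error(canonicalize_trial(still), "progression")
})

test_that("feature assembly yields 6 channels per marker in combo order", {
  tr <- canonicalize_trial(fixture_trial("HS", n_strides = 2))
  for (case in list(list("TOE|HEE", 12), list("HLX|PMT5|HEE", 18),
                    list("HEE", 6), list("HLX|TOE|HEE", 18))) {
    f <- assemble_features(tr, case[[1]])
    expect_equal(ncol(f$values), case[[2]])
    expect_equal(nrow(f$channels), case[[2]])
  }
  f <- assemble_features(tr, "TOE|HEE")
  expect_equal(f$channels$marker, rep(c("TOE", "HEE"), each = 6))
  expect_equal(f$channels$kind[1:6], rep(c("position", "velocity"), each = 3))
  expect_error(assemble_features(tr, "TOE|TOE"), "duplicate")
  expect_error(assemble_features(tr, "FOO|HEE"), "unknown")

  # standardization: z-scored channels have mean 0, sd 1 on the fit data
  sc <- fit_feature_scaler(list(f))
  fs <- assemble_features(tr, "TOE|HEE", scaler = sc)
  expect_equal(unname(colMeans(fs$values)), rep(0, 12), tolerance = 1e-9)
  expect_equal(unname(apply(fs$values, 2, sd)), rep(1, 12), tolerance = 1e-9)
})

test_that("training windows are centred up to a bounded uniform offset", {
  tr <- canonicalize_trial(fixture_trial("HS", n_strides = 4))
  f <- assemble_features(tr, "TOE|HEE")
  ev <- list(time_s = 500 / f$rate, event_type = "IC")  # frame 500, 0-based
  w0 <- extract_training_window(f, ev, offset = 0)
  expect_equal(nrow(w0$values), 150)
  expect_equal(w0$start, 426)  # frames 425..574 in 0-based indexing
  expect_equal(w0$offset_frames, 0L)

  set.seed(99); d1 <- extract_training_window(f, ev)$offset_frames
  set.seed(99); d2 <- extract_training_window(f, ev)$offset_frames
  expect_identical(d1, d2)

  # offsets are uniform over the 61 integers [-30, 30]
  set.seed(123)
  draws <- replicate(1e4, extract_training_window(f, ev)$offset_frames)
  expect_equal(max(abs(draws)), 30)
  p <- suppressWarnings(chisq.test(table(factor(draws, -30:30)))$p.value)
  expect_gt(p, 0.01)

  # the generating event always stays inside the window
  enc <- encoder_config()
  for (d in c(-30, 0, 30)) {
    w <- extract_training_window(f, ev, offset = d)
    ev_pos <- w$event_frame - w$start + 1
    expect_true(ev_pos >= 1 && ev_pos <= 150)
  }

  # edge clamping shifts the window inward instead of zero-padding
  early <- list(time_s = 10 / f$rate, event_type = "IC")
  we <- extract_training_window(f, early, offset = -30)
  expect_equal(we$start, 1L)
  expect_equal(nrow(we$values), 150)
})

test_that("IC pattern classification recovers the generating pattern", {
  for (pat in c("HS", "MF", "FF")) {
    tr <- fixture_trial(pat, noise_sd = 0, n_strides = 3)
    expect_equal(classify_ic_pattern(tr), pat)
  }
  # pitch mode distinguishes heel-strike from toe-walking
  hs <- fixture_trial("HS", noise_sd = 0, n_strides = 3)
  ff <- fixture_trial("FF", noise_sd = 0, n_strides = 3)
  expect_equal(classify_ic_pattern(hs, mode = "pitch"), "HS")
  expect_equal(classify_ic_pattern(ff, mode = "pitch"), "FF")
  expect_error(classify_ic_pattern(hs, ic_events = gait_events()), "IC")
})
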