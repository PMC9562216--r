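test_that("threshold crossings are interpolated linearly and labelled IC/TO", {
  # ramp 0 -> 100 N over 1 s, then 100 -> 0 N over 1 s, sampled at 100 Hz:
  # 100 t = 20 at t = 0.2 s (IC); 100 (2 - t) = 20 at t = 1.8 s (TO)
  rate <- 100
  tt <- seq(0, 2, by = 1 / rate)
  v <- ifelse(tt <= 1, 100 * tt, 100 * (2 - tt))
  ev <- extract_force_events(list(values = v, rate = rate), 20)
  expect_equal(ev$event_type, c("IC", "TO"))
  expect_equal(ev$time_s, c(0.2, 1.8), tolerance = 1e-9)

  expect_equal(nrow(extract_force_events(list(values = rep(0, 50), rate = 100), 20)), 0)
  expect_equal(nrow(extract_force_events(list(values = rep(50, 50), rate = 100), 20)), 0)
  expect_error(extract_force_events(list(values = c(0, NA, 50), rate = 100), 20),
               "finite")
})

test_that("force events alternate IC/TO within each stance for arbitrary traces", {
  set.seed(31)
  for (rep in 1:25) {
    n <- 200
    v <- pmax(0, 60 * sin(seq(0, runif(1, 1, 6) * pi, length.out = n)) +
                rnorm(n, sd = 5))
    ev <- extract_force_events(list(values = v, rate = 100), 20)
    if (nrow(ev) == 0) next
    expect_equal(ev$event_type[1], "IC")
    runs <- rle(ev$event_type)$lengths
    expect_true(all(runs == 1))  # strict alternation after debouncing
    n_ic <- sum(ev$event_type == "IC"); n_to <- sum(ev$event_type == "TO")
    expect_true(n_ic >= n_to && n_to >= n_ic - 1)
  }
})

test_that("completeness check reports missing frame ranges inside the span", {
  tr <- fixture_trial("MF", n_strides = 2)
  expect_true(check_marker_completeness(tr)$pass)

  tr$markers$R_HEE$missing[10:12] <- TRUE
  res <- check_marker_completeness(tr)
  expect_false(res$pass)
  expect_equal(res$report$marker, "HEE")
  expect_equal(res$report$frames, "10-12")

  # missing frames outside the analysis span do not fail the trial
  res2 <- check_marker_completeness(tr, span = c(20, tr$n_frames))
  expect_true(res2$pass)
})

test_that("event tables round-trip through CSV and JSON", {
  ev <- gait_events(event_type = c("IC", "TO", "IC"),
                    time_s = c(1.25, 1.8, 2.3125),
                    side = "L", source = c("force", "manual", "predicted"),
                    trial_id = "T1")
  for (ext in c("csv", "json")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_events(ev, path)
    back <- read_events(path)
    expect_equal(back, ev, ignore_attr = TRUE)
  }
  # empty list -> header-only CSV, readable back as zero events
  path <- tempfile(fileext = ".csv")
  write_events(gait_events(), path)
  expect_equal(nrow(read_events(path)), 0)
  expect_match(readLines(path, n = 1), "trial_id")
})

test_that("marker tables round-trip and flag blank cells as missing", {
  tr <- fixture_trial("HS", n_strides = 2, noise_sd = 1)
  path <- tempfile(fileext = ".csv")
  write_trial_table(tr, path)
  back <- read_trial_table(path, side = "R", subject_id = tr$subject_id)
  expect_equal(back$n_frames, tr$n_frames)
  expect_equal(get_marker(back, "TOE")$positions,
               get_marker(tr, "TOE")$positions, tolerance = 1e-8)

  # one blank z-cell masks that frame for that marker only
  df <- utils::read.csv(path, check.names = FALSE)
  df$R_HEE_z[3] <- NA
  path2 <- tempfile(fileext = ".csv")
  utils::write.csv(df, path2, row.names = FALSE, na = "")
  back2 <- read_trial_table(path2, side = "R")
  expect_true(get_marker(back2, "HEE")$missing[3])
  expect_false(any(get_marker(back2, "TOE")$missing))

  # non-monotone time column is rejected
  df2 <- utils::read.csv(path, check.names = FALSE)
  df2$time[5] <- df2$time[3]
  path3 <- tempfile(fileext = ".csv")
  utils::write.csv(df2, path3, row.names = FALSE)
  expect_error(read_trial_table(path3), "increasing")
})

test_that("alias table accepts lab-specific labels including both TOE designations", {
  al <- marker_aliases()
  lk <- gaitevents:::alias_lookup_table(al)
  expect_equal(lk[["HEEL"]], "HEE")
  expect_equal(lk[["MT1"]], "TOE")
  expect_equal(lk[["MT2"]], "TOE")
  expect_equal(lk[["MT5"]], "PMT5")
  df <- data.frame(time = c(0, 1/150, 2/150),
                   `R_HEEL_x` = 1, `R_HEEL_y` = 2, `R_HEEL_z` = 3,
                   check.names = FALSE)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  tr <- read_trial_table(path, side = "both")
  expect_named(tr$markers, "R_HEE")
  expect_equal(tr$n_frames, 3)
  expect_false(any(tr$markers$R_HEE$missing))
})
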