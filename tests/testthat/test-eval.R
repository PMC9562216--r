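test_that("peak detection applies the threshold, plateau and separation rules", {
  ft <- (0:99) / 100
  expect_equal(nrow(detect_events(rep(0, 100), ft)), 0)

  tri <- c(rep(0, 40), seq(0, 0.6, length.out = 11),
           seq(0.6, 0, length.out = 11)[-1], rep(0, 39))
  ev <- detect_events(tri, ft)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$time_s, ft[51])

  # sub-threshold local maxima are ignored
  s <- rep(0, 100)
  s[20 + -2:2] <- c(0.2, 0.4, 0.45, 0.4, 0.2)
  s[70 + -2:2] <- c(0.3, 0.6, 0.8, 0.6, 0.3)
  ev <- detect_events(s, ft)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$time_s, ft[70])  # apex of the supra-threshold peak

  # plateaus resolve to their midpoint frame
  sp <- rep(0, 100); sp[40:44] <- 0.9
  expect_equal(detect_events(sp, ft)$time_s, ft[42])

  # peaks closer than the separation: the higher one wins
  s2 <- rep(0, 100)
  s2[30 + -1:1] <- c(0.5, 0.7, 0.5)
  s2[40 + -1:1] <- c(0.6, 0.9, 0.6)
  ev2 <- detect_events(s2, ft, detection_config(min_peak_separation_s = 0.25))
  expect_equal(ev2$time_s, ft[40])

  # threshold sweep: near-zero keeps every local maximum, near-one none
  s3 <- abs(sin(seq(0, 8 * pi, length.out = 400))) * 0.8
  ft3 <- (0:399) / 400
  lo <- detect_events(s3, ft3, detection_config(peak_threshold = 1e-6,
                                                min_peak_separation_s = 1e-3))
  expect_equal(nrow(lo), 8)
  hi <- detect_events(s3, ft3, detection_config(peak_threshold = 1 - 1e-9,
                                                min_peak_separation_s = 1e-3))
  expect_equal(nrow(hi), 0)
})

test_that("tolerance matching follows inclusive +/-16 ms coverage semantics", {
  m <- match_events(1.010, 1.000)
  expect_true(m$detected)
  expect_true(m$true_positive)
  expect_equal(m$errors_ms, 10)

  m2 <- match_events(1.020, 1.000)
  expect_false(m2$detected)     # truth missed (20 > 16)
  expect_false(m2$true_positive) # and the prediction is a false alarm
  expect_length(m2$errors_ms, 0)

  # exactly at the boundary counts as a success
  m3 <- match_events(1.016, 1.000)
  expect_true(m3$detected)

  m4 <- match_events(numeric(0), c(1, 2))
  expect_equal(sum(m4$detected), 0)
  expect_equal(m4$n_pred, 0)

  expect_error(match_events(gait_events("IC", 1, "R", "predicted"),
                            gait_events("TO", 1, "R", "force")),
               "differ")
})

test_that("matching agrees with a brute-force all-pairs oracle", {
  brute <- function(pred, truth, tol_s) {
    det <- vapply(truth, function(t) any(abs(pred - t) <= tol_s), logical(1))
    tp <- vapply(pred, function(p) any(abs(truth - p) <= tol_s), logical(1))
    list(detected = det, true_positive = tp)
  }
  set.seed(202)
  for (i in 1:300) {
    nt <- sample(0:20, 1); np <- sample(0:20, 1)
    truth <- sort(runif(nt, 0, 10))
    pred <- sort(runif(np, 0, 10))
    if (nt == 0) next
    m <- match_events(pred, truth, tolerance_ms = 16)
    o <- brute(pred, truth, 0.016)
    expect_identical(m$detected, o$detected)
    expect_identical(m$true_positive, o$true_positive)
  }
})

test_that("evaluation pools counts per group with exact rate complements", {
  # truth {1, 2}, predicted {1.005}: recall 50%, precision 100%
  m <- match_events(1.005, c(1, 2))
  r <- evaluate_detection(list(m))
  expect_equal(r$overall$recall, 50)
  expect_equal(r$overall$precision, 100)
  expect_equal(r$overall$false_alarm, 0)
  expect_equal(r$overall$missed, 50)

  # perfect predictions
  mp <- match_events(c(1, 2), c(1, 2))
  rp <- evaluate_detection(list(mp))
  expect_equal(rp$overall$recall, 100)
  expect_equal(rp$overall$precision, 100)

  # all predictions far away
  mf <- match_events(c(5, 6), c(1, 2))
  rf <- evaluate_detection(list(mf))
  expect_equal(rf$overall$recall, 0)
  expect_equal(rf$overall$false_alarm, 100)

  # zero predictions: precision undefined, flagged
  m0 <- match_events(numeric(0), c(1, 2))
  r0 <- evaluate_detection(list(m0))
  expect_true(is.na(r0$overall$precision))
  expect_false(r0$precision_defined)

  # per-group stratification and the exact complement identity
  g <- evaluate_detection(list(match_events(1.005, c(1, 2)),
                               match_events(c(3, 4.1), c(3, 4))),
                          groups = c("HS", "FF"))
  expect_setequal(g$by_group$group, c("HS", "FF"))
  expect_equal(g$by_group$precision + g$by_group$false_alarm, c(100, 100))
  expect_equal(g$overall$n_truth, 4)
})

test_that("rates never decrease as the tolerance widens", {
  set.seed(404)
  for (i in 1:50) {
    truth <- sort(runif(sample(1:15, 1), 0, 10))
    pred <- sort(runif(sample(1:15, 1), 0, 10))
    tols <- c(4, 8, 16, 32, 64)
    rec <- prec <- numeric(length(tols))
    for (j in seq_along(tols)) {
      r <- evaluate_detection(list(match_events(pred, truth, tols[j])))
      rec[j] <- r$overall$recall
      prec[j] <- r$overall$precision
    }
    expect_sorted(rec)
    expect_sorted(prec)
  }
})

test_that("error percentiles and trimmed means summarise the error pool", {
  expect_equal(unique(error_percentile_curve(rep(5, 10))$error_ms), 5)
  pc <- error_percentile_curve(0:100)
  expect_equal(pc$error_ms[pc$percentile == 50], 50)
  set.seed(5)
  pc2 <- error_percentile_curve(rexp(100, 1 / 8))
  expect_sorted(pc2$error_ms)
  expect_error(error_percentile_curve(numeric(0)))

  expect_equal(trimmed_mean_error(c(1, 2, 3, 100), 0.75), 2)
  x <- c(4, 8, 15, 16, 23)
  expect_equal(trimmed_mean_error(x, 1), mean(x))
  expect_equal(trimmed_mean_error(rep(7, 9), 0.5), 7)
  expect_error(trimmed_mean_error(numeric(0)))
})

test_that("reports serialise to JSON and CSV with per-group rows", {
  r <- evaluate_detection(list(match_events(c(1, 2.005), c(1, 2)),
                               match_events(2.9, c(3))),
                          groups = c("HS", "FF"))
  jp <- tempfile(fileext = ".json"); cp <- tempfile(fileext = ".csv")
  write_report(r, json_path = jp, csv_path = cp)
  tab <- utils::read.csv(cp)
  expect_setequal(tab$group, c("HS", "FF", "overall"))
  j <- jsonlite::fromJSON(jp)
  expect_equal(nrow(j$table), 3)
  expect_true(all(c("95", "99") %in% names(j$trimmed_ms)))
})
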