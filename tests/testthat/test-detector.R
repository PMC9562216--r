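test_that("hyper-parameter presets reproduce all tuned rows", {
  expected <- list(
    "IC:HLX|HEE"      = c(12, 2, 512), "IC:TOE|HEE"      = c(12, 5, 256),
    "IC:HLX|PMT5|HEE" = c(18, 2, 256), "IC:TOE|PMT5|HEE" = c(18, 5, 256),
    "IC:HLX|TOE|HEE"  = c(18, 2, 512),
    "TO:HLX|HEE"      = c(12, 5, 256), "TO:TOE|HEE"      = c(12, 2, 512),
    "TO:HLX|PMT5|HEE" = c(18, 2, 256), "TO:TOE|PMT5|HEE" = c(18, 5, 256),
    "TO:HLX|TOE|HEE"  = c(18, 2, 256))
  for (nm in names(expected)) {
    h <- hyperparam_preset(nm)
    expect_equal(c(h$n_input_features, h$n_recurrent_layers, h$hidden_size),
                 expected[[nm]], label = nm, ignore_attr = TRUE)
    expect_equal(h$dropout, 0.3)
    expect_equal(h$learning_rate, 0.001)
    # feature count is consistent with the combo: 6 channels per marker
    combo <- sub("^(IC|TO):", "", nm)
    expect_equal(h$n_input_features, 6 * length(marker_combo(combo)))
  }
  expect_error(hyperparam_preset("IC:HEE"), "unknown preset")
})

test_that("subject-level splits are disjoint, exhaustive and deterministic", {
  ids <- sprintf("S%02d", 1:10)
  sp <- split_by_subject(ids, c(0.8, 0.1, 0.1), seed = 4)
  expect_equal(lengths(sp), c(train = 8L, val = 1L, test = 1L))
  expect_setequal(unlist(sp), ids)
  expect_equal(length(intersect(sp$train, sp$val)), 0)
  expect_equal(length(intersect(sp$train, sp$test)), 0)
  expect_identical(sp, split_by_subject(ids, c(0.8, 0.1, 0.1), seed = 4))
  expect_error(split_by_subject(character()), "empty|3 subjects")
})

test_that("no subject crosses splits over many random seeds", {
  ids <- sprintf("S%03d", 1:37)
  for (seed in 1:100) {
    sp <- split_by_subject(ids, c(0.8, 0.1, 0.1), seed = seed)
    expect_equal(length(intersect(sp$train, sp$val)), 0)
    expect_equal(length(intersect(sp$train, sp$test)), 0)
    expect_equal(length(intersect(sp$val, sp$test)), 0)
    expect_setequal(unlist(sp), ids)
  }
})

test_that("balanced sampling hits the 4:2:1 ratio within binomial noise", {
  groups <- rep(c("HS", "MF", "FF"), times = c(50, 30, 10))
  set.seed(8)
  n <- 7000
  idx <- balanced_group_sampler(groups, n)
  counts <- table(groups[idx])
  for (case in list(c("HS", 4 / 7), c("MF", 2 / 7), c("FF", 1 / 7))) {
    p <- as.numeric(case[2])
    expect_lt(abs(counts[[case[1]]] - n * p), 3 * sqrt(n * p * (1 - p)))
  }
  # degenerate ratio draws only from the named group
  idx1 <- balanced_group_sampler(groups, 100, ratio = c(HS = 1))
  expect_true(all(groups[idx1] == "HS"))
  expect_error(balanced_group_sampler(rep("HS", 5), 10,
                                      ratio = c(HS = 4, MF = 2, FF = 1)),
               "MF")
})

test_that("weighted cross-entropy matches hand arithmetic and its limits", {
  # y = [1, 0], p = [0.5, 0.5], w = 2: -(2 log 0.5 + log 0.5) / 2
  expect_equal(weighted_bce_loss(c(0.5, 0.5), c(1, 0), 2), 1.5 * log(2))
  # w = 1 reduces to plain binary cross-entropy
  p <- c(0.2, 0.7); y <- c(0, 1)
  expect_equal(weighted_bce_loss(p, y, 1),
               -mean(y * log(p) + (1 - y) * log(1 - p)))
  # near-perfect predictions give near-zero loss
  eps <- 1e-9
  expect_lt(weighted_bce_loss(c(eps, 1 - eps), c(0, 1), 2), 1e-6)
  expect_error(weighted_bce_loss(c(0.5), c(1, 0), 1), "mismatch")
  # default weight: negative to positive mass
  y <- c(rep(0, 90), rep(1, 10))
  expect_equal(compute_pos_weight(y), 9)
})

test_that("training edge cases behave: zero epochs, degenerate targets", {
  w <- fixture_tiny_windows()
  hyper <- detector_hyperparams(12, 1, 8, dropout = 0, learning_rate = 0.005)
  m0 <- train_detector(w, list(), "IC", hyper,
                       train_config(max_epochs = 0, seed = 1),
                       combo = "TOE|HEE")
  expect_s3_class(m0, "trained_detector")
  expect_equal(nrow(m0$history), 0)

  # all-zero targets drive scores towards zero
  wz <- lapply(w, function(x) {
    x$targets$IC <- x$targets$IC * 0
    x$targets$IC[1] <- 1e-9  # keep the weight finite
    x
  })
  hyper_fast <- detector_hyperparams(12, 1, 8, dropout = 0,
                                     learning_rate = 0.02)
  mz <- train_detector(wz, list(), "IC", hyper_fast,
                       train_config(max_epochs = 15, pos_weight = 1, seed = 2),
                       combo = "TOE|HEE")
  f <- prepare_features(simulate_trial(sim_config("HS", n_strides = 3, seed = 77)),
                        "TOE|HEE")
  expect_lt(mean(predict_scores(mz, f)), 0.1)

  expect_error(train_detector(list(), list(), "IC", hyper, train_config()),
               "empty")
  expect_error(train_detector(w, list(), "IC",
                              detector_hyperparams(18, 1, 8),
                              train_config()),
               "channels")
})

test_that("training is reproducible and prediction deterministic", {
  w <- fixture_tiny_windows()
  hyper <- detector_hyperparams(12, 1, 8, dropout = 0.2, learning_rate = 0.005)
  cfg <- train_config(batch_size = 16, max_epochs = 2, seed = 31)
  n <- length(w)
  tr_idx <- seq_len(n - 6)
  va_idx <- (n - 5):n
  m1 <- train_detector(w[tr_idx], w[va_idx], "IC", hyper, cfg, combo = "TOE|HEE")
  m2 <- train_detector(w[tr_idx], w[va_idx], "IC", hyper, cfg, combo = "TOE|HEE")
  expect_equal(m1$history, m2$history)
  expect_identical(m1$params$head$Wy, m2$params$head$Wy)

  f <- prepare_features(simulate_trial(sim_config("MF", n_strides = 3, seed = 5)),
                        "TOE|HEE")
  s1 <- predict_scores(m1, f)
  s2 <- predict_scores(m1, f)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 <= 1))
  # sliding-window inference stays in range and close to full-sequence
  s3 <- predict_scores(m1, f, mode = "sliding")
  expect_true(all(s3 >= 0 & s3 <= 1))
  expect_equal(length(s3), length(s1))
})

test_that("checkpoints round-trip through save/load", {
  m <- fixture_mini_model()
  path <- tempfile(fileext = ".rds")
  save_detector(m, path)
  back <- load_detector(path)
  expect_identical(back$params, m$params)
  expect_identical(back$combo, m$combo)
  expect_error(load_detector({p <- tempfile(); saveRDS(list(), p); p}),
               "checkpoint")
})

test_that("repeated runs keep the test set fixed and aggregate as mean +/- SEM", {
  # SEM arithmetic on synthetic per-run reports
  fake_report <- function(recall, precision) {
    structure(list(
      by_group = data.frame(group = "HS", n_truth = 10, n_pred = 10,
                            n_detected = 9, n_true_positive = 9,
                            recall = recall, precision = precision,
                            false_alarm = 100 - precision,
                            missed = 100 - recall),
      overall = list(n_truth = 10, n_pred = 10, n_detected = 9,
                     n_true_positive = 9, recall = recall,
                     precision = precision, false_alarm = 100 - precision,
                     missed = 100 - recall)),
      class = "evaluation_report")
  }
  vals <- c(80, 90, 85)
  agg <- aggregate_runs(lapply(vals, fake_report, precision = 75))
  row <- agg[agg$group == "overall" & agg$metric == "recall", ]
  expect_equal(row$mean, mean(vals))
  expect_equal(row$sem, sd(vals) / sqrt(3))
  # a single run has no defined SEM
  agg1 <- aggregate_runs(list(fake_report(80, 75)))
  expect_true(is.na(agg1$sem[agg1$metric == "recall" &
                               agg1$group == "overall"]))
  # identical metrics across runs give SEM 0
  agg0 <- aggregate_runs(lapply(c(80, 80), fake_report, precision = 75))
  expect_equal(agg0$sem[agg0$metric == "recall" & agg0$group == "overall"], 0)

  # a miniature two-run protocol end to end
  trials <- cached("proto_trials",
                   simulate_cohort(8, mix = c(HS = 1, MF = 1),
                                   seed = 13, n_strides = 3))
  subj <- vapply(trials, `[[`, character(1), "subject_id")
  test_trials <- trials[subj %in% c("S001", "S005")]
  pool <- trials[!(subj %in% c("S001", "S005"))]
  set.seed(13)
  w <- build_training_windows(pool, "IC", "TOE|HEE")
  hyper <- detector_hyperparams(12, 1, 8, dropout = 0, learning_rate = 0.005)
  cfg <- train_config(batch_size = 16, max_epochs = 2,
                      group_ratio = c(HS = 1, MF = 1), seed = 17)
  res <- repeated_training_protocol(w, test_trials, "IC", "TOE|HEE", hyper,
                                    cfg, n_runs = 2, val_fraction = 0.2)
  expect_length(res$runs, 2)
  expect_true(all(c("mean", "sem") %in% names(res$summary)))
  # leakage guard: windows containing test subjects abort
  expect_error(
    repeated_training_protocol(
      build_training_windows(trials[subj == "S001"], "IC", "TOE|HEE"),
      test_trials, "IC", "TOE|HEE", hyper, cfg, n_runs = 1),
    "leak")
})
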