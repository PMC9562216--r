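# Shared fixture builders. Everything is generated in code; heavier objects
# are cached per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A short clean trial per pattern, reused across files.
fixture_trial <- function(pattern = "HS", noise_sd = 0, n_strides = 4,
                          seed = 7, ...) {
  simulate_trial(sim_config(pattern, n_strides = n_strides,
                            noise_sd = noise_sd, seed = seed, ...))
}

# Small three-pattern cohort with windows, for training-path tests.
fixture_tiny_windows <- function() {
  cached("tiny_windows", {
    trials <- simulate_cohort(6, mix = c(HS = 1, MF = 1, FF = 1),
                              seed = 21, n_strides = 4, noise_sd = 1)
    set.seed(21)
    build_training_windows(trials, "IC", "TOE|HEE")
  })
}

# A quickly trained miniature detector for prediction/evaluation tests.
fixture_mini_model <- function() {
  cached("mini_model", {
    w <- fixture_tiny_windows()
    hyper <- detector_hyperparams(12, 1, 16, dropout = 0,
                                  learning_rate = 0.005)
    cfg <- train_config(batch_size = 16, max_epochs = 4, patience = 4,
                        seed = 5)
    train_detector(w, list(), "IC", hyper, cfg, combo = "TOE|HEE")
  })
}

expect_sorted <- function(x) expect_true(all(diff(x) >= 0))
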