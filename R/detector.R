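#' Detector hyper-parameters
#'
#' @param n_input_features Feature channels (6 per marker in the
#'   combination).
#' @param n_recurrent_layers Number of stacked bidirectional LSTM layers.
#' @param hidden_size Hidden units per direction.
#' @param dropout Dropout rate between recurrent layers, in \[0, 1).
#' @param learning_rate Adam learning rate.
#' @return List of class `detector_hyperparams`.
#' @export
detector_hyperparams <- function(n_input_features, n_recurrent_layers,
                                 hidden_size, dropout = 0.3,
                                 learning_rate = 0.001) {
  stopifnot(n_input_features > 0, n_recurrent_layers > 0, hidden_size > 0,
            dropout >= 0, dropout < 1, learning_rate > 0)
  structure(list(n_input_features = as.integer(n_input_features),
                 n_recurrent_layers = as.integer(n_recurrent_layers),
                 hidden_size = as.integer(hidden_size),
                 dropout = dropout, learning_rate = learning_rate),
            class = "detector_hyperparams")
}

# The tuned hyper-parameter rows per event type and marker combination:
# columns features / LSTM layers / hidden size / dropout / learning rate.
HYPERPARAM_PRESETS <- list(
  "IC:HLX|HEE"       = c(12, 2, 512, 0.3, 0.001),
  "IC:TOE|HEE"       = c(12, 5, 256, 0.3, 0.001),
  "IC:HLX|PMT5|HEE"  = c(18, 2, 256, 0.3, 0.001),
  "IC:TOE|PMT5|HEE"  = c(18, 5, 256, 0.3, 0.001),
  "IC:HLX|TOE|HEE"   = c(18, 2, 512, 0.3, 0.001),
  "TO:HLX|HEE"       = c(12, 5, 256, 0.3, 0.001),
  "TO:TOE|HEE"       = c(12, 2, 512, 0.3, 0.001),
  "TO:HLX|PMT5|HEE"  = c(18, 2, 256, 0.3, 0.001),
  "TO:TOE|PMT5|HEE"  = c(18, 5, 256, 0.3, 0.001),
  "TO:HLX|TOE|HEE"   = c(18, 2, 256, 0.3, 0.001)
)

#' Named hyper-parameter presets
#'
#' `"<event>:<combo>"` presets (e.g. `"IC:TOE|HEE"`) reproduce the tuned
#' settings for each event type and marker combination; `"test"` is a small
#' profile (1 layer, 64 hidden units, no dropout) for fast desk-scale
#' experiments and continuous integration.
#'
#' @param name Preset name.
#' @return A [detector_hyperparams()].
#' @export
hyperparam_preset <- function(name) {
  if (identical(name, "test"))
    return(detector_hyperparams(12, 1, 64, dropout = 0, learning_rate = 0.003))
  row <- HYPERPARAM_PRESETS[[name]]
  if (is.null(row))
    stop(sprintf("unknown preset '%s'; available: %s, test", name,
                 paste(names(HYPERPARAM_PRESETS), collapse = ", ")))
  detector_hyperparams(row[1], row[2], row[3], row[4], row[5])
}

#' Training configuration
#'
#' @param split_fractions Train/validation/test fractions over subjects
#'   (must sum to 1).
#' @param group_ratio Sampling ratio of the HS/MF/FF gait groups during
#'   training, default `c(HS = 4, MF = 2, FF = 1)`.
#' @param window_length Training window length, frames.
#' @param max_offset Maximum random window offset, frames.
#' @param batch_size Windows per gradient step.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param pos_weight Positive-class weight for the cross-entropy loss;
#'   `NULL` computes `sum(1 - y) / sum(y)` over the training targets once.
#' @param seed Seed for all training randomness.
#' @return List of class `train_config`.
#' @export
train_config <- function(split_fractions = c(0.8, 0.1, 0.1),
                         group_ratio = c(HS = 4, MF = 2, FF = 1),
                         window_length = 150, max_offset = 30,
                         batch_size = 64, max_epochs = 100, patience = 10,
                         pos_weight = NULL, seed = 1L) {
  stopifnot(abs(sum(split_fractions) - 1) < 1e-9, all(split_fractions >= 0),
            all(group_ratio >= 0), window_length > 0, max_offset >= 0,
            batch_size > 0, max_epochs >= 0, patience >= 1)
  structure(list(split_fractions = split_fractions, group_ratio = group_ratio,
                 window_length = as.integer(window_length),
                 max_offset = as.integer(max_offset),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 pos_weight = pos_weight, seed = as.integer(seed)),
            class = "train_config")
}

#' Subject-level dataset split
#'
#' Subjects (never individual trials or windows) are partitioned into
#' train/validation/test so no subject contributes to more than one subset.
#' Sizes follow the fractions with largest-remainder rounding; the
#' partition is deterministic given the seed.
#'
#' @param subject_ids Character vector (duplicates allowed; the unique set
#'   is split).
#' @param fractions Length-3 fractions summing to 1.
#' @param seed Integer seed.
#' @return List with `train`, `val`, `test` character vectors.
#' @export
split_by_subject <- function(subject_ids, fractions = c(0.8, 0.1, 0.1),
                             seed = 1L) {
  ids <- unique(as.character(subject_ids))
  if (length(ids) == 0) stop("empty subject list")
  if (length(ids) < 3) stop("need at least 3 subjects to split")
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-9)
  sizes <- largest_remainder(length(ids) * fractions)
  ids <- with_seed(seed, sample(ids))
  list(train = ids[seq_len(sizes[1])],
       val = ids[sizes[1] + seq_len(sizes[2])],
       test = ids[sizes[1] + sizes[2] + seq_len(sizes[3])])
}

#' Balanced gait-group sampling
#'
#' Draws sample indices with replacement: each draw first picks a gait
#' group with probability proportional to its ratio entry, then picks
#' uniformly within that group. Counteracts the class imbalance between
#' heel-strike, midfoot and forefoot walkers.
#'
#' @param groups Character/factor vector of group labels, one per sample.
#' @param n Number of draws.
#' @param ratio Named sampling ratio, default `c(HS = 4, MF = 2, FF = 1)`.
#' @return Integer vector of `n` sample indices. Uses the session RNG.
#' @export
balanced_group_sampler <- function(groups, n, ratio = c(HS = 4, MF = 2, FF = 1)) {
  ratio <- ratio[ratio > 0]
  if (length(ratio) == 0) stop("all ratio entries are zero")
  idx_by_group <- split(seq_along(groups), as.character(groups))
  for (g in names(ratio)) {
    if (is.null(idx_by_group[[g]]) || length(idx_by_group[[g]]) == 0)
      stop(sprintf("group '%s' has positive ratio but no samples", g))
  }
  gdraw <- sample(names(ratio), n, replace = TRUE, prob = ratio / sum(ratio))
  vapply(gdraw, function(g) {
    pool <- idx_by_group[[g]]
    pool[sample.int(length(pool), 1L)]
  }, integer(1), USE.NAMES = FALSE)
}

#' Binary-weighted cross-entropy loss
#'
#' `mean(-(w * y * log(p) + (1 - y) * log(1 - p)))` over all frames, where
#' `w` up-weights the (rare) event frames. With `w = 1` this is plain
#' binary cross-entropy.
#'
#' @param scores Predicted probabilities in (0, 1).
#' @param targets Targets in \[0, 1\], same shape.
#' @param pos_weight Positive-class weight `w`.
#' @return Non-negative scalar.
#' @export
weighted_bce_loss <- function(scores, targets, pos_weight = 1) {
  if (length(scores) != length(targets)) stop("shape mismatch")
  p <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
  y <- targets
  -mean(pos_weight * y * log(p) + (1 - y) * log(1 - p))
}

#' Default positive-class weight from training targets
#' @param targets Numeric vector/matrix of training targets in \[0, 1\].
#' @return `sum(1 - y) / sum(y)`.
#' @export
compute_pos_weight <- function(targets) {
  s <- sum(targets)
  if (s <= 0) stop("targets contain no positive mass")
  sum(1 - targets) / s
}

# Stack a list of window_samples into X (B x T x C) and Y (B x T) arrays.
stack_windows <- function(windows, event_type) {
  B <- length(windows)
  T_ <- nrow(windows[[1]]$values)
  C <- ncol(windows[[1]]$values)
  X <- array(0, dim = c(B, T_, C))
  Y <- matrix(0, B, T_)
  for (b in seq_len(B)) {
    X[b, , ] <- windows[[b]]$values
    Y[b, ] <- windows[[b]]$targets[[event_type]]
  }
  list(X = X, Y = Y)
}

#' Train an event detector
#'
#' Trains the bidirectional LSTM labeller with Adam and the weighted
#' cross-entropy loss. Feature channels are z-scored with statistics fitted
#' on the training windows; batches are drawn by [balanced_group_sampler()]
#' when group labels are present. Training stops early when the validation
#' loss has not improved for `config$patience` epochs and the
#' best-validation parameters are returned. Fully deterministic given
#' `config$seed`.
#'
#' @param train_windows,val_windows Lists of `window_sample`s (raw,
#'   unstandardized features, targets attached) with `$group` and
#'   `$subject_id` set.
#' @param event_type `"IC"` or `"TO"`.
#' @param hyper A [detector_hyperparams()].
#' @param config A [train_config()].
#' @param combo Marker combination the windows were built from (stored for
#'   provenance and input checking).
#' @param verbose Print per-epoch losses.
#' @return Object of class `trained_detector`: parameters, scaler, history,
#'   hyper-parameters, configuration.
#' @export
train_detector <- function(train_windows, val_windows, event_type, hyper,
                           config = train_config(), combo = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(hyper, "detector_hyperparams"),
            inherits(config, "train_config"))
  if (length(train_windows) == 0) stop("empty training set")
  C <- ncol(train_windows[[1]]$values)
  if (C != hyper$n_input_features)
    stop(sprintf("window has %d channels but hyper-params expect %d",
                 C, hyper$n_input_features))

  scaler <- fit_feature_scaler(lapply(train_windows, `[[`, "values"))
  tr <- stack_windows(train_windows, event_type)
  for (b in seq_len(dim(tr$X)[1]))
    tr$X[b, , ] <- apply_feature_scaler(tr$X[b, , ], scaler)
  has_val <- length(val_windows) > 0
  if (has_val) {
    va <- stack_windows(val_windows, event_type)
    for (b in seq_len(dim(va$X)[1]))
      va$X[b, , ] <- apply_feature_scaler(va$X[b, , ], scaler)
  }
  pos_w <- if (is.null(config$pos_weight)) compute_pos_weight(tr$Y)
           else config$pos_weight
  groups <- vapply(train_windows, function(w)
    if (is.null(w$group)) NA_character_ else w$group, character(1))
  use_balanced <- !anyNA(groups) &&
    all(names(config$group_ratio)[config$group_ratio > 0] %in% groups)

  n_train <- length(train_windows)
  steps <- max(1L, ceiling(n_train / config$batch_size))

  with_seed(config$seed, {
    params <- init_bilstm_params(C, hyper$n_recurrent_layers, hyper$hidden_size)
    flat <- flatten_params(params)
    opt <- adam_init(flat)
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric())
    best_val <- Inf; best_flat <- flat; wait <- 0L
    epoch <- 0L
    while (epoch < config$max_epochs) {
      epoch <- epoch + 1L
      ep_loss <- 0
      for (s in seq_len(steps)) {
        idx <- if (use_balanced)
          balanced_group_sampler(groups, config$batch_size, config$group_ratio)
        else sample.int(n_train, config$batch_size, replace = TRUE)
        Xb <- tr$X[idx, , , drop = FALSE]
        Yb <- tr$Y[idx, , drop = FALSE]
        fwd <- bilstm_forward(params, Xb, dropout = hyper$dropout,
                              training = TRUE)
        ep_loss <- ep_loss + weighted_bce_loss(fwd$P, Yb, pos_w)
        dS <- ((1 - Yb) * fwd$P - pos_w * Yb * (1 - fwd$P)) / length(Yb)
        grads <- bilstm_backward(params, fwd, dS)
        gflat <- flatten_params(grads)
        upd <- adam_step(flat, gflat, opt, hyper$learning_rate)
        flat <- upd$flat; opt <- upd$state
        params <- unflatten_into(params, flat)
      }
      ep_loss <- ep_loss / steps
      val_loss <- if (has_val) {
        fv <- bilstm_forward(params, va$X, training = FALSE)
        weighted_bce_loss(fv$P, va$Y, pos_w)
      } else ep_loss
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = ep_loss,
                                           val_loss = val_loss))
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch, ep_loss,
                        val_loss))
      if (val_loss < best_val - 1e-6) {
        best_val <- val_loss; best_flat <- flat; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    params <- unflatten_into(params, best_flat)
    structure(
      list(version = 1L, event_type = match.arg(event_type, EVENT_TYPES),
           combo = combo, params = params, scaler = scaler, hyper = hyper,
           config = config, pos_weight = pos_w, history = history,
           best_val_loss = if (nrow(history)) best_val else NA_real_,
           seed = config$seed),
      class = "trained_detector")
  })
}

#' Per-frame event scores for a trial
#'
#' Runs the trained network over the whole sequence in evaluation mode
#' (default) — the bidirectional network accepts any length, avoiding
#' window-stitching artifacts — or in a sliding-window mode (fixed-length
#' windows, stride half a window, overlaps averaged).
#'
#' @param model A `trained_detector`.
#' @param features A `feature_matrix` from [assemble_features()]
#'   (unstandardized; the model's own scaler is applied).
#' @param mode `"full"` or `"sliding"`.
#' @param window,stride Sliding-mode window length and stride, frames.
#' @return Numeric vector of per-frame scores in \[0, 1\], with attribute
#'   `frame_times`. Deterministic: identical input gives identical output.
#' @export
predict_scores <- function(model, features, mode = c("full", "sliding"),
                           window = 150, stride = 75) {
  mode <- match.arg(mode)
  vals <- if (inherits(features, "feature_matrix")) features$values
          else as.matrix(features)
  if (ncol(vals) != model$hyper$n_input_features)
    stop(sprintf("feature matrix has %d channels but model expects %d",
                 ncol(vals), model$hyper$n_input_features))
  vals <- apply_feature_scaler(vals, model$scaler)
  run <- function(m) {
    X <- array(m, dim = c(1, nrow(m), ncol(m)))
    as.numeric(bilstm_forward(model$params, X, training = FALSE)$P)
  }
  n <- nrow(vals)
  if (mode == "full" || n <= window) {
    scores <- run(vals)
  } else {
    acc <- numeric(n); cnt <- numeric(n)
    starts <- unique(c(seq(1L, n - window + 1L, by = stride), n - window + 1L))
    for (s in starts) {
      idx <- s:(s + window - 1L)
      acc[idx] <- acc[idx] + run(vals[idx, , drop = FALSE])
      cnt[idx] <- cnt[idx] + 1
    }
    scores <- acc / cnt
  }
  if (inherits(features, "feature_matrix"))
    attr(scores, "frame_times") <- features$frame_times
  scores
}

#' Save / load a trained detector
#'
#' A trained detector is a self-contained, versioned single-file bundle of
#' parameters, hyper-parameters, marker combination, scaler statistics and
#' training provenance (seed, history).
#'
#' @param model A `trained_detector`.
#' @param path File path.
#' @return `save_detector`: the path, invisibly; `load_detector`: the model.
#' @export
save_detector <- function(model, path) {
  stopifnot(inherits(model, "trained_detector"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_detector
#' @export
load_detector <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "trained_detector") || is.null(model$version))
    stop("not a trained_detector checkpoint")
  model
}

#' Repeated-training protocol with a fixed test set
#'
#' Runs `n_runs` trainings that differ only in the train/validation split
#' of the non-test subjects (run `r` uses split seed `seed + r`), evaluates
#' each on the same held-out test trials, and aggregates every metric as
#' mean and standard error of the mean across runs.
#'
#' @param windows List of `window_sample`s for the non-test subjects.
#' @param test_trials List of held-out [gait_trial()]s (fixed across runs).
#' @param event_type `"IC"` or `"TO"`.
#' @param combo Marker combination used to build windows/features.
#' @param hyper,config Model and training configuration.
#' @param detection A [detection_config()].
#' @param n_runs Number of training runs (default 10).
#' @param val_fraction Fraction of non-test subjects used for validation in
#'   each run.
#' @param verbose Print progress.
#' @return List with `runs` (per-run evaluation reports), `models`, and
#'   `summary` (metric, mean, sem, n_runs).
#' @export
repeated_training_protocol <- function(windows, test_trials, event_type,
                                       combo, hyper, config = train_config(),
                                       detection = detection_config(),
                                       n_runs = 10, val_fraction = 0.125,
                                       verbose = FALSE) {
  if (n_runs < 1) stop("n_runs must be >= 1")
  subjects <- unique(vapply(windows, `[[`, character(1), "subject_id"))
  test_ids <- unique(vapply(test_trials, `[[`, character(1), "subject_id"))
  if (length(intersect(subjects, test_ids)) > 0)
    stop("test subjects leak into the training windows")
  reports <- vector("list", n_runs)
  models <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    sp <- split_by_subject(subjects,
                           c(1 - val_fraction, val_fraction, 0),
                           seed = config$seed + r)
    wtrain <- windows[vapply(windows, function(w) w$subject_id %in% sp$train,
                             logical(1))]
    wval <- windows[vapply(windows, function(w) w$subject_id %in% sp$val,
                           logical(1))]
    cfg_r <- config
    cfg_r$seed <- config$seed + r
    model <- train_detector(wtrain, wval, event_type, hyper, cfg_r,
                            combo = combo, verbose = verbose)
    models[[r]] <- model
    reports[[r]] <- evaluate_model(model, test_trials, combo,
                                   detection = detection)
    if (verbose)
      message(sprintf("run %d/%d: recall %.1f%%, precision %.1f%%", r, n_runs,
                      reports[[r]]$overall$recall,
                      reports[[r]]$overall$precision))
  }
  list(runs = reports, models = models, summary = aggregate_runs(reports))
}

#' Aggregate repeated-run evaluation reports
#'
#' @param reports List of reports from [evaluate_model()] /
#'   [evaluate_detection()].
#' @return Data frame with one row per (group, metric): mean, sem (sample
#'   SD / sqrt(runs); `NA` for a single run) and n_runs.
#' @export
aggregate_runs <- function(reports) {
  metrics <- c("recall", "precision", "false_alarm", "missed")
  rows <- list()
  groups <- unique(unlist(lapply(reports, function(r) r$by_group$group)))
  groups <- c(groups, "overall")
  for (g in groups) {
    for (m in metrics) {
      vals <- vapply(reports, function(r) {
        if (g == "overall") r$overall[[m]]
        else {
          i <- match(g, r$by_group$group)
          if (is.na(i)) NA_real_ else r$by_group[[m]][i]
        }
      }, numeric(1))
      vals <- vals[!is.na(vals)]
      n <- length(vals)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, metric = m,
        mean = if (n) mean(vals) else NA_real_,
        sem = if (n >= 2) stats::sd(vals) / sqrt(n) else NA_real_,
        n_runs = n)
    }
  }
  do.call(rbind, rows)
}
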