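#' Build training windows from a set of trials
#'
#' The standard dataset-assembly path: each trial is canonicalized and
#' downsampled, features are assembled for the marker combination (raw —
#' standardization happens inside [train_detector()] with training-set
#' statistics), event times are encoded into Gaussian target series, and
#' one window is cut around every annotated event of the requested type,
#' with a random offset. Each window carries its subject id and gait-group
#' label for subject-level splitting and balanced sampling.
#'
#' @param trials List of [gait_trial()]s with ground-truth events and
#'   pattern labels.
#' @param event_type `"IC"` or `"TO"`.
#' @param combo Marker combination (see [marker_combo()]).
#' @param encoder An [encoder_config()].
#' @param length_frames,max_offset Window geometry (defaults 150 / 30).
#' @param target_rate Feature rate, Hz.
#' @param windows_per_event Windows cut per event (different random
#'   offsets).
#' @return List of `window_sample`s. Uses the session RNG for offsets;
#'   seed with `set.seed()` for reproducibility.
#' @export
build_training_windows <- function(trials, event_type, combo,
                                   encoder = encoder_config(),
                                   length_frames = 150, max_offset = 30,
                                   target_rate = 150,
                                   windows_per_event = 1) {
  event_type <- match.arg(event_type, EVENT_TYPES)
  combo <- marker_combo(combo)
  out <- list()
  for (trial in trials) {
    tr <- canonicalize_trial(downsample_trial(trial, target_rate))
    feats <- assemble_features(tr, combo)
    targets <- lapply(setNames(EVENT_TYPES, EVENT_TYPES), function(et) {
      ev <- tr$events[tr$events$event_type == et, , drop = FALSE]
      encode_gaussian_targets(ev$time_s, feats$frame_times, encoder)
    })
    evs <- tr$events[tr$events$event_type == event_type, , drop = FALSE]
    for (i in seq_len(nrow(evs))) {
      for (k in seq_len(windows_per_event)) {
        w <- extract_training_window(feats, evs[i, ], targets = targets,
                                     length_frames = length_frames,
                                     max_offset = max_offset)
        w$subject_id <- tr$subject_id
        w$trial_id <- tr$trial_id
        w$group <- tr$pattern
        out[[length(out) + 1L]] <- w
      }
    }
  }
  out
}

#' Assemble features for one trial the way the training pipeline does
#'
#' Convenience wrapper: canonicalize, downsample, assemble.
#'
#' @param trial A [gait_trial()].
#' @param combo Marker combination.
#' @param target_rate Feature rate, Hz.
#' @param scaler Optional `feature_scaler`.
#' @return A `feature_matrix`.
#' @export
prepare_features <- function(trial, combo, target_rate = 150, scaler = NULL) {
  tr <- canonicalize_trial(downsample_trial(trial, target_rate))
  assemble_features(tr, combo, scaler = scaler)
}
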