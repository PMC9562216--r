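#' Downsample a trial to a target rate
#'
#' When the source rate is an integer multiple of the target (the common
#' 300 Hz -> 150 Hz case) every k-th frame is kept; otherwise positions are
#' linearly interpolated onto the uniform target grid. Event times are in
#' seconds and unchanged. The force trace, if present, is resampled the same
#' way.
#'
#' @param trial A [gait_trial()].
#' @param target_rate Target rate in Hz (default 150).
#' @return A [gait_trial()] at `target_rate`.
#' @export
downsample_trial <- function(trial, target_rate = 150) {
  if (target_rate > trial$rate + 1e-9)
    stop("target_rate exceeds the trial's sampling rate")
  if (abs(trial$rate - target_rate) < 1e-9) return(trial)
  k <- trial$rate / target_rate
  if (abs(k - round(k)) < 1e-9) {
    k <- as.integer(round(k))
    idx <- seq(1L, trial$n_frames, by = k)
    markers <- lapply(trial$markers, function(m) {
      marker_trajectory(m$marker, m$side, m$positions[idx, , drop = FALSE],
                        target_rate, missing = m$missing[idx])
    })
  } else {
    old_t <- trial_frame_times(trial)
    new_t <- seq(0, old_t[length(old_t)], by = 1 / target_rate)
    markers <- lapply(trial$markers, function(m) {
      pos <- apply(m$positions, 2, function(col)
        stats::approx(old_t, col, xout = new_t)$y)
      # a target frame is missing if either bracketing source frame is
      miss_f <- stats::approx(old_t, as.numeric(m$missing), xout = new_t,
                              method = "constant", f = 0)$y > 0 |
                stats::approx(old_t, as.numeric(m$missing), xout = new_t,
                              method = "constant", f = 1)$y > 0
      pos[miss_f, ] <- NA_real_
      marker_trajectory(m$marker, m$side, pos, target_rate, missing = miss_f)
    })
  }
  force <- trial$force
  if (!is.null(force) && abs(force$rate - trial$rate) < 1e-9) {
    ft <- (seq_along(force$values) - 1) / force$rate
    if (exists("idx", inherits = FALSE)) {
      force <- list(values = force$values[idx], rate = target_rate)
    } else {
      force <- list(values = stats::approx(ft, force$values, xout = new_t)$y,
                    rate = target_rate)
    }
  }
  out <- gait_trial(trial$subject_id, trial$trial_id, markers, target_rate,
                    force = force, events = trial$events,
                    pattern = trial$pattern)
  out$canonical <- trial$canonical
  out
}

#' Forward-difference marker velocities
#'
#' Computes `v[n] = (s[n+1] - s[n]) * rate` (mm/s for mm positions). The
#' final frame's velocity is replicated from the penultimate one so
#' positions and velocities share a frame grid.
#'
#' @param positions Frames x d numeric matrix (or vector).
#' @param rate Sampling rate, Hz.
#' @return Matrix of the same shape as `positions`.
#' @export
compute_velocities <- function(positions, rate) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2) stop("need at least two frames to differentiate")
  if (rate <= 0) stop("rate must be positive")
  v <- (positions[-1, , drop = FALSE] - positions[-n, , drop = FALSE]) * rate
  rbind(v, v[n - 1, , drop = FALSE])
}

#' Canonicalize a trial's coordinate frame
#'
#' Makes model inputs invariant to walkway direction and foot side: rotates
#' the horizontal plane so the principal axis of the heel's horizontal
#' displacement points along +x (sign fixed so net progression is
#' positive), subtracts the first-frame mid-foot centroid, and mirrors
#' left-foot markers across the sagittal plane (y -> -y) so both feet share
#' one model frame. Idempotent; a trial with no net progression (standing)
#' is an error.
#'
#' @param trial A [gait_trial()].
#' @param min_progression_mm Minimum net heel displacement to accept, mm.
#' @return The canonicalized [gait_trial()] (flag `canonical = TRUE`).
#' @export
canonicalize_trial <- function(trial, min_progression_mm = 100) {
  if (isTRUE(trial$canonical)) return(trial)
  sides <- trial_sides(trial)
  if (length(sides) != 1)
    stop("canonicalize one side at a time (use split_trial_sides first)")
  hee <- get_marker(trial, "HEE")
  xy <- hee$positions[!hee$missing, 1:2, drop = FALSE]
  disp <- xy[nrow(xy), ] - xy[1, ]
  pc <- prcomp(xy, center = TRUE)$rotation[, 1]
  if (sum(pc * disp) < 0) pc <- -pc
  if (sqrt(sum(disp^2)) < min_progression_mm)
    stop("no net progression: trial appears to be standing still")
  ct <- pc[1]; st <- pc[2]
  rot <- matrix(c(ct, st, -st, ct), 2, 2)  # rotates pc onto +x
  mirror <- sides == "L"

  rot_pos <- function(pos) {
    pos[, 1:2] <- pos[, 1:2, drop = FALSE] %*% rot
    if (mirror) pos[, 2] <- -pos[, 2]
    pos
  }
  markers <- lapply(trial$markers, function(m) {
    marker_trajectory(m$marker, m$side, rot_pos(m$positions), m$rate,
                      missing = m$missing)
  })
  centroid <- colMeans(do.call(rbind, lapply(markers, function(m)
    m$positions[1, , drop = FALSE])))
  markers <- lapply(markers, function(m) {
    m$positions <- sweep(m$positions, 2, centroid)
    m
  })
  out <- gait_trial(trial$subject_id, trial$trial_id, markers, trial$rate,
                    force = trial$force, events = trial$events,
                    pattern = trial$pattern)
  out$canonical <- TRUE
  out
}

#' The five marker-combination presets
#'
#' The marker combinations evaluated for event detection, written
#' `"HLX|HEE"`, `"TOE|HEE"`, `"HLX|PMT5|HEE"`, `"TOE|PMT5|HEE"`,
#' `"HLX|TOE|HEE"`. Any `|`-separated subset of the four foot markers is
#' also accepted as a custom combination.
#'
#' @param combo Combination string or character vector of marker names.
#' @return Character vector of marker names in order.
#' @export
marker_combo <- function(combo) {
  if (length(combo) == 1 && grepl("|", combo, fixed = TRUE))
    combo <- strsplit(combo, "|", fixed = TRUE)[[1]]
  combo <- toupper(trimws(combo))
  if (length(combo) == 0) stop("empty marker combination")
  if (anyDuplicated(combo)) stop("duplicate markers in combination")
  if (!all(combo %in% FOOT_MARKERS))
    stop(sprintf("unknown marker(s): %s",
                 paste(setdiff(combo, FOOT_MARKERS), collapse = ", ")))
  combo
}

MARKER_COMBO_PRESETS <- c("HLX|HEE", "TOE|HEE", "HLX|PMT5|HEE",
                          "TOE|PMT5|HEE", "HLX|TOE|HEE")

#' Assemble the model's feature matrix from a trial
#'
#' For each marker of the combination, in order: x, y, z position (mm) then
#' x, y, z forward-difference velocity (mm/s) — 6 channels per marker. If a
#' scaler is supplied, channels are z-scored with its (training-set)
#' statistics.
#'
#' @param trial A canonicalized, downsampled [gait_trial()].
#' @param combo Marker combination (see [marker_combo()]).
#' @param scaler Optional scaler from [fit_feature_scaler()].
#' @return An object of class `feature_matrix`: list with `values`
#'   (frames x channels), `channels` (layout data.frame), `rate`,
#'   `frame_times`.
#' @export
assemble_features <- function(trial, combo, scaler = NULL) {
  combo <- marker_combo(combo)
  blocks <- list()
  layout <- list()
  for (nm in combo) {
    m <- get_marker(trial, nm)
    if (any(m$missing))
      stop(sprintf("marker %s has missing frames; exclude or repair the trial", nm))
    vel <- compute_velocities(m$positions, trial$rate)
    blocks[[nm]] <- cbind(m$positions, vel)
    layout[[nm]] <- data.frame(marker = nm,
                               axis = rep(c("x", "y", "z"), 2),
                               kind = rep(c("position", "velocity"), each = 3))
  }
  values <- do.call(cbind, blocks)
  channels <- do.call(rbind, layout)
  rownames(channels) <- NULL
  colnames(values) <- paste(channels$marker, channels$kind, channels$axis,
                            sep = ".")
  if (!is.null(scaler)) values <- apply_feature_scaler(values, scaler)
  structure(list(values = values, channels = channels, rate = trial$rate,
                 frame_times = trial_frame_times(trial)),
            class = "feature_matrix")
}

#' Fit a per-channel standardization scaler
#'
#' Mean and standard deviation per feature channel, pooled over a list of
#' feature matrices (the training set). Channels with zero spread get unit
#' scale.
#'
#' @param feature_list List of `feature_matrix` objects (or plain matrices).
#' @return List with `mean` and `sd` vectors, class `feature_scaler`.
#' @export
fit_feature_scaler <- function(feature_list) {
  vals <- do.call(rbind, lapply(feature_list, function(f)
    if (inherits(f, "feature_matrix")) f$values else f))
  mu <- colMeans(vals)
  sdv <- apply(vals, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  structure(list(mean = mu, sd = sdv), class = "feature_scaler")
}

apply_feature_scaler <- function(values, scaler) {
  sweep(sweep(values, 2, scaler$mean), 2, scaler$sd, "/")
}

#' Cut one training window around an annotated event
#'
#' Windows are `length_frames` long, nominally centred on the event, and
#' jittered by an integer offset drawn uniformly from
#' `[-max_offset, +max_offset]` so the network cannot learn a fixed event
#' position. Window start is `round(event frame) - length/2 + offset`. At
#' trial edges the window is shifted inward (clamped) rather than
#' zero-padded.
#'
#' @param features A `feature_matrix` from [assemble_features()].
#' @param event One-row event (list or data.frame row with `time_s`,
#'   `event_type`).
#' @param targets Optional named list of per-frame target vectors (one per
#'   event type, aligned with `features`); the window slice is attached.
#' @param length_frames Window length (default 150 frames).
#' @param max_offset Maximum |offset| in frames (default 30). The offset is
#'   drawn from the session RNG; seed with `set.seed()` for reproducibility.
#' @param offset Optional forced offset (overrides the random draw).
#' @return A `window_sample`: list with `values`, `targets`, `start`,
#'   `offset_frames`, `event_frame`, `rate`, plus `group`/`subject_id` slots
#'   filled by the caller.
#' @export
extract_training_window <- function(features, event, targets = NULL,
                                    length_frames = 150, max_offset = 30,
                                    offset = NULL) {
  n <- nrow(features$values)
  if (n < length_frames) stop("trial shorter than the window length")
  if (is.null(offset))
    offset <- sample.int(2L * max_offset + 1L, 1L) - max_offset - 1L
  if (abs(offset) > max_offset) stop("|offset| exceeds max_offset")
  ev_frame <- round(event$time_s * features$rate) + 1L  # 1-based frame index
  half <- length_frames %/% 2L
  start <- ev_frame - half + offset
  start <- max(1L, min(start, n - length_frames + 1L))
  idx <- start:(start + length_frames - 1L)
  tw <- if (!is.null(targets)) lapply(targets, function(y) y[idx]) else NULL
  structure(
    list(values = features$values[idx, , drop = FALSE], targets = tw,
         start = start, offset_frames = as.integer(offset),
         event_frame = ev_frame, event_type = event$event_type,
         rate = features$rate),
    class = "window_sample"
  )
}

#' Classify the initial-contact pattern of a trial
#'
#' Default `"height"` mode compares marker heights at each IC: heel-strike
#' (`HS`) when the heel marker is lower than every forefoot marker by more
#' than the contact margin, forefoot (`FF`) when a forefoot marker is lower
#' than the heel by more than the margin, midfoot (`MF`) otherwise. The
#' trial label is the majority vote over its ICs, ties resolved to `MF`.
#' The alternative `"pitch"` mode thresholds the foot's sagittal pitch
#' angle (HEE->TOE elevation, degrees, positive = toes up) at IC with
#' user-supplied cutoffs — an angle-based proxy for dorsiflexion grading
#' when only foot markers are available.
#'
#' @param trial A [gait_trial()] (any one side).
#' @param ic_events Event table of IC events; defaults to the trial's own
#'   IC events.
#' @param margin_mm Contact margin for the height rule, mm (default 5, about
#'   half a marker diameter).
#' @param mode `"height"` or `"pitch"`.
#' @param pitch_thresholds For `"pitch"`: named vector
#'   `c(hs = <deg>, ff = <deg>)`; pitch above `hs` classifies HS, below
#'   `ff` classifies FF.
#' @return `"HS"`, `"MF"` or `"FF"`.
#' @export
classify_ic_pattern <- function(trial, ic_events = NULL, margin_mm = 5,
                                mode = c("height", "pitch"),
                                pitch_thresholds = c(hs = 5, ff = -5)) {
  mode <- match.arg(mode)
  if (is.null(ic_events))
    ic_events <- trial$events[trial$events$event_type == "IC", , drop = FALSE]
  if (nrow(ic_events) == 0) stop("no IC events to classify")
  hee <- get_marker(trial, "HEE")
  fore_names <- intersect(c("TOE", "HLX", "PMT5"),
                          vapply(trial$markers, `[[`, character(1), "marker"))
  if (length(fore_names) == 0) stop("no forefoot marker present")
  votes <- character(nrow(ic_events))
  for (i in seq_len(nrow(ic_events))) {
    fr <- min(max(1L, round(ic_events$time_s[i] * trial$rate) + 1L),
              trial$n_frames)
    if (mode == "height") {
      hee_z <- hee$positions[fr, 3]
      fore_z <- min(vapply(fore_names, function(nm)
        get_marker(trial, nm)$positions[fr, 3], numeric(1)))
      votes[i] <- if (hee_z < fore_z - margin_mm) "HS"
                  else if (fore_z < hee_z - margin_mm) "FF"
                  else "MF"
    } else {
      toe <- get_marker(trial, "TOE")$positions[fr, ]
      heep <- hee$positions[fr, ]
      dx <- sqrt(sum((toe[1:2] - heep[1:2])^2))
      pitch <- atan2(toe[3] - heep[3], dx) * 180 / pi
      votes[i] <- if (pitch > pitch_thresholds[["hs"]]) "HS"
                  else if (pitch < pitch_thresholds[["ff"]]) "FF"
                  else "MF"
    }
  }
  tab <- table(factor(votes, GAIT_PATTERNS))
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1) "MF" else top
}

#' Split a two-sided trial into per-side trials
#' @param trial A [gait_trial()] possibly holding both feet.
#' @return Named list of single-side trials (`L`, `R` as present); events
#'   are filtered to the matching side.
#' @export
split_trial_sides <- function(trial) {
  sides <- trial_sides(trial)
  out <- lapply(sides, function(s) {
    mk <- trial$markers[vapply(trial$markers, function(m) m$side == s,
                               logical(1))]
    ev <- trial$events[trial$events$side == s, , drop = FALSE]
    tr <- gait_trial(trial$subject_id, paste0(trial$trial_id, "_", s),
                     mk, trial$rate, force = trial$force, events = ev,
                     pattern = trial$pattern)
    tr
  })
  names(out) <- sides
  out
}
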