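#' Construct a marker trajectory
#'
#' A single foot marker's 3D trajectory in the laboratory frame, with a
#' per-frame missing mask for occluded frames.
#'
#' @param marker Marker identifier, one of `"HEE"`, `"TOE"`, `"HLX"`,
#'   `"PMT5"` (calcaneus, distal metatarsal head, hallux, proximal fifth
#'   metatarsal).
#' @param side Foot side, `"L"` or `"R"`.
#' @param positions Numeric matrix, frames x 3 (x, y, z), millimetres.
#' @param rate Sampling rate in Hz.
#' @param missing Logical vector, one element per frame; `TRUE` marks an
#'   occluded/invalid frame. Defaults to all observed.
#' @return An object of class `marker_trajectory`.
#' @export
marker_trajectory <- function(marker, side, positions, rate, missing = NULL) {
  marker <- match.arg(toupper(marker), FOOT_MARKERS)
  side <- match.arg(toupper(side), c("L", "R"))
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be a frames x 3 matrix")
  storage.mode(positions) <- "double"
  dimnames(positions) <- NULL
  n <- nrow(positions)
  if (is.null(missing)) missing <- rep(FALSE, n)
  missing <- as.logical(missing)
  if (length(missing) != n) stop("missing mask length must equal frame count")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a positive scalar (Hz)")
  if (any(!is.finite(positions[!missing, , drop = FALSE])))
    stop("non-finite coordinates on frames not flagged missing")
  structure(
    list(marker = marker, side = side, positions = positions,
         missing = missing, rate = as.numeric(rate)),
    class = "marker_trajectory"
  )
}

#' Construct a gait-event table
#'
#' @param event_type Character vector, each `"IC"` or `"TO"`.
#' @param time_s Numeric vector of event times in seconds from trial start.
#'   Times are continuous and need not fall on a frame.
#' @param side Character vector, `"L"`/`"R"`.
#' @param source Character vector: `"force"`, `"manual"`, `"synthetic"` or
#'   `"predicted"`.
#' @param trial_id Optional trial identifier column.
#' @return A `data.frame` with one row per event, sorted by time.
#' @export
gait_events <- function(event_type = character(), time_s = numeric(),
                        side = character(), source = character(),
                        trial_id = NA_character_) {
  n <- length(time_s)
  event_type <- rep_len(as.character(event_type), n)
  side <- rep_len(as.character(side), n)
  source <- rep_len(as.character(source), n)
  trial_id <- rep_len(as.character(trial_id), n)
  if (n > 0) {
    stopifnot(all(event_type %in% EVENT_TYPES),
              all(side %in% c("L", "R")),
              all(source %in% EVENT_SOURCES),
              all(is.finite(time_s)), all(time_s >= 0))
  }
  df <- data.frame(trial_id = trial_id, side = side, event_type = event_type,
                   time_s = as.numeric(time_s), source = source,
                   stringsAsFactors = FALSE)
  df[order(df$time_s), , drop = FALSE]
}

#' Construct a walking trial
#'
#' One subject's barefoot walking pass: marker trajectories, an optional
#' vertical ground-reaction-force trace, ground-truth events, and an optional
#' initial-contact pattern label.
#'
#' @param subject_id,trial_id Identifiers.
#' @param markers List of [marker_trajectory()] objects.
#' @param rate Marker sampling rate in Hz (all trajectories must agree).
#' @param force Optional list with elements `values` (vGRF in newtons, one
#'   per force frame) and `rate` (Hz), or `NULL`.
#' @param events Event table as returned by [gait_events()].
#' @param pattern Optional initial-contact pattern label: `"HS"`, `"MF"` or
#'   `"FF"`.
#' @return An object of class `gait_trial`.
#' @export
gait_trial <- function(subject_id, trial_id, markers, rate, force = NULL,
                       events = gait_events(), pattern = NULL) {
  stopifnot(length(markers) >= 1L)
  lens <- vapply(markers, function(m) nrow(m$positions), integer(1))
  rates <- vapply(markers, function(m) m$rate, numeric(1))
  if (length(unique(lens)) != 1L)
    stop("all marker trajectories must share one frame count")
  if (any(abs(rates - rate) > 1e-9))
    stop("all marker trajectories must share the trial rate")
  names(markers) <- vapply(markers, function(m) paste(m$side, m$marker, sep = "_"),
                           character(1))
  if (anyDuplicated(names(markers)))
    stop("duplicate marker (side, name) pairs")
  if (!is.null(force)) {
    stopifnot(is.list(force), is.numeric(force$values), force$rate > 0)
    if (any(!is.finite(force$values))) stop("force values must be finite")
  }
  if (!is.null(pattern)) pattern <- match.arg(pattern, GAIT_PATTERNS)
  dur <- lens[[1]] / rate
  if (nrow(events) > 0 && any(events$time_s > dur + 1e-9))
    stop("event time beyond trial duration")
  structure(
    list(subject_id = as.character(subject_id),
         trial_id = as.character(trial_id),
         markers = markers, rate = as.numeric(rate), force = force,
         events = events, pattern = pattern,
         n_frames = lens[[1]], canonical = FALSE),
    class = "gait_trial"
  )
}

#' Number of frames and duration of a trial
#' @param trial A `gait_trial`.
#' @return Duration in seconds.
#' @export
trial_duration <- function(trial) trial$n_frames / trial$rate

#' Frame times of a trial
#' @param trial A `gait_trial`.
#' @return Numeric vector of frame times in seconds (first frame at 0).
#' @export
trial_frame_times <- function(trial) (seq_len(trial$n_frames) - 1) / trial$rate

#' Fetch one marker trajectory from a trial
#'
#' @param trial A `gait_trial`.
#' @param marker Marker name (`"HEE"`, `"TOE"`, `"HLX"`, `"PMT5"`).
#' @param side `"L"` or `"R"`; if `NULL` and the trial holds only one side,
#'   that side is used.
#' @return A `marker_trajectory`.
#' @export
get_marker <- function(trial, marker, side = NULL) {
  if (is.null(side)) {
    sides <- unique(vapply(trial$markers, `[[`, character(1), "side"))
    if (length(sides) != 1L)
      stop("trial holds both sides; specify side explicitly")
    side <- sides
  }
  key <- paste(toupper(side), toupper(marker), sep = "_")
  m <- trial$markers[[key]]
  if (is.null(m)) stop(sprintf("marker %s not present in trial", key))
  m
}

#' Sides present in a trial
#' @param trial A `gait_trial`.
#' @return Character vector of sides (`"L"`, `"R"`).
#' @export
trial_sides <- function(trial)
  sort(unique(vapply(trial$markers, `[[`, character(1), "side")))

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("<gait_trial> subject %s, trial %s: %d frames @ %g Hz (%.2f s)\n",
              x$subject_id, x$trial_id, x$n_frames, x$rate, trial_duration(x)))
  cat(sprintf("  markers: %s\n", paste(names(x$markers), collapse = ", ")))
  cat(sprintf("  events: %d (%s)  pattern: %s  force: %s\n",
              nrow(x$events),
              paste(sprintf("%d %s", table(factor(x$events$event_type, EVENT_TYPES)),
                            EVENT_TYPES), collapse = ", "),
              if (is.null(x$pattern)) "-" else x$pattern,
              if (is.null(x$force)) "none" else sprintf("%g Hz", x$force$rate)))
  invisible(x)
}

#' @export
print.marker_trajectory <- function(x, ...) {
  cat(sprintf("<marker_trajectory> %s_%s: %d frames @ %g Hz, %d missing\n",
              x$side, x$marker, nrow(x$positions), x$rate, sum(x$missing)))
  invisible(x)
}
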