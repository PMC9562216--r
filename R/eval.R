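#' Event-detection configuration
#'
#' @param peak_threshold Minimum score for a peak to count as an event
#'   (default 0.5, strict inequality).
#' @param min_peak_separation_s Minimum time between detected peaks,
#'   seconds (default 0.25, a physiological lower bound on step time).
#' @param tolerance_ms Temporal matching tolerance, milliseconds
#'   (default 16, inclusive).
#' @return List of class `detection_config`.
#' @export
detection_config <- function(peak_threshold = 0.5, min_peak_separation_s = 0.25,
                             tolerance_ms = 16) {
  stopifnot(peak_threshold > 0, peak_threshold < 1, min_peak_separation_s > 0,
            tolerance_ms > 0)
  structure(list(peak_threshold = peak_threshold,
                 min_peak_separation_s = min_peak_separation_s,
                 tolerance_ms = tolerance_ms),
            class = "detection_config")
}

#' Extract events from a score curve by peak detection
#'
#' Finds local maxima with value strictly above the threshold, merges
#' plateaus to their midpoint frame, and enforces the minimum peak
#' separation by keeping higher peaks first (as standard peak detectors
#' do). The event time is the frame time of the peak.
#'
#' @param scores Per-frame scores in \[0, 1\].
#' @param frame_times Frame times, seconds.
#' @param config A [detection_config()].
#' @param side,event_type Labels stamped on the returned events.
#' @return Event table ([gait_events()]) with `source = "predicted"`.
#' @export
detect_events <- function(scores, frame_times = NULL,
                          config = detection_config(), side = "R",
                          event_type = "IC") {
  if (is.null(frame_times)) frame_times <- attr(scores, "frame_times")
  scores <- as.numeric(scores)
  if (any(!is.finite(scores))) stop("scores must be finite")
  n <- length(scores)
  if (n < 3) return(gait_events())
  peaks <- integer()
  i <- 2L
  while (i < n) {
    if (scores[i] > scores[i - 1]) {
      j <- i
      while (j < n && scores[j + 1] == scores[i]) j <- j + 1L
      if (j < n && scores[j + 1] < scores[i]) {
        peaks <- c(peaks, (i + j) %/% 2L)  # plateau midpoint
        i <- j + 1L
        next
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  peaks <- peaks[scores[peaks] > config$peak_threshold]
  if (length(peaks) > 1) {
    ord <- peaks[order(scores[peaks], decreasing = TRUE)]
    kept <- integer()
    for (p in ord) {
      if (all(abs(frame_times[p] - frame_times[kept]) >=
              config$min_peak_separation_s))
        kept <- c(kept, p)
    }
    peaks <- sort(kept)
  }
  if (length(peaks) == 0) return(gait_events())
  gait_events(event_type = event_type, time_s = frame_times[peaks],
              side = side, source = "predicted")
}

event_times_of <- function(x) {
  if (is.numeric(x)) return(sort(as.numeric(x)))
  if (is.data.frame(x)) {
    if (nrow(x) > 0 && length(unique(x$event_type)) > 1)
      stop("mixed event types; match one event type at a time")
    return(sort(x$time_s))
  }
  stop("expected numeric times or an event table")
}

#' Match predicted events to ground truth within a temporal tolerance
#'
#' Coverage semantics, not one-to-one assignment: a truth event counts as
#' detected if at least one prediction lies within the tolerance
#' (inclusive, `|dt| <= tolerance`), and a prediction is a true positive if
#' at least one truth event lies within the tolerance; predictions further
#' away are false alarms. Each true-positive prediction contributes a
#' signed error (prediction minus nearest truth).
#'
#' @param predicted,truth Event tables (single event type) or numeric time
#'   vectors, seconds.
#' @param tolerance_ms Tolerance in milliseconds (default 16).
#' @return List: `detected` (logical per truth), `true_positive` (logical
#'   per prediction), `errors_ms` (signed, one per true-positive
#'   prediction), `n_truth`, `n_pred`, `tolerance_ms`.
#' @export
match_events <- function(predicted, truth, tolerance_ms = 16) {
  pt <- event_times_of(predicted)
  tt <- event_times_of(truth)
  if (is.data.frame(predicted) && is.data.frame(truth) &&
      nrow(predicted) > 0 && nrow(truth) > 0 &&
      !identical(unique(predicted$event_type), unique(truth$event_type)))
    stop("predicted and truth event types differ")
  tol <- tolerance_ms / 1000
  nearest <- function(x, pool) {
    if (length(pool) == 0) return(rep(NA_real_, length(x)))
    vapply(x, function(xi) pool[which.min(abs(pool - xi))], numeric(1))
  }
  nt <- nearest(tt, pt)
  detected <- !is.na(nt) & abs(nt - tt) <= tol + 1e-12
  np <- nearest(pt, tt)
  dp <- np - pt  # nearest truth minus prediction
  true_positive <- !is.na(np) & abs(dp) <= tol + 1e-12
  errors_ms <- (pt[true_positive] - np[true_positive]) * 1000
  list(detected = detected, true_positive = true_positive,
       errors_ms = errors_ms, n_truth = length(tt), n_pred = length(pt),
       tolerance_ms = tolerance_ms)
}

#' Aggregate match results into an evaluation report
#'
#' Pools event counts across trials, per gait group and overall:
#' recall = % of true events with a prediction within tolerance,
#' precision = % of predictions matching a true event,
#' false-alarm rate = 100 - precision, missed rate = 100 - recall.
#' Also pools the signed timing errors into a percentile curve and 95%/99%
#' trimmed-mean absolute errors.
#'
#' @param matches List of match structures from [match_events()], one per
#'   trial (or per trial x side).
#' @param groups Optional character vector of gait-group labels (`"HS"`,
#'   `"MF"`, `"FF"`), one per match.
#' @return List of class `evaluation_report`: `by_group` data frame,
#'   `overall` row, `errors_ms`, `percentiles`, `trimmed_ms`, and
#'   `precision_defined` (FALSE when there were no predictions at all).
#' @export
evaluate_detection <- function(matches, groups = NULL) {
  if (length(matches) == 0) stop("no match results")
  if (is.null(groups)) groups <- rep(NA_character_, length(matches))
  stopifnot(length(groups) == length(matches))
  n_truth_tot <- sum(vapply(matches, `[[`, numeric(1), "n_truth"))
  if (n_truth_tot == 0) stop("no ground-truth events to evaluate against")

  pool <- function(sel) {
    ms <- matches[sel]
    n_truth <- sum(vapply(ms, `[[`, numeric(1), "n_truth"))
    n_pred <- sum(vapply(ms, `[[`, numeric(1), "n_pred"))
    n_det <- sum(vapply(ms, function(m) sum(m$detected), numeric(1)))
    n_tp <- sum(vapply(ms, function(m) sum(m$true_positive), numeric(1)))
    recall <- if (n_truth > 0) 100 * n_det / n_truth else NA_real_
    precision <- if (n_pred > 0) 100 * n_tp / n_pred else NA_real_
    data.frame(n_truth = n_truth, n_pred = n_pred, n_detected = n_det,
               n_true_positive = n_tp, recall = recall,
               precision = precision, false_alarm = 100 - precision,
               missed = 100 - recall)
  }
  glabs <- intersect(GAIT_PATTERNS, unique(groups[!is.na(groups)]))
  by_group <- do.call(rbind, lapply(glabs, function(g)
    cbind(group = g, pool(which(groups == g)))))
  if (is.null(by_group))
    by_group <- cbind(group = character(), pool(integer())[0, ])
  overall <- pool(seq_along(matches))
  errors_ms <- unlist(lapply(matches, `[[`, "errors_ms"))
  abs_err <- abs(errors_ms)
  percentiles <- if (length(abs_err) > 0) error_percentile_curve(abs_err)
                 else NULL
  trimmed <- if (length(abs_err) > 0)
    c("95" = trimmed_mean_error(abs_err, 0.95),
      "99" = trimmed_mean_error(abs_err, 0.99))
  else c("95" = NA_real_, "99" = NA_real_)
  structure(
    list(by_group = by_group, overall = as.list(overall),
         errors_ms = errors_ms, percentiles = percentiles,
         trimmed_ms = trimmed,
         precision_defined = overall$n_pred > 0),
    class = "evaluation_report")
}

#' Percentile curve of absolute prediction errors
#'
#' @param abs_errors_ms Absolute timing errors, milliseconds.
#' @param percentiles Percentile grid (default 0-100).
#' @return Data frame `percentile`, `error_ms`; nondecreasing in
#'   `percentile` (linear-interpolation quantiles).
#' @export
error_percentile_curve <- function(abs_errors_ms, percentiles = 0:100) {
  if (length(abs_errors_ms) == 0) stop("no errors to summarise")
  data.frame(percentile = percentiles,
             error_ms = as.numeric(stats::quantile(abs_errors_ms,
                                                   percentiles / 100,
                                                   type = 7)))
}

#' Trimmed-mean absolute error
#'
#' Mean of the smallest `ceiling(keep_fraction * n)` absolute errors — the
#' worst tail is discarded before averaging, so a few badly mispredicted
#' events do not dominate the summary.
#'
#' @param abs_errors_ms Absolute timing errors, milliseconds.
#' @param keep_fraction Fraction of (best) errors to keep, in (0, 1\].
#' @return Trimmed mean in milliseconds.
#' @export
trimmed_mean_error <- function(abs_errors_ms, keep_fraction = 0.95) {
  if (length(abs_errors_ms) == 0) stop("empty error list")
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  k <- ceiling(keep_fraction * length(abs_errors_ms))
  mean(sort(abs_errors_ms)[seq_len(k)])
}

#' Evaluate a trained detector on held-out trials
#'
#' For each trial: canonicalize and downsample, assemble features for the
#' model's marker combination, predict the score curve over the full
#' sequence, extract events by peak detection, and match them against the
#' trial's ground-truth events of the model's event type.
#'
#' @param model A `trained_detector`.
#' @param trials List of [gait_trial()]s with ground-truth events.
#' @param combo Marker combination (defaults to the one stored in the
#'   model).
#' @param detection A [detection_config()].
#' @param target_rate Feature rate, Hz (default 150).
#' @return An `evaluation_report` (see [evaluate_detection()]).
#' @export
evaluate_model <- function(model, trials, combo = NULL,
                           detection = detection_config(), target_rate = 150) {
  if (is.null(combo)) combo <- model$combo
  if (is.null(combo)) stop("no marker combination available")
  matches <- vector("list", length(trials))
  groups <- character(length(trials))
  for (i in seq_along(trials)) {
    tr <- canonicalize_trial(downsample_trial(trials[[i]], target_rate))
    feats <- assemble_features(tr, combo)
    scores <- predict_scores(model, feats)
    side <- trial_sides(tr)[1]
    pred <- detect_events(scores, feats$frame_times, detection, side = side,
                          event_type = model$event_type)
    truth <- tr$events[tr$events$event_type == model$event_type, ,
                       drop = FALSE]
    matches[[i]] <- match_events(pred, truth,
                                 tolerance_ms = detection$tolerance_ms)
    groups[i] <- if (is.null(tr$pattern)) NA_character_ else tr$pattern
  }
  evaluate_detection(matches, groups)
}

#' Write an evaluation report to JSON and/or CSV
#'
#' The CSV mirrors the per-group table layout (one row per gait group plus
#' the overall row); the JSON carries the full report including the
#' percentile curve and trimmed means.
#'
#' @param report An `evaluation_report`.
#' @param json_path,csv_path Output paths (`NULL` to skip).
#' @return Invisibly, the report.
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  tab <- rbind(report$by_group,
               cbind(group = "overall",
                     as.data.frame(report$overall)))
  if (!is.null(csv_path)) utils::write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(table = tab, trimmed_ms = as.list(report$trimmed_ms),
           percentiles = report$percentiles,
           precision_defined = report$precision_defined),
      json_path, digits = NA, auto_unbox = TRUE, dataframe = "rows")
  }
  invisible(report)
}

#' Plot the absolute-error percentile curve
#' @param report An `evaluation_report`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_error_percentiles <- function(report, ...) {
  pc <- report$percentiles
  if (is.null(pc)) stop("report has no matched predictions")
  graphics::plot(pc$percentile, pc$error_ms, type = "l",
                 xlab = "Percentile of predictions",
                 ylab = "Absolute error (ms)", ...)
  graphics::abline(h = 16, lty = 2)
  invisible(report)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  tab <- rbind(x$by_group, cbind(group = "overall", as.data.frame(x$overall)))
  print(tab, row.names = FALSE, digits = 4)
  cat(sprintf("trimmed mean |error|: 95%% = %.2f ms, 99%% = %.2f ms\n",
              x$trimmed_ms[["95"]], x$trimmed_ms[["99"]]))
  invisible(x)
}
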