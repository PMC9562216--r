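#' Derive ground-truth gait events from a vertical ground-reaction force
#'
#' The standard force-plate convention: an initial contact (IC) is placed at
#' each upward crossing of the force threshold and a toe-off (TO) at the
#' subsequent downward crossing. Crossing times are found by linear
#' interpolation between the bracketing samples, so events are continuous
#' times rather than frame-snapped. Crossings separated by less than
#' `debounce_s` are merged to suppress chatter when the trace hovers around
#' the threshold.
#'
#' @param force List with `values` (vGRF, newtons) and `rate` (Hz), as in
#'   [gait_trial()].
#' @param threshold_N Force threshold in newtons; 20 N by default.
#' @param side Side label to stamp on the events.
#' @param debounce_s Minimum time between successive crossings, seconds.
#' @return Event table ([gait_events()]) with `source = "force"`, sorted by
#'   time. A trace that never crosses the threshold yields zero events.
#' @export
extract_force_events <- function(force, threshold_N = 20, side = "R",
                                 debounce_s = 0.05) {
  v <- force$values
  if (any(!is.finite(v))) stop("force trace contains non-finite values")
  if (length(v) < 2) return(gait_events())
  tt <- (seq_along(v) - 1) / force$rate
  above <- v > threshold_N
  d <- diff(above)
  up <- which(d == 1L)    # v[i] <= thr < v[i+1]
  down <- which(d == -1L) # v[i] > thr >= v[i+1]
  crossings <- rbind(
    if (length(up)) data.frame(time_s = tt[up] + (threshold_N - v[up]) /
                                 (v[up + 1] - v[up]) * (1 / force$rate),
                               dir = "up"),
    if (length(down)) data.frame(time_s = tt[down] + (threshold_N - v[down]) /
                                   (v[down + 1] - v[down]) * (1 / force$rate),
                                 dir = "down")
  )
  if (is.null(crossings) || nrow(crossings) == 0) return(gait_events())
  crossings <- crossings[order(crossings$time_s), , drop = FALSE]
  # Debounce in adjacent pairs: two crossings closer than debounce_s are a
  # short excursion across the threshold (chatter) — removing both preserves
  # the up/down alternation of the remaining crossings.
  repeat {
    gaps <- diff(crossings$time_s)
    i <- which(gaps < debounce_s)
    if (length(i) == 0) break
    crossings <- crossings[-c(i[1], i[1] + 1), , drop = FALSE]
  }
  # a leading downward crossing belongs to a stance already in progress at
  # trace start: no IC was observed for it, so it is dropped
  if (nrow(crossings) > 0 && crossings$dir[1] == "down")
    crossings <- crossings[-1, , drop = FALSE]
  gait_events(event_type = ifelse(crossings$dir == "up", "IC", "TO"),
              time_s = crossings$time_s, side = side, source = "force")
}

#' Check a trial for marker occlusions
#'
#' Trials in which a required foot marker is occluded inside the analysis
#' span are excluded from training and evaluation. This reports the
#' offending markers and their missing frame ranges.
#'
#' @param trial A [gait_trial()].
#' @param required Marker names that must be fully observed.
#' @param span Optional integer frame range `c(first, last)` defining the
#'   analysis span; defaults to the whole trial.
#' @return List with `pass` (logical) and `report`, a data.frame with
#'   columns `marker`, `side`, `frames` (compact range strings such as
#'   `"10-12"`) and `n_missing`.
#' @export
check_marker_completeness <- function(trial, required = FOOT_MARKERS,
                                      span = NULL) {
  if (is.null(span)) span <- c(1L, trial$n_frames)
  rows <- list()
  for (m in trial$markers) {
    if (!(m$marker %in% required)) next
    idx <- which(m$missing)
    idx <- idx[idx >= span[1] & idx <= span[2]]
    if (length(idx) > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        marker = m$marker, side = m$side,
        frames = compact_ranges(idx), n_missing = length(idx),
        stringsAsFactors = FALSE)
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(marker = character(), side = character(),
               frames = character(), n_missing = integer())
  list(pass = nrow(report) == 0, report = report)
}

# 1,2,3,7 -> "1-3, 7"
compact_ranges <- function(idx) {
  idx <- sort(unique(idx))
  brk <- c(0, which(diff(idx) > 1), length(idx))
  parts <- vapply(seq_len(length(brk) - 1), function(i) {
    a <- idx[brk[i] + 1]; b <- idx[brk[i + 1]]
    if (a == b) as.character(a) else paste0(a, "-", b)
  }, character(1))
  paste(parts, collapse = ", ")
}

#' Write gait events to CSV or JSON
#'
#' Lossless round-trip of the event fields. CSV columns: `trial_id`,
#' `side`, `event_type`, `time_s`, `source`. An empty event list yields a
#' header-only CSV (or empty JSON array).
#'
#' @param events Event table ([gait_events()]).
#' @param path Output file path; format inferred from the extension unless
#'   given explicitly.
#' @param format `"csv"` or `"json"`.
#' @return The path, invisibly.
#' @export
write_events <- function(events, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  cols <- c("trial_id", "side", "event_type", "time_s", "source")
  df <- events[, cols, drop = FALSE]
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, digits = NA, dataframe = "rows")
  }
  invisible(path)
}

#' Read gait events written by [write_events()]
#' @param path CSV or JSON file path.
#' @return Event table ([gait_events()]).
#' @export
read_events <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    if (length(df) == 0) return(gait_events())
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(trial_id = "character"))
  }
  if (nrow(df) == 0) return(gait_events())
  gait_events(event_type = df$event_type, time_s = df$time_s, side = df$side,
              source = df$source, trial_id = df$trial_id)
}

#' Read a trial from a delimited marker table
#'
#' Expects a text table with a time column and x/y/z columns per marker.
#' Column names are matched case-insensitively against the marker alias
#' table: a marker column is `<side><sep><alias><sep><axis>` with optional
#' separators `_` or `.`, e.g. `R_HEE_x`, `LTOE.z`, `r_mt5_y`. Blank or NaN
#' cells flag the frame as missing for that marker.
#'
#' @param path Delimited text file (comma, tab or semicolon separated).
#' @param side `"L"`, `"R"` or `"both"`.
#' @param subject_id,trial_id Identifiers to stamp on the trial.
#' @param aliases Alias table from [marker_aliases()].
#' @param rate Sampling rate; if `NULL`, inferred from the time column.
#' @param time_col Name of the time column (seconds).
#' @return A [gait_trial()].
#' @export
read_trial_table <- function(path, side = c("both", "L", "R"),
                             subject_id = "unknown", trial_id = basename(path),
                             aliases = marker_aliases(), rate = NULL,
                             time_col = "time") {
  side <- match.arg(side)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(";", first)) ";" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) < 1) stop("empty marker table")
  tc <- which(tolower(names(df)) == tolower(time_col))
  if (length(tc) != 1) stop(sprintf("time column '%s' not found", time_col))
  tt <- as.numeric(df[[tc]])
  if (any(diff(tt) <= 0)) stop("time column must be strictly increasing")
  if (is.null(rate)) rate <- 1 / stats::median(diff(tt))

  parsed <- parse_marker_columns(names(df), aliases)
  want_sides <- if (side == "both") c("L", "R") else side
  markers <- list()
  for (s in want_sides) {
    for (nm in FOOT_MARKERS) {
      sel <- parsed$side == s & parsed$marker == nm
      if (!any(sel, na.rm = TRUE)) next
      cols <- parsed[which(sel), , drop = FALSE]
      cols <- cols[match(c("x", "y", "z"), cols$axis), , drop = FALSE]
      if (any(is.na(cols$col)))
        stop(sprintf("marker %s_%s lacks a full x/y/z column set", s, nm))
      pos <- as.matrix(df[, cols$col, drop = FALSE])
      storage.mode(pos) <- "double"
      miss <- apply(pos, 1, function(r) any(!is.finite(r)))
      pos[miss, ] <- NA_real_
      markers[[paste(s, nm, sep = "_")]] <-
        marker_trajectory(nm, s, pos, rate, missing = miss)
    }
  }
  if (length(markers) == 0) stop("no recognisable marker columns found")
  if (side != "both") {
    present <- vapply(markers, `[[`, character(1), "marker")
    absent <- setdiff(FOOT_MARKERS, present)
    if (length(absent))
      stop(sprintf("required marker(s) absent: %s", paste(absent, collapse = ", ")))
  }
  gait_trial(subject_id, trial_id, markers, rate)
}

#' Write a trial's marker trajectories to a CSV table
#'
#' Inverse of [read_trial_table()]: one `time` column plus
#' `<side>_<marker>_<axis>` columns. Missing frames are written as empty
#' cells.
#'
#' @param trial A [gait_trial()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_trial_table <- function(trial, path) {
  out <- data.frame(time = trial_frame_times(trial))
  for (m in trial$markers) {
    pos <- m$positions
    pos[m$missing, ] <- NA_real_
    for (j in 1:3) {
      out[[paste(m$side, m$marker, c("x", "y", "z")[j], sep = "_")]] <- pos[, j]
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

# Match column names like "R_HEE_x" / "LTOE.z" / "r-mt5-y" to
# (side, marker, axis); returns a data.frame aligned to `cols`.
parse_marker_columns <- function(cols, aliases) {
  res <- data.frame(col = seq_along(cols), side = NA_character_,
                    marker = NA_character_, axis = NA_character_,
                    stringsAsFactors = FALSE)
  alias_lookup <- alias_lookup_table(aliases)
  pat <- "^([LRlr])[._-]?([A-Za-z0-9]+)[._-]?([XYZxyz])$"
  m <- regmatches(cols, regexec(pat, cols))
  for (i in seq_along(cols)) {
    if (length(m[[i]]) == 4) {
      alias <- toupper(m[[i]][3])
      canon <- alias_lookup[[alias]]
      if (!is.null(canon)) {
        res$side[i] <- toupper(m[[i]][2])
        res$marker[i] <- canon
        res$axis[i] <- tolower(m[[i]][4])
      }
    }
  }
  res
}

#' Marker alias table
#'
#' Laboratories label the Conventional Gait Model foot markers differently;
#' the alias table maps lab-specific labels (case-insensitive, with the
#' side prefix stripped) to the four canonical names. The default table
#' ships as a YAML file and deliberately accepts both the first- and
#' second-metatarsal designations for the distal forefoot marker.
#'
#' @param path Optional path to a YAML file mapping canonical names to alias
#'   vectors; defaults to the table shipped with the package.
#' @return Named list canonical name -> character vector of aliases.
#' @export
marker_aliases <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "marker_aliases.yaml", package = "gaitevents")
  al <- yaml::read_yaml(path)
  stopifnot(all(names(al) %in% FOOT_MARKERS))
  lapply(al, toupper)
}

alias_lookup_table <- function(aliases) {
  lk <- list()
  for (canon in names(aliases)) {
    for (a in unique(c(canon, aliases[[canon]]))) lk[[toupper(a)]] <- canon
  }
  lk
}
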