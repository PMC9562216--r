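#' Simulation configuration for one synthetic walking trial
#'
#' Defines a desk-scale synthetic barefoot walking pass in one of three
#' initial-contact patterns: heel-strike (`HS`), midfoot (`MF`) or forefoot
#' (`FF`, toe-walking). Stance occupies 60% of the stride for HS/MF and 65%
#' for FF, literature-typical values for paediatric gait. Marker geometry is
#' a rigid foot template (heel at the origin, forefoot markers offset along
#' the foot axis) whose vertical coordinates follow pattern-specific
#' keyframe curves, so ground truth is exact by construction.
#'
#' @param pattern `"HS"`, `"MF"` or `"FF"`.
#' @param n_strides Number of strides (= IC/TO event pairs) to simulate.
#' @param cadence Steps per minute.
#' @param speed Walking speed, m/s.
#' @param rate Marker sampling rate, Hz (150 or 300 in practice; any
#'   positive value accepted).
#' @param noise_sd Standard deviation of i.i.d. Gaussian observation noise
#'   added to every marker coordinate, mm. The force trace stays noiseless.
#' @param side Simulated foot, `"L"` or `"R"`.
#' @param foot_length_mm Heel-to-toe marker distance, mm.
#' @param body_mass_kg Body mass used to scale the synthetic vGRF.
#' @param lead_s Quiet-standing lead-in/lead-out before the first IC and
#'   after the last stride, seconds; gives training windows margin around
#'   edge events.
#' @param marker_offsets_mm Optional named list overriding the per-marker
#'   (x, y) offsets of the rigid foot template.
#' @param seed Integer seed; the trial is fully reproducible given the
#'   configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(pattern, n_strides = 10, cadence = 110, speed = 1.05,
                       rate = 150, noise_sd = 1, side = "R",
                       foot_length_mm = 180, body_mass_kg = 35,
                       lead_s = 1.0, marker_offsets_mm = NULL, seed = 1L) {
  pattern <- match.arg(pattern, GAIT_PATTERNS)
  stopifnot(n_strides >= 1, cadence > 0, speed > 0, rate > 0, noise_sd >= 0,
            foot_length_mm > 0, body_mass_kg > 0, lead_s >= 0)
  side <- match.arg(toupper(side), c("L", "R"))
  structure(
    list(pattern = pattern, n_strides = as.integer(n_strides),
         cadence = cadence, speed = speed, rate = rate, noise_sd = noise_sd,
         side = side, foot_length_mm = foot_length_mm,
         body_mass_kg = body_mass_kg, lead_s = lead_s,
         marker_offsets_mm = marker_offsets_mm, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Evaluate RNG-dependent code under a local seed without disturbing the
# caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Periodic keyframe interpolation over stride phase u in [0, 1): cosine
# easing between consecutive keys, zero slope at each key, wrapping the last
# key back to the first. Vectorized over u.
periodic_keyframe <- function(u, key_u, key_v) {
  o <- order(key_u)
  key_u <- key_u[o]; key_v <- key_v[o]
  ku <- c(key_u, key_u[1] + 1)
  kv <- c(key_v, key_v[1])
  u <- u %% 1
  i <- findInterval(u, ku, rightmost.closed = FALSE)
  i[i < 1] <- 1
  p <- (u - ku[i]) / (ku[i + 1] - ku[i])
  w <- (1 - cos(pi * p)) / 2
  kv[i] * (1 - w) + kv[i + 1] * w
}

# Minimum-jerk 0 -> 1 easing (zero velocity and acceleration at both ends);
# used for the swing-phase forward progression so the foot lands and lifts
# smoothly.
min_jerk <- function(p) {
  p <- pmin(pmax(p, 0), 1)
  10 * p^3 - 15 * p^4 + 6 * p^5
}

# Pattern-specific vertical keyframes (stride phase -> marker height, mm).
# u = 0 is initial contact. Heights place the marker centre ~15 mm above the
# floor when that part of the foot is on the ground.
sim_z_keys <- function(pattern, stance_frac) {
  sf <- stance_frac
  mid <- sf + (1 - sf) * 0.5      # mid-swing
  lat <- sf + (1 - sf) * 0.55     # forefoot swing apex, slightly later
  switch(pattern,
    HS = list(
      HEE  = list(u = c(0, 0.75 * sf, sf, mid),        v = c(15, 15, 90, 115)),
      TOE  = list(u = c(0, 0.25 * sf, 0.97 * sf, lat), v = c(60, 18, 18, 90)),
      HLX  = list(u = c(0, 0.25 * sf, 0.97 * sf, lat), v = c(70, 20, 20, 95)),
      PMT5 = list(u = c(0, 0.20 * sf, 0.95 * sf, lat), v = c(45, 16, 16, 75))
    ),
    MF = list(
      HEE  = list(u = c(0, 0.75 * sf, sf, mid),        v = c(15, 15, 80, 105)),
      TOE  = list(u = c(0, 0.97 * sf, lat),            v = c(16, 16, 85)),
      HLX  = list(u = c(0, 0.97 * sf, lat),            v = c(17, 17, 90)),
      PMT5 = list(u = c(0, 0.92 * sf, lat),            v = c(15, 15, 70))
    ),
    FF = list(
      HEE  = list(u = c(0, 0.45 * sf, 0.95 * sf, mid), v = c(75, 55, 85, 130)),
      TOE  = list(u = c(0, 0.95 * sf, lat),            v = c(18, 18, 85)),
      HLX  = list(u = c(0, 0.95 * sf, lat),            v = c(20, 20, 90)),
      PMT5 = list(u = c(0, 0.95 * sf, lat),            v = c(20, 20, 80))
    )
  )
}

# (x, y) offsets of each marker from the heel in the foot frame of a RIGHT
# foot, mm; x along the foot axis, y medial-positive. Left feet mirror y.
sim_xy_offsets <- function(foot_len) {
  list(HEE  = c(0.00 * foot_len, 0),
       TOE  = c(0.80 * foot_len, 8),
       HLX  = c(1.00 * foot_len, 20),
       PMT5 = c(0.60 * foot_len, -35))
}

stance_fraction <- function(pattern) if (pattern == "FF") 0.65 else 0.60

#' Simulate one synthetic walking trial with exact ground truth
#'
#' Generates marker trajectories for HEE, TOE, HLX and PMT5 of one foot, a
#' synthetic vertical ground-reaction-force trace (double-bump stance
#' profile, zero in swing), and the exact IC/TO times used to drive the
#' kinematic template. During stance the foot is stationary in the
#' progression direction; during swing it advances by one stride length
#' along a minimum-jerk profile. Vertical marker motion follows the
#' pattern-specific keyframe curves, so at each IC the heel is lowest for
#' HS, the forefoot lowest for FF, and all markers level for MF.
#'
#' @param config A [sim_config()].
#' @return A [gait_trial()] carrying truth events (source `"synthetic"`),
#'   the generating pattern label, and the synthetic force trace.
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  step_t <- 60 / cfg$cadence
  stride_t <- 2 * step_t
  stride_len <- cfg$speed * stride_t * 1000  # mm
  sf <- stance_fraction(cfg$pattern)

  t_ic0 <- cfg$lead_s
  dur <- cfg$lead_s + cfg$n_strides * stride_t + cfg$lead_s
  n <- floor(dur * cfg$rate) + 1L
  tt <- (seq_len(n) - 1) / cfg$rate

  ic_times <- t_ic0 + (seq_len(cfg$n_strides) - 1) * stride_t
  to_times <- ic_times + sf * stride_t

  # global stride phase, clamped to the walking span
  g <- (tt - t_ic0) / stride_t
  g <- pmin(pmax(g, 0), cfg$n_strides)
  k <- pmin(floor(g), cfg$n_strides - 1)
  u <- g - k

  # forward progression of the foot origin (heel), mm
  swing_p <- (u - sf) / (1 - sf)
  x_foot <- k * stride_len + stride_len * min_jerk(swing_p)

  zk <- sim_z_keys(cfg$pattern, sf)
  offs <- sim_xy_offsets(cfg$foot_length_mm)
  if (!is.null(cfg$marker_offsets_mm)) {
    for (nm in names(cfg$marker_offsets_mm)) offs[[nm]] <- cfg$marker_offsets_mm[[nm]]
  }
  mirror <- if (cfg$side == "L") -1 else 1
  y_base <- mirror * -100  # lateral lane offset of the foot, mm
  sway <- 5 * sin(2 * pi * g)  # small mediolateral sway

  markers <- with_seed(cfg$seed, {
    lapply(FOOT_MARKERS, function(nm) {
      z <- periodic_keyframe(u, zk[[nm]]$u, zk[[nm]]$v)
      pos <- cbind(x = x_foot + offs[[nm]][1],
                   y = y_base + mirror * (offs[[nm]][2] + sway),
                   z = z)
      if (cfg$noise_sd > 0)
        pos <- pos + matrix(rnorm(length(pos), sd = cfg$noise_sd), nrow = n)
      marker_trajectory(nm, cfg$side, pos, cfg$rate)
    })
  })

  force <- list(values = synth_vgrf(tt, ic_times, to_times, cfg$body_mass_kg),
                rate = cfg$rate)

  ev <- gait_events(event_type = rep(c("IC", "TO"), each = cfg$n_strides),
                    time_s = c(ic_times, to_times),
                    side = cfg$side, source = "synthetic")
  gait_trial(subject_id = "sim", trial_id = "sim",
             markers = markers, rate = cfg$rate, force = force,
             events = ev, pattern = cfg$pattern)
}

# Double-bump stance vGRF: two peaks of ~1.5 body weight around a mid-stance
# valley, with steep linear loading/unloading ramps over the first/last 8% of
# stance so the 20 N threshold crossing sits within ~2 ms of the true event.
synth_vgrf <- function(tt, ic_times, to_times, body_mass_kg, ramp_frac = 0.08) {
  bw <- body_mass_kg * 9.81
  f <- numeric(length(tt))
  for (i in seq_along(ic_times)) {
    u <- (tt - ic_times[i]) / (to_times[i] - ic_times[i])
    inside <- u > 0 & u < 1
    env <- pmin(1, pmin(u[inside], 1 - u[inside]) / ramp_frac)
    f[inside] <- f[inside] + bw * (1.2 + 0.4 * cos(2 * pi * u[inside])) * env
  }
  f
}

#' Simulate a cohort of synthetic subjects
#'
#' Draws per-subject gait parameters (cadence, speed, foot length, body
#' mass) so that subject-level dataset splits are meaningful, allocates
#' subjects to the HS/MF/FF patterns in the requested ratio (largest-
#' remainder rounding), and simulates `trials_per_subject` trials each.
#'
#' @param n_subjects Number of subjects.
#' @param mix Named numeric ratio of pattern prevalences, e.g.
#'   `c(HS = 4, MF = 2, FF = 1)`.
#' @param trials_per_subject Trials per subject.
#' @param seed Integer seed for the whole cohort.
#' @param ... Further arguments forwarded to [sim_config()] (e.g.
#'   `n_strides`, `rate`, `noise_sd`).
#' @return List of [gait_trial()] objects with populated `subject_id`,
#'   `trial_id` and `pattern`.
#' @export
simulate_cohort <- function(n_subjects, mix = c(HS = 4, MF = 2, FF = 1),
                            trials_per_subject = 1, seed = 1L, ...) {
  stopifnot(n_subjects >= 1, trials_per_subject >= 1)
  mix <- mix[mix > 0]
  if (length(mix) == 0) stop("pattern mix is empty")
  if (!all(names(mix) %in% GAIT_PATTERNS)) stop("unknown pattern in mix")
  counts <- largest_remainder(n_subjects * mix / sum(mix))
  patterns <- rep(names(mix), counts)

  extra <- list(...)
  with_seed(seed, {
    trials <- vector("list", n_subjects * trials_per_subject)
    idx <- 1L
    for (s in seq_len(n_subjects)) {
      cadence <- max(80, rnorm(1, 112, 10))
      speed <- max(0.6, rnorm(1, 1.05, 0.12))
      foot_len <- max(120, rnorm(1, 175, 15))
      mass <- max(15, rnorm(1, 35, 8))
      side <- sample(c("L", "R"), 1)
      sid <- sprintf("S%03d", s)
      for (tr in seq_len(trials_per_subject)) {
        args <- c(list(pattern = patterns[s], cadence = cadence, speed = speed,
                       foot_length_mm = foot_len, body_mass_kg = mass,
                       side = side, seed = sample.int(.Machine$integer.max, 1)),
                  extra)
        trial <- simulate_trial(do.call(sim_config, args))
        trial$subject_id <- sid
        trial$trial_id <- sprintf("%s_T%d", sid, tr)
        trial$events$trial_id <- trial$trial_id
        trials[[idx]] <- trial
        idx <- idx + 1L
      }
    }
    trials
  })
}

# Integer allocation by largest remainder; preserves the total.
largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- round(sum(x)) - sum(fl)
  if (rem > 0) {
    o <- order(x - fl, decreasing = TRUE)
    fl[o[seq_len(rem)]] <- fl[o[seq_len(rem)]] + 1
  }
  as.integer(fl)
}
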