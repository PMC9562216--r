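# Minimal C3D support: Intel (little-endian) processor type, floating-point
# point data, the POINT parameter group, no analog channels. This covers the
# files this package writes and the common case of modern optical-capture
# exports; integer-scaled or DEC/MIPS files are rejected with a clear error.

C3D_BLOCK <- 512L
C3D_PROC_INTEL <- 84L

#' Read a walking trial from a C3D file
#'
#' Reads labelled 3D point data and returns the four foot markers for the
#' requested side(s). Point labels are matched case-insensitively against
#' the marker alias table after stripping the `L`/`R` prefix (so `LHEE`,
#' `L_HEE` and `l.heel` all map to the left calcaneus marker). Frames whose
#' residual is negative are flagged missing.
#'
#' @param path C3D file path.
#' @param side `"L"`, `"R"` or `"both"`. For a single side all four foot
#'   markers must be present; with `"both"`, whatever foot markers exist are
#'   returned.
#' @param subject_id,trial_id Identifiers to stamp on the trial.
#' @param aliases Alias table from [marker_aliases()].
#' @return A [gait_trial()].
#' @export
read_trial_c3d <- function(path, side = c("both", "L", "R"),
                           subject_id = "unknown", trial_id = basename(path),
                           aliases = marker_aliases()) {
  side <- match.arg(side)
  raw <- read_c3d(path)
  alias_lookup <- alias_lookup_table(aliases)
  want_sides <- if (side == "both") c("L", "R") else side

  markers <- list()
  pat <- "^([LRlr])[._-]?([A-Za-z0-9]+)$"
  for (j in seq_along(raw$labels)) {
    lab <- trimws(raw$labels[j])
    m <- regmatches(lab, regexec(pat, lab))[[1]]
    if (length(m) != 3) next
    canon <- alias_lookup[[toupper(m[3])]]
    s <- toupper(m[2])
    if (is.null(canon) || !(s %in% want_sides)) next
    pos <- raw$points[, , j]
    miss <- raw$residuals[, j] < 0
    pos[miss, ] <- NA_real_
    markers[[paste(s, canon, sep = "_")]] <-
      marker_trajectory(canon, s, pos, raw$rate, missing = miss)
  }
  if (side != "both") {
    present <- vapply(markers, `[[`, character(1), "marker")
    absent <- setdiff(FOOT_MARKERS, present)
    if (length(absent))
      stop(sprintf("required marker(s) absent from %s: %s", basename(path),
                   paste(absent, collapse = ", ")))
  }
  if (length(markers) == 0) stop("no recognisable foot-marker labels in C3D")
  gait_trial(subject_id, trial_id, markers, raw$rate)
}

#' Write a trial's marker trajectories to a C3D file
#'
#' Writes a floating-point, little-endian C3D with one labelled point per
#' marker trajectory (labels `RHEE`, `LTOE`, ...). Missing frames get a
#' residual of -1 and zeroed coordinates, per the C3D invalid-point
#' convention.
#'
#' @param trial A [gait_trial()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_trial_c3d <- function(trial, path) {
  labels <- vapply(trial$markers, function(m) paste0(m$side, m$marker),
                   character(1))
  n_pts <- length(labels)
  n_frames <- trial$n_frames
  pts <- array(0, dim = c(n_frames, 3, n_pts))
  res <- matrix(0, n_frames, n_pts)
  for (j in seq_len(n_pts)) {
    m <- trial$markers[[j]]
    p <- m$positions
    p[m$missing, ] <- 0
    pts[, , j] <- p
    res[m$missing, j] <- -1
  }
  write_c3d(path, pts, res, labels, trial$rate)
  invisible(path)
}

# ---- low-level reader -------------------------------------------------

read_c3d <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", C3D_BLOCK)
  if (length(hdr) < C3D_BLOCK) stop("truncated C3D header")
  if (as.integer(hdr[2]) != 0x50) stop("not a C3D file (magic byte)")
  param_block <- as.integer(hdr[1])
  w <- function(i) readBin(hdr[(2 * i - 1):(2 * i)], "integer", 1, size = 2,
                           endian = "little")
  f <- function(i) readBin(hdr[(2 * i - 1):(2 * i + 2)], "double", 1, size = 4,
                           endian = "little")
  n_pts <- w(2)
  first_frame <- w(4); last_frame <- w(5)
  hdr_scale <- f(7)
  data_block <- w(9)
  rate <- f(11)
  n_frames <- last_frame - first_frame + 1L

  # parameter section
  seek(con, (param_block - 1) * C3D_BLOCK)
  ph <- readBin(con, "raw", 4)
  n_param_blocks <- as.integer(ph[3])
  proc <- as.integer(ph[4])
  if (proc != C3D_PROC_INTEL)
    stop(sprintf("unsupported C3D processor type %d (only Intel/PC supported)", proc))
  params <- readBin(con, "raw", n_param_blocks * C3D_BLOCK - 4)

  groups <- list()   # id -> name
  values <- list()   # "GROUP:PARAM" -> value
  pos <- 1L
  int8 <- function(r) { v <- as.integer(r); ifelse(v > 127, v - 256, v) }
  while (pos + 1 <= length(params)) {
    nname <- int8(params[pos])
    id <- int8(params[pos + 1])
    if (nname == 0 || id == 0) break
    name <- rawToChar(params[(pos + 2):(pos + 1 + abs(nname))])
    off_at <- pos + 2 + abs(nname)
    offset <- readBin(params[off_at:(off_at + 1)], "integer", 1, size = 2,
                      endian = "little")
    body <- off_at + 2L
    if (id < 0) {
      groups[[as.character(-id)]] <- toupper(name)
    } else {
      type <- int8(params[body])
      ndim <- int8(params[body + 1])
      dims <- if (ndim > 0) as.integer(params[(body + 2):(body + 1 + ndim)]) else integer()
      dstart <- body + 2 + ndim
      nelem <- if (ndim > 0) prod(dims) else 1L
      sz <- abs(type)
      dat_raw <- params[dstart:(dstart + nelem * sz - 1)]
      val <- switch(as.character(type),
        "-1" = rawToChar(dat_raw),
        "1"  = int8(dat_raw),
        "2"  = readBin(dat_raw, "integer", nelem, size = 2, endian = "little"),
        "4"  = readBin(dat_raw, "double", nelem, size = 4, endian = "little"),
        stop("unknown C3D parameter type"))
      if (type == -1 && length(dims) == 2) {
        # fixed-width char array: split into dims[2] strings of width dims[1]
        val <- vapply(seq_len(dims[2]), function(k)
          substr(val, (k - 1) * dims[1] + 1, k * dims[1]), character(1))
      }
      values[[paste0(as.character(id), ":", toupper(name))]] <- val
    }
    if (offset == 0) break
    pos <- off_at + offset
  }
  # resolve group names
  point_id <- names(groups)[vapply(groups, identical, logical(1), "POINT")]
  if (length(point_id) != 1) stop("C3D lacks a POINT parameter group")
  gv <- function(nm) values[[paste0(point_id, ":", nm)]]
  if (!is.null(gv("USED"))) n_pts <- gv("USED")
  if (!is.null(gv("FRAMES"))) n_frames <- gv("FRAMES")
  if (!is.null(gv("RATE"))) rate <- gv("RATE")
  scale <- if (!is.null(gv("SCALE"))) gv("SCALE") else hdr_scale
  if (!is.null(gv("DATA_START"))) data_block <- gv("DATA_START")
  labels <- gv("LABELS")
  if (is.null(labels)) stop("C3D lacks POINT:LABELS")
  labels <- trimws(labels[seq_len(n_pts)])
  if (scale >= 0)
    stop("integer-scaled C3D point data not supported (POINT:SCALE >= 0)")

  seek(con, (data_block - 1) * C3D_BLOCK)
  nvals <- n_frames * n_pts * 4L
  dat <- readBin(con, "double", nvals, size = 4, endian = "little")
  if (length(dat) < nvals) stop("truncated C3D data section")
  arr <- array(dat, dim = c(4, n_pts, n_frames))
  points <- aperm(arr[1:3, , , drop = FALSE], c(3, 1, 2))  # frames x 3 x pts
  residuals <- t(arr[4, , ])                               # frames x pts
  dim(residuals) <- c(n_frames, n_pts)
  list(points = points, residuals = residuals, labels = labels,
       rate = rate, n_frames = n_frames)
}

# ---- low-level writer -------------------------------------------------

write_c3d <- function(path, points, residuals, labels, rate) {
  n_frames <- dim(points)[1]; n_pts <- dim(points)[3]
  if (n_frames > 32767) stop("C3D writer limited to 32767 frames")
  labels <- toupper(labels)
  width <- max(4L, max(nchar(labels)))
  lab_chr <- paste(vapply(labels, function(l)
    formatC(l, width = width, flag = "-"), character(1)), collapse = "")

  # parameter records: group POINT (id 1) + USED, FRAMES, RATE, SCALE,
  # DATA_START, LABELS
  rec_group <- function(name, id) {
    nm <- charToRaw(name)
    c(as.raw(length(nm)), as.raw(256 + (-id)), nm,
      writeBin(3L, raw(), size = 2, endian = "little"),  # offset: desc_len + desc(0) -> next
      as.raw(0))
  }
  rec_param <- function(name, id, type, dims, data_raw) {
    nm <- charToRaw(name)
    body_len <- 2L + length(dims) + length(data_raw) + 1L  # type+ndim+dims+data+desclen
    c(as.raw(length(nm)), as.raw(id), nm,
      writeBin(as.integer(body_len + 2L), raw(), size = 2, endian = "little"),
      as.raw(if (type < 0) 256 + type else type), as.raw(length(dims)),
      as.raw(dims), data_raw, as.raw(0))
  }
  int16r <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  floatr <- function(x) writeBin(as.numeric(x), raw(), size = 4, endian = "little")

  recs <- c(
    rec_group("POINT", 1L),
    rec_param("USED", 1L, 2L, c(1L), int16r(n_pts)),
    rec_param("FRAMES", 1L, 2L, c(1L), int16r(n_frames)),
    rec_param("RATE", 1L, 4L, c(1L), floatr(rate)),
    rec_param("SCALE", 1L, 4L, c(1L), floatr(-1.0)),
    rec_param("LABELS", 1L, -1L, c(width, n_pts), charToRaw(lab_chr))
  )
  # DATA_START depends on parameter section size; parameter section starts at
  # block 2. Reserve space for the DATA_START record itself (fixed size).
  ds_rec_len <- 2L + nchar("DATA_START") + 2L + 2L + 1L + 2L + 1L
  fixed_rec_len <- function(name) 2L + nchar(name) + 2L
  total_param_bytes <- 4L + length(recs) + ds_rec_len + 2L  # + terminator
  n_param_blocks <- as.integer(ceiling(total_param_bytes / C3D_BLOCK))
  data_block <- 2L + n_param_blocks

  recs <- c(recs,
            rec_param("DATA_START", 1L, 2L, c(1L), int16r(data_block)),
            as.raw(c(0, 0)))  # terminator

  # header block
  hdr <- raw(C3D_BLOCK)
  hdr[1] <- as.raw(2)                 # parameter section at block 2
  hdr[2] <- as.raw(0x50)
  hdr[3:4] <- int16r(n_pts)           # word 2
  hdr[5:6] <- int16r(0L)              # analog per frame
  hdr[7:8] <- int16r(1L)              # first frame
  hdr[9:10] <- int16r(n_frames)       # last frame
  hdr[11:12] <- int16r(0L)            # max gap
  hdr[13:16] <- floatr(-1.0)          # scale
  hdr[17:18] <- int16r(data_block)    # data start block
  hdr[19:20] <- int16r(0L)            # analog samples per frame
  hdr[21:24] <- floatr(rate)

  pblock <- raw(n_param_blocks * C3D_BLOCK)
  pblock[1] <- as.raw(1)
  pblock[2] <- as.raw(0x50)
  pblock[3] <- as.raw(n_param_blocks)
  pblock[4] <- as.raw(C3D_PROC_INTEL)
  pblock[4 + seq_along(recs)] <- recs

  # data: per frame, per point: x y z residual (floats)
  arr <- array(0, dim = c(4, n_pts, n_frames))
  arr[1:3, , ] <- aperm(points, c(2, 3, 1))
  arr[4, , ] <- t(residuals)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(pblock, con)
  writeBin(as.numeric(arr), con, size = 4, endian = "little")
  invisible(path)
}
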