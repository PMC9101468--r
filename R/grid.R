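#' Parse a clock time to minutes since midnight
#'
#' Accepts `"HH:MM"` or `"HH:MM:SS"` (seconds are fractional minutes).
#' Used for analysis-window and episode endpoints.
#'
#' @param x Character vector of clock times, or numeric (already minutes).
#' @return Numeric vector of minutes since midnight.
#' @keywords internal
parse_clock <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (!length(p) %in% 2:3 || anyNA(suppressWarnings(as.numeric(p))))
      stop("invalid clock time: ", paste(p, collapse = ":"))
    p <- as.numeric(p)
    p[1] * 60 + p[2] + if (length(p) == 3) p[3] / 60 else 0
  }, numeric(1))
}

format_clock <- function(min) {
  sprintf("%02d:%02d", floor(min / 60) %% 24, round(min %% 60))
}

#' Define the analysis timeslot grid
#'
#' Discretizes a daily analysis window into fixed-length timeslots. Slots are
#' half-open intervals `[t, t + slot_minutes)`: an episode ending exactly at
#' a slot's start does not occupy it. The default grid is the 12-hour window
#' from 08:00 to 20:00 at 15-minute resolution, i.e. 48 slots.
#'
#' @param window_start,window_end Clock times (`"HH:MM"`) bounding the
#'   analysis window, `window_end` strictly later.
#' @param slot_minutes Positive slot length in minutes; must divide the
#'   window length exactly.
#'
#' @return An object of class `"timeslot_grid"`: a list with
#'   `window_start`, `window_end` (minutes since midnight), `slot_minutes`,
#'   and `n_slots`.
#' @export
#' @examples
#' g <- timeslot_grid()          # 08:00-20:00, 15 min -> 48 slots
#' g$n_slots
#' slot_starts(g)[1:4]
timeslot_grid <- function(window_start = "08:00", window_end = "20:00",
                          slot_minutes = 15) {
  ws <- parse_clock(window_start)
  we <- parse_clock(window_end)
  if (we <= ws)
    stop("grid: window_end must be later than window_start")
  if (slot_minutes <= 0)
    stop("grid: slot_minutes must be positive")
  len <- we - ws
  rem <- len %% slot_minutes
  if (abs(rem) > 1e-9)
    stop(sprintf("grid: window of %g min is not divisible by %g-min slots (remainder %g min)",
                 len, slot_minutes, rem))
  structure(list(window_start = ws, window_end = we,
                 slot_minutes = slot_minutes,
                 n_slots = as.integer(round(len / slot_minutes))),
            class = "timeslot_grid")
}

#' @export
print.timeslot_grid <- function(x, ...) {
  cat(sprintf("Timeslot grid: %s-%s, %g-min slots (%d slots)\n",
              format_clock(x$window_start), format_clock(x$window_end),
              x$slot_minutes, x$n_slots))
  invisible(x)
}

#' Slot start times of a grid
#'
#' @param grid A [timeslot_grid()].
#' @param as Return `"clock"` strings (`"HH:MM"`) or `"minutes"` since
#'   midnight.
#' @return Vector of length `grid$n_slots`.
#' @export
slot_starts <- function(grid, as = c("clock", "minutes")) {
  as <- match.arg(as)
  m <- grid$window_start + (seq_len(grid$n_slots) - 1L) * grid$slot_minutes
  if (as == "clock") format_clock(m) else m
}

#' Rasterize continuous activity episodes onto the timeslot grid
#'
#' Converts a set of continuous episodes (activity, start, end) -- e.g.
#' annotations of camera epochs -- into per-slot activity sets. An activity
#' is present in a slot iff its overlap with the half-open slot interval is
#' at least `min_overlap` minutes; with the default `min_overlap = 0`, any
#' positive overlap counts. Episodes extending beyond the grid window are
#' clipped with a warning.
#'
#' @param episodes Data frame with columns `code`, `start`, `end`
#'   (clock times or minutes since midnight; `end > start`).
#' @param grid A [timeslot_grid()].
#' @param min_overlap Minimum overlap in minutes for presence; `0` means any
#'   positive overlap.
#' @param catalog Optional [activity_catalog()]; if supplied, unknown codes
#'   are rejected.
#'
#' @return A list of length `grid$n_slots`; each element is a character
#'   vector of activity codes present in that slot.
#' @export
#' @examples
#' g <- timeslot_grid()
#' ep <- data.frame(code = "cooking", start = "08:00", end = "08:30")
#' lengths(rasterize_intervals(ep, g))[1:3]   # 1 1 0
rasterize_intervals <- function(episodes, grid, min_overlap = 0, catalog = NULL) {
  stopifnot(is.data.frame(episodes),
            all(c("code", "start", "end") %in% names(episodes)))
  s <- parse_clock(episodes$start)
  e <- parse_clock(episodes$end)
  if (any(e <= s))
    stop("rasterize: episodes must have end > start")
  if (!is.null(catalog)) {
    bad <- setdiff(episodes$code, catalog$code)
    if (length(bad))
      stop("rasterize: unknown activity codes: ", paste(bad, collapse = ", "))
  }
  if (any(s < grid$window_start | e > grid$window_end)) {
    warning("rasterize: episode(s) outside the grid window were clipped")
    s <- pmax(s, grid$window_start)
    e <- pmin(e, grid$window_end)
  }
  starts <- grid$window_start + (seq_len(grid$n_slots) - 1L) * grid$slot_minutes
  ends <- starts + grid$slot_minutes
  slots <- vector("list", grid$n_slots)
  for (k in seq_len(grid$n_slots)) {
    ov <- pmin(e, ends[k]) - pmax(s, starts[k])
    keep <- if (min_overlap > 0) ov >= min_overlap - 1e-9 else ov > 1e-9
    slots[[k]] <- unique(episodes$code[keep & e > s])
  }
  slots
}

#' Expected frame count for a fixed-interval wearable camera
#'
#' Number of frames captured by a camera taking one picture every
#' `interval_seconds` seconds over a wear period:
#' `floor(wear seconds / interval_seconds)`. A 06:00-21:00 wear at one frame
#' per 30 s yields 1800 frames.
#'
#' @param wear_start,wear_end Clock times (`"HH:MM"` or `"HH:MM:SS"`),
#'   `wear_end` strictly later.
#' @param interval_seconds Positive capture interval in seconds.
#' @return Integer frame count.
#' @export
#' @examples
#' camera_frame_count("06:00", "21:00", 30)   # 1800
camera_frame_count <- function(wear_start, wear_end, interval_seconds = 30) {
  if (interval_seconds <= 0)
    stop("camera_frame_count: interval_seconds must be positive")
  secs <- (parse_clock(wear_end) - parse_clock(wear_start)) * 60
  if (secs <= 0)
    stop("camera_frame_count: wear_end must be later than wear_start")
  as.integer(floor(secs / interval_seconds + 1e-9))
}
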