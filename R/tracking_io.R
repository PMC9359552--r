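## Timestamps are unix seconds at 0.1 s resolution. All joins and interval
## arithmetic run on integer deciseconds to avoid floating-point drift.
## (kept as doubles: decisecond counts of unix times exceed integer range)
.ds <- function(t) round(t * 10)
.from_ds <- function(ds) ds / 10

.event_types <- c(
  "kick", "handball", "mark", "ball_up", "throw_in", "out_of_bounds",
  "goal", "behind", "umpire_possession", "quarter_start", "quarter_end"
)
.possession_types <- c("kick", "handball", "mark")
.restart_types <- c("ball_up", "throw_in")

#' Read a player-tracking CSV
#'
#' Expects a UTF-8 file with header
#' `match_id,unix_time,player_id,team,x_m,y_m,on_field`, `team` in
#' \{home, away\} and `on_field` in \{0, 1\}. Timestamps are rounded to the
#' nearest 0.1 s. Rows with non-numeric or missing coordinates are rejected
#' (their count is kept in the `n_rejected` attribute); the stream is
#' stably re-sorted by (time, player_id).
#'
#' @param path Path to the tracking CSV.
#' @return Data frame with columns `t`, `player_id`, `team`, `x`, `y`,
#'   `on_field`, sorted by (`t`, `player_id`), with attribute `n_rejected`.
#' @export
read_tracking <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("match_id", "unix_time", "player_id", "team", "x_m", "y_m", "on_field")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    stop("tracking file missing required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  t <- suppressWarnings(as.numeric(raw$unix_time))
  x <- suppressWarnings(as.numeric(raw$x_m))
  y <- suppressWarnings(as.numeric(raw$y_m))
  onf <- suppressWarnings(as.integer(raw$on_field))
  ok <- is.finite(t) & is.finite(x) & is.finite(y) &
    raw$team %in% c("home", "away") & !is.na(onf) & onf %in% c(0L, 1L)
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    message(sprintf("read_tracking: rejected %d malformed row(s)", n_rejected))
  }
  out <- data.frame(
    t = .from_ds(.ds(t[ok])),
    player_id = raw$player_id[ok],
    team = raw$team[ok],
    x = x[ok], y = y[ok],
    on_field = onf[ok] == 1L,
    stringsAsFactors = FALSE
  )
  out <- out[order(.ds(out$t), out$player_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write a tracking stream back to CSV
#'
#' Inverse of [read_tracking()]: coordinates are printed at 0.01 m and
#' timestamps at 0.1 s, so a write/read round trip reproduces the stream
#' exactly at that precision.
#'
#' @param positions Data frame as returned by [read_tracking()].
#' @param path Output path.
#' @param match_id Match identifier written to every row.
#' @export
write_tracking <- function(positions, path, match_id = "M1") {
  df <- data.frame(
    match_id = match_id,
    unix_time = sprintf("%.1f", positions$t),
    player_id = positions$player_id,
    team = positions$team,
    x_m = sprintf("%.2f", positions$x),
    y_m = sprintf("%.2f", positions$y),
    on_field = as.integer(positions$on_field)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a match-event CSV
#'
#' Expects header `match_id,unix_time,quarter,event_type,player_id,team`
#' (`player_id` / `team` empty for neutral events such as ball-ups). Events
#' are returned time-ordered. Disposal events (kick, handball) must carry a
#' player id.
#'
#' @param path Path to the events CSV.
#' @return Data frame with columns `t`, `quarter`, `event_type`,
#'   `player_id`, `team`, sorted by time.
#' @export
read_events <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("match_id", "unix_time", "quarter", "event_type", "player_id", "team")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    stop("events file missing required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  bad <- !raw$event_type %in% .event_types
  if (any(bad)) {
    stop("unknown event_type(s): ", paste(unique(raw$event_type[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  out <- data.frame(
    t = suppressWarnings(as.numeric(raw$unix_time)),
    quarter = raw$quarter,
    event_type = raw$event_type,
    player_id = ifelse(raw$player_id == "", NA_character_, raw$player_id),
    team = ifelse(raw$team == "", NA_character_, raw$team),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(out$t))) stop("non-numeric event timestamp", call. = FALSE)
  disp <- out$event_type %in% c("kick", "handball")
  if (any(disp & is.na(out$player_id))) {
    stop("disposal events must carry a player_id", call. = FALSE)
  }
  out <- out[order(.ds(out$t), method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an event stream to CSV
#'
#' @param events Data frame as returned by [read_events()].
#' @param path Output path.
#' @param match_id Match identifier written to every row.
#' @export
write_events <- function(events, path, match_id = "M1") {
  df <- data.frame(
    match_id = match_id,
    unix_time = sprintf("%.1f", events$t),
    quarter = events$quarter,
    event_type = events$event_type,
    player_id = ifelse(is.na(events$player_id), "", events$player_id),
    team = ifelse(is.na(events$team), "", events$team)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the attacking-direction sidecar
#'
#' YAML mapping of team to quarter to the sign of x toward that team's
#' attacking goal, e.g. `home: \{Q1: 1, Q2: -1, ...\}`.
#'
#' @param path Path to the YAML sidecar.
#' @return Named list `attack[[team]][[quarter]]` of +1 / -1.
#' @export
read_attack <- function(path) {
  att <- yaml::read_yaml(path)
  stopifnot(all(c("home", "away") %in% names(att)))
  for (team in c("home", "away")) {
    s <- unlist(att[[team]])
    if (!all(s %in% c(-1, 1))) stop("attack signs must be +1/-1", call. = FALSE)
  }
  att
}

#' Assemble admitted 36-player frames from a position stream
#'
#' Groups positions by timestamp, keeps the last occurrence of any duplicate
#' (timestamp, player) row, restricts to on-field players, and admits only
#' timestamps with exactly 36 on-field players, 18 per team — periods of play
#' with a lost player position are dropped, and the dropped timestamps are
#' recorded.
#'
#' @param positions Time-ordered data frame from [read_tracking()].
#' @return An object of class `frame_set`: a list with `positions` (admitted
#'   on-field rows: `t`, `player_id`, `team`, `x`, `y`), `timestamps` (admitted
#'   frame times), `dropped_t` (rejected frame times) and `n_duplicates`.
#' @export
build_frames <- function(positions) {
  key <- paste(.ds(positions$t), positions$player_id)
  dup <- duplicated(key, fromLast = TRUE)
  n_dup <- sum(dup)
  if (n_dup > 0) {
    message(sprintf("build_frames: %d duplicate (t, player) row(s), keeping last", n_dup))
  }
  pos <- positions[!dup, , drop = FALSE]
  onf <- pos[pos$on_field, c("t", "player_id", "team", "x", "y"), drop = FALSE]

  ds <- .ds(onf$t)
  all_ds <- sort(unique(.ds(pos$t)))
  n_home <- tapply(onf$team == "home", ds, sum)
  n_tot <- tapply(rep(1L, nrow(onf)), ds, sum)
  ok_ds <- as.numeric(names(n_tot))[n_tot == 36L & n_home == 18L]
  admitted <- onf[ds %in% ok_ds, , drop = FALSE]
  admitted <- admitted[order(.ds(admitted$t), admitted$player_id, method = "radix"), ,
    drop = FALSE
  ]
  rownames(admitted) <- NULL
  structure(
    list(
      positions = admitted,
      timestamps = .from_ds(sort(ok_ds)),
      dropped_t = .from_ds(setdiff(all_ds, ok_ds)),
      n_duplicates = n_dup
    ),
    class = "frame_set"
  )
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf(
    "<frame_set> %d admitted frame(s), %d dropped\n",
    length(x$timestamps), length(x$dropped_t)
  ))
  invisible(x)
}

#' Synchronise events with admitted frames
#'
#' Attaches each event to the admitted frame with the nearest timestamp
#' within +/- 0.05 s (half the 10 Hz frame period). Events with no frame in
#' the window get `frame_t = NA` and are counted as unmatched.
#'
#' @param frames A `frame_set` from [build_frames()].
#' @param events Data frame from [read_events()].
#' @return `events` with a `frame_t` column appended; attribute
#'   `n_unmatched` counts events without a frame.
#' @export
synchronise <- function(frames, events) {
  stopifnot(inherits(frames, "frame_set"))
  ft <- frames$timestamps
  frame_t <- rep(NA_real_, nrow(events))
  if (length(ft)) {
    idx <- findInterval(events$t, ft)
    for (i in seq_len(nrow(events))) {
      cand <- unique(pmin(pmax(c(idx[i], idx[i] + 1L), 1L), length(ft)))
      d <- abs(ft[cand] - events$t[i])
      j <- which.min(d)
      if (d[j] <= 0.05 + 1e-9) frame_t[i] <- ft[cand[j]]
    }
  }
  events$frame_t <- frame_t
  attr(events, "n_unmatched") <- sum(is.na(frame_t))
  events
}

#' Infer the ball track from possession events
#'
#' Between a possession event (kick, handball, mark) by player p and the next
#' possession event, the ball is taken to be at p's tracked position in every
#' admitted frame; before the first possession event the ball sits with the
#' eventual first possessor. Frames inside an umpire-possession interval
#' (from `umpire_possession` to the next ball-up / throw-in) are emitted with
#' `in_play = FALSE`. If the possessor is missing from a frame the previous
#' ball position is carried forward.
#'
#' @param frames A `frame_set`.
#' @param events Synchronised events from [synchronise()].
#' @return Data frame `t`, `x`, `y`, `possessor_id`, `possessor_team`,
#'   `in_play`, one row per admitted frame.
#' @export
infer_ball_track <- function(frames, events) {
  stopifnot(inherits(frames, "frame_set"))
  ft <- frames$timestamps
  n <- length(ft)
  if (n == 0L) {
    return(data.frame(
      t = numeric(0), x = numeric(0), y = numeric(0),
      possessor_id = character(0), possessor_team = character(0),
      in_play = logical(0), stringsAsFactors = FALSE
    ))
  }
  poss <- events[events$event_type %in% .possession_types & !is.na(events$player_id), ,
    drop = FALSE
  ]
  fds <- .ds(ft)
  # possessor at each frame: last possession event at or before the frame;
  # frames before the first possession use the first possessor
  pid <- rep(NA_character_, n)
  pteam <- rep(NA_character_, n)
  if (nrow(poss)) {
    k <- findInterval(fds, .ds(poss$t))
    k[k == 0L] <- 1L
    pid <- poss$player_id[k]
    pteam <- poss$team[k]
  }

  pos <- frames$positions
  pos_key <- paste(.ds(pos$t), pos$player_id)
  row_of <- match(paste(fds, pid), pos_key)

  x <- pos$x[row_of]
  y <- pos$y[row_of]
  n_carried <- 0L
  for (i in seq_len(n)) {
    if (is.na(x[i])) {
      if (i > 1L) {
        x[i] <- x[i - 1L]
        y[i] <- y[i - 1L]
        n_carried <- n_carried + 1L
      }
    }
  }
  if (n_carried > 0) {
    message(sprintf("infer_ball_track: carried ball position for %d frame(s)", n_carried))
  }

  in_play <- rep(TRUE, n)
  ump <- which(events$event_type == "umpire_possession")
  for (u in ump) {
    t0 <- .ds(events$t[u])
    later <- which(.ds(events$t) > t0 &
      events$event_type %in% c(.restart_types, "quarter_end"))
    t1 <- if (length(later)) .ds(events$t[later[1]]) else Inf
    in_play[fds >= t0 & fds < t1] <- FALSE
  }

  data.frame(
    t = ft, x = x, y = y,
    possessor_id = pid, possessor_team = pteam,
    in_play = in_play, stringsAsFactors = FALSE
  )
}

## Exclusion intervals [start, end) in deciseconds, with reasons.
.exclusion_intervals <- function(events) {
  eds <- .ds(events$t)
  qs <- eds[events$event_type == "quarter_start"]
  qe <- eds[events$event_type == "quarter_end"]
  out <- list()
  add <- function(start, end, reason) {
    out[[length(out) + 1L]] <<- data.frame(
      start = start, end = end, reason = reason,
      stringsAsFactors = FALSE
    )
  }
  # frames outside any [quarter_start, quarter_end] are handled by the caller
  end_of_quarter <- function(t0) {
    later <- qe[qe >= t0]
    if (length(later)) later[1] else Inf
  }
  for (i in which(events$event_type %in% c("goal", "behind"))) {
    t0 <- eds[i]
    later <- which(eds > t0 & events$event_type %in% c(.restart_types, "quarter_end"))
    t1 <- if (length(later)) eds[later[1]] else end_of_quarter(t0)
    add(t0 + 1L, t1, "after_score") # open at the score instant, restart frame kept
  }
  for (i in which(events$event_type == "umpire_possession")) {
    t0 <- eds[i]
    later <- which(eds > t0 & events$event_type %in% c(.restart_types, "quarter_end"))
    t1 <- if (length(later)) eds[later[1]] else end_of_quarter(t0)
    add(t0, t1, "umpire_possession")
  }
  if (length(out)) do.call(rbind, out) else {
    data.frame(start = integer(0), end = integer(0), reason = character(0))
  }
}

#' Restrict frames to in-play periods
#'
#' Removes frames (a) outside any `[quarter_start, quarter_end]` interval,
#' (b) strictly after a goal or behind until the subsequent restart
#' (ball-up / throw-in; the restart frame itself is retained), and (c) from
#' an umpire-possession event until the next restart. A stoppage that never
#' restarts is excluded through the end of its quarter. Retained frames are
#' annotated with their quarter.
#'
#' @param frames A `frame_set`.
#' @param events Data frame from [read_events()] (must contain the
#'   quarter_start / quarter_end events).
#' @return A `frame_set` whose `positions` carry a `quarter` column; the
#'   applied exclusion intervals (deciseconds, `[start, end)`) are stored in
#'   attribute `exclusions`.
#' @export
filter_in_play <- function(frames, events) {
  stopifnot(inherits(frames, "frame_set"))
  fds <- .ds(frames$timestamps)
  eds <- .ds(events$t)

  qrows <- which(events$event_type == "quarter_start")
  quarter_of <- rep(NA_character_, length(fds))
  keep <- rep(FALSE, length(fds))
  for (i in qrows) {
    t0 <- eds[i]
    later <- which(eds >= t0 & events$event_type == "quarter_end")
    t1 <- if (length(later)) eds[later[1]] else Inf
    sel <- fds >= t0 & fds <= t1
    keep[sel] <- TRUE
    quarter_of[sel] <- events$quarter[i]
  }

  excl <- .exclusion_intervals(events)
  for (i in seq_len(nrow(excl))) {
    keep[fds >= excl$start[i] & fds < excl$end[i]] <- FALSE
  }

  kept_ds <- fds[keep]
  pos <- frames$positions
  sel <- .ds(pos$t) %in% kept_ds
  pos <- pos[sel, , drop = FALSE]
  pos$quarter <- quarter_of[match(.ds(pos$t), fds)]
  rownames(pos) <- NULL
  structure(
    list(
      positions = pos,
      timestamps = frames$timestamps[keep],
      dropped_t = frames$dropped_t,
      n_duplicates = frames$n_duplicates,
      quarter = quarter_of[keep]
    ),
    class = "frame_set",
    exclusions = excl
  )
}
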