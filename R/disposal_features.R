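#' Snapshot of a disposal
#'
#' Joins a disposal event (kick or handball) to the positional state of all
#' 36 on-field players at that instant, together with the carrier's facing
#' direction and the attacking sign of the carrier's team. This is the input
#' of the nine spatiotemporal features used by the disposal-congestion
#' classifier.
#'
#' @param t Unix time of the disposal (0.1 s resolution).
#' @param carrier_id Identifier of the ball-carrier.
#' @param players Data frame `player_id`, `team`, `x`, `y` for the 36
#'   on-field players (the carrier included).
#' @param heading Unit length-2 vector: the carrier's facing direction.
#' @param attack_sign +1 / -1: sign of x toward the carrier's attacking goal.
#' @param field A [field_spec()].
#' @return Object of class `disposal_snapshot`.
#' @export
disposal_snapshot <- function(t, carrier_id, players, heading, attack_sign,
                              field = field_spec()) {
  stopifnot(
    all(c("player_id", "team", "x", "y") %in% names(players)),
    carrier_id %in% players$player_id,
    length(heading) == 2L, attack_sign %in% c(-1, 1)
  )
  nh <- sqrt(sum(heading^2))
  if (nh < 1e-12) stop("heading must be a non-zero vector", call. = FALSE)
  structure(
    list(
      t = t, carrier_id = carrier_id, players = players,
      heading = heading / nh, attack_sign = attack_sign, field = field
    ),
    class = "disposal_snapshot"
  )
}

.carrier_row <- function(snapshot) {
  which(snapshot$players$player_id == snapshot$carrier_id)[1]
}

.rel_positions <- function(snapshot) {
  i <- .carrier_row(snapshot)
  p <- snapshot$players
  list(
    dx = p$x[-i] - p$x[i], dy = p$y[-i] - p$y[i],
    team = p$team[-i], carrier_team = p$team[i],
    cx = p$x[i], cy = p$y[i]
  )
}

#' Count players within a radius of the ball-carrier
#'
#' Distance thresholds are closed (<= radius); the carrier is never counted.
#'
#' @param snapshot A [disposal_snapshot()].
#' @param radius Radius in metres.
#' @param defenders_only If `TRUE`, count only players of the opposing team.
#' @return Integer count.
#' @export
radius_count <- function(snapshot, radius, defenders_only = FALSE) {
  stopifnot(inherits(snapshot, "disposal_snapshot"), radius > 0)
  r <- .rel_positions(snapshot)
  d <- sqrt(r$dx^2 + r$dy^2)
  sel <- d <= radius
  if (defenders_only) sel <- sel & r$team != r$carrier_team
  sum(sel)
}

## Clockwise bearing (degrees) of each surrounding player from the carrier's
## heading, in (-45, 315]; the quadrant bins are right-closed.
.bearing_cw <- function(dx, dy, heading) {
  dot <- dx * heading[1] + dy * heading[2]
  crs <- heading[1] * dy - heading[2] * dx # CCW-positive
  ang <- -atan2(crs, dot) * 180 / pi # clockwise-positive, (-180, 180]
  ang[ang <= -45] <- ang[ang <= -45] + 360
  ang
}

#' Quadrant player counts around the ball-carrier
#'
#' Bins the players within `radius` of the carrier into four 90-degree
#' quadrants relative to the carrier's heading: frontal (-45, 45] degrees,
#' right (45, 135], behind (135, 225] and left (225, 315], with the bearing
#' measured clockwise from the heading. A player coincident with the carrier
#' has no defined bearing and is assigned to the frontal quadrant.
#'
#' @param snapshot A [disposal_snapshot()].
#' @param radius Radius in metres.
#' @return Named integer vector `c(FPC=, RPC=, LPC=, BPC=)`.
#' @export
quadrant_counts <- function(snapshot, radius) {
  stopifnot(inherits(snapshot, "disposal_snapshot"), radius > 0)
  r <- .rel_positions(snapshot)
  d <- sqrt(r$dx^2 + r$dy^2)
  sel <- d <= radius
  dx <- r$dx[sel]
  dy <- r$dy[sel]
  degenerate <- dx == 0 & dy == 0
  if (any(degenerate)) {
    message(sprintf(
      "quadrant_counts: %d player(s) coincident with carrier, binned frontal",
      sum(degenerate)
    ))
  }
  ang <- .bearing_cw(dx, dy, snapshot$heading)
  fpc <- sum(degenerate | (!degenerate & ang > -45 & ang <= 45))
  rpc <- sum(!degenerate & ang > 45 & ang <= 135)
  bpc <- sum(!degenerate & ang > 135 & ang <= 225)
  lpc <- sum(!degenerate & ang > 225 & ang <= 315)
  c(FPC = fpc, RPC = rpc, LPC = lpc, BPC = bpc)
}

#' Carrier heading from a short trailing track
#'
#' Direction of the carrier's net displacement over the preceding window
#' (default 0.5 s). If the track holds fewer than two samples, or the net
#' displacement is below `min_displacement`, the heading falls back to the
#' attacking direction `(attack_sign, 0)`.
#'
#' @param track Data frame `t`, `x`, `y`: carrier positions over the window,
#'   time-ordered.
#' @param attack_sign +1 / -1 fallback direction.
#' @param window Window length in seconds.
#' @param min_displacement Minimum net displacement in metres to trust the
#'   track.
#' @return Unit length-2 numeric vector.
#' @export
carrier_heading <- function(track, attack_sign, window = 0.5,
                            min_displacement = 0.5) {
  stopifnot(attack_sign %in% c(-1, 1))
  fallback <- c(attack_sign, 0)
  if (is.null(track) || nrow(track) < 2L) return(fallback)
  t_end <- max(track$t)
  w <- track[track$t >= t_end - window - 1e-9, , drop = FALSE]
  if (nrow(w) < 2L) return(fallback)
  dx <- w$x[nrow(w)] - w$x[1]
  dy <- w$y[nrow(w)] - w$y[1]
  disp <- sqrt(dx^2 + dy^2)
  if (disp < min_displacement) return(fallback)
  c(dx, dy) / disp
}

#' Available space around the ball-carrier
#'
#' Area of the disc of the given radius around the carrier clipped to the
#' playing surface, in square metres (see [clipped_disc_area()]).
#'
#' @param snapshot A [disposal_snapshot()].
#' @param radius Radius in metres.
#' @return Area in square metres.
#' @export
available_space <- function(snapshot, radius) {
  stopifnot(inherits(snapshot, "disposal_snapshot"))
  i <- .carrier_row(snapshot)
  clipped_disc_area(
    snapshot$field, snapshot$players$x[i], snapshot$players$y[i], radius
  )
}

#' Feature radii configuration
#'
#' Radii (metres) of the nine disposal features: immediate counts (IPC/IDC),
#' extended counts (EPC/EDC), the quadrant counts and the available-space
#' disc. The immediate and extended radii follow the feature definitions
#' (5 m and 10 m); the quadrant and available-space radii default to the
#' extended 10 m scale.
#'
#' @param immediate,extended,quadrant,available_space Radii in metres.
#' @return Named list of radii.
#' @export
feature_radii <- function(immediate = 5, extended = 10, quadrant = 10,
                          available_space = 10) {
  stopifnot(immediate > 0, extended >= immediate, quadrant > 0, available_space > 0)
  list(
    immediate = immediate, extended = extended,
    quadrant = quadrant, available_space = available_space
  )
}

#' Extract the nine disposal features
#'
#' Assembles the full spatiotemporal feature vector for one disposal:
#' immediate and extended player counts (IPC, EPC), immediate and extended
#' defender counts (IDC, EDC), the four quadrant counts (FPC, RPC, LPC,
#' BPC) and the available space (AS, square metres).
#'
#' @param snapshot A [disposal_snapshot()].
#' @param radii A [feature_radii()] list.
#' @return One-row data frame with columns `IPC`, `EPC`, `IDC`, `EDC`,
#'   `FPC`, `RPC`, `LPC`, `BPC`, `AS`.
#' @export
extract_features <- function(snapshot, radii = feature_radii()) {
  q <- quadrant_counts(snapshot, radii$quadrant)
  data.frame(
    IPC = radius_count(snapshot, radii$immediate),
    EPC = radius_count(snapshot, radii$extended),
    IDC = radius_count(snapshot, radii$immediate, defenders_only = TRUE),
    EDC = radius_count(snapshot, radii$extended, defenders_only = TRUE),
    FPC = unname(q["FPC"]), RPC = unname(q["RPC"]),
    LPC = unname(q["LPC"]), BPC = unname(q["BPC"]),
    AS = available_space(snapshot, radii$available_space)
  )
}
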