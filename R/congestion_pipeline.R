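#' Summarise one clustered frame
#'
#' Converts the per-player congestion labels of a frame into the proportions
#' of the 36 players in primary, secondary and outside congestion, and
#' attaches the field zone of the ball (relative to the attacking direction
#' of the team in possession) and the quarter.
#'
#' @param labels A labelled `cluster_assignment` from [translate_labels()].
#' @param ball_x,ball_y Inferred ball position in metres.
#' @param attack_sign +1 / -1 for the team in possession.
#' @param field A [field_spec()].
#' @param quarter Quarter identifier (e.g. "Q1").
#' @param t Frame timestamp.
#' @return One-row data frame `t`, `quarter`, `zone`, `p_primary`,
#'   `p_secondary`, `p_outside`, `n_players`, or `NULL` (with a message) if
#'   the ball position falls outside the field.
#' @export
summarise_frame <- function(labels, ball_x, ball_y, attack_sign, field, quarter,
                            t = NA_real_) {
  stopifnot(inherits(labels, "cluster_assignment"), "label" %in% names(labels))
  if (!field_contains(field, ball_x, ball_y)) {
    message(sprintf("summarise_frame: ball out of field at t=%.1f, frame skipped", t))
    return(NULL)
  }
  n <- nrow(labels)
  counts <- table(factor(labels$label, levels = c("primary", "secondary", "outside")))
  data.frame(
    t = t, quarter = quarter,
    zone = as.character(zone_of(field, ball_x, ball_y, attack_sign)),
    p_primary = unname(counts["primary"]) / n,
    p_secondary = unname(counts["secondary"]) / n,
    p_outside = unname(counts["outside"]) / n,
    n_players = n,
    stringsAsFactors = FALSE
  )
}

#' Run the continuous-congestion pipeline over one match
#'
#' Full per-match orchestration: admit 36-player frames, synchronise events,
#' infer the ball track, restrict to in-play frames, cluster every frame,
#' translate labels and summarise. The zone of each frame is taken relative
#' to the attacking direction of the team in possession (the team of the
#' last possession event; frames before the first possession use the first
#' possessing team).
#'
#' @param tracking Position stream from [read_tracking()].
#' @param events Event stream from [read_events()].
#' @param attack Attacking-direction list from [read_attack()].
#' @param field A [field_spec()].
#' @param params A [clustering_params()].
#' @return Data frame of frame summaries (one row per retained frame).
#' @export
run_match <- function(tracking, events, attack, field = field_spec(),
                      params = clustering_params()) {
  frames <- build_frames(tracking)
  ev <- synchronise(frames, events)
  inplay <- filter_in_play(frames, ev)
  ball <- infer_ball_track(inplay, ev)

  pos <- inplay$positions
  ts <- inplay$timestamps
  qs <- inplay$quarter
  pos_ds <- .ds(pos$t)
  out <- vector("list", length(ts))
  n_no_ball <- 0L
  for (i in seq_along(ts)) {
    if (!ball$in_play[i]) next
    if (is.na(ball$x[i])) { # no possession established yet in this stream
      n_no_ball <- n_no_ball + 1L
      next
    }
    fr <- pos[pos_ds == .ds(ts[i]), , drop = FALSE]
    asg <- translate_labels(cluster_frame(fr, params))
    team <- ball$possessor_team[i]
    if (is.na(team)) team <- "home"
    sgn <- attack[[team]][[qs[i]]]
    out[[i]] <- summarise_frame(
      asg, ball$x[i], ball$y[i], sgn, field, qs[i],
      t = ts[i]
    )
  }
  if (n_no_ball > 0) {
    message(sprintf("run_match: %d frame(s) without an inferable ball position skipped", n_no_ball))
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(
      t = numeric(0), quarter = character(0), zone = character(0),
      p_primary = numeric(0), p_secondary = numeric(0), p_outside = numeric(0),
      n_players = integer(0), stringsAsFactors = FALSE
    )
  }
  rownames(res) <- NULL
  res
}

#' Aggregate frame summaries across matches
#'
#' For each match the mean proportion of players in each congestion label is
#' computed per grouping cell (field zone or quarter); the table then
#' reports the cross-match mean and sample (n-1) standard deviation of those
#' per-match means, so every match contributes equally. A match with no
#' frames in some cell is excluded from that cell. With a single match the
#' SD is reported as 0 and flagged.
#'
#' @param summaries Named list of per-match frame-summary data frames (as
#'   returned by [run_match()]), or a single data frame (treated as one
#'   match).
#' @param by Grouping: `"zone"` or `"quarter"`.
#' @return Data frame `group_type`, `group`, `label`, `mean`, `sd`,
#'   `n_matches`, with attribute `single_match` when only one match was
#'   supplied.
#' @export
aggregate_congestion <- function(summaries, by = c("zone", "quarter")) {
  by <- match.arg(by)
  if (is.data.frame(summaries)) summaries <- list(match1 = summaries)
  labels <- c("primary", "secondary", "outside")
  pcols <- paste0("p_", labels)

  per_match <- lapply(summaries, function(s) {
    if (!nrow(s)) return(NULL)
    g <- s[[by]]
    agg <- stats::aggregate(s[pcols], by = list(group = g), FUN = mean)
    agg
  })
  per_match <- per_match[!vapply(per_match, is.null, logical(1))]
  if (!length(per_match)) stop("no frames to aggregate", call. = FALSE)

  groups <- sort(unique(unlist(lapply(per_match, function(a) a$group))))
  rows <- list()
  for (g in groups) {
    vals <- lapply(per_match, function(a) {
      i <- match(g, a$group)
      if (is.na(i)) NULL else unlist(a[i, pcols])
    })
    vals <- vals[!vapply(vals, is.null, logical(1))]
    mat <- do.call(rbind, vals)
    n <- nrow(mat)
    for (j in seq_along(labels)) {
      rows[[length(rows) + 1L]] <- data.frame(
        group_type = by, group = g, label = labels[j],
        mean = mean(mat[, j]),
        sd = if (n > 1L) stats::sd(mat[, j]) else 0,
        n_matches = n, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "single_match") <- length(per_match) == 1L
  out
}

#' Build disposal snapshots from match streams
#'
#' Joins every matched disposal event (kick or handball) to the admitted
#' frame at its timestamp, derives the carrier heading from the carrier's
#' trailing 0.5 s track, and returns the list of snapshots ready for
#' [extract_features()].
#'
#' @param tracking Position stream from [read_tracking()].
#' @param events Event stream from [read_events()].
#' @param attack Attacking-direction list from [read_attack()].
#' @param field A [field_spec()].
#' @return List of [disposal_snapshot()] objects; disposals whose carrier is
#'   missing from the frame are skipped with a message.
#' @export
match_disposal_snapshots <- function(tracking, events, attack,
                                     field = field_spec()) {
  frames <- build_frames(tracking)
  ev <- synchronise(frames, events)
  inplay <- filter_in_play(frames, ev)
  pos <- inplay$positions
  pos_ds <- .ds(pos$t)

  disp <- ev[ev$event_type %in% c("kick", "handball") & !is.na(ev$frame_t), ,
    drop = FALSE
  ]
  snaps <- list()
  for (i in seq_len(nrow(disp))) {
    fds <- .ds(disp$frame_t[i])
    fr <- pos[pos_ds == fds, , drop = FALSE]
    if (!nrow(fr)) next # disposal inside an excluded period
    carrier <- disp$player_id[i]
    if (!carrier %in% fr$player_id) {
      message(sprintf(
        "match_disposal_snapshots: carrier %s absent at t=%.1f, skipped",
        carrier, disp$frame_t[i]
      ))
      next
    }
    q <- fr$quarter[1]
    team <- disp$team[i]
    if (is.na(team)) team <- fr$team[fr$player_id == carrier][1]
    sgn <- attack[[team]][[q]]
    trail <- frames$positions
    trail <- trail[trail$player_id == carrier &
      .ds(trail$t) >= fds - 5L & .ds(trail$t) <= fds, , drop = FALSE]
    heading <- carrier_heading(trail, sgn)
    snaps[[length(snaps) + 1L]] <- disposal_snapshot(
      t = disp$frame_t[i], carrier_id = carrier,
      players = fr[, c("player_id", "team", "x", "y")],
      heading = heading, attack_sign = sgn, field = field
    )
  }
  snaps
}
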