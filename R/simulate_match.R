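#' Simulate a full synthetic match
#'
#' Emits dialect-conformant tracking and event streams for a four-quarter
#' match under the configured conditions: 44 tracked players of whom 36 are
#' on field (18 per team), 10 Hz frames, passages of play with planted dense
#' groups drifting at constant velocity, scheduled disposals, umpire
#' stoppages and scoring events (with the out-of-play intervals they
#' create), frames spilling past the quarter boundaries, and dropout
#' passages in which one player's positions are lost so the affected frames
#' fail admission. Every planted fact is returned as ground truth.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; when given, writes `tracking.csv`,
#'   `events.csv`, `attack.yaml`, `truth.csv` and `members.csv`.
#' @param match_id Match identifier used in the files.
#' @return (Invisibly) a list with `tracking`, `events` (data frames in the
#'   IO dialect), `attack`, `frame_truth` (per emitted frame: `t`,
#'   `quarter`, `passage_id`, `in_play`, `dropped`, planted
#'   `n_primary` / `n_secondary` / `n_outside`), `memberships` (per passage:
#'   planted cluster per player), `field`, `config` and (if written) `paths`.
#' @export
simulate_match <- function(config = sim_config(), dir = NULL, match_id = "M1") {
  field <- config$field
  qlen <- config$frames_per_quarter # in deciseconds (one frame per ds)
  pf <- config$passage_frames
  pre_post <- 20 # 2 s of break frames either side of each quarter
  break_ds <- 600
  t0 <- 16000000000 # unix 1.6e9 in deciseconds
  drift_max <- max(config$drift_speed)
  passage_s <- pf / 10
  margin <- 0.5 + drift_max * passage_s

  ids <- .player_ids()
  bench <- data.frame(
    player_id = c(sprintf("H%02d", 19:22), sprintf("A%02d", 19:22)),
    team = rep(c("home", "away"), each = 4L),
    x = rep(c(field$length_m / 2 + 5, -field$length_m / 2 - 5), each = 4L),
    y = rep(c(-3, -1, 1, 3), times = 2L),
    stringsAsFactors = FALSE
  )

  res <- .with_seed(config$seed, {
    track_parts <- list()
    event_rows <- list()
    truth_rows <- list()
    memberships <- list()
    passage_id <- 0L

    add_event <- function(ds, quarter, type, player = NA_character_, team = NA_character_) {
      event_rows[[length(event_rows) + 1L]] <<- data.frame(
        t = ds / 10, quarter = quarter, event_type = type,
        player_id = player, team = team, stringsAsFactors = FALSE
      )
    }

    for (q in 1:4) {
      qname <- paste0("Q", q)
      qs <- t0 + (q - 1) * (qlen + break_ds)
      qe <- qs + qlen
      f_start <- qs - pre_post
      f_end <- qe + pre_post
      add_event(qs, qname, "quarter_start")
      add_event(qe, qname, "quarter_end")

      # interruption schedule: umpire stoppages and scores, evenly slotted,
      # each restarted by a ball-up 3 s later
      n_int <- config$stoppages_per_quarter + config$scores_per_quarter
      int_type <- rep(c("umpire_possession", "goal"),
        c(config$stoppages_per_quarter, config$scores_per_quarter)
      )
      excl <- matrix(numeric(0), ncol = 2)
      if (n_int > 0) {
        slots <- qs + round(qlen * seq_len(n_int) / (n_int + 1))
        # stoppage windows are 3 s; keep only slots whose windows neither
        # overlap each other nor run past the quarter end
        ok <- rep(TRUE, n_int)
        last_end <- -Inf
        for (i in seq_len(n_int)) {
          if (slots[i] <= last_end + 10 || slots[i] + 40 > qe) {
            ok[i] <- FALSE
          } else {
            last_end <- slots[i] + 30
          }
        }
        slots <- slots[ok]
        int_type <- int_type[ok]
        n_int <- length(slots)
      }
      if (n_int > 0) {
        for (i in seq_len(n_int)) {
          add_event(slots[i], qname, int_type[i])
          add_event(slots[i] + 30, qname, "ball_up")
          start <- if (int_type[i] == "umpire_possession") slots[i] else slots[i] + 1
          excl <- rbind(excl, c(start, slots[i] + 30))
        }
      }
      in_excl <- function(ds) {
        if (nrow(excl) == 0L) return(rep(FALSE, length(ds)))
        out <- rep(FALSE, length(ds))
        for (i in seq_len(nrow(excl))) {
          out <- out | (ds >= excl[i, 1] & ds < excl[i, 2])
        }
        out
      }

      # disposals every disposal_interval_s, padded away from interruptions
      int_ds <- round(config$disposal_interval_s * 10)
      disp_ds <- seq(qs + int_ds, qe - 10, by = int_ds)
      if (n_int > 0) {
        for (i in seq_len(nrow(excl))) {
          disp_ds <- disp_ds[!(disp_ds >= excl[i, 1] - 10 & disp_ds < excl[i, 2] + 10)]
        }
      }
      for (d in disp_ds) {
        pid <- sample(ids$id, 1)
        add_event(
          d, qname, sample(c("kick", "handball"), 1),
          player = pid, team = ids$team[match(pid, ids$id)]
        )
      }

      # passages of play
      p_starts <- seq(f_start, f_end, by = pf)
      in_quarter_p <- p_starts >= qs & p_starts < qe
      n_drop <- min(config$dropout_passages_per_quarter, sum(in_quarter_p))
      drop_passages <- if (n_drop > 0) {
        sort(sample(which(in_quarter_p), n_drop))
      } else {
        integer(0)
      }

      for (pi in seq_along(p_starts)) {
        ps <- p_starts[pi]
        pe <- min(ps + pf - 1, f_end)
        frames_ds <- seq(ps, pe)
        passage_id <- passage_id + 1L

        sizes <- config$group_plan[[sample.int(length(config$group_plan), 1)]]
        sf <- simulate_frame(field, sizes,
          sigma = config$sigma, eps = config$eps,
          boundary_margin = margin
        )
        memberships[[passage_id]] <- data.frame(
          passage_id = passage_id,
          player_id = sf$frame$player_id,
          cluster = sf$membership, stringsAsFactors = FALSE
        )

        # one constant velocity per planted unit (group or lone player)
        unit <- ifelse(sf$membership < 0, seq_along(sf$membership) + 1000L, sf$membership)
        u_ids <- unique(unit)
        sp <- stats::runif(length(u_ids), config$drift_speed[1], config$drift_speed[2])
        th <- stats::runif(length(u_ids), 0, 2 * pi)
        vx <- (sp * cos(th))[match(unit, u_ids)]
        vy <- (sp * sin(th))[match(unit, u_ids)]

        dropped_player <- if (pi %in% drop_passages) sample(ids$id, 1) else NA_character_

        nf <- length(frames_ds)
        dt <- rep((frames_ds - ps) / 10, each = 36L)
        px <- rep(sf$frame$x, times = nf) + rep(vx, times = nf) * dt
        py <- rep(sf$frame$y, times = nf) + rep(vy, times = nf) * dt
        part <- data.frame(
          t = rep(frames_ds / 10, each = 36L),
          player_id = rep(sf$frame$player_id, times = nf),
          team = rep(sf$frame$team, times = nf),
          x = round(px, 2), y = round(py, 2),
          on_field = TRUE, stringsAsFactors = FALSE
        )
        if (!is.na(dropped_player)) {
          part <- part[part$player_id != dropped_player, , drop = FALSE]
        }
        track_parts[[length(track_parts) + 1L]] <- part
        track_parts[[length(track_parts) + 1L]] <- data.frame(
          t = rep(frames_ds / 10, each = nrow(bench)),
          player_id = rep(bench$player_id, times = nf),
          team = rep(bench$team, times = nf),
          x = rep(bench$x, times = nf), y = rep(bench$y, times = nf),
          on_field = FALSE, stringsAsFactors = FALSE
        )

        n_in_groups <- sum(sizes)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          t = frames_ds / 10,
          quarter = ifelse(frames_ds >= qs & frames_ds <= qe, qname, NA_character_),
          passage_id = passage_id,
          in_play = frames_ds >= qs & frames_ds <= qe & !in_excl(frames_ds),
          dropped = !is.na(dropped_player),
          n_primary = if (length(sizes)) max(sizes) else 0L,
          n_secondary = if (length(sizes)) sum(sizes) - max(sizes) else 0L,
          n_outside = 36L - n_in_groups,
          stringsAsFactors = FALSE
        )
      }
    }

    tracking <- do.call(rbind, track_parts)
    tracking <- tracking[order(.ds(tracking$t), tracking$player_id, method = "radix"), ,
      drop = FALSE
    ]
    rownames(tracking) <- NULL
    events <- do.call(rbind, event_rows)
    events <- events[order(.ds(events$t), method = "radix"), , drop = FALSE]
    rownames(events) <- NULL
    frame_truth <- do.call(rbind, truth_rows)
    frame_truth <- frame_truth[order(.ds(frame_truth$t)), , drop = FALSE]
    rownames(frame_truth) <- NULL
    list(
      tracking = tracking, events = events, frame_truth = frame_truth,
      memberships = memberships
    )
  })

  attack <- list(
    home = list(Q1 = 1L, Q2 = -1L, Q3 = 1L, Q4 = -1L),
    away = list(Q1 = -1L, Q2 = 1L, Q3 = -1L, Q4 = 1L)
  )
  out <- c(res, list(attack = attack, field = field, config = config))

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      tracking = file.path(dir, "tracking.csv"),
      events = file.path(dir, "events.csv"),
      attack = file.path(dir, "attack.yaml"),
      truth = file.path(dir, "truth.csv"),
      members = file.path(dir, "members.csv")
    )
    write_tracking(res$tracking, paths$tracking, match_id)
    write_events(res$events, paths$events, match_id)
    yaml::write_yaml(attack, paths$attack)
    tr <- res$frame_truth
    tr$t <- sprintf("%.1f", tr$t)
    utils::write.csv(tr, paths$truth, row.names = FALSE, quote = FALSE)
    utils::write.csv(do.call(rbind, res$memberships), paths$members,
      row.names = FALSE, quote = FALSE
    )
    out$paths <- paths
  }
  invisible(out)
}
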