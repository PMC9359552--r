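# Small hand-built streams exercising admission, synchronisation, ball
# inference and in-play filtering.

write_min_tracking <- function(lines, path) {
  writeLines(c("match_id,unix_time,player_id,team,x_m,y_m,on_field", lines), path)
}

# a full 36-player frame at time t as CSV lines
frame_lines <- function(t, drop = character(0), extra_bench = TRUE) {
  ids <- c(sprintf("H%02d", 1:18), sprintf("A%02d", 1:18))
  teams <- rep(c("home", "away"), each = 18)
  keep <- !ids %in% drop
  lines <- sprintf(
    "M1,%.1f,%s,%s,%.2f,%.2f,1", t, ids[keep], teams[keep],
    seq(-35, 35, length.out = 36)[keep], rep(0, sum(keep))
  )
  if (extra_bench) {
    lines <- c(lines, sprintf("M1,%.1f,H19,home,85.00,0.00,0", t))
  }
  lines
}

test_that("tracking files round-trip and reject malformed rows", {
  p <- withr::local_tempfile(fileext = ".csv")
  write_min_tracking(c(
    "M1,100.0,P1,home,1.23,4.56,1",
    "M1,100.0,P2,away,-2.00,3.10,1",
    "M1,99.9,P1,home,1.20,4.50,1", # out of order: re-sorted
    "M1,100.1,P3,away,NaN,1.00,1", # rejected
    "M1,100.1,P4,home,bad,1.00,1" # rejected
  ), p)
  expect_message(tr <- read_tracking(p), "rejected 2")
  expect_equal(nrow(tr), 3)
  expect_equal(attr(tr, "n_rejected"), 2)
  expect_equal(tr$t, c(99.9, 100.0, 100.0)) # stable (t, player) order
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_tracking(tr, p2)
  tr2 <- read_tracking(p2)
  expect_equal(tr2$x, tr$x)
  expect_equal(tr2$y, tr$y)
  expect_equal(tr2$t, tr$t)

  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("match_id,unix_time,player_id,team,x_m", p3)
  expect_error(read_tracking(p3), "missing required column")
})

test_that("frame admission requires exactly 36 on-field players, 18 a side", {
  p <- withr::local_tempfile(fileext = ".csv")
  write_min_tracking(c(
    frame_lines(100.0), # complete: admitted (44-row style, 36 on field)
    frame_lines(100.1, drop = "H05"), # 35 players: dropped
    frame_lines(100.2) # complete
  ), p)
  fs <- build_frames(read_tracking(p))
  expect_equal(fs$timestamps, c(100.0, 100.2))
  expect_equal(fs$dropped_t, 100.1)
  expect_true(all(table(fs$positions$t) == 36))
  # admitted + dropped = distinct timestamps
  expect_equal(length(fs$timestamps) + length(fs$dropped_t), 3L)
})

test_that("duplicate (t, player) rows keep the last occurrence", {
  p <- withr::local_tempfile(fileext = ".csv")
  write_min_tracking(c(
    frame_lines(100.0),
    "M1,100.0,H01,home,9.99,9.99,1" # duplicate of H01, later in file
  ), p)
  expect_message(fs <- build_frames(read_tracking(p)), "duplicate")
  h01 <- fs$positions[fs$positions$player_id == "H01", ]
  expect_equal(h01$x, 9.99)
  expect_equal(nrow(fs$positions), 36)
})

test_that("events attach to the nearest frame within half a frame period", {
  p <- withr::local_tempfile(fileext = ".csv")
  write_min_tracking(c(frame_lines(100.0), frame_lines(100.1)), p)
  fs <- build_frames(read_tracking(p))
  ev <- data.frame(
    t = c(100.0, 100.04, 100.3), quarter = "Q1",
    event_type = c("kick", "mark", "handball"),
    player_id = c("H01", "H02", "H03"), team = "home",
    stringsAsFactors = FALSE
  )
  sy <- synchronise(fs, ev)
  expect_equal(sy$frame_t, c(100.0, 100.0, NA))
  expect_equal(attr(sy, "n_unmatched"), 1L)
})

test_that("ball follows the possessor and switches on new possessions", {
  p <- withr::local_tempfile(fileext = ".csv")
  write_min_tracking(unlist(lapply(seq(100.0, 101.0, by = 0.1), frame_lines)), p)
  fs <- build_frames(read_tracking(p))
  ev <- data.frame(
    t = c(100.0, 100.5), quarter = "Q1",
    event_type = c("kick", "mark"), player_id = c("H01", "A03"),
    team = c("home", "away"), stringsAsFactors = FALSE
  )
  ball <- infer_ball_track(fs, synchronise(fs, ev))
  h01x <- fs$positions$x[fs$positions$player_id == "H01"][1]
  a03x <- fs$positions$x[fs$positions$player_id == "A03"][1]
  expect_equal(ball$x[ball$t < 100.5], rep(h01x, 5))
  expect_equal(ball$x[ball$t >= 100.5], rep(a03x, 6))
  expect_true(all(ball$in_play))
})

test_that("umpire possession marks frames as not in play", {
  p <- withr::local_tempfile(fileext = ".csv")
  write_min_tracking(unlist(lapply(seq(100.0, 101.0, by = 0.1), frame_lines)), p)
  fs <- build_frames(read_tracking(p))
  ev <- data.frame(
    t = c(100.0, 100.3, 100.8), quarter = "Q1",
    event_type = c("kick", "umpire_possession", "ball_up"),
    player_id = c("H01", NA, NA), team = c("home", NA, NA),
    stringsAsFactors = FALSE
  )
  ball <- infer_ball_track(fs, synchronise(fs, ev))
  expect_equal(ball$in_play, !(ball$t >= 100.3 & ball$t < 100.8))
})

test_that("in-play filtering removes breaks, stoppages and post-score periods", {
  ts <- seq(99.0, 108.0, by = 0.1)
  p <- withr::local_tempfile(fileext = ".csv")
  write_min_tracking(unlist(lapply(ts, frame_lines)), p)
  fs <- build_frames(read_tracking(p))
  ev <- data.frame(
    t = c(100.0, 102.0, 103.0, 104.0, 105.0, 107.0),
    quarter = "Q1",
    event_type = c(
      "quarter_start", "goal", "ball_up", "umpire_possession",
      "throw_in", "quarter_end"
    ),
    player_id = NA_character_, team = NA_character_,
    stringsAsFactors = FALSE
  )
  ip <- filter_in_play(fs, ev)
  got <- ip$timestamps
  # before quarter start and after quarter end: excluded
  expect_false(any(got < 100.0 | got > 107.0))
  # after the goal, before the ball-up: excluded (goal frame itself retained)
  expect_true(102.0 %in% got)
  expect_false(any(got > 102.0 & got < 103.0))
  expect_true(103.0 %in% got)
  # umpire stoppage: excluded from the event until the throw-in
  expect_false(any(got >= 104.0 & got < 105.0))
  expect_true(105.0 %in% got)
  # output is a subset of input
  expect_true(all(got %in% fs$timestamps))
  expect_equal(unique(ip$quarter), "Q1")
})

test_that("attack sidecar round-trips through YAML", {
  p <- withr::local_tempfile(fileext = ".yaml")
  att <- list(
    home = list(Q1 = 1L, Q2 = -1L, Q3 = 1L, Q4 = -1L),
    away = list(Q1 = -1L, Q2 = 1L, Q3 = -1L, Q4 = 1L)
  )
  yaml::write_yaml(att, p)
  got <- read_attack(p)
  expect_equal(got$home$Q2, -1L)
  expect_equal(got$away$Q3, -1L)
})
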