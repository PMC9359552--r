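snapshot_at <- function(carrier_xy, others, teams_others,
                        heading = c(1, 0), field = field_spec()) {
  players <- data.frame(
    player_id = sprintf("P%02d", seq_len(nrow(others) + 1L)),
    team = c("home", teams_others),
    x = c(carrier_xy[1], others[, 1]),
    y = c(carrier_xy[2], others[, 2]),
    stringsAsFactors = FALSE
  )
  disposal_snapshot(
    t = 0, carrier_id = "P01", players = players,
    heading = heading, attack_sign = 1, field = field
  )
}

test_that("radius counts enumerate surrounding players with closed thresholds", {
  # 2 teammates at 3 m, 1 opponent at 4 m, 1 opponent at 8 m
  snap <- snapshot_at(
    c(0, 0),
    rbind(c(3, 0), c(0, 3), c(0, -4), c(8, 0)),
    c("home", "home", "away", "away")
  )
  expect_equal(radius_count(snap, 5), 3)
  expect_equal(radius_count(snap, 10), 4)
  expect_equal(radius_count(snap, 5, defenders_only = TRUE), 1)
  expect_equal(radius_count(snap, 10, defenders_only = TRUE), 2)

  # boundary: exactly 5.0 m counts
  snap2 <- snapshot_at(c(0, 0), rbind(c(5, 0)), "away")
  expect_equal(radius_count(snap2, 5), 1)

  # carrier alone
  snap3 <- snapshot_at(c(0, 0), rbind(c(30, 0)), "away")
  expect_equal(radius_count(snap3, 10), 0)
})

test_that("quadrant counts bin by clockwise bearing from the heading", {
  # heading +x; y is to the left of +x, so (0,-5) is to the right
  snap <- snapshot_at(
    c(0, 0),
    rbind(c(5, 0), c(0, -5), c(-5, 0), c(0, 5)),
    rep("away", 4)
  )
  expect_equal(
    quadrant_counts(snap, 10),
    c(FPC = 1L, RPC = 1L, LPC = 1L, BPC = 1L)
  )
  # no one within radius
  snap2 <- snapshot_at(c(0, 0), rbind(c(30, 0)), "away")
  expect_equal(sum(quadrant_counts(snap2, 10)), 0)
  # coincident player binned frontal with a message
  snap3 <- snapshot_at(c(0, 0), rbind(c(0, 0)), "away")
  expect_message(q <- quadrant_counts(snap3, 10), "coincident")
  expect_equal(unname(q["FPC"]), 1L)
})

test_that("carrier heading uses trailing displacement with a fallback", {
  tr <- data.frame(t = c(0, 0.5), x = c(0, 2), y = c(0, 0))
  expect_equal(carrier_heading(tr, 1), c(1, 0))
  # stationary: fall back to the attacking direction
  tr2 <- data.frame(t = c(0, 0.5), x = c(0, 0.1), y = c(0, 0))
  expect_equal(carrier_heading(tr2, -1), c(-1, 0))
  # diagonal displacement is normalised
  tr3 <- data.frame(t = c(0, 0.5), x = c(0, 1), y = c(0, 1))
  expect_equal(carrier_heading(tr3, 1), c(sqrt(2) / 2, sqrt(2) / 2))
  # single sample: fallback
  expect_equal(carrier_heading(data.frame(t = 0, x = 0, y = 0), 1), c(1, 0))
})

test_that("feature vectors match the brute-force oracle on random snapshots", {
  set.seed(13)
  for (k in 1:120) {
    snap <- random_snapshot()
    got <- extract_features(snap)
    want <- brute_features(snap)
    for (col in c("IPC", "EPC", "IDC", "EDC", "FPC", "RPC", "LPC", "BPC")) {
      expect_identical(got[[col]], want[[col]])
    }
    expect_lt(abs(got$AS - want$AS) / want$AS, 0.005)
    # structural invariants
    expect_lte(got$IPC, got$EPC)
    expect_lte(got$IDC, got$EDC)
    expect_lte(got$IDC, got$IPC)
    expect_lte(got$EDC, got$EPC)
    expect_equal(got$FPC + got$RPC + got$LPC + got$BPC, got$EPC)
    expect_gt(got$AS, 0)
    expect_lte(got$AS, pi * 100 + 1e-6)
  }
})

test_that("counts are equivariant under rigid motions", {
  set.seed(14)
  big <- field_spec(length_m = 2000, width_m = 1500) # clipping never binds
  for (k in 1:10) {
    xy <- cbind(runif(10, -20, 20), runif(10, -20, 20))
    snap <- snapshot_at(c(0, 0), xy, rep(c("home", "away"), 5),
      heading = c(1, 0), field = big
    )
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    shift <- runif(2, -50, 50)
    xy2 <- t(R %*% t(xy)) + matrix(shift, 10, 2, byrow = TRUE)
    snap2 <- snapshot_at(shift, xy2, rep(c("home", "away"), 5),
      heading = as.numeric(R %*% c(1, 0)), field = big
    )
    f1 <- extract_features(snap)
    f2 <- extract_features(snap2)
    cols <- c("IPC", "EPC", "IDC", "EDC", "FPC", "RPC", "LPC", "BPC")
    expect_equal(f1[cols], f2[cols])
  }
})

test_that("adding a player within 5 m increments both player counts", {
  snap <- snapshot_at(c(0, 0), rbind(c(3, 0), c(20, 0)), c("away", "home"))
  f1 <- extract_features(snap)
  snap2 <- snapshot_at(
    c(0, 0), rbind(c(3, 0), c(20, 0), c(0, 4)),
    c("away", "home", "home")
  )
  f2 <- extract_features(snap2)
  expect_equal(f2$IPC, f1$IPC + 1L)
  expect_equal(f2$EPC, f1$EPC + 1L)
})

test_that("empty neighbourhoods yield zero counts but positive space", {
  snap <- snapshot_at(c(0, 0), cbind(runif(35, 40, 70), runif(35, -20, 20)),
    rep(c("home", "away"), length.out = 35)
  )
  f <- extract_features(snap)
  expect_equal(
    unlist(f[c("IPC", "EPC", "IDC", "EDC", "FPC", "RPC", "LPC", "BPC")]),
    c(IPC = 0L, EPC = 0L, IDC = 0L, EDC = 0L, FPC = 0L, RPC = 0L, LPC = 0L, BPC = 0L)
  )
  expect_equal(f$AS, pi * 100, tolerance = 1e-3)
})
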