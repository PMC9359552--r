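# Independent oracles used across the suite. Each recomputes a quantity by
# the most direct method available (brute force, quadrature, rejection
# sampling), sharing no code path with the implementation it checks.

# Classic DBSCAN by breadth-first search over core points; border points
# attach to the first in-range core by index. Returns 1-based cluster labels
# (NA = noise), core flags, and whether any border point is ambiguous
# (in range of cores from two different clusters).
dbscan_oracle <- function(xy, eps = 7.5, min_additional = 3) {
  n <- nrow(xy)
  D <- as.matrix(stats::dist(xy))
  core <- vapply(seq_len(n), function(i) sum(D[i, -i] <= eps) >= min_additional, logical(1))
  lab <- rep(NA_integer_, n)
  cid <- 0L
  for (i in which(core)) {
    if (!is.na(lab[i])) next
    cid <- cid + 1L
    stack <- i
    while (length(stack)) {
      j <- stack[[1]]
      stack <- stack[-1]
      if (!is.na(lab[j])) next
      lab[j] <- cid
      if (core[j]) stack <- c(stack, which(D[j, ] <= eps & is.na(lab) & core))
    }
  }
  ambiguous <- FALSE
  for (i in which(!core)) {
    nb <- which(D[i, ] <= eps & core)
    nb <- nb[nb != i]
    if (length(unique(lab[nb])) > 1L) ambiguous <- TRUE
    if (length(nb)) lab[i] <- lab[nb[1]]
  }
  list(lab = lab, core = core, ambiguous = ambiguous)
}

# Partition equality up to label permutation, with identical noise sets.
partitions_equal <- function(a, b) {
  na <- is.na(a)
  nb <- is.na(b)
  if (!all(na == nb)) return(FALSE)
  if (!any(!na)) return(TRUE)
  a2 <- a[!na]
  b2 <- b[!na]
  length(unique(paste(a2, b2))) == length(unique(a2)) &&
    length(unique(a2)) == length(unique(b2))
}

# Monte-Carlo rejection estimate of the disc/ellipse intersection area:
# sample uniformly in the disc, count the fraction landing on the field.
mc_clipped_area <- function(field, cx, cy, r, n = 1e6) {
  u <- stats::runif(n)
  th <- stats::runif(n, 0, 2 * pi)
  rr <- r * sqrt(u)
  x <- cx + rr * cos(th)
  y <- cy + rr * sin(th)
  pi * r^2 * mean((2 * x / field$length_m)^2 + (2 * y / field$width_m)^2 <= 1)
}

# Deterministic 1-D quadrature oracle for the same area: integrate the
# overlap of the vertical chords of disc and ellipse.
chord_clipped_area <- function(field, cx, cy, r, n = 4001) {
  a <- field$length_m / 2
  b <- field$width_m / 2
  lo <- max(cx - r, -a)
  hi <- min(cx + r, a)
  if (lo >= hi) return(0)
  xs <- seq(lo, hi, length.out = n)
  sd <- sqrt(pmax(0, r^2 - (xs - cx)^2))
  e <- b * sqrt(pmax(0, 1 - (xs / a)^2))
  len <- pmax(0, pmin(cy + sd, e) - pmax(cy - sd, -e))
  sum((len[-1] + len[-n]) / 2) * (xs[2] - xs[1])
}

# Brute-force recomputation of the nine disposal features using complex
# arithmetic for the quadrant bearings (clockwise from heading, right-closed
# bins) and the chord oracle for the available space.
brute_features <- function(snapshot, radii = feature_radii()) {
  p <- snapshot$players
  ci <- which(p$player_id == snapshot$carrier_id)[1]
  dx <- p$x[-ci] - p$x[ci]
  dy <- p$y[-ci] - p$y[ci]
  opp <- p$team[-ci] != p$team[ci]
  d <- sqrt(dx^2 + dy^2)
  h <- complex(real = snapshot$heading[1], imaginary = snapshot$heading[2])
  z <- complex(real = dx, imaginary = dy)
  cw <- -Arg(z * Conj(h)) * 180 / pi # clockwise bearing in (-180, 180]
  cw[cw <= -45 & !is.na(cw)] <- cw[cw <= -45 & !is.na(cw)] + 360
  inq <- d <= radii$quadrant
  degen <- dx == 0 & dy == 0
  qc <- c(
    FPC = sum(inq & (degen | (cw > -45 & cw <= 45))),
    RPC = sum(inq & !degen & cw > 45 & cw <= 135),
    LPC = sum(inq & !degen & cw > 225 & cw <= 315),
    BPC = sum(inq & !degen & cw > 135 & cw <= 225)
  )
  data.frame(
    IPC = sum(d <= radii$immediate),
    EPC = sum(d <= radii$extended),
    IDC = sum(d <= radii$immediate & opp),
    EDC = sum(d <= radii$extended & opp),
    FPC = unname(qc["FPC"]), RPC = unname(qc["RPC"]),
    LPC = unname(qc["LPC"]), BPC = unname(qc["BPC"]),
    AS = chord_clipped_area(
      snapshot$field, p$x[ci], p$y[ci], radii$available_space
    )
  )
}

# Random 36-player disposal-like snapshot with no placement constraints.
random_snapshot <- function(field = field_spec()) {
  a <- field$length_m / 2
  b <- field$width_m / 2
  x <- numeric(0)
  y <- numeric(0)
  while (length(x) < 36) {
    cx <- stats::runif(80, -a, a)
    cy <- stats::runif(80, -b, b)
    keep <- (cx / a)^2 + (cy / b)^2 <= 0.99
    x <- c(x, cx[keep])
    y <- c(y, cy[keep])
  }
  x <- x[1:36]
  y <- y[1:36]
  n <- 36L
  teams <- rep(c("home", "away"), length.out = n)
  players <- data.frame(
    player_id = sprintf("P%02d", seq_len(n)),
    team = sample(teams), x = round(x, 2), y = round(y, 2),
    stringsAsFactors = FALSE
  )
  th <- stats::runif(1, 0, 2 * pi)
  disposal_snapshot(
    t = 0, carrier_id = sample(players$player_id, 1), players = players,
    heading = c(cos(th), sin(th)),
    attack_sign = sample(c(-1, 1), 1), field = field
  )
}

# Small deterministic frame builder.
make_frame <- function(xy, teams = rep(c("home", "away"), length.out = nrow(xy))) {
  data.frame(
    player_id = sprintf("P%02d", seq_len(nrow(xy))),
    team = teams, x = xy[, 1], y = xy[, 2],
    stringsAsFactors = FALSE
  )
}
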