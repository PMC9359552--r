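## Synthetic matches and disposals with planted ground truth. The generator
## emulates the study conditions the congestion methods assume: 36 on-field
## players (18 per team, 44 tracked), a 159.5 m x 128.8 m oval, 10 Hz frames,
## a variable number of dense player groups per frame, and disposal
## snapshots realising the high / nearby / low label semantics. Separation
## margins are chosen so the planted structure is provably recoverable by
## the clustering at eps = 7.5 m (see the methods vignette).

#' Simulation configuration
#'
#' @param seed Integer master seed; every random draw of the generator is a
#'   function of it.
#' @param field A [field_spec()].
#' @param eps Clustering radius the margins are built around (metres).
#' @param sigma Within-group dispersion (metres, isotropic Gaussian,
#'   truncated at 2 sigma); must satisfy `sigma <= eps / 4` so that planted
#'   groups are mutually reachable.
#' @param frames_per_quarter Frames emitted per quarter (10 Hz).
#' @param passage_frames Frames per passage of play; positions are redrawn
#'   at passage boundaries and drift linearly inside one.
#' @param group_plan List of integer vectors; each passage draws one element
#'   as its group sizes (every size >= 4). The default plants a primary
#'   group of 9 players (a per-frame primary fraction of 0.25) with varying
#'   secondary structure.
#' @param drift_speed Range (m/s) of the constant-velocity drift applied to
#'   each group and each scattered player within a passage.
#' @param disposal_interval_s Seconds between scheduled disposals.
#' @param stoppages_per_quarter Number of umpire-possession stoppages.
#' @param scores_per_quarter Number of scoring events.
#' @param dropout_passages_per_quarter Passages in which one player's
#'   positions are omitted, so the affected frames fail admission.
#' @param label_mix Target proportions of high / nearby / low disposal
#'   labels (must sum to 1).
#' @param high_min_within_5 Minimum players within 5 m that operationalises
#'   "several" for a high-congestion disposal.
#' @param nearby_min_ring Minimum players in the 5-10 m ring for a
#'   nearby-congestion disposal.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, field = field_spec(), eps = 7.5, sigma = 1,
                       frames_per_quarter = 600L, passage_frames = 20L,
                       group_plan = list(c(9L, 5L), 9L, c(9L, 4L)),
                       drift_speed = c(0.5, 1.5),
                       disposal_interval_s = 2,
                       stoppages_per_quarter = 1L,
                       scores_per_quarter = 1L,
                       dropout_passages_per_quarter = 1L,
                       label_mix = c(high = 1 / 3, nearby = 1 / 3, low = 1 / 3),
                       high_min_within_5 = 4L,
                       nearby_min_ring = 2L) {
  stopifnot(
    sigma > 0, sigma <= eps / 4, frames_per_quarter >= passage_frames,
    abs(sum(label_mix) - 1) < 1e-9,
    all(vapply(group_plan, function(g) all(g >= 4L), logical(1)))
  )
  structure(
    list(
      seed = as.integer(seed), field = field, eps = eps, sigma = sigma,
      frames_per_quarter = as.integer(frames_per_quarter),
      passage_frames = as.integer(passage_frames),
      group_plan = group_plan, drift_speed = drift_speed,
      disposal_interval_s = disposal_interval_s,
      stoppages_per_quarter = as.integer(stoppages_per_quarter),
      scores_per_quarter = as.integer(scores_per_quarter),
      dropout_passages_per_quarter = as.integer(dropout_passages_per_quarter),
      label_mix = label_mix,
      high_min_within_5 = as.integer(high_min_within_5),
      nearby_min_ring = as.integer(nearby_min_ring)
    ),
    class = "sim_config"
  )
}

## Uniform point in the ellipse with semi-axes (a, b), by rejection.
.runif_ellipse <- function(a, b) {
  repeat {
    x <- stats::runif(1, -a, a)
    y <- stats::runif(1, -b, b)
    if ((x / a)^2 + (y / b)^2 <= 1) return(c(x, y))
  }
}

.player_ids <- function() {
  list(
    id = c(sprintf("H%02d", 1:18), sprintf("A%02d", 1:18)),
    team = rep(c("home", "away"), each = 18L)
  )
}

#' Simulate one 36-player frame with planted clusters
#'
#' Places the requested dense groups (isotropic Gaussians truncated at
#' 2 sigma, centroids separated by more than `2 * (eps + 3 * sigma)` and
#' kept off the boundary) and scatters the remaining players so that every
#' scattered player is more than `2 * eps` from everyone else. Under these
#' margins the clustering at radius `eps` provably recovers the planted
#' partition: group members are mutually within `eps`, and no two players
#' of different units are within `eps` of each other. Draws from the current
#' RNG state.
#'
#' @param field A [field_spec()].
#' @param group_sizes Integer vector of group sizes (each >= 4, so every
#'   member has at least 3 others within `eps`); may be empty.
#' @param sigma Within-group dispersion in metres (`<= eps / 4`).
#' @param eps Clustering radius the margins protect (metres).
#' @param n_players Total players in the frame.
#' @param boundary_margin Extra keep-off distance from the boundary for
#'   group centroids, on top of `2 * sigma`.
#' @param max_tries Rejection-sampling budget per placement.
#' @return List with `frame` (data frame `player_id`, `team`, `x`, `y`) and
#'   `membership` (planted cluster per row: 0-based group index, -1 for
#'   scattered players).
#' @export
simulate_frame <- function(field, group_sizes = c(9L, 5L), sigma = 1, eps = 7.5,
                           n_players = 36L, boundary_margin = 0.5,
                           max_tries = 5000L) {
  stopifnot(
    inherits(field, "field_spec"), sigma > 0, sigma <= eps / 4,
    all(group_sizes >= 4L), sum(group_sizes) <= n_players
  )
  a <- field$length_m / 2
  b <- field$width_m / 2
  cm <- 2 * sigma + boundary_margin
  sep <- 2 * (eps + 3 * sigma)

  centroids <- matrix(numeric(0), ncol = 2)
  for (g in seq_along(group_sizes)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      c_xy <- .runif_ellipse(a - cm, b - cm)
      if (nrow(centroids) == 0 ||
        all(sqrt((centroids[, 1] - c_xy[1])^2 + (centroids[, 2] - c_xy[2])^2) > sep)) {
        centroids <- rbind(centroids, c_xy)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("infeasible plan: cannot place group centroids", call. = FALSE)
  }

  pts <- matrix(numeric(0), ncol = 2)
  membership <- integer(0)
  for (g in seq_along(group_sizes)) {
    for (k in seq_len(group_sizes[g])) {
      repeat { # truncate the Gaussian at 2 sigma
        d_xy <- stats::rnorm(2, 0, sigma)
        if (sum(d_xy^2) <= (2 * sigma)^2) break
      }
      pts <- rbind(pts, centroids[g, ] + d_xy)
      membership <- c(membership, g - 1L)
    }
  }
  n_scatter <- n_players - sum(group_sizes)
  for (k in seq_len(n_scatter)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      p <- .runif_ellipse(a - boundary_margin, b - boundary_margin)
      if (nrow(pts) == 0 ||
        all(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) > 2 * eps)) {
        pts <- rbind(pts, p)
        membership <- c(membership, -1L)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("infeasible plan: cannot scatter remaining players", call. = FALSE)
  }

  ids <- .player_ids()
  perm <- sample.int(n_players) # detach planted structure from team identity
  frame <- data.frame(
    player_id = ids$id[perm], team = ids$team[perm],
    x = round(pts[, 1], 2), y = round(pts[, 2], 2),
    stringsAsFactors = FALSE
  )
  list(frame = frame, membership = membership, centroids = centroids)
}

#' Simulate one labelled disposal snapshot
#'
#' Places the ball-carrier and 35 surrounding players so that the snapshot
#' realises the requested congestion label: `high` puts at least
#' `high_min_within_5` players within 5 m of the carrier; `nearby` puts at
#' most one player within 5 m and at least `nearby_min_ring` in the 5-10 m
#' ring; `low` puts at most one player within 10 m and none within 5 m. All
#' remaining players are more than 15 m away. Teams are assigned at random
#' (17 teammates, 18 opponents) and the heading is a random unit vector.
#' Draws from the current RNG state.
#'
#' @param field A [field_spec()].
#' @param target `"high"`, `"nearby"` or `"low"`.
#' @param high_min_within_5,nearby_min_ring Label operationalisation, see
#'   [sim_config()].
#' @param n_players Total players including the carrier.
#' @param max_tries Rejection-sampling budget per placement.
#' @return List with `snapshot` (a [disposal_snapshot()]) and `truth`
#'   (`label`, `n_within_5`, `n_within_10`).
#' @export
simulate_disposal <- function(field, target = c("high", "nearby", "low"),
                              high_min_within_5 = 4L, nearby_min_ring = 2L,
                              n_players = 36L, max_tries = 5000L) {
  target <- match.arg(target)
  a <- field$length_m / 2
  b <- field$width_m / 2
  carrier <- .runif_ellipse(a - 1, b - 1)

  place_near <- function(r_min, r_max) {
    for (try in seq_len(max_tries)) {
      r <- stats::runif(1, r_min, r_max)
      th <- stats::runif(1, 0, 2 * pi)
      p <- carrier + r * c(cos(th), sin(th))
      if (field_contains(field, p[1], p[2])) return(p)
    }
    stop("cannot place neighbour inside field", call. = FALSE)
  }

  near <- list()
  if (target == "high") {
    n5 <- sample(high_min_within_5:(high_min_within_5 + 3L), 1)
    nring <- sample(0:3, 1)
    for (k in seq_len(n5)) near[[length(near) + 1L]] <- place_near(0.5, 4.9)
    for (k in seq_len(nring)) near[[length(near) + 1L]] <- place_near(5.1, 9.9)
  } else if (target == "nearby") {
    n5 <- sample(0:1, 1)
    nring <- sample(nearby_min_ring:(nearby_min_ring + 3L), 1)
    for (k in seq_len(n5)) near[[length(near) + 1L]] <- place_near(1.5, 4.9)
    for (k in seq_len(nring)) near[[length(near) + 1L]] <- place_near(5.1, 9.9)
  } else {
    n10 <- sample(0:1, 1)
    for (k in seq_len(n10)) near[[length(near) + 1L]] <- place_near(5.5, 9.9)
  }

  pts <- rbind(carrier, do.call(rbind, near))
  n_far <- n_players - nrow(pts)
  for (k in seq_len(n_far)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      p <- .runif_ellipse(a - 0.5, b - 0.5)
      if (sqrt(sum((p - carrier)^2)) > 15) {
        pts <- rbind(pts, p)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("cannot place distant players", call. = FALSE)
  }

  ids <- .player_ids()
  perm <- sample.int(n_players)
  players <- data.frame(
    player_id = ids$id[perm], team = ids$team[perm],
    x = round(pts[, 1], 2), y = round(pts[, 2], 2),
    stringsAsFactors = FALSE
  )
  th <- stats::runif(1, 0, 2 * pi)
  carrier_team <- players$team[1]
  snap <- disposal_snapshot(
    t = 0, carrier_id = players$player_id[1], players = players,
    heading = c(cos(th), sin(th)),
    attack_sign = if (carrier_team == "home") 1 else -1,
    field = field
  )
  d <- sqrt((players$x[-1] - players$x[1])^2 + (players$y[-1] - players$y[1])^2)
  list(
    snapshot = snap,
    truth = list(
      label = target,
      n_within_5 = sum(d <= 5),
      n_within_10 = sum(d <= 10)
    )
  )
}

#' Simulate a labelled disposal dataset
#'
#' Generates `n` disposal snapshots whose labels follow `label_mix` (exact
#' class counts by the floor rule, remainders to the largest fractional
#' shares), extracts the nine features for each, and shuffles the order.
#'
#' @param n Number of disposals.
#' @param config A [sim_config()]; supplies the seed, field and label
#'   semantics.
#' @param radii A [feature_radii()].
#' @return List with `features` (n x 9 data frame), `labels` (factor with
#'   levels high / nearby / low), `snapshots` (list) and `truth` (list).
#' @export
simulate_disposals <- function(n, config = sim_config(), radii = feature_radii()) {
  mix <- config$label_mix
  classes <- c("high", "nearby", "low")
  raw <- n * mix[classes]
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(-(raw - base), seq_along(classes))[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  targets <- rep(classes, times = base)
  .with_seed(config$seed, {
    targets <- sample(targets)
    out <- lapply(targets, function(tg) {
      simulate_disposal(
        config$field, tg,
        high_min_within_5 = config$high_min_within_5,
        nearby_min_ring = config$nearby_min_ring
      )
    })
  })
  features <- do.call(rbind, lapply(out, function(o) extract_features(o$snapshot, radii)))
  list(
    features = features,
    labels = factor(targets, levels = classes),
    snapshots = lapply(out, `[[`, "snapshot"),
    truth = lapply(out, `[[`, "truth")
  )
}

#' Synthetic data for studying feature elimination
#'
#' Builds a three-class dataset in which the class signal is spread across
#' `n_informative` features in a "sparse carrier" design. Each informative
#' feature is tied to a *pair* of classes (round-robin over the three class
#' pairs); each sample picks one informative feature at random and only that
#' feature fires, at level 5 for the first class of the pair or 9 for the
#' second, against a standard-normal background. Every informative feature
#' is therefore individually necessary: removing one leaves its samples
#' with no signal at all, and because those samples span two classes, no
#' classifier can recover them from the remaining columns. An appended
#' pure-noise column carries no signal and should be eliminated first.
#' One-sided firing keeps the dataset learnable under shallow,
#' strongly-regularised trees.
#'
#' @param n Number of samples.
#' @param n_informative Number of informative features (>= 3).
#' @param noise_feature Append a pure-noise column named `NOISE`?
#' @param seed Integer seed.
#' @return List with `x` (data frame) and `y` (factor with three levels).
#' @export
simulate_elimination_data <- function(n, n_informative = 8L,
                                      noise_feature = TRUE, seed = 1L) {
  stopifnot(n_informative >= 3L)
  .with_seed(seed, {
    classes <- c("high", "nearby", "low")
    pairs <- list(
      c("high", "nearby"), c("nearby", "low"), c("low", "high")
    )
    feature_pair <- rep_len(pairs, n_informative)
    carrier <- sample.int(n_informative, n, replace = TRUE)
    side <- sample.int(2L, n, replace = TRUE)
    y <- vapply(seq_len(n), function(i) feature_pair[[carrier[i]]][side[i]], character(1))
    x <- matrix(stats::rnorm(n * n_informative), nrow = n)
    x[cbind(seq_len(n), carrier)] <- c(5, 9)[side] + stats::rnorm(n, 0, 0.3)
    colnames(x) <- sprintf("F%d", seq_len(n_informative))
    x <- as.data.frame(x)
    if (noise_feature) x$NOISE <- stats::rnorm(n)
    list(x = x, y = factor(y, levels = classes))
  })
}
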