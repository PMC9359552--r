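#' Density-clustering parameters
#'
#' Holds the two parameters of the per-frame congestion clustering: the
#' neighbourhood radius and the minimum number of *additional* players that
#' must fall inside it for a player to be a core point. The neighbourhood is
#' closed (distance <= eps) and never includes the player itself, so
#' `min_additional = 3` corresponds to a conventional MinPts of 4 when the
#' point itself is counted.
#'
#' @param eps Neighbourhood radius in metres (default 7.5).
#' @param min_additional Minimum number of other players within `eps` for
#'   core status (default 3).
#' @return An object of class `clustering_params`.
#' @export
clustering_params <- function(eps = 7.5, min_additional = 3L) {
  stopifnot(is.numeric(eps), eps > 0, min_additional >= 1)
  structure(
    list(eps = as.numeric(eps), min_additional = as.integer(min_additional)),
    class = "clustering_params"
  )
}

#' Core distance of a player
#'
#' Distance from `p` to its `min_additional`-th nearest other player, or
#' `NA` (UNDEFINED) when fewer than `min_additional` other players lie within
#' `eps` of `p`. When defined, the core distance never exceeds `eps`.
#'
#' @param p Numeric length-2 position of the player (metres).
#' @param others Two-column matrix of the other players' positions; must not
#'   include `p`.
#' @param params A [clustering_params()].
#' @return Core distance in metres, or `NA_real_` if undefined.
#' @export
core_distance <- function(p, others, params = clustering_params()) {
  d <- sqrt((others[, 1] - p[1])^2 + (others[, 2] - p[2])^2)
  within <- d[d <= params$eps]
  if (length(within) < params$min_additional) return(NA_real_)
  sort(within, partial = params$min_additional)[params$min_additional]
}

#' Reachability distance of o from p
#'
#' `max(core_distance(p), dist(o, p))` when `p` is a core point, `NA`
#' (UNDEFINED) otherwise. `others` is the set of players other than `p`
#' (it may contain `o`), used to establish `p`'s core distance.
#'
#' @param o,p Numeric length-2 positions (metres).
#' @param others Two-column matrix of positions excluding `p`.
#' @param params A [clustering_params()].
#' @return Reachability distance in metres, or `NA_real_` if undefined.
#' @export
reachability_distance <- function(o, p, others, params = clustering_params()) {
  cd <- core_distance(p, others, params)
  if (is.na(cd)) return(NA_real_)
  max(cd, sqrt(sum((o - p)^2)))
}

#' Cluster one frame of player positions
#'
#' Runs OPTICS over the players of a single frame with maximum radius `eps`
#' and extracts clusters at the `eps` threshold (DBSCAN-equivalent): core
#' points transitively within `eps` of each other share a cluster; non-core
#' points within `eps` of a core point join that core's cluster as border
#' points; everything else is noise. The result is deterministic: the seed
#' order is players sorted by (team, player_id), and priority-queue ties are
#' broken by that same order. A border point reachable from cores of two
#' clusters attaches to the cluster that reaches it first in the OPTICS
#' ordering.
#'
#' @param frame Data frame with columns `player_id`, `team`, `x`, `y`
#'   (one row per on-field player).
#' @param params A [clustering_params()].
#' @return A data frame of class `cluster_assignment` with one row per input
#'   player (original row order preserved): `player_id`, `team`, `x`, `y`,
#'   `order_index` (position in the OPTICS ordering), `core` (logical),
#'   `core_distance`, `reachability` (both `NA` when undefined) and
#'   `cluster_id` (0-based contiguous integers; `NA` for noise).
#' @export
cluster_frame <- function(frame, params = clustering_params()) {
  stopifnot(all(c("player_id", "team", "x", "y") %in% names(frame)))
  n <- nrow(frame)
  seed <- order(frame$team, frame$player_id)
  xy <- cbind(frame$x, frame$y)[seed, , drop = FALSE]
  eps <- params$eps
  m <- params$min_additional

  if (n < m + 1L) {
    out <- data.frame(
      player_id = frame$player_id, team = frame$team,
      x = frame$x, y = frame$y,
      order_index = order(seed), core = FALSE,
      core_distance = NA_real_, reachability = NA_real_,
      cluster_id = NA_integer_, stringsAsFactors = FALSE
    )
    class(out) <- c("cluster_assignment", "data.frame")
    return(out)
  }

  D <- as.matrix(stats::dist(xy))
  core_dist <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    within <- d[d <= eps]
    if (length(within) < m) NA_real_ else sort(within)[m]
  }, numeric(1))
  is_core <- !is.na(core_dist)

  processed <- logical(n)
  reach <- rep(NA_real_, n)
  ord <- integer(0)

  update_seeds <- function(p, rq) {
    nb <- which(D[p, ] <= eps & !processed)
    nb <- nb[nb != p]
    newr <- pmax(core_dist[p], D[p, nb])
    better <- newr < rq[nb]
    rq[nb[better]] <- newr[better]
    rq
  }

  for (s in seq_len(n)) {
    if (processed[s]) next
    processed[s] <- TRUE
    ord <- c(ord, s)
    rq <- rep(Inf, n) # candidate reachabilities for this expansion
    if (is_core[s]) rq <- update_seeds(s, rq)
    repeat {
      cand <- which(!processed & is.finite(rq))
      if (!length(cand)) break
      j <- cand[which.min(rq[cand])] # which.min takes the first => tie by seed order
      processed[j] <- TRUE
      reach[j] <- rq[j]
      ord <- c(ord, j)
      if (is_core[j]) rq <- update_seeds(j, rq)
    }
  }

  # eps-threshold extraction along the ordering
  cluster <- rep(NA_integer_, n)
  cid <- -1L
  for (k in ord) {
    r <- reach[k]
    if (is.na(r) || r > eps) {
      if (is_core[k]) {
        cid <- cid + 1L
        cluster[k] <- cid
      } # else noise
    } else {
      cluster[k] <- cid
    }
  }

  # border attachment: a non-core point visited by the seed loop before its
  # cluster's cores is expanded has no reachability yet is within eps of a
  # core; it is a cluster member, attached to the cluster whose in-range
  # core appears earliest in the ordering
  ord_pos <- integer(n)
  ord_pos[ord] <- seq_len(n)
  for (k in which(is.na(cluster))) {
    in_range_cores <- which(is_core & D[k, ] <= eps)
    in_range_cores <- in_range_cores[in_range_cores != k]
    if (length(in_range_cores)) {
      first <- in_range_cores[which.min(ord_pos[in_range_cores])]
      cluster[k] <- cluster[first]
    }
  }

  inv <- integer(n)
  inv[seed] <- seq_len(n) # row in seed space for each original row
  order_index <- integer(n)
  order_index[ord] <- seq_len(n)

  out <- data.frame(
    player_id = frame$player_id, team = frame$team,
    x = frame$x, y = frame$y,
    order_index = order_index[inv],
    core = is_core[inv],
    core_distance = core_dist[inv],
    reachability = reach[inv],
    cluster_id = cluster[inv],
    stringsAsFactors = FALSE
  )
  class(out) <- c("cluster_assignment", "data.frame")
  out
}

#' Translate raw cluster ids into congestion labels
#'
#' The cluster with the most players becomes *primary* congestion; every
#' other cluster becomes *secondary* congestion (indexed 1, 2, ... by
#' descending size); noise becomes *outside* congestion. When two clusters
#' have equal size, the one whose earliest OPTICS ordering index is smaller
#' wins, which makes the labelling deterministic.
#'
#' @param assignment A `cluster_assignment` from [cluster_frame()].
#' @return The assignment with columns `label` (factor primary / secondary /
#'   outside), `secondary_index` (`NA` unless secondary) and `cluster_size`
#'   (`NA` for outside) appended.
#' @export
translate_labels <- function(assignment) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  lab <- rep("outside", nrow(assignment))
  sec_idx <- rep(NA_integer_, nrow(assignment))
  size <- rep(NA_integer_, nrow(assignment))
  cl <- assignment$cluster_id
  if (any(!is.na(cl))) {
    ids <- sort(unique(cl[!is.na(cl)]))
    sizes <- vapply(ids, function(k) sum(cl == k, na.rm = TRUE), integer(1))
    first_ord <- vapply(ids, function(k) {
      min(assignment$order_index[!is.na(cl) & cl == k])
    }, integer(1))
    rank_order <- order(-sizes, first_ord)
    primary <- ids[rank_order[1]]
    lab[!is.na(cl) & cl == primary] <- "primary"
    if (length(ids) > 1L) {
      secs <- ids[rank_order[-1]]
      for (i in seq_along(secs)) {
        sel <- !is.na(cl) & cl == secs[i]
        lab[sel] <- "secondary"
        sec_idx[sel] <- i
      }
    }
    for (i in seq_along(ids)) {
      size[!is.na(cl) & cl == ids[i]] <- sizes[i]
    }
  }
  assignment$label <- factor(lab, levels = c("primary", "secondary", "outside"))
  assignment$secondary_index <- sec_idx
  assignment$cluster_size <- size
  assignment
}
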