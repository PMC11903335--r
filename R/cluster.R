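#' Single DBSCAN pass over superposition vectors
#'
#' DBSCAN with `minPts = 2`: a point is a core point when it has at
#' least one other point within `epsilon` (at least two neighbours
#' including itself). Clusters are grown from core points by core-point
#' expansion; non-core neighbours are attached to the first cluster that
#' reaches them, without expanding through them; points with no
#' neighbour stay unclustered. The starting core point of each cluster
#' is the lowest-index unvisited core point, which makes the pass
#' deterministic (set `random_core_start` in [mm_config()] to restore a
#' randomized start for robustness experiments).
#'
#' @param points Numeric n x k matrix (n >= 2), typically the normalized
#'   superposition matrix. A zero-column matrix means all points are at
#'   mutual distance 0.
#' @param epsilon Neighbourhood radius (inclusive).
#' @param config An [mm_config()].
#' @return List of clusters, each a list with `members` (sorted row
#'   indices) and `seed` (the initiating core point's row index).
#' @export
dbscan_once <- function(points, epsilon, config = mm_config()) {
  n <- nrow(points)
  if (n < 2L) stop("DBSCAN needs at least 2 points")
  d <- as.matrix(stats::dist(points))
  if (ncol(points) == 0L) d[] <- 0
  nb <- d <= epsilon  # n x n neighbour relation, includes self
  is_core <- rowSums(nb) >= 2L
  visited <- rep(FALSE, n)
  clusters <- list()
  core_order <- which(is_core)
  if (config$random_core_start) core_order <- sample(core_order)
  for (start in core_order) {
    if (visited[start]) next
    members <- integer(0)
    frontier <- start
    visited[start] <- TRUE
    while (length(frontier) > 0L) {
      members <- c(members, frontier)
      nxt <- unique(unlist(lapply(frontier, function(i) which(nb[i, ]))))
      nxt <- nxt[is_core[nxt] & !visited[nxt]]
      visited[nxt] <- TRUE
      frontier <- nxt
    }
    border <- unique(unlist(lapply(members, function(i) which(nb[i, ]))))
    border <- border[!is_core[border] & !visited[border]]
    visited[border] <- TRUE
    clusters[[length(clusters) + 1L]] <-
      list(members = sort(c(members, border)), seed = start)
  }
  clusters
}

# chain-usage table for a set of matrix rows
row_chain_pairs <- function(rows, alignments) {
  q <- vapply(alignments[rows], function(a) a$query_chain_index, integer(1))
  t <- vapply(alignments[rows], function(a) a$target_chain_index, integer(1))
  cbind(query = q, target = t)
}

cluster_is_valid <- function(rows, alignments) {
  cp <- row_chain_pairs(rows, alignments)
  !anyDuplicated(cp[, 1]) && !anyDuplicated(cp[, 2])
}

#' Rescue a chain-reusing cluster
#'
#' A cluster of superposition vectors is a valid chain assignment only if
#' no query chain and no target chain occurs in two of its alignments.
#' An invalid cluster is rescued by admitting its points in increasing
#' distance from the initiating core point (the seed itself first, at
#' distance 0); admission *stops* at the first point that reuses an
#' already-admitted chain — later compatible points are not picked up.
#'
#' @param cluster A cluster from [dbscan_once()] (`members`, `seed`).
#' @param alignments The chain alignments the matrix rows refer to.
#' @param points The matrix the cluster was found in (for seed
#'   distances).
#' @return A `cluster_candidate`: list with `member_rows`, `seed_row`,
#'   `size`.
#' @export
rescue_valid_subgroup <- function(cluster, alignments, points) {
  rows <- cluster$members
  if (cluster_is_valid(rows, alignments)) {
    return(structure(list(member_rows = sort(rows), seed_row = cluster$seed,
                          size = length(rows)),
                     class = "cluster_candidate"))
  }
  if (ncol(points) == 0L) {
    dist_to_seed <- rep(0, length(rows))
  } else {
    dif <- sweep(points[rows, , drop = FALSE], 2, points[cluster$seed, ])
    dist_to_seed <- sqrt(rowSums(dif^2))
  }
  ord <- rows[order(dist_to_seed, rows)]  # seed first (distance 0); ties by index
  used_q <- integer(0)
  used_t <- integer(0)
  admitted <- integer(0)
  for (r in ord) {
    a <- alignments[[r]]
    if (a$query_chain_index %in% used_q || a$target_chain_index %in% used_t)
      break  # stop, do not skip
    admitted <- c(admitted, r)
    used_q <- c(used_q, a$query_chain_index)
    used_t <- c(used_t, a$target_chain_index)
  }
  structure(list(member_rows = sort(admitted), seed_row = cluster$seed,
                 size = length(admitted)),
            class = "cluster_candidate")
}

#' @export
print.cluster_candidate <- function(x, ...) {
  cat(sprintf("<cluster_candidate> size %d, rows {%s}, seed %d\n",
              x$size, paste(x$member_rows, collapse = ","), x$seed_row))
  invisible(x)
}

candidate_pairing_key <- function(cand, alignments) {
  cp <- row_chain_pairs(cand$member_rows, alignments)
  paste(sort(paste(cp[, 1], cp[, 2], sep = ":")), collapse = ",")
}

#' Iterative DBSCAN over a superposition matrix
#'
#' Runs [dbscan_once()] on the normalized superposition vectors at an
#' increasing radius: epsilon starts at the minimum pairwise distance
#' (minDist) and grows by `epsilon_delta` (default 0.1) up to the
#' maximum pairwise distance (maxDist), inclusive. After each pass every
#' cluster is validity-checked and rescued ([rescue_valid_subgroup()]);
#' rescued clusters at least as large as the current best size are added
#' to the candidate list, and whenever a strictly larger one appears the
#' best size is updated and smaller candidates are purged. Iteration
#' stops early when no larger or additional distinct cluster can exist
#' (best size equals `min(c_q, c_t)` and the candidate list has reached
#' `max(c_q, c_t)` entries), or when a pass yields no cluster at least
#' as large as the best once candidates exist. Candidates describing the
#' same chain pairing are kept once. A single-row matrix bypasses
#' clustering and returns that row as a size-1 candidate.
#'
#' @param m A prepared [normalize_columns()] superposition matrix.
#' @param c_q,c_t Chain counts of the query and target complex.
#' @param config An [mm_config()].
#' @return List of `cluster_candidate`s, all of the maximal valid size.
#' @export
iterative_cluster <- function(m, c_q, c_t, config = mm_config()) {
  alignments <- m$alignment_refs
  n <- nrow(m$rows)
  if (n == 1L) {
    return(list(structure(list(member_rows = 1L, seed_row = 1L, size = 1L),
                          class = "cluster_candidate")))
  }
  pts <- m$normalized
  d <- stats::dist(pts)
  if (ncol(pts) == 0L) d[] <- 0
  min_dist <- min(d)
  max_dist <- max(d)
  max_size <- 0L
  candidates <- list()
  keys <- character(0)
  epsilon <- min_dist
  repeat {
    raw <- dbscan_once(pts, epsilon, config)
    rescued <- lapply(raw, rescue_valid_subgroup, alignments = alignments,
                      points = pts)
    sizes <- vapply(rescued, function(x) x$size, integer(1))
    for (cand in rescued[order(-sizes)]) {
      if (cand$size < max_size || cand$size == 0L) next
      if (cand$size > max_size) {
        max_size <- cand$size
        candidates <- list()
        keys <- character(0)
      }
      key <- candidate_pairing_key(cand, alignments)
      if (key %in% keys) next
      cand$epsilon_found <- epsilon
      candidates <- c(candidates, list(cand))
      keys <- c(keys, key)
    }
    # early stop: no bigger valid cluster, and no further distinct ones
    if (max_size == min(c_q, c_t) && length(candidates) >= max(c_q, c_t))
      break
    # all of this pass's clusters smaller than the best: nothing to gain
    if (length(candidates) > 0L &&
        (length(sizes) == 0L || max(sizes) < max_size))
      break
    epsilon <- epsilon + config$epsilon_delta
    if (epsilon > max_dist + 1e-12) break
  }
  candidates
}
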