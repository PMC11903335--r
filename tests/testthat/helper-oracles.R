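# Independent oracles used across the suite. Each reimplements the
# quantity it checks by a different route than the package code.

# Closed-form least-squares superposition by Horn's quaternion method
# (eigenvector of the 4x4 profile matrix) -- independent of the SVD
# route used by the package.
horn_superpose <- function(q, t) {
  qc <- colMeans(q)
  tc <- colMeans(t)
  Qc <- sweep(q, 2, qc)
  Tc <- sweep(t, 2, tc)
  M <- t(Tc) %*% Qc  # M[a, b] = sum_i t_ia * q_ib
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
                Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
                Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
                Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz),
              4, 4, byrow = TRUE)
  qv <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- qv[1]; x <- qv[2]; y <- qv[3]; z <- qv[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
              3, 3, byrow = TRUE)
  tr <- qc - as.numeric(R %*% tc)
  fit <- sweep(t %*% t(R), 2, tr, "+")
  list(R = R, t = tr, rmsd = sqrt(mean(rowSums((q - fit)^2))))
}

# Naive order-free reference DBSCAN with minPts = 2: core components by
# union-find over the core-core neighbour graph; border points attach to
# the component (among those containing a core neighbour) whose minimal
# core index is smallest -- i.e. to the cluster that is built first.
naive_dbscan <- function(points, eps) {
  n <- nrow(points)
  d <- as.matrix(stats::dist(points))
  if (ncol(points) == 0) d[] <- 0
  nb <- d <= eps
  dimnames(nb) <- NULL
  core <- which(rowSums(nb) >= 2)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in core) for (b in core) if (a < b && nb[a, b]) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  comp <- vapply(core, find, integer(1))
  clusters <- lapply(sort(unique(comp)), function(r) core[comp == r])
  border <- setdiff(which(rowSums(nb) >= 1), core)
  assigned <- lapply(clusters, identity)
  for (b in border) {
    hit <- which(vapply(clusters, function(cl) any(nb[b, cl]), logical(1)))
    if (length(hit) > 0) {
      k <- hit[which.min(vapply(clusters[hit], min, integer(1)))]
      assigned[[k]] <- c(assigned[[k]], b)
    }
  }
  lapply(assigned, function(x) unname(sort(x)))
}

# Exhaustive-seed TM-score oracle over paired coordinates: every
# contiguous fragment of every length >= 5 seeds a Horn superposition,
# refined by the distance-subset iteration, all in plain R.
tm_oracle_sum <- function(Qp, Tp, d0, min_len = 5) {
  n <- nrow(Qp)
  dcut2 <- max(d0, 4.5)^2
  best <- -1
  for (l in seq(min_len, n)) {
    for (s in seq_len(n - l + 1)) {
      sub <- s:(s + l - 1)
      for (it in 1:30) {
        fit <- horn_superpose(Qp[sub, , drop = FALSE], Tp[sub, , drop = FALSE])
        Tt <- sweep(Tp %*% t(fit$R), 2, fit$t, "+")
        d2 <- rowSums((Qp - Tt)^2)
        best <- max(best, sum(1 / (1 + d2 / d0^2)))
        nsub <- which(d2 < dcut2)
        if (length(nsub) < 3 || identical(nsub, sub)) break
        sub <- nsub
      }
      if (l == n) break
    }
  }
  best
}

# All permutations of 1:n as rows of a matrix.
perm_mat <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- perm_mat(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) cbind(k, p + (p >= k))))
}

# Minimal candidate wrapper for score_assignment.
as_candidate <- function(rows) {
  structure(list(member_rows = rows, seed_row = rows[1],
                 size = length(rows)), class = "cluster_candidate")
}

# All chain-to-chain alignments of a complex pair, ordered query-major.
all_chain_alignments <- function(Q, T, config = mm_config()) {
  alns <- list()
  for (i in seq_along(Q$chains)) {
    for (j in seq_along(T$chains)) {
      a <- align_chains(Q$chains[[i]], T$chains[[j]], config,
                        query_chain_index = i, target_chain_index = j)
      if (!is.null(a)) alns[[length(alns) + 1L]] <- a
    }
  }
  alns
}

# Exhaustive argmax-TM chain pairing over all complete injective
# mappings, each scored with score_assignment. Returns the best mapping
# (target index per query chain), its score, and all scores.
brute_force_pairing <- function(Q, T, alns) {
  n <- length(Q$chains)
  stopifnot(length(T$chains) == n)
  key <- vapply(alns, function(a)
    paste(a$query_chain_index, a$target_chain_index), character(1))
  P <- perm_mat(n)
  scores <- rep(NA_real_, nrow(P))
  for (r in seq_len(nrow(P))) {
    rows <- match(paste(seq_len(n), P[r, ]), key)
    if (anyNA(rows)) next
    ca <- score_assignment(Q, T, as_candidate(rows), alns)
    scores[r] <- ca$tm_query_norm + ca$tm_target_norm
  }
  best <- which.max(scores)
  list(mapping = P[best, ], score = scores[best], scores = scores, perms = P)
}

# Pairing of a complex_alignment as a canonical string.
pairing_string <- function(a) {
  if (is.data.frame(a)) {
    paste(sort(paste(a$query, a$target, sep = ":")), collapse = ",")
  } else {
    paste(sort(paste(a$chain_pairs[, 1], a$chain_pairs[, 2], sep = ":")),
          collapse = ",")
  }
}

# Deterministic random rigid transform for test loops.
with_seed_transform <- function(seed) {
  set.seed(seed)
  rigid_transform(random_rotation(), rnorm(3, sd = 10))
}

# All inter-point distances between two coordinate sets.
dist_between <- function(a, b) {
  sqrt(pmax(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b), 0))
}
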