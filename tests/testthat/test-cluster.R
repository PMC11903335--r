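fake_row_alignment <- function(qi, ti) {
  structure(list(query_chain_index = as.integer(qi),
                 target_chain_index = as.integer(ti),
                 pairs = cbind(query = 1:3, target = 1:3),
                 transform = identity_transform(),
                 tm_query_norm = 1, tm_target_norm = 1),
            class = "chain_alignment")
}

test_that("dbscan separates distant pairs and finds no cluster without neighbours", {
  pts <- matrix(c(0, 0.05, 9, 9.05), 4, 1)
  cl <- dbscan_once(pts, 0.1)
  expect_equal(lapply(cl, `[[`, "members"), list(1:2, 3:4))

  spread <- matrix(c(0, 10, 20, 30), 4, 1)
  expect_equal(length(dbscan_once(spread, 1)), 0L)
})

test_that("clusters grow transitively through chains of core points", {
  # consecutive 0.4-spaced points chain into one cluster even though the
  # ends are far apart; the isolated point 4 stays unclustered
  pts <- matrix(c(0, 0.4, 0.8, 3.0), 4, 1)
  cl <- dbscan_once(pts, 0.45)
  expect_equal(lapply(cl, `[[`, "members"), list(1:3))
  expect_equal(cl[[1]]$seed, 1L)  # lowest-index core starts the cluster
})

test_that("dbscan memberships match a naive O(n^2) reference", {
  set.seed(404)
  for (k in 1:30) {
    n <- sample(8:30, 1)
    pts <- matrix(rnorm(n * 3, sd = 1.2), n, 3)
    for (eps in c(0.3, 0.6, 1.0, 1.8)) {
      got <- lapply(dbscan_once(pts, eps), `[[`, "members")
      ref <- naive_dbscan(pts, eps)
      expect_equal(got, ref)
    }
  }
})

test_that("rescue keeps valid clusters untouched", {
  alns <- list(fake_row_alignment(1, 1), fake_row_alignment(2, 2),
               fake_row_alignment(3, 3))
  pts <- matrix(rnorm(9), 3, 3)
  cand <- rescue_valid_subgroup(list(members = 1:3, seed = 2), alns, pts)
  expect_equal(cand$member_rows, 1:3)
  expect_equal(cand$size, 3L)
})

test_that("rescue admits by seed distance and STOPS at first chain reuse", {
  # rows: (qA:tA), (qB:tB), (qA:tC) at seed distances 0, 1, 2
  alns <- list(fake_row_alignment(1, 1), fake_row_alignment(2, 2),
               fake_row_alignment(1, 3))
  pts <- matrix(c(0, 1, 2), 3, 1)
  cand <- rescue_valid_subgroup(list(members = 1:3, seed = 1), alns, pts)
  expect_equal(cand$member_rows, c(1L, 2L))

  # rows: (qA:tA), (qA:tC), (qB:tB): stop at the second point -- the
  # compatible third point is NOT picked up (stop, not skip)
  alns2 <- list(fake_row_alignment(1, 1), fake_row_alignment(1, 3),
                fake_row_alignment(2, 2))
  cand2 <- rescue_valid_subgroup(list(members = 1:3, seed = 1), alns2, pts)
  expect_equal(cand2$member_rows, 1L)
})

test_that("iterative clustering recovers the planted dimer pairing", {
  fx <- random_fixture_pair(66, n_chains = 2, noise_sigma = 0.5)
  alns <- all_chain_alignments(fx$query, fx$target)
  m <- multimeralign:::prepare_matrix(alns)
  cands <- iterative_cluster(m, 2, 2)
  expect_true(length(cands) >= 1)
  expect_equal(cands[[1]]$size, 2L)
  got <- score_assignment(fx$query, fx$target, cands[[1]], alns)
  expect_equal(pairing_string(got), pairing_string(fx$pairing))
})

test_that("1 query chain vs 3 distant target chains: size-1 candidates, bounded list", {
  alns <- list(fake_row_alignment(1, 1), fake_row_alignment(1, 2),
               fake_row_alignment(1, 3))
  m <- build_matrix(alns)
  # plant mutually distant rows
  m$rows[1, 10:12] <- c(0, 0, 0)
  m$rows[2, 10:12] <- c(50, 0, 0)
  m$rows[3, 10:12] <- c(0, 50, 0)
  m <- normalize_columns(filter_columns(m))
  cands <- iterative_cluster(m, 1, 3)
  # with one query chain every valid cluster has size 1 = C_Q, and the
  # candidate list can never exceed C_T = 3; under the deterministic
  # lowest-index seed rule every rescue of a merged cluster returns the
  # same lowest row, so exactly that pairing is recorded
  sizes <- vapply(cands, function(x) x$size, integer(1))
  expect_true(all(sizes == 1L))
  expect_lte(length(cands), 3L)
  expect_gte(length(cands), 1L)
})

test_that("identical rows fall back to one all-member candidate", {
  alns <- list(fake_row_alignment(1, 1), fake_row_alignment(2, 2))
  m <- build_matrix(alns)  # identical identity transforms
  m <- normalize_columns(filter_columns(m))
  expect_equal(ncol(m$normalized), 0L)
  cands <- iterative_cluster(m, 2, 2)
  expect_equal(length(cands), 1L)
  expect_equal(cands[[1]]$member_rows, 1:2)
})

test_that("single-row matrices bypass clustering", {
  alns <- list(fake_row_alignment(1, 1))
  m <- multimeralign:::prepare_matrix(alns)
  cands <- iterative_cluster(m, 1, 1)
  expect_equal(length(cands), 1L)
  expect_equal(cands[[1]]$member_rows, 1L)
})

test_that("all candidates are valid one-to-one pairings of maximal size", {
  for (seed in c(91, 92, 93, 94, 95)) {
    fx <- random_fixture_pair(seed, noise_sigma = 1)
    alns <- all_chain_alignments(fx$query, fx$target)
    m <- multimeralign:::prepare_matrix(alns)
    cands <- iterative_cluster(m, length(fx$query$chains),
                               length(fx$target$chains))
    sizes <- vapply(cands, function(x) x$size, integer(1))
    expect_true(all(sizes == max(sizes)))
    for (cand in cands) {
      cp <- t(vapply(alns[cand$member_rows], function(a)
        c(a$query_chain_index, a$target_chain_index), integer(2)))
      expect_false(any(duplicated(cp[, 1])))
      expect_false(any(duplicated(cp[, 2])))
      expect_lte(cand$size, min(length(fx$query$chains),
                                length(fx$target$chains)))
    }
  }
})

test_that("clustering is deterministic across repeated runs", {
  fx <- random_fixture_pair(77, noise_sigma = 0.5)
  alns <- all_chain_alignments(fx$query, fx$target)
  m <- multimeralign:::prepare_matrix(alns)
  c1 <- iterative_cluster(m, length(fx$query$chains),
                          length(fx$target$chains))
  c2 <- iterative_cluster(m, length(fx$query$chains),
                          length(fx$target$chains))
  expect_identical(c1, c2)
})

test_that("candidate sizes are maximal over a brute-force epsilon sweep", {
  # oracle: run dbscan_once at every pairwise distance and rescue every
  # cluster; no valid cluster anywhere may beat the returned size
  for (seed in c(111, 112, 113)) {
    fx <- random_fixture_pair(seed, noise_sigma = 1)
    alns <- all_chain_alignments(fx$query, fx$target)
    m <- multimeralign:::prepare_matrix(alns)
    cands <- iterative_cluster(m, length(fx$query$chains),
                               length(fx$target$chains))
    got_size <- max(vapply(cands, function(x) x$size, integer(1)))
    pts <- m$normalized
    best_ref <- 0L
    for (eps in unique(as.numeric(stats::dist(pts)))) {
      for (cl in dbscan_once(pts, eps)) {
        r <- rescue_valid_subgroup(cl, alns, pts)
        best_ref <- max(best_ref, r$size)
      }
    }
    expect_gte(got_size, best_ref)
  }
})
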