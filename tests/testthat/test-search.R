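test_that("pairwise mode recovers a homodimer pair with high TM", {
  fx <- random_fixture_pair(201, n_chains = 2, noise_sigma = 0.5)
  a <- align_pair(fx$query, fx$target)
  expect_equal(nrow(a$chain_pairs), 2L)
  expect_gt(max(a$tm_query_norm, a$tm_target_norm), 0.9)
  expect_equal(pairing_string(a), pairing_string(fx$pairing))
})

test_that("unrelated complexes score below the 0.65 cutoff but are reported", {
  below <- 0L
  n <- 10L
  for (seed in seq_len(n)) {
    q <- random_fixture_pair(seed + 300, n_chains = 2, noise_sigma = 0)$query
    t <- random_fixture_pair(seed + 350, n_chains = 2, noise_sigma = 0)$query
    a <- align_pair(q, t)
    expect_false(is.null(a))  # pair mode never suppresses
    if (max(a$tm_query_norm, a$tm_target_norm) < 0.65) below <- below + 1L
  }
  expect_equal(below, n)
})

test_that("monomer vs monomer degenerates to the single chain alignment", {
  ch <- make_chain(42, seed = 17)
  q <- complex_structure("mono1", list(ch))
  t <- complex_structure("mono2", list(chain_structure(
    "Z", ch$ca_coords + matrix(rnorm(126, sd = 0.3), 42, 3),
    ch$residue_names)))
  a <- align_pair(q, t)
  expect_equal(nrow(a$chain_pairs), 1L)
  ca <- align_chains(q$chains[[1]], t$chains[[1]])
  expect_equal(a$tm_query_norm, ca$tm_query_norm, tolerance = 0.01)
})

test_that("database search ranks the true target first at TM ~ 1", {
  fx <- random_fixture_pair(210, n_chains = 2, noise_sigma = 0)
  decoys <- lapply(1:4, function(k)
    random_fixture_pair(k + 500, n_chains = 2, noise_sigma = 0)$query)
  targets <- c(decoys[1:2], list(fx$target), decoys[3:4])
  res <- search_database(list(fx$query), targets, threshold = 0.65)
  expect_equal(length(res), 1L)
  expect_equal(res[[1]]$target_id, fx$target$complex_id)
  expect_equal(res[[1]]$tm_query_norm, 1, tolerance = 1e-4)

  expect_equal(length(search_database(list(fx$query), list())), 0L)
})

test_that("passing-target counts are non-increasing in noise", {
  count_pass <- function(sg) {
    hits <- 0L
    for (seed in 1:6) {
      fx <- random_fixture_pair(seed + 230, n_chains = 2, noise_sigma = sg)
      res <- search_database(list(fx$query), list(fx$target))
      hits <- hits + length(res)
    }
    hits
  }
  counts <- vapply(c(0.5, 2, 4), count_pass, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("monomeric targets are rejected for multimer queries unless included", {
  fx <- random_fixture_pair(215, n_chains = 2, noise_sigma = 0)
  mono <- complex_structure("m", list(fx$target$chains[[1]]))
  res <- search_database(list(fx$query), list(mono), threshold = 0)
  expect_equal(length(res), 0L)
  res2 <- search_database(list(fx$query), list(mono), threshold = 0,
                          include_monomers = TRUE)
  expect_equal(length(res2), 1L)
})

test_that("the length-ratio prescreen never removes a passing hit", {
  for (seed in 1:10) {
    fx <- random_fixture_pair(seed + 260, noise_sigma = 1)
    plain <- search_database(list(fx$query), list(fx$target))
    gated <- search_database(list(fx$query), list(fx$target),
                             prescreen = TRUE)
    expect_equal(vapply(plain, `[[`, character(1), "target_id"),
                 vapply(gated, `[[`, character(1), "target_id"))
  }
})

make_clustered_db <- function() {
  # three clusters of 3 members each: members are noisy copies of their
  # representative (planted cluster structure)
  reps <- list()
  members <- list()
  map <- NULL
  for (k in 1:3) {
    base <- random_fixture_pair(k + 270, n_chains = 2, noise_sigma = 0)
    rep_cx <- base$query
    rep_cx$complex_id <- sprintf("rep%d", k)
    reps[[k]] <- rep_cx
    members[[rep_cx$complex_id]] <- rep_cx
    map <- rbind(map, data.frame(representative = rep_cx$complex_id,
                                 member = rep_cx$complex_id))
    for (j in 1:2) {
      mem <- rep_cx
      mem$complex_id <- sprintf("rep%d_m%d", k, j)
      # members are noisy copies of their representative
      set.seed(k * 100 + j)
      mem$chains <- lapply(rep_cx$chains, function(c) {
        c$ca_coords <- c$ca_coords +
          matrix(rnorm(length(c$ca_coords), sd = 0.8), ncol = 3)
        c
      })
      members[[mem$complex_id]] <- mem
      map <- rbind(map, data.frame(representative = rep_cx$complex_id,
                                   member = mem$complex_id))
    }
  }
  list(reps = reps, members = members, map = map)
}

test_that("clustered search: expansion finds non-representative members", {
  set.seed(999)
  db <- make_clustered_db()
  # query = a noisy copy of member rep2_m1 (true match not a representative)
  query <- db$members[["rep2_m1"]]
  query$complex_id <- "query"
  res <- search_clustered(list(query), db$reps, db$map, db$members,
                          expand_threshold = 0.3, threshold = 0.65)
  expect_true("rep2_m1" %in% vapply(res, `[[`, character(1), "target_id"))
})

test_that("expand_threshold 0 equals exhaustive search over the whole db", {
  set.seed(1000)
  db <- make_clustered_db()
  query <- db$members[["rep3_m2"]]
  query$complex_id <- "query"
  clustered <- search_clustered(list(query), db$reps, db$map, db$members,
                                expand_threshold = 0, threshold = 0.65)
  exhaustive <- search_database(list(query), unname(db$members),
                                threshold = 0.65)
  key <- function(r) sort(vapply(r, function(a)
    paste(a$target_id, sprintf("%.4f", a$tm_query_norm)), character(1)))
  expect_equal(key(clustered), key(exhaustive))
})

test_that("no expansion happens when no representative qualifies", {
  set.seed(1001)
  db <- make_clustered_db()
  query <- random_fixture_pair(777, n_chains = 2, noise_sigma = 0)$query
  query$complex_id <- "query"
  res <- search_clustered(list(query), db$reps, db$map, db$members,
                          expand_threshold = 0.98, threshold = 0)
  expect_true(all(vapply(res, `[[`, character(1), "target_id") %in%
                    vapply(db$reps, `[[`, character(1), "complex_id")))
})

test_that("missing member structures are skipped with a warning", {
  db <- make_clustered_db()
  query <- db$members[["rep1_m1"]]
  query$complex_id <- "query"
  members <- db$members
  members[["rep1_m1"]] <- NULL
  expect_warning(
    search_clustered(list(query), db$reps, db$map, members,
                     expand_threshold = 0, threshold = 0.99),
    "no structure")
})

test_that("TSV output round-trips and formats as specified", {
  fx <- random_fixture_pair(220, n_chains = 2, noise_sigma = 0)
  a <- align_pair(fx$query, fx$query)  # self: qtm exactly 1
  path <- tempfile(fileext = ".tsv")
  write_results(list(a), path)
  lines <- readLines(path)
  expect_match(lines[1], "^#query_id\t")
  fields <- strsplit(lines[2], "\t")[[1]]
  expect_equal(length(fields), 10L)
  expect_equal(fields[7], "1.0000")
  df <- parse_results(path)
  expect_equal(df$query_id, a$query_id)
  expect_equal(df$assignment,
               paste(a$chain_pairs[, 1], a$chain_pairs[, 2], sep = ":",
                     collapse = ","))
  expect_equal(df$qtm, round(a$tm_query_norm, 4))
  expect_lt(max(abs(df$rotation[[1]] - a$transform$rotation)), 1e-6)
  expect_lt(max(abs(df$translation[[1]] - a$transform$translation)), 1e-3)

  empty <- tempfile(fileext = ".tsv")
  write_results(list(), empty)
  expect_equal(length(readLines(empty)), 1L)
  expect_equal(nrow(parse_results(empty)), 0L)
})
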