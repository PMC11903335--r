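#' Align two protein complexes
#'
#' The full pipeline for one complex pair: every query chain is aligned
#' against every target chain ([align_chains()]); each chain alignment
#' contributes a superposition vector; the vectors are filtered,
#' normalized and clustered ([iterative_cluster()]); the best valid
#' cluster defines the chain assignment, which is scored with the
#' complex TM-score ([score_assignment()]). A monomer-vs-monomer pair
#' degenerates to a single chain alignment reported as a complex
#' alignment.
#'
#' @param Q,T [complex_structure()]s.
#' @param config An [mm_config()].
#' @return A `complex_alignment`, or `NULL` when no chain pair is
#'   alignable.
#' @export
align_pair <- function(Q, T, config = mm_config()) {
  alignments <- list()
  for (i in seq_along(Q$chains)) {
    for (j in seq_along(T$chains)) {
      a <- align_chains(Q$chains[[i]], T$chains[[j]], config,
                        query_chain_index = i, target_chain_index = j)
      if (!is.null(a)) alignments[[length(alignments) + 1L]] <- a
    }
  }
  if (length(alignments) == 0L) return(NULL)
  m <- prepare_matrix(alignments, config)
  candidates <- iterative_cluster(m, length(Q$chains), length(T$chains),
                                  config)
  best_alignment(candidates, Q, T, alignments)
}

result_score <- function(a, norm = "max") {
  switch(norm,
         max = max(a$tm_query_norm, a$tm_target_norm),
         query = a$tm_query_norm,
         target = a$tm_target_norm,
         avg = (a$tm_query_norm + a$tm_target_norm) / 2)
}

#' Search query complexes against a target database
#'
#' Runs [align_pair()] for every query x target combination and returns
#' the alignments whose complex TM-score (normalization per
#' `tm_threshold_norm` in the config, default the larger of the two) is
#' at least `threshold`, ranked per query by descending score.
#'
#' @param queries,targets Lists of [complex_structure()]s.
#' @param threshold Report threshold on the complex TM-score.
#'   Default 0.65.
#' @param config An [mm_config()].
#' @param include_monomers Align monomeric targets to multimeric
#'   queries? Default FALSE (mirrors the usual monomer-exclusion mode).
#' @param prescreen Optional cheap gate that skips hopeless pairs
#'   (every query chain more than 3x longer or shorter than every
#'   target chain). OFF by default; it never removes a pair that could
#'   reach the threshold.
#' @return List of `complex_alignment`s.
#' @export
search_database <- function(queries, targets, threshold = 0.65,
                            config = mm_config(), include_monomers = FALSE,
                            prescreen = FALSE) {
  results <- list()
  for (Q in queries) {
    hits <- list()
    for (T in targets) {
      if (!include_monomers && length(Q$chains) > 1L &&
          length(T$chains) == 1L) next
      if (prescreen && !prescreen_pass(Q, T)) next
      a <- tryCatch(align_pair(Q, T, config), error = function(e) {
        warning("alignment of ", Q$complex_id, " vs ", T$complex_id,
                " failed: ", conditionMessage(e), call. = FALSE)
        NULL
      })
      if (is.null(a)) next
      if (result_score(a, config$tm_threshold_norm) >= threshold)
        hits[[length(hits) + 1L]] <- a
    }
    if (length(hits) > 0L) {
      sc <- vapply(hits, result_score, numeric(1),
                   norm = config$tm_threshold_norm)
      hits <- hits[order(-sc)]
    }
    results <- c(results, hits)
  }
  results
}

# Length-ratio gate: passes unless every query chain is >3x longer or
# shorter than every target chain (such pairs cannot align usefully).
prescreen_pass <- function(Q, T) {
  ql <- vapply(Q$chains, chain_length, integer(1))
  tl <- vapply(T$chains, chain_length, integer(1))
  r <- outer(ql, tl, function(a, b) pmax(a / b, b / a))
  any(r <= 3)
}

#' Search against a clustered database
#'
#' Two-phase search over a database reduced to cluster representatives:
#' phase 1 aligns the queries against the representatives; every cluster
#' whose representative reaches `expand_threshold` is expanded, and
#' phase 2 aligns its remaining members. The union of both phases is
#' filtered and ranked exactly as in [search_database()]. With
#' `expand_threshold = 0` every cluster is expanded, which is equivalent
#' to an exhaustive search over representatives plus members.
#'
#' @param queries List of query [complex_structure()]s.
#' @param representatives List of representative [complex_structure()]s.
#' @param cluster_map Data frame (or 2-column matrix) mapping
#'   `representative` id to `member` id; members are resolved in
#'   `members`.
#' @param members Named list of member [complex_structure()]s (may
#'   include the representatives themselves; missing members are skipped
#'   with a warning).
#' @param expand_threshold TM-score a representative must reach for its
#'   cluster to be expanded. Default 0.3 (permissive).
#' @param threshold Report threshold, as in [search_database()].
#' @param config An [mm_config()].
#' @param include_monomers As in [search_database()].
#' @return List of `complex_alignment`s.
#' @export
search_clustered <- function(queries, representatives, cluster_map, members,
                             expand_threshold = 0.3, threshold = 0.65,
                             config = mm_config(), include_monomers = FALSE) {
  cluster_map <- as.data.frame(cluster_map, stringsAsFactors = FALSE)
  names(cluster_map)[1:2] <- c("representative", "member")
  rep_ids <- vapply(representatives, function(s) s$complex_id, character(1))
  results <- list()
  for (Q in queries) {
    hits <- list()
    rep_score <- setNames(numeric(length(rep_ids)) * NA, rep_ids)
    for (k in seq_along(representatives)) {
      T <- representatives[[k]]
      if (!include_monomers && length(Q$chains) > 1L &&
          length(T$chains) == 1L) next
      a <- align_pair(Q, T, config)
      if (is.null(a)) next
      rep_score[rep_ids[k]] <- result_score(a, config$tm_threshold_norm)
      if (result_score(a, config$tm_threshold_norm) >= threshold)
        hits[[length(hits) + 1L]] <- a
    }
    expand <- rep_ids[expand_threshold <= 0 |
                        (!is.na(rep_score) & rep_score >= expand_threshold)]
    member_ids <- unique(cluster_map$member[
      cluster_map$representative %in% expand])
    member_ids <- setdiff(member_ids, rep_ids)  # representatives done in phase 1
    for (mid in member_ids) {
      T <- members[[mid]]
      if (is.null(T)) {
        warning("cluster member ", mid, " has no structure; skipped",
                call. = FALSE)
        next
      }
      if (!include_monomers && length(Q$chains) > 1L &&
          length(T$chains) == 1L) next
      a <- align_pair(Q, T, config)
      if (is.null(a)) next
      if (result_score(a, config$tm_threshold_norm) >= threshold)
        hits[[length(hits) + 1L]] <- a
    }
    if (length(hits) > 0L) {
      sc <- vapply(hits, result_score, numeric(1),
                   norm = config$tm_threshold_norm)
      hits <- hits[order(-sc)]
    }
    results <- c(results, hits)
  }
  results
}

#' Write complex alignments to a TSV report
#'
#' One row per alignment, tab-separated, header prefixed with `#`.
#' Columns: query_id, target_id, n_query_chains, n_target_chains,
#' assignment (comma-joined `qchain:tchain`), aligned_residues, qtm,
#' ttm (4 decimals), rotation (9 comma-joined values, 6 decimals,
#' row-major) and translation (3 comma-joined values, 3 decimals).
#'
#' @param results List of `complex_alignment`s.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(paste0("#", paste(
    c("query_id", "target_id", "n_query_chains", "n_target_chains",
      "assignment", "aligned_residues", "qtm", "ttm", "rotation",
      "translation"), collapse = "\t")), con)
  for (a in results) {
    writeLines(paste(
      a$query_id, a$target_id,
      a$n_query_chains %||% nrow(a$chain_pairs),
      a$n_target_chains %||% nrow(a$chain_pairs),
      paste(a$chain_pairs[, 1], a$chain_pairs[, 2], sep = ":",
            collapse = ","),
      a$aligned_residues,
      sprintf("%.4f", a$tm_query_norm), sprintf("%.4f", a$tm_target_norm),
      paste(sprintf("%.6f", as.vector(t(a$transform$rotation))),
            collapse = ","),
      paste(sprintf("%.3f", a$transform$translation), collapse = ","),
      sep = "\t"), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a TSV report written by [write_results()]
#'
#' @param path Path to the report.
#' @return A data frame with one row per alignment; `rotation` and
#'   `translation` are list-columns holding the numeric transform.
#' @export
parse_results <- function(path) {
  lines <- readLines(path)
  header <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  body <- lines[-1]
  if (length(body) == 0L) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(header)),
                                 header))
    return(df)
  }
  f <- do.call(rbind, strsplit(body, "\t"))
  df <- data.frame(query_id = f[, 1], target_id = f[, 2],
                   n_query_chains = as.integer(f[, 3]),
                   n_target_chains = as.integer(f[, 4]),
                   assignment = f[, 5],
                   aligned_residues = as.integer(f[, 6]),
                   qtm = as.numeric(f[, 7]), ttm = as.numeric(f[, 8]),
                   stringsAsFactors = FALSE)
  df$rotation <- lapply(strsplit(f[, 9], ","), function(v)
    matrix(as.numeric(v), 3, 3, byrow = TRUE))
  df$translation <- lapply(strsplit(f[, 10], ","), as.numeric)
  df
}
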