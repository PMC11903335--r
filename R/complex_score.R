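#' TM-score of an aligned coordinate pair
#'
#' Computes the TM-score
#' \deqn{TM = \max_U \frac{1}{L_{norm}} \sum_i \frac{1}{1 + (d_i/d_0(L_{norm}))^2}}
#' where the maximum is over rigid superpositions and `d_i` is the
#' distance between aligned residues after superposition. The search
#' seeds superpositions from contiguous alignment fragments of lengths
#' `L_a`, `L_a/2` and `L_a/4` (aligned length `L_a`) at stride
#' `max(1, L_a/10)`, and refines each by iterating Kabsch on the pairs
#' closer than `max(d0, 4.5)` Angstrom until the subset is stable.
#'
#' @param q_coords,t_coords Coordinate matrices of the two structures
#'   (full chains, not only aligned residues).
#' @param pairs Two-column matrix of 1-based aligned indices
#'   (query, target), strictly increasing in both columns.
#' @param L_norm Normalizing length; must cover the aligned index span.
#' @return List with `tm` (the score), `transform` (the maximizing
#'   [rigid_transform()], target onto query) and `sum` (the
#'   unnormalized sum).
#' @export
tm_score <- function(q_coords, t_coords, pairs, L_norm) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0L) stop("empty alignment")
  q_coords <- as_coord_matrix(q_coords)
  t_coords <- as_coord_matrix(t_coords)
  if (L_norm < nrow(pairs)) stop("L_norm smaller than the aligned length")
  d0 <- max(tm_d0(L_norm), 0.5)
  res <- .tm_search_cpp(q_coords[pairs[, 1], , drop = FALSE],
                        t_coords[pairs[, 2], , drop = FALSE], d0)
  list(tm = res$sum / L_norm,
       transform = rigid_transform(res$rotation, as.numeric(res$translation)),
       sum = res$sum)
}

new_complex_alignment <- function(query_id, target_id, chain_pairs,
                                  per_pair_alignments, transform,
                                  tm_query_norm, tm_target_norm,
                                  aligned_residues, n_query_chains,
                                  n_target_chains) {
  stopifnot(!anyDuplicated(chain_pairs[, 1]), !anyDuplicated(chain_pairs[, 2]))
  structure(list(query_id = query_id, target_id = target_id,
                 chain_pairs = chain_pairs,
                 per_pair_alignments = per_pair_alignments,
                 transform = transform, tm_query_norm = tm_query_norm,
                 tm_target_norm = tm_target_norm,
                 aligned_residues = aligned_residues,
                 n_query_chains = n_query_chains,
                 n_target_chains = n_target_chains),
            class = "complex_alignment")
}

#' @export
print.complex_alignment <- function(x, ...) {
  cat(sprintf("<complex_alignment> %s vs %s\n", x$query_id, x$target_id))
  cat(sprintf("  assignment: %s\n",
              paste(x$chain_pairs[, 1], x$chain_pairs[, 2], sep = ":",
                    collapse = ", ")))
  cat(sprintf("  TM %.4f (query-norm) / %.4f (target-norm), %d aligned residues\n",
              x$tm_query_norm, x$tm_target_norm, x$aligned_residues))
  invisible(x)
}

#' Score a candidate chain assignment as a complex alignment
#'
#' The matched query chains are concatenated in their order within the
#' query complex; the matched target chains are concatenated in the
#' order of their pairwise matches to the query chains. Residue pairs of
#' each per-chain alignment are offset into the concatenated frame and a
#' single TM superposition search is run over them. Both normalizations
#' divide the same unnormalized sum — by the total residue count of the
#' query and of the target complex respectively (all chains, matched or
#' not), so `tm_query_norm * L_Q == tm_target_norm * L_T` holds exactly;
#' the search uses `d0(min(L_Q, L_T))`.
#'
#' @param Q,T [complex_structure()]s.
#' @param candidate A `cluster_candidate` (one-to-one chain assignment).
#' @param alignments The chain alignments the candidate's rows refer to.
#' @return A `complex_alignment`.
#' @export
score_assignment <- function(Q, T, candidate, alignments) {
  sel <- alignments[candidate$member_rows]
  qidx <- vapply(sel, function(a) a$query_chain_index, integer(1))
  ord <- order(qidx)  # query complex chain order
  sel <- sel[ord]
  qidx <- qidx[ord]
  tidx <- vapply(sel, function(a) a$target_chain_index, integer(1))
  q_lens <- vapply(Q$chains, chain_length, integer(1))
  t_lens <- vapply(T$chains, chain_length, integer(1))
  q_cat <- do.call(rbind, lapply(Q$chains[qidx], function(c) c$ca_coords))
  t_cat <- do.call(rbind, lapply(T$chains[tidx], function(c) c$ca_coords))
  q_off <- cumsum(c(0L, q_lens[qidx]))[seq_along(qidx)]
  t_off <- cumsum(c(0L, t_lens[tidx]))[seq_along(tidx)]
  pairs <- do.call(rbind, lapply(seq_along(sel), function(k) {
    cbind(sel[[k]]$pairs[, 1] + q_off[k], sel[[k]]$pairs[, 2] + t_off[k])
  }))
  L_Q <- total_length(Q)
  L_T <- total_length(T)
  d0 <- max(tm_d0(min(L_Q, L_T)), 0.5)
  res <- .tm_search_cpp(q_cat[pairs[, 1], , drop = FALSE],
                        t_cat[pairs[, 2], , drop = FALSE], d0)
  cp <- cbind(query = chain_ids(Q)[qidx], target = chain_ids(T)[tidx])
  new_complex_alignment(
    Q$complex_id, T$complex_id, cp, sel,
    rigid_transform(res$rotation, as.numeric(res$translation)),
    tm_query_norm = res$sum / L_Q, tm_target_norm = res$sum / L_T,
    aligned_residues = nrow(pairs),
    n_query_chains = length(Q$chains), n_target_chains = length(T$chains))
}

#' Pick the best-scoring valid cluster
#'
#' Scores every candidate with [score_assignment()] and returns the one
#' maximizing `tm_query_norm + tm_target_norm`; ties are broken by more
#' aligned residues, then by lexicographically smallest chain pairing,
#' so the choice is deterministic.
#'
#' @param candidates List of `cluster_candidate`s.
#' @param Q,T [complex_structure()]s.
#' @param alignments The chain alignments the candidates refer to.
#' @return The winning `complex_alignment`, or `NULL` for an empty
#'   candidate list.
#' @export
best_alignment <- function(candidates, Q, T, alignments) {
  if (length(candidates) == 0L) return(NULL)
  scored <- lapply(candidates, function(cand)
    score_assignment(Q, T, cand, alignments))
  key <- vapply(scored, function(a)
    paste(a$chain_pairs[, 1], a$chain_pairs[, 2], sep = ":", collapse = ","),
    character(1))
  tm <- vapply(scored, function(a) a$tm_query_norm + a$tm_target_norm,
               numeric(1))
  nres <- vapply(scored, function(a) a$aligned_residues, numeric(1))
  ord <- order(-tm, -nres, key)
  scored[[ord[1]]]
}
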