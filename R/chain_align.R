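#' Default alignment configuration
#'
#' Tunables of the chain-to-chain aligner and the downstream clustering.
#'
#' @param gap_penalty Gap opening penalty in the alignment dynamic
#'   program (no extension penalty). Default -0.6.
#' @param max_iters Maximum refinement iterations per seed. Default 30.
#' @param seed_fragment_len Fragment length for gapless-threading seeds;
#'   the effective length is `min(seed_fragment_len, L)`. Default 20.
#' @param seed_stride Stride between fragment starts, as a fraction
#'   denominator: the stride is `max(1, floor(L / seed_stride))`.
#'   Default 10.
#' @param cv_threshold Column-informativeness threshold for the
#'   superposition matrix filter. Default 0.1.
#' @param cv_absolute_mean Use `|mean|` in the coefficient of variation
#'   (the columns are signed). Default TRUE.
#' @param sd_denominator `"n"` (population, default) or `"n-1"` for the
#'   column standard deviation.
#' @param epsilon_delta Radius increment of the iterative DBSCAN.
#'   Default 0.1 (normalized units).
#' @param random_core_start If TRUE, DBSCAN picks the starting core point
#'   at random instead of by lowest index (robustness testing only; the
#'   default keeps the whole pipeline deterministic).
#' @param tm_threshold Report threshold on the complex TM-score in search
#'   mode. Default 0.65.
#' @param tm_threshold_norm Which normalization the threshold applies to:
#'   `"max"` (default), `"query"`, `"target"` or `"avg"`.
#' @return A named list of class `mm_config`.
#' @export
mm_config <- function(gap_penalty = -0.6, max_iters = 30L,
                      seed_fragment_len = 20L, seed_stride = 10L,
                      cv_threshold = 0.1, cv_absolute_mean = TRUE,
                      sd_denominator = c("n", "n-1"),
                      epsilon_delta = 0.1, random_core_start = FALSE,
                      tm_threshold = 0.65,
                      tm_threshold_norm = c("max", "query", "target", "avg")) {
  structure(list(gap_penalty = gap_penalty, max_iters = as.integer(max_iters),
                 seed_fragment_len = as.integer(seed_fragment_len),
                 seed_stride = as.integer(seed_stride),
                 cv_threshold = cv_threshold,
                 cv_absolute_mean = isTRUE(cv_absolute_mean),
                 sd_denominator = match.arg(sd_denominator),
                 epsilon_delta = epsilon_delta,
                 random_core_start = isTRUE(random_core_start),
                 tm_threshold = tm_threshold,
                 tm_threshold_norm = match.arg(tm_threshold_norm)),
            class = "mm_config")
}

#' TM-score distance scale d0
#'
#' The standard length-dependent distance scale of the TM-score:
#' `d0(L) = 1.24 (L - 15)^(1/3) - 1.8` for `L > 21`, else 0.5 Angstrom.
#'
#' @param L Normalizing length (residues).
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(L) {
  ifelse(L > 21, 1.24 * (L - 15)^(1 / 3) - 1.8, 0.5)
}

new_chain_alignment <- function(query_chain_index, target_chain_index, pairs,
                                transform, tm_query_norm, tm_target_norm) {
  pairs <- as.matrix(pairs)
  colnames(pairs) <- c("query", "target")
  stopifnot(nrow(pairs) >= 3L,
            all(diff(pairs[, 1]) > 0), all(diff(pairs[, 2]) > 0))
  structure(list(query_chain_index = query_chain_index,
                 target_chain_index = target_chain_index,
                 pairs = pairs, transform = transform,
                 tm_query_norm = tm_query_norm,
                 tm_target_norm = tm_target_norm),
            class = "chain_alignment")
}

#' @export
print.chain_alignment <- function(x, ...) {
  cat(sprintf(
    "<chain_alignment> q[%d] vs t[%d]: %d pairs, TM %.3f (query) / %.3f (target)\n",
    x$query_chain_index, x$target_chain_index, nrow(x$pairs),
    x$tm_query_norm, x$tm_target_norm))
  invisible(x)
}

# Needleman-Wunsch on sequence identity, used as one alignment seed.
seq_identity_pairs <- function(q_names, t_names, gap = -0.6) {
  S <- outer(q_names, t_names, function(a, b) ifelse(a == b, 1, 0))
  .dp_align_cpp(S, gap)
}

#' Align two chains structurally
#'
#' TM-align-style iterative chain alignment. Seed superpositions come
#' from gapless threading of fragments and from a sequence-identity
#' Needleman-Wunsch alignment; each seed is refined by alternating
#' Kabsch superposition, residue-pair scoring with
#' `1/(1 + (d/d0)^2)`, and dynamic-programming realignment with the
#' configured gap penalty, until the pair set is stable (a refinement
#' step is only accepted if it does not lower the alignment score). The
#' best seed by `tm_query_norm + tm_target_norm` wins; ties go to the
#' earlier seed. The whole procedure is deterministic.
#'
#' @param q,t [chain_structure()]s with at least 3 residues each.
#' @param config An [mm_config()].
#' @param query_chain_index,target_chain_index Indices stored in the
#'   result (used when aligning chains of complexes).
#' @return A `chain_alignment`, or `NULL` if no alignment of at least 3
#'   residue pairs was found. The alignment's `transform` maps target
#'   coordinates into the query frame. The attribute `score_trace` holds
#'   the per-iteration score trace of the winning seed (non-decreasing).
#' @export
align_chains <- function(q, t, config = mm_config(),
                         query_chain_index = 1L, target_chain_index = 1L) {
  Q <- q$ca_coords
  T_ <- t$ca_coords
  L1 <- nrow(Q)
  L2 <- nrow(T_)
  if (L1 < 3L || L2 < 3L) stop("chains must have at least 3 residues")
  Lmin <- min(L1, L2)
  d0 <- max(tm_d0(Lmin), 0.5)
  seeds <- alignment_seeds(q, t, config)
  best <- NULL
  seen <- character(0)
  results <- list()
  for (sd in seeds) {
    ref <- .align_refine_cpp(Q, T_, sd$rotation, sd$translation, d0,
                             config$gap_penalty, config$max_iters)
    if (!isTRUE(ref$ok)) next
    key <- paste(ref$pairs[, 1], ref$pairs[, 2], collapse = ";")
    if (key %in% seen) next
    seen <- c(seen, key)
    results[[length(results) + 1L]] <- ref
  }
  if (length(results) == 0L) return(NULL)
  # rank distinct pair sets by their DP alignment score and evaluate the
  # full TM-score search only for the leading ones (the DP score is the
  # same sum at a fixed d0, so the ranking is faithful)
  ord <- order(vapply(results, function(r) r$score, numeric(1)),
               decreasing = TRUE)
  results <- results[ord[seq_len(min(8L, length(results)))]]
  best <- NULL
  best_tm <- -Inf
  for (ref in results) {
    tq <- tm_score(Q, T_, ref$pairs, L1)
    tt <- tm_score(Q, T_, ref$pairs, L2)
    if (tq$tm + tt$tm > best_tm + 1e-12) {
      best_tm <- tq$tm + tt$tm
      best <- list(ref = ref, tq = tq, tt = tt)
    }
  }
  fit <- kabsch_superpose(Q[best$ref$pairs[, 1], , drop = FALSE],
                          T_[best$ref$pairs[, 2], , drop = FALSE])
  aln <- new_chain_alignment(query_chain_index, target_chain_index,
                             best$ref$pairs, fit$transform,
                             best$tq$tm, best$tt$tm)
  attr(aln, "score_trace") <- best$ref$score_trace
  aln
}

# Seed transforms: gapless fragment threading + sequence-identity NW.
alignment_seeds <- function(q, t, config) {
  Q <- q$ca_coords
  T_ <- t$ca_coords
  L1 <- nrow(Q)
  L2 <- nrow(T_)
  Lmin <- min(L1, L2)
  f <- min(config$seed_fragment_len, Lmin)
  stride <- max(1L, Lmin %/% config$seed_stride)
  seeds <- list()
  qi <- seq(1L, L1 - f + 1L, by = stride)
  ti <- seq(1L, L2 - f + 1L, by = stride)
  for (i in qi) for (j in ti) {
    fit <- try_kabsch(Q[i:(i + f - 1L), , drop = FALSE],
                      T_[j:(j + f - 1L), , drop = FALSE])
    if (!is.null(fit)) seeds[[length(seeds) + 1L]] <- fit
  }
  sp <- seq_identity_pairs(q$residue_names, t$residue_names,
                           config$gap_penalty)
  if (nrow(sp) >= 3L) {
    fit <- try_kabsch(Q[sp[, 1], , drop = FALSE], T_[sp[, 2], , drop = FALSE])
    if (!is.null(fit)) seeds[[length(seeds) + 1L]] <- fit
  }
  seeds
}

try_kabsch <- function(Qs, Ts) {
  res <- tryCatch(.kabsch_cpp(Qs, Ts), error = function(e) NULL)
  if (is.null(res)) return(NULL)
  list(rotation = res$rotation, translation = as.numeric(res$translation))
}
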