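#' Build the superposition matrix from chain alignments
#'
#' Each chain-to-chain alignment contributes one 12-component row: the
#' nine rotation-matrix entries (row-major) followed by the three
#' translation components (Angstrom) of its superposition of the target
#' chain onto the query chain. Chain alignments that share one rigid
#' relation produce (near-)identical rows, which is what the downstream
#' clustering exploits.
#'
#' @param alignments Non-empty list of `chain_alignment`s.
#' @return An object of class `superposition_matrix` with elements
#'   `rows` (n x 12 matrix), `alignment_refs`, and unset filter /
#'   normalization slots (see [filter_columns()], [normalize_columns()]).
#' @export
build_matrix <- function(alignments) {
  if (length(alignments) == 0L) stop("need at least one chain alignment")
  rows <- t(vapply(alignments, function(a) {
    c(as.vector(t(a$transform$rotation)), a$transform$translation)
  }, numeric(12)))
  colnames(rows) <- c(paste0("u", rep(1:3, each = 3), rep(1:3, 3)),
                      paste0("t", 1:3))
  structure(list(rows = rows, alignment_refs = alignments,
                 retained_mask = NULL, column_means = NULL,
                 column_sds = NULL, normalized = NULL),
            class = "superposition_matrix")
}

#' @export
print.superposition_matrix <- function(x, ...) {
  cat(sprintf("<superposition_matrix> %d row(s)", nrow(x$rows)))
  if (!is.null(x$retained_mask))
    cat(sprintf(", %d/12 columns retained", sum(x$retained_mask)))
  cat("\n")
  invisible(x)
}

column_stats <- function(rows, sd_denominator = "n") {
  n <- nrow(rows)
  mu <- colMeans(rows)
  dev <- sweep(rows, 2, mu)
  ss <- colSums(dev^2)
  denom <- if (sd_denominator == "n-1" && n > 1) n - 1 else n
  list(mean = mu, sd = sqrt(ss / denom))
}

#' Drop uninformative superposition-matrix columns
#'
#' Columns whose values barely vary across the chain alignments carry no
#' signal for separating superpositions, and would dilute the clustering
#' distances. For each column the criterion is the coefficient of
#' variation `sd/|mean|`; when `|mean| < 1` the standard deviation itself
#' is used instead (the CV blows up near zero mean). A column is excluded
#' when its criterion value is below `cv_threshold` (default 0.1).
#'
#' @param m A [build_matrix()] result with at least 2 rows.
#' @param config An [mm_config()]; `cv_threshold`, `cv_absolute_mean` and
#'   `sd_denominator` are honoured.
#' @return `m` with `retained_mask`, `column_means`, `column_sds` set.
#' @export
filter_columns <- function(m, config = mm_config()) {
  if (nrow(m$rows) < 2L)
    stop("column filtering needs at least 2 rows (single-row matrices bypass clustering)")
  st <- column_stats(m$rows, config$sd_denominator)
  mu <- if (config$cv_absolute_mean) abs(st$mean) else st$mean
  crit <- ifelse(mu >= 1, st$sd / mu, st$sd)
  m$retained_mask <- crit >= config$cv_threshold
  m$column_means <- st$mean
  m$column_sds <- st$sd
  m
}

#' Z-score the retained superposition-matrix columns
#'
#' Retained columns are centred on their mean and divided by their
#' standard deviation, so that rotation entries (unitless, order 1) and
#' translations (Angstrom, order 10-100) contribute comparably to the
#' clustering distances. If every column was excluded (all superpositions
#' effectively identical) the normalized matrix has zero columns and all
#' rows are mutually at distance 0.
#'
#' @param m A [filter_columns()] result.
#' @param config An [mm_config()].
#' @return `m` with `normalized` set (n x k matrix over retained columns).
#' @export
normalize_columns <- function(m, config = mm_config()) {
  if (is.null(m$retained_mask)) stop("call filter_columns() first")
  keep <- which(m$retained_mask)
  z <- sweep(m$rows[, keep, drop = FALSE], 2, m$column_means[keep])
  sds <- m$column_sds[keep]
  pos <- sds > 0
  z[, pos] <- sweep(z[, pos, drop = FALSE], 2, sds[pos], "/")
  m$normalized <- z
  m
}

# Build + filter + normalize in one go, handling the 1-row bypass.
prepare_matrix <- function(alignments, config = mm_config()) {
  m <- build_matrix(alignments)
  if (nrow(m$rows) < 2L) {
    m$retained_mask <- rep(FALSE, 12L)
    st <- column_stats(m$rows, config$sd_denominator)
    m$column_means <- st$mean
    m$column_sds <- st$sd
    m$normalized <- m$rows[, integer(0), drop = FALSE]
    return(m)
  }
  normalize_columns(filter_columns(m, config), config)
}
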