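# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Deterministic per-stage / per-participant seed derivation, kept < 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 65011) * 33013 + offset %% 33013) %% 2147483629L
}

#' Enumerate unordered stimulus pairs
#'
#' Returns the unique unordered pairs of a stimulus-id vector, in the order
#' used throughout the package for the vectorised lower triangle of a
#' dissimilarity matrix (column-major lower triangle).
#'
#' @param stimulus_ids integer vector of distinct stimulus ids.
#' @return data.frame with columns `stim_i`, `stim_j` (`stim_i` > `stim_j`
#'   positionally: row index > column index in the matrix), one row per pair;
#'   36 stimuli give 630 rows.
#' @export
stim_pairs <- function(stimulus_ids) {
  s <- as.integer(stimulus_ids)
  if (anyDuplicated(s)) stop("stimulus ids must be distinct")
  n <- length(s)
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  data.frame(stim_i = s[idx[, 1]], stim_j = s[idx[, 2]])
}

#' Lower-triangle cells of a dissimilarity stack
#'
#' Extracts the unique cells of an S x S x T dissimilarity array as a
#' (pairs x T) matrix in [stim_pairs()] order — the vectorized form used for
#' all RSA correlations and regressions.
#'
#' @param values S x S x T array (e.g. the `values` of an `rdm_series`).
#' @return numeric matrix, `choose(S, 2)` rows by T columns.
#' @export
lower_tri_mat <- function(values) {
  stopifnot(length(dim(values)) == 3L)
  n <- dim(values)[1]
  lt <- lower.tri(matrix(0, n, n))
  apply(values, 3, function(m) m[lt])
}

#' Lower-triangle cells of a dissimilarity matrix
#'
#' @param m square symmetric matrix.
#' @return numeric vector of the strictly-lower-triangle cells (column-major),
#'   the 630 unique cells for a 36 x 36 RDM.
#' @export
lower_tri_values <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  m[lower.tri(m)]
}

# Average fractional ranks with NA propagation; constant vectors -> NA
# (zero rank variance, Spearman undefined).
safe_rank <- function(x) {
  if (anyNA(x)) return(rep(NA_real_, length(x)))
  r <- rank(x, ties.method = "average")
  if (length(unique(r)) < 2L) return(rep(NA_real_, length(x)))
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a
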