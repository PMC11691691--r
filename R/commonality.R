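# Commonality analysis: partition neural RDM variance into components
# unique to each behavioral model and common to both, with a
# stimulus-label permutation null.

#' Partition neural RDM variance between two model predictors
#'
#' Fits ordinary least squares (with intercept) of the neural RDM cells on
#' the image-model cells, the concept-model cells, and both together, and
#' partitions the full-model R-squared by differences of nested-model
#' R-squared values: the variance unique to the image model is
#' `r2_full - r2_concept`, the variance unique to the concept model is
#' `r2_full - r2_image`, and the commonality is
#' `r2_image + r2_concept - r2_full`. The three components sum to `r2_full`
#' exactly. Negative commonality (possible with suppressor structure) is
#' reported as-is.
#'
#' @param neural_cells numeric vector of unique RDM cells (e.g. 630 values).
#' @param image_model,concept_model predictor vectors aligned on the same
#'   pair ordering; cells incomplete in any vector are dropped.
#' @return list of class `variance_partition` with `r2_full`, `r2_image`,
#'   `r2_concept`, `unique_image`, `unique_concept`, `common`, `n_cells`.
#' @export
variance_partition <- function(neural_cells, image_model, concept_model) {
  ok <- complete.cases(neural_cells, image_model, concept_model)
  y <- neural_cells[ok]
  x1 <- image_model[ok]
  x2 <- concept_model[ok]
  if (length(y) < 4) stop("need at least 4 complete cells")
  if (sd(x1) == 0 || sd(x2) == 0) stop("constant model predictor")
  r12 <- cor(x1, x2)
  if (abs(r12) >= 1 - 1e-12)
    stop("collinear model predictors: common variance undefined")
  r2 <- partition_r2(y, cbind(x1, x2))
  structure(list(r2_full = r2[["full"]], r2_image = r2[["x1"]],
                 r2_concept = r2[["x2"]],
                 unique_image = r2[["full"]] - r2[["x2"]],
                 unique_concept = r2[["full"]] - r2[["x1"]],
                 common = r2[["x1"]] + r2[["x2"]] - r2[["full"]],
                 n_cells = length(y)),
            class = "variance_partition")
}

# R^2 of y on each single predictor and on both, via projections onto an
# orthonormal basis of the centered design (no lm() overhead; exact OLS).
partition_r2 <- function(y, X) {
  yc <- y - mean(y)
  ss <- sum(yc^2)
  if (ss == 0) stop("zero-variance response")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  q <- qr.Q(qr(Xc))
  full <- sum(crossprod(q, yc)^2) / ss
  single <- vapply(1:2, function(j) {
    u <- Xc[, j] / sqrt(sum(Xc[, j]^2))
    sum(u * yc)^2 / ss
  }, numeric(1))
  c(full = full, x1 = single[1], x2 = single[2])
}

#' Permutation test for commonality components over time
#'
#' Computes the observed variance partition at every time point of a neural
#' RDM series, then compares each component against a null distribution
#' obtained by randomly permuting the stimulus labels of the neural RDM
#' (joint row/column permutation, which preserves RDM symmetry and the
#' multiset of cell values) and recomputing the partition. One permutation
#' of the labels is shared across time points within a repetition,
#' preserving the temporal dependence of the null. p-values use the add-one
#' convention, p = (1 + #(null >= observed)) / (1 + n_permutations), and a
#' component is flagged significant when the observed value exceeds all
#' permutations (p = 1/(n+1); with 1000 permutations, p < 0.001).
#'
#' @param neural an `rdm_series` (or an n x n x T array of group-mean RDMs).
#' @param image_model,concept_model model RDMs over the same stimuli.
#' @param n_permutations number of label permutations (default 1000).
#' @param seed integer seed.
#' @return object of class `permutation_null`: list with `time`, `observed`
#'   (components x T matrix), `p` and `significant` (same shape),
#'   `n_permutations`.
#' @export
commonality_permutation_test <- function(neural, image_model, concept_model,
                                         n_permutations = 1000, seed = 1L) {
  stopifnot(n_permutations >= 1)
  values <- if (inherits(neural, "rdm_series")) neural$values else neural
  time <- if (inherits(neural, "rdm_series")) neural$time else
    seq_len(dim(values)[3])
  n <- dim(values)[1]
  x1 <- lower_tri_values(rdm_values(image_model))
  x2 <- lower_tri_values(rdm_values(concept_model))
  comp <- c("unique_image", "unique_concept", "common")

  part_cols <- function(vals) {
    lt <- lower_tri_mat(vals)
    out <- apply(lt, 2, function(y) {
      p <- variance_partition(y, x1, x2)
      c(p$unique_image, p$unique_concept, p$common)
    })
    rownames(out) <- comp
    out
  }
  observed <- part_cols(values)

  exceed <- matrix(0L, nrow = 3, ncol = dim(values)[3], dimnames = list(comp, NULL))
  nullmax <- matrix(-Inf, nrow = 3, ncol = dim(values)[3], dimnames = list(comp, NULL))
  with_seed(derive_seed(seed, 1303L), {
    for (r in seq_len(n_permutations)) {
      pm <- sample.int(n)
      null_r <- part_cols(values[pm, pm, , drop = FALSE])
      exceed <- exceed + (null_r >= observed)
      nullmax <- pmax(nullmax, null_r)
    }
  })
  p <- (1 + exceed) / (1 + n_permutations)
  structure(list(time = time, observed = observed, p = p,
                 significant = observed > nullmax,
                 n_permutations = as.integer(n_permutations), seed = seed),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("<permutation_null> %d time points, %d permutations\n",
              length(x$time), x$n_permutations))
  for (k in rownames(x$observed))
    cat(sprintf("  %s: %d/%d time points exceed all permutations\n",
                k, sum(x$significant[k, ]), length(x$time)))
  invisible(x)
}
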