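# Behavioral dissimilarity from triplet odd-one-out judgments, stimulus
# model RDMs, and neural-behavior correlation.

#' Estimate a behavioral RDM from triplet responses
#'
#' Each trial contributes three pair codes: the chosen odd one out is coded
#' as dissimilar (1) from each of the two remaining stimuli, and the
#' remaining pair is coded as similar (0). A pair's dissimilarity is the
#' mean code over all trials -- pooled across participants -- in which the
#' two stimuli appeared together; pairs never observed together are left
#' undefined (NA) and reported, and downstream correlations use
#' pairwise-complete cells.
#'
#' @param responses a `triplet_responses` data.frame (see
#'   [generate_triplet_responses()] for the format).
#' @param n_stimuli number of stimuli (ids 1..n assumed).
#' @return object of class `behavioral_rdm`: list with `values` (n x n
#'   symmetric matrix in [0,1], diagonal NA), `pair_counts` (co-occurrence
#'   counts), `n_unobserved` (pairs never seen together).
#' @export
build_rdm_from_triplets <- function(responses, n_stimuli = 36) {
  stopifnot(all(c("stim_a", "stim_b", "stim_c", "chosen") %in% names(responses)))
  trip <- cbind(responses$stim_a, responses$stim_b, responses$stim_c)
  if (any(apply(trip, 1, anyDuplicated) > 0))
    stop("triplets must contain three distinct stimuli")
  chosen <- match(responses$chosen, c("a", "b", "c"))
  if (anyNA(chosen)) stop("chosen must be one of 'a', 'b', 'c'")

  dsum <- matrix(0, n_stimuli, n_stimuli)
  cnt <- matrix(0L, n_stimuli, n_stimuli)
  pair_cols <- rbind(c(1, 2), c(1, 3), c(2, 3))
  for (k in 1:3) {
    i <- trip[, pair_cols[k, 1]]
    j <- trip[, pair_cols[k, 2]]
    # pair is dissimilar iff it includes the chosen stimulus
    code <- as.numeric(chosen == pair_cols[k, 1] | chosen == pair_cols[k, 2])
    for (sym in 1:2) {
      idx <- if (sym == 1) cbind(i, j) else cbind(j, i)
      agg_c <- tapply(rep(1L, length(i)), list(idx[, 1], idx[, 2]), sum)
      agg_d <- tapply(code, list(idx[, 1], idx[, 2]), sum)
      ri <- as.integer(rownames(agg_c))
      ci <- as.integer(colnames(agg_c))
      pos <- which(!is.na(agg_c), arr.ind = TRUE)
      cells <- cbind(ri[pos[, 1]], ci[pos[, 2]])
      cnt[cells] <- cnt[cells] + agg_c[pos]
      dsum[cells] <- dsum[cells] + agg_d[pos]
    }
  }
  values <- ifelse(cnt > 0, dsum / pmax(cnt, 1L), NA_real_)
  diag(values) <- NA_real_
  diag(cnt) <- 0L
  n_unobserved <- sum(cnt[lower.tri(cnt)] == 0)
  structure(list(values = values, pair_counts = cnt,
                 n_unobserved = n_unobserved, provenance = "triplet task"),
            class = "behavioral_rdm")
}

#' @export
print.behavioral_rdm <- function(x, ...) {
  cat(sprintf("<behavioral_rdm> %d stimuli; %d unobserved pairs; %s\n",
              nrow(x$values), x$n_unobserved, x$provenance))
  invisible(x)
}

#' Binary stimulus model RDMs
#'
#' Builds the two stimulus models used to interpret neural and behavioral
#' dissimilarity: the image model codes a pair as similar (0) when both
#' stimuli are of the same modality (both images or both words) and
#' dissimilar (1) otherwise; the concept model codes a pair as similar when
#' the stimuli share the same object concept regardless of modality.
#'
#' @param stimuli a [stimulus_set()].
#' @return list with `image_model` and `concept_model`, each a
#'   `behavioral_rdm`-like object with binary `values` (diagonal NA).
#' @export
build_model_rdms <- function(stimuli = stimulus_set()) {
  n <- nrow(stimuli)
  img <- 1 - outer(stimuli$modality, stimuli$modality, "==")
  con <- 1 - outer(stimuli$concept, stimuli$concept, "==")
  storage.mode(img) <- "double"
  storage.mode(con) <- "double"
  diag(img) <- NA_real_
  diag(con) <- NA_real_
  mk <- function(v, what) structure(list(values = v, pair_counts = NULL,
                                         n_unobserved = 0L, provenance = what),
                                    class = "behavioral_rdm")
  list(image_model = mk(img, "image model"),
       concept_model = mk(con, "concept model"))
}

# Accept behavioral_rdm objects or plain matrices.
rdm_values <- function(x) {
  if (inherits(x, "behavioral_rdm")) x$values
  else if (is.matrix(x)) x
  else stop("expected an RDM matrix or behavioral_rdm")
}

#' Spearman correlation between two RDMs
#'
#' Rank-correlates the unique lower-triangle cells of two dissimilarity
#' matrices over the same stimuli, using pairwise-complete cells. An
#' optional permutation p-value shuffles stimulus labels (joint row/column
#' permutation of one RDM), respecting the non-independence of RDM cells.
#'
#' @param a,b RDM matrices or `behavioral_rdm` objects.
#' @param n_perm permutations for the p-value (0 = no p-value).
#' @param seed seed for the permutations.
#' @return list of class `rdm_correlation`: `rho`, `n_pairs`, and `p`
#'   (NA when `n_perm = 0`).
#' @export
correlate_rdms <- function(a, b, n_perm = 0, seed = 1L) {
  ma <- rdm_values(a)
  mb <- rdm_values(b)
  stopifnot(all(dim(ma) == dim(mb)))
  va <- lower_tri_values(ma)
  vb <- lower_tri_values(mb)
  ok <- complete.cases(va, vb)
  if (sum(ok) < 3) stop("need at least 3 complete RDM cell pairs")
  rho <- cor(va[ok], vb[ok], method = "spearman")
  p <- NA_real_
  if (n_perm > 0) {
    n <- nrow(ma)
    with_seed(derive_seed(seed, 977L), {
      null <- vapply(seq_len(n_perm), function(i) {
        pm <- sample.int(n)
        vp <- lower_tri_values(ma[pm, pm])
        okp <- complete.cases(vp, vb)
        if (sum(okp) < 3) return(NA_real_)
        cor(vp[okp], vb[okp], method = "spearman")
      }, numeric(1))
    })
    p <- (1 + sum(abs(null) >= abs(rho), na.rm = TRUE)) / (1 + sum(!is.na(null)))
  }
  structure(list(rho = rho, n_pairs = sum(ok), p = p), class = "rdm_correlation")
}

#' Steiger's z for two dependent correlations sharing one variable
#'
#' Tests whether a common variable (e.g. a stimulus model RDM) correlates
#' more strongly with one measure than another, given the correlation
#' between the two measures. Uses Fisher-transformed correlations with the
#' pooled-correlation covariance correction (Steiger, 1980). Positive z
#' means `r1` exceeds `r2`.
#'
#' @param r1,r2 the two dependent correlations (each with the shared
#'   variable).
#' @param r12 correlation between the two non-shared variables.
#' @param n number of observations the correlations were computed from.
#' @return list of class `dependent_cor_test`: `z`, the inputs, and a
#'   two-sided normal `p`.
#' @export
compare_dependent_correlations <- function(r1, r2, r12, n) {
  stopifnot(abs(r1) < 1, abs(r2) < 1, abs(r12) < 1, n > 3)
  z1 <- atanh(r1)
  z2 <- atanh(r2)
  rbar <- (r1 + r2) / 2
  # covariance of the two correlations via the pooled estimate (Steiger 1980)
  psi <- r12 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r12^2)
  cbar <- psi / (1 - rbar^2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cbar))
  structure(list(z = z, r1 = r1, r2 = r2, r12 = r12, n = n,
                 p = 2 * stats::pnorm(-abs(z))),
            class = "dependent_cor_test")
}

#' Correlate a neural RDM series with a behavioral RDM over time
#'
#' Applies [correlate_rdms()] at every time point of a neural RDM series,
#' giving the time course of behavioral relevance of the neural
#' representational structure.
#'
#' @param neural an `rdm_series`.
#' @param behavior a behavioral or model RDM over the same stimuli.
#' @return object of class `correlation_timecourse`: list with `values`
#'   (Spearman rho per time point), `time`, labels.
#' @export
neural_behavior_timecourse <- function(neural, behavior) {
  stopifnot(inherits(neural, "rdm_series"))
  mb <- rdm_values(behavior)
  if (!all(dim(mb) == length(neural$stimuli)))
    stop("behavioral RDM dimensions must match the neural stimulus set")
  vb <- safe_rank(lower_tri_values(mb))
  lt <- lower_tri_mat(neural$values)
  vals <- apply(lt, 2, function(v) {
    rv <- safe_rank(v)
    if (anyNA(rv) || anyNA(vb)) {
      ok <- complete.cases(v, lower_tri_values(mb))
      if (sum(ok) < 3) return(NA_real_)
      return(cor(v[ok], lower_tri_values(mb)[ok], method = "spearman"))
    }
    cor(rv, vb)
  })
  structure(list(values = vals, time = neural$time,
                 condition = neural$condition, hemisphere = neural$hemisphere,
                 hemifield = neural$hemifield),
            class = "correlation_timecourse")
}
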