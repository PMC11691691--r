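# Interhemispheric representational similarity: time x time correlation
# surfaces, transfer-delay profiles, asymmetry tests, split-half consistency.

# Column-wise average-fractional ranks of the pair x time matrix; columns
# with zero variance (or NA) become all-NA so their correlations are
# undefined rather than spurious.
rank_columns <- function(m) {
  apply(m, 2, safe_rank)
}

# Pearson correlation between all column pairs of two pair x time rank
# matrices: standardize columns, crossprod. NA columns give NA rows/cols.
cor_columns <- function(ra, rb) {
  n <- nrow(ra)
  za <- scale(ra)
  zb <- scale(rb)
  out <- crossprod(za, zb) / (n - 1)
  out[out > 1] <- 1
  out[out < -1] <- -1
  out
}

#' Time-generalized cross-hemisphere RDM correlation
#'
#' Correlates the neural RDMs of two hemispheres for every pair of time
#' points, using split-half cross-validation so that correlated trial noise
#' cannot inflate the result: RDM series from odd sequences of one
#' hemisphere are correlated with even sequences of the other, both cross
#' pairings are computed (odd-A x even-B and even-A x odd-B) and averaged.
#' The correlation at each (t_a, t_b) is the Spearman rank correlation of
#' the unique lower-triangle cells (630 for 36 stimuli). Time points whose
#' triangle has zero variance yield undefined (NA) entries, which downstream
#' averages exclude.
#'
#' @param a_odd,a_even `rdm_series` for hemisphere A (rows of the output;
#'   by convention the contralateral hemisphere), odd and even splits.
#' @param b_odd,b_even `rdm_series` for hemisphere B (columns; ipsilateral).
#'   If `a_even`/`b_odd` are NULL only the single pairing
#'   `a_odd` x `b_even` is used.
#' @return object of class `timegen_matrix`: list with `values`
#'   (T_a x T_b matrix of rank correlations), `time_a`, `time_b`, labels.
#' @export
crosscorrelate_timegen <- function(a_odd, b_even, a_even = NULL, b_odd = NULL) {
  stopifnot(inherits(a_odd, "rdm_series"), inherits(b_even, "rdm_series"))
  if (!identical(a_odd$stimuli, b_even$stimuli))
    stop("RDM series must share the same stimulus set")
  if (identical(a_odd$split, b_even$split) && a_odd$split != "all")
    stop("split-half correlation requires different splits")
  ra <- rank_columns(lower_tri_mat(a_odd$values))
  rb <- rank_columns(lower_tri_mat(b_even$values))
  m <- cor_columns(ra, rb)
  if (!is.null(a_even) && !is.null(b_odd)) {
    stopifnot(inherits(a_even, "rdm_series"), inherits(b_odd, "rdm_series"))
    m2 <- cor_columns(rank_columns(lower_tri_mat(a_even$values)),
                      rank_columns(lower_tri_mat(b_odd$values)))
    both_na <- is.na(m) & is.na(m2)
    m <- apply(simplify2array(list(m, m2)), c(1, 2), mean, na.rm = TRUE)
    m[both_na] <- NA_real_
  }
  structure(list(values = m, time_a = a_odd$time, time_b = b_even$time,
                 condition = a_odd$condition,
                 hemisphere_a = a_odd$hemisphere, hemisphere_b = b_even$hemisphere),
            class = "timegen_matrix")
}

#' @export
print.timegen_matrix <- function(x, ...) {
  cat(sprintf("<timegen_matrix> %d x %d time points (%s rows x %s columns), condition %s\n",
              nrow(x$values), ncol(x$values), x$hemisphere_a, x$hemisphere_b,
              x$condition))
  invisible(x)
}

#' Interhemispheric delay profile from a time x time correlation matrix
#'
#' Averages the time-generalization surface along off-center diagonals: for
#' each delay d, the mean of `values[t, t + d]` over reference times t inside
#' `window` (cells falling outside either axis, or undefined, are skipped).
#' With rows = contralateral time and columns = ipsilateral time, positive
#' delays mean the contralateral hemisphere leads; the profile peaks near the
#' true transfer delay.
#'
#' @param tg a `timegen_matrix`.
#' @param delays integer delays in ms (default -100..100).
#' @param window ms pair restricting the reference (row) times (default
#'   0..500).
#' @return object of class `delay_profile`: list with `delays` and `values`
#'   (mean correlation per delay).
#' @export
delay_profile <- function(tg, delays = -100:100, window = c(0, 500)) {
  stopifnot(inherits(tg, "timegen_matrix"))
  rows <- which(tg$time_a >= window[1] & tg$time_a <= window[2])
  if (!length(rows)) stop("window lies outside the row time axis")
  vals <- vapply(delays, function(d) {
    cols <- match(tg$time_a[rows] + d, tg$time_b)
    ok <- !is.na(cols)
    if (!any(ok)) return(NA_real_)
    mean(tg$values[cbind(rows[ok], cols[ok])], na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(vals))) stop("no diagonal cells remain after clipping")
  structure(list(delays = as.integer(delays), values = vals),
            class = "delay_profile")
}

#' Test the asymmetry of interhemispheric delay profiles
#'
#' For each absolute delay |d|, compares the profile value at +d
#' ("contralateral earlier") with the value at -d ("ipsilateral earlier")
#' across participants using the directional interval-null JZS Bayes factor
#' ([jzs_interval_bf()] with mu0 = 0). Evidence for positive differences at
#' an offset band indicates that contralateral processing precedes
#' ipsilateral processing by delays in that band.
#'
#' @param profiles list of `delay_profile` objects (one per participant, all
#'   on the same delay grid) or a participants x delays matrix whose column
#'   names are the delays.
#' @param spec a [bf_spec()]; default: direction "greater", mu0 = 0.
#' @return data.frame with columns `abs_delay` and `bf`.
#' @export
asymmetry_test <- function(profiles, spec = bf_spec(direction = "greater", mu0 = 0)) {
  if (is.list(profiles) && inherits(profiles[[1]], "delay_profile")) {
    delays <- profiles[[1]]$delays
    mat <- do.call(rbind, lapply(profiles, function(p) {
      stopifnot(identical(p$delays, delays))
      p$values
    }))
    colnames(mat) <- delays
  } else {
    mat <- as.matrix(profiles)
    delays <- as.integer(colnames(mat))
  }
  if (nrow(mat) < 2) stop("asymmetry test requires at least 2 participants")
  pos <- sort(delays[delays > 0])
  pos <- pos[(-pos) %in% delays]
  if (!length(pos)) stop("no matching +/- delay pairs in the profile grid")
  bf <- vapply(pos, function(d) {
    diffs <- mat[, as.character(d)] - mat[, as.character(-d)]
    jzs_interval_bf(diffs, spec)
  }, numeric(1))
  data.frame(abs_delay = pos, bf = bf)
}

#' Split-half consistency within and across hemispheres
#'
#' Quantifies how reliable each hemisphere's representational structure is
#' (within-hemisphere split-half correlation, a noise ceiling) versus how
#' much of it is shared across hemispheres (between-hemisphere split-half
#' correlation), per time point along the diagonal. Results are collapsed to
#' contralateral/ipsilateral via [collapse_contra_ipsi()] for the within
#' curves; the across curve is averaged over hemifields.
#'
#' @param rdms named list of `rdm_series` with names
#'   `<hemisphere>_<hemifield>_<split>` covering both hemispheres, both
#'   hemifields and both odd/even splits (8 elements).
#' @return list of numeric time courses `within_contra`, `within_ipsi`,
#'   `across`, plus `time`.
#' @export
consistency_within_across <- function(rdms) {
  need <- as.vector(outer(c("left", "right"),
                          as.vector(outer(c("LVF", "RVF"), c("odd", "even"),
                                          paste, sep = "_")),
                          paste, sep = "_"))
  missing <- setdiff(need, names(rdms))
  if (length(missing)) stop("missing rdm series: ", paste(missing, collapse = ", "))
  diag_cor <- function(a, b) {
    m <- cor_columns(rank_columns(lower_tri_mat(a$values)),
                     rank_columns(lower_tri_mat(b$values)))
    diag(m)
  }
  within <- lapply(c(left_LVF = "left_LVF", left_RVF = "left_RVF",
                     right_LVF = "right_LVF", right_RVF = "right_RVF"),
                   function(k) diag_cor(rdms[[paste0(k, "_odd")]],
                                        rdms[[paste0(k, "_even")]]))
  wc <- collapse_contra_ipsi(within)
  across_hf <- lapply(c("LVF", "RVF"), function(hf) {
    tg <- crosscorrelate_timegen(rdms[[paste0("left_", hf, "_odd")]],
                                 rdms[[paste0("right_", hf, "_even")]],
                                 rdms[[paste0("left_", hf, "_even")]],
                                 rdms[[paste0("right_", hf, "_odd")]])
    diag(tg$values)
  })
  list(within_contra = wc$contralateral, within_ipsi = wc$ipsilateral,
       across = (across_hf[[1]] + across_hf[[2]]) / 2,
       time = rdms[["left_LVF_odd"]]$time)
}
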