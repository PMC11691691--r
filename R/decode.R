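#' Occipito-temporal electrode clusters
#'
#' Default hemisphere clusters used for lateralized decoding: six
#' occipito-temporal electrodes per side in 10-20 nomenclature.
#'
#' @param n_channels electrodes per cluster (1..6; the first `n_channels`
#'   of each default cluster are used).
#' @return list with character vectors `left` and `right`.
#' @export
electrode_clusters <- function(n_channels = 6) {
  left <- c("O1", "PO3", "PO7", "P3", "P5", "P7")
  right <- c("O2", "PO4", "PO8", "P4", "P6", "P8")
  stopifnot(n_channels >= 1, n_channels <= length(left))
  list(left = left[seq_len(n_channels)], right = right[seq_len(n_channels)])
}

#' Subsample word-stimulus presentations to match image counts
#'
#' Word stimuli appear twice as often as image stimuli in the design (two
#' case variants of each label share a typeface). To equate trial numbers
#' per class before decoding, each word stimulus is subsampled without
#' replacement to `n_keep` presentations per hemifield per condition,
#' stratified over sequences as evenly as possible. Image presentations are
#' untouched. Dropped presentations are blanked (set to NA) in the relevant
#' hemifield column; a dual-condition row keeps its other-hemifield stimulus,
#' and a single-condition row whose only stimulus is dropped is removed.
#'
#' @param trials a trial table from [generate_design()].
#' @param stimuli the matching [stimulus_set()].
#' @param n_keep presentations to retain per word stimulus per hemifield per
#'   condition (48 in the emulated design: half of the 96 available).
#' @param seed integer seed for the random subsampling.
#' @return trial table with word presentations balanced. Deterministic for a
#'   given seed.
#' @export
balance_word_trials <- function(trials, stimuli = stimulus_set(), n_keep = 48,
                                seed = 1L) {
  stopifnot(n_keep >= 1)
  word_ids <- stimuli$stimulus_id[stimuli$modality == "word"]
  out <- as.data.frame(trials)
  with_seed(derive_seed(seed, 211L), {
    for (cond in unique(out$condition)) {
      for (hf_col in c("lvf_stimulus", "rvf_stimulus")) {
        for (w in word_ids) {
          rows <- which(out$condition == cond & !is.na(out[[hf_col]]) &
                          out[[hf_col]] == w)
          n_avail <- length(rows)
          if (n_avail == 0) next
          if (n_avail < n_keep)
            stop(sprintf(
              "stimulus %d has only %d %s presentations in the %s condition (need %d)",
              w, n_avail, if (hf_col == "lvf_stimulus") "LVF" else "RVF",
              cond, n_keep))
          if (n_avail == n_keep) next
          seqs <- out$sequence_index[rows]
          drop_rows <- rows[-even_stratified_sample(seqs, n_keep)]
          out[[hf_col]][drop_rows] <- NA_integer_
        }
      }
    }
  })
  empty <- out$condition == "single" & is.na(out$lvf_stimulus) & is.na(out$rvf_stimulus)
  out <- out[!empty, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trial_table", "data.frame")
  out
}

# Sample `k` positions from a vector of stratum labels, spreading the picks
# over strata as evenly as the per-stratum capacities allow. Returns indices
# into `strata`.
even_stratified_sample <- function(strata, k) {
  groups <- split(seq_along(strata), strata)
  groups <- lapply(groups, function(g) g[sample.int(length(g))])
  cap <- vapply(groups, length, integer(1))
  if (sum(cap) < k) stop("not enough trials to sample")
  alloc <- integer(length(groups))
  for (i in seq_len(k)) {
    open <- which(alloc < cap)
    pick <- open[alloc[open] == min(alloc[open])]
    if (length(pick) > 1) pick <- sample(pick, 1)
    alloc[pick] <- alloc[pick] + 1L
  }
  unlist(lapply(seq_along(groups), function(g) head(groups[[g]], alloc[g])),
         use.names = FALSE)
}

#' Time-resolved pairwise linear-discriminant decoding
#'
#' For every unordered pair of stimuli and every time sample, trains a
#' two-class linear discriminant on the channel pattern of one electrode
#' cluster (training folds) and scores the held-out fold; accuracy is the
#' proportion of correct predictions pooled over folds. Folds contain whole,
#' independent trial sequences: sequences of the chosen split are ordered
#' and assigned to folds round-robin, so `n_folds` must divide the sequence
#' count (12 for the full design, 6 within an odd/even half). The shared
#' covariance is regularized with Ledoit-Wolf analytic shrinkage toward the
#' scaled identity (needed for stability with 6 channels and few trials per
#' fold); decisions on the boundary go to the first class by stimulus id.
#' Decoding is applied to each participant's trials separately by the caller.
#'
#' @param epochs an `epoch_set` (one participant's data).
#' @param cluster "left" or "right": which hemisphere cluster to decode from.
#' @param condition "single" or "dual".
#' @param hemifield "LVF" or "RVF": decode the stimulus shown in this
#'   hemifield (its identity labels the trials).
#' @param n_folds cross-validation folds; must divide the sequence count.
#' @param split "all", "odd" or "even" trial sequences (split-half RSA uses
#'   the odd/even halves so correlations never share trials).
#' @param shrinkage "lw" for Ledoit-Wolf analytic shrinkage or a fixed
#'   intensity in [0, 1] (0 disables regularization).
#' @param time_window optional ms pair restricting the decoded time axis.
#' @return object of class `rdm_series`: list with `values`
#'   (n_stim x n_stim x T symmetric accuracy array, diagonal NA), `stimuli`
#'   (ids on the matrix axes), `time`, and the `split`, `condition`,
#'   `hemifield`, `hemisphere`, `n_folds` labels. 36 stimuli give 630 unique
#'   informative cells per time point.
#' @export
pairwise_decode <- function(epochs, cluster = c("left", "right"),
                            condition = c("single", "dual"),
                            hemifield = c("LVF", "RVF"),
                            n_folds = 12, split = c("all", "odd", "even"),
                            shrinkage = "lw", time_window = NULL) {
  cluster <- match.arg(cluster)
  condition <- match.arg(condition)
  hemifield <- match.arg(hemifield)
  split <- match.arg(split)
  stopifnot(inherits(epochs, "epoch_set"))
  if (length(unique(epochs$trials$participant)) > 1)
    stop("pairwise_decode expects a single participant's epochs")

  ch <- which(epochs$channels$cluster == cluster)
  expect_ch <- electrode_clusters(max(1, length(ch)))[[cluster]]
  missing_ch <- setdiff(expect_ch, epochs$channels$name[ch])
  if (length(ch) == 0 || length(missing_ch))
    stop(sprintf("cluster '%s' channels missing from epochs: %s", cluster,
                 paste(missing_ch, collapse = ", ")))

  stim_col <- if (hemifield == "LVF") "lvf_stimulus" else "rvf_stimulus"
  keep <- epochs$trials$condition == condition & !is.na(epochs$trials[[stim_col]])
  if (split != "all") {
    parity <- if (split == "odd") 1 else 0
    keep <- keep & (epochs$trials$sequence_index %% 2 == parity)
  }
  if (!any(keep)) stop(sprintf("no %s trials with a %s stimulus (split %s)",
                               condition, hemifield, split))
  tr <- epochs$trials[keep, , drop = FALSE]
  stim <- tr[[stim_col]]
  seqs <- sort(unique(tr$sequence_index))
  if (length(seqs) %% n_folds != 0)
    stop(sprintf("n_folds = %d does not divide the %d sequences of split '%s'",
                 n_folds, length(seqs), split))
  fold <- (match(tr$sequence_index, seqs) - 1L) %% n_folds

  stim_ids <- sort(unique(stim))
  labels <- match(stim, stim_ids)
  tab <- table(factor(labels, levels = seq_along(stim_ids)),
               factor(fold, levels = 0:(n_folds - 1)))
  if (any(tab == 0)) {
    bad <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("stimulus %d absent from fold %d", stim_ids[bad[1]], bad[2] - 1))
  }

  t_idx <- seq_along(epochs$time)
  if (!is.null(time_window)) {
    t_idx <- which(epochs$time >= time_window[1] & epochs$time <= time_window[2])
    if (!length(t_idx)) stop("time_window outside the epoch time axis")
  }
  x <- epochs$data[keep, ch, t_idx, drop = FALSE]

  shrink <- if (identical(shrinkage, "lw")) -1 else {
    stopifnot(is.numeric(shrinkage), shrinkage >= 0, shrinkage <= 1)
    as.numeric(shrinkage)
  }
  values <- cpp_pairwise_decode(x, as.integer(labels), as.integer(fold),
                                length(stim_ids), shrink)
  dimnames(values) <- list(stim_ids, stim_ids, NULL)
  structure(list(values = values, stimuli = stim_ids,
                 time = epochs$time[t_idx], split = split,
                 condition = condition, hemifield = hemifield,
                 hemisphere = cluster, n_folds = n_folds),
            class = "rdm_series")
}

#' @export
print.rdm_series <- function(x, ...) {
  cat(sprintf("<rdm_series> %d stimuli (%d pairs) x %d time points; %s/%s/%s hemisphere, split %s\n",
              length(x$stimuli), choose(length(x$stimuli), 2), length(x$time),
              x$condition, x$hemifield, x$hemisphere, x$split))
  invisible(x)
}

#' Mean pairwise decoding accuracy over time
#'
#' Averages the unique lower-triangle cells of a neural RDM series at each
#' time point, the standard summary of stimulus information in a cluster.
#'
#' @param rdm an `rdm_series` from [pairwise_decode()].
#' @return object of class `accuracy_timecourse`: list with `values`
#'   (numeric, one mean accuracy per time point), `time`, and condition
#'   labels carried over.
#' @export
mean_accuracy <- function(rdm) {
  stopifnot(inherits(rdm, "rdm_series"))
  lt <- lower_tri_mat(rdm$values)
  structure(list(values = colMeans(lt, na.rm = TRUE), time = rdm$time,
                 condition = rdm$condition, hemifield = rdm$hemifield,
                 hemisphere = rdm$hemisphere, split = rdm$split),
            class = "accuracy_timecourse")
}

#' Collapse hemisphere-by-hemifield results to contralateral/ipsilateral
#'
#' Averages the four hemisphere x hemifield combinations into contralateral
#' (left hemisphere with RVF stimuli, right hemisphere with LVF stimuli) and
#' ipsilateral (left/LVF, right/RVF) results. Averaging is cell-wise for RDM
#' series and sample-wise for time courses or plain numeric arrays.
#'
#' @param results named list with elements `left_LVF`, `left_RVF`,
#'   `right_LVF`, `right_RVF` (all of the same type and shape).
#' @return list with elements `contralateral` and `ipsilateral`.
#' @export
collapse_contra_ipsi <- function(results) {
  need <- c("left_LVF", "left_RVF", "right_LVF", "right_RVF")
  missing <- setdiff(need, names(results))
  if (length(missing))
    stop("missing hemisphere x hemifield combination(s): ",
         paste(missing, collapse = ", "))
  avg2 <- function(a, b) {
    if (inherits(a, "rdm_series") || inherits(a, "accuracy_timecourse")) {
      out <- a
      out$values <- (a$values + b$values) / 2
      out$hemisphere <- "collapsed"
      out$hemifield <- "collapsed"
      out
    } else {
      (a + b) / 2
    }
  }
  list(contralateral = avg2(results$left_RVF, results$right_LVF),
       ipsilateral = avg2(results$left_LVF, results$right_RVF))
}
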