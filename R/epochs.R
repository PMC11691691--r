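#' Generate EEG-like epochs with known hemispheric structure
#'
#' Simulates epoched multichannel data for every trial of a trial table.
#' Each stimulus has a latent activation pattern per hemifield (i.e. per
#' contralateral source hemisphere). The cluster contralateral to a stimulus
#' receives that pattern, projected through a participant-specific random
#' orthonormal channel map and modulated by a half-cosine response kernel
#' starting at `contra_onset`. The ipsilateral cluster receives a
#' rank-reduced copy (the first `ceiling(retention * pattern_dim)` latent
#' components), scaled by `ipsi_gain` and delayed by `transfer_delay` --
#' the generator's model of interhemispheric transfer. In dual trials both
#' hemifields' stimuli contribute and all pattern amplitude after
#' `interference_onset` is attenuated by `interference_attenuation`.
#' Additive AR(1) Gaussian noise is scaled so that the ratio of signal RMS to
#' noise RMS on cluster channels within 0-500 ms equals `snr`; `snr = 0`
#' yields pure-noise epochs.
#'
#' When `w_image` or `w_concept` is nonzero, each stimulus pattern is a
#' normalized mixture of a stimulus-unique component, a component shared by
#' all stimuli of the same modality (weight `w_image`), and a component
#' shared by all stimuli of the same concept (weight `w_concept`), making
#' same-modality / same-concept stimulus pairs harder to discriminate and
#' injecting structure that behavioral model RDMs can explain.
#'
#' Fully reproducible: a given config (including its seed) and trial table
#' give bit-identical output.
#'
#' @param config a [simulation_config()].
#' @param trials a trial table from [generate_design()] (may be a subset,
#'   e.g. a single participant or condition).
#' @param stimuli the [stimulus_set()] the trial table was built from.
#' @return list of class `epoch_set` with elements `data` (trials x channels
#'   x time array), `trials` (the metadata rows), `channels` (data.frame with
#'   `name`, `cluster` in left/right/other), `time` (ms, step 1).
#' @export
generate_epochs <- function(config, trials, stimuli = stimulus_set()) {
  stopifnot(inherits(config, "simulation_config"), nrow(trials) > 0)
  validate_simulation_config(config)
  time <- seq(config$epoch_window[1], config$epoch_window[2])
  n_t <- length(time)
  C <- config$n_channels_per_cluster
  d <- config$pattern_dim

  clusters <- electrode_clusters(C)
  channels <- data.frame(
    name = c(clusters$left, clusters$right, c("Oz", "POz")),
    cluster = c(rep("left", C), rep("right", C), rep("other", 2)),
    stringsAsFactors = FALSE)
  n_ch <- nrow(channels)
  ch_idx <- list(left = which(channels$cluster == "left"),
                 right = which(channels$cluster == "right"))

  # response kernels sampled on the epoch time axis
  kern <- function(onset) {
    tau <- time - onset
    k <- numeric(n_t)
    inside <- tau >= 0 & tau <= config$kernel_width
    k[inside] <- sin(pi * tau[inside] / config$kernel_width)
    k
  }
  k_contra <- kern(config$contra_onset)
  k_ipsi <- kern(config$contra_onset + config$transfer_delay)
  if (config$contra_onset + config$transfer_delay >= config$epoch_window[2])
    stop("transfer delay pushes the ipsilateral response past the epoch end")

  d_keep <- max(1L, as.integer(ceiling(config$retention * d)))
  sid <- stimuli$stimulus_id
  n_stim_max <- max(sid)
  w_u <- 1  # unique-component weight; modality/concept components add to it
  norm_w <- sqrt(w_u + config$w_image + config$w_concept)

  participants <- sort(unique(trials$participant))
  data <- array(0, dim = c(nrow(trials), n_ch, n_t))
  interference <- time >= config$interference_onset

  for (p in participants) {
    p_rows <- which(trials$participant == p)
    ptr <- trials[p_rows, , drop = FALSE]
    with_seed(derive_seed(config$seed, 7001L + p), {
      # latent patterns per hemifield (contralateral source) x stimulus
      shared_mod <- list(image = matrix(rnorm(2 * d), d, 2),
                         word = matrix(rnorm(2 * d), d, 2))
      concepts <- unique(stimuli$concept)
      shared_con <- array(rnorm(d * length(concepts) * 2),
                          dim = c(d, length(concepts), 2))
      P <- array(NA_real_, dim = c(d, n_stim_max, 2))  # dims: comp, stim, hemifield
      for (hf in 1:2) {
        for (i in seq_along(sid)) {
          u <- rnorm(d)
          m <- shared_mod[[stimuli$modality[i]]][, hf]
          cc <- shared_con[, match(stimuli$concept[i], concepts), hf]
          P[, sid[i], hf] <- (sqrt(w_u) * u + sqrt(config$w_image) * m +
                                sqrt(config$w_concept) * cc) / norm_w
        }
      }
      # participant-specific orthonormal channel maps per hemisphere
      A <- list(left = qr.Q(qr(matrix(rnorm(C * d), C, d))),
                right = qr.Q(qr(matrix(rnorm(C * d), C, d))))

      signal <- array(0, dim = c(length(p_rows), n_ch, n_t))
      if (config$snr > 0) {
        hf_cols <- c(lvf = "lvf_stimulus", rvf = "rvf_stimulus")
        hf_num <- c(lvf = 1L, rvf = 2L)
        contra_of <- c(lvf = "right", rvf = "left")
        for (hf in c("lvf", "rvf")) {
          s_trial <- ptr[[hf_cols[hf]]]
          present <- which(!is.na(s_trial))
          if (!length(present)) next
          contra <- contra_of[[hf]]
          ipsi <- setdiff(c("left", "right"), contra)
          pat <- P[, , hf_num[hf], drop = TRUE]
          if (is.null(dim(pat))) pat <- matrix(pat, nrow = d)
          pat_ipsi <- pat
          if (d_keep < d) pat_ipsi[(d_keep + 1):d, ] <- 0
          topo_c <- A[[contra]] %*% pat            # C x n_stim_max
          topo_i <- config$ipsi_gain * (A[[ipsi]] %*% pat_ipsi)
          for (s in unique(s_trial[present])) {
            trs <- present[s_trial[present] == s]
            blk_c <- outer(topo_c[, s], k_contra)  # C x n_t
            blk_i <- outer(topo_i[, s], k_ipsi)
            rep_c <- aperm(array(blk_c, dim = c(C, n_t, length(trs))), c(3, 1, 2))
            rep_i <- aperm(array(blk_i, dim = c(C, n_t, length(trs))), c(3, 1, 2))
            signal[trs, ch_idx[[contra]], ] <- signal[trs, ch_idx[[contra]], ] + rep_c
            signal[trs, ch_idx[[ipsi]], ] <- signal[trs, ch_idx[[ipsi]], ] + rep_i
          }
        }
        dual <- ptr$condition == "dual"
        if (any(dual) && config$interference_attenuation < 1 && any(interference)) {
          signal[dual, , interference] <-
            signal[dual, , interference] * config$interference_attenuation
        }
        win <- time >= 0 & time <= 500
        sig_ch <- c(ch_idx$left, ch_idx$right)
        rms_sig <- sqrt(mean(signal[, sig_ch, win, drop = FALSE]^2))
        sigma <- if (rms_sig > 0) rms_sig / config$snr else 1
      } else {
        sigma <- 1
      }

      phi <- config$noise_autocorr
      innov_sd <- sigma * sqrt(1 - phi^2)
      n_series <- length(p_rows) * n_ch
      eps <- matrix(rnorm(n_series * n_t, sd = innov_sd), nrow = n_t)
      if (phi > 0) {
        noise <- eps
        noise[1, ] <- rnorm(n_series, sd = sigma)  # stationary start
        for (tt in 2:n_t) noise[tt, ] <- phi * noise[tt - 1, ] + eps[tt, ]
      } else {
        noise <- eps
      }
      noise <- aperm(array(noise, dim = c(n_t, length(p_rows), n_ch)), c(2, 3, 1))
      data[p_rows, , ] <- signal + noise
    })
  }

  structure(list(data = data, trials = as.data.frame(trials),
                 channels = channels, time = time),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d channels x %d time points (%d..%d ms)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$time), max(x$time)))
  cat(sprintf("  participants: %s; conditions: %s\n",
              paste(sort(unique(x$trials$participant)), collapse = ","),
              paste(sort(unique(x$trials$condition)), collapse = ",")))
  invisible(x)
}
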