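#' Simulation configuration
#'
#' Bundles and validates every parameter of the synthetic EEG generator. The
#' defaults mirror the experimental design being emulated (20 participants,
#' 24 single-peripheral and 12 dual-peripheral sequences, 1000-Hz sampling,
#' epochs -100..800 ms) together with physiologically motivated values for
#' the quantities the generator must invent: an interhemispheric transfer
#' delay of 20 ms (reported estimates cluster around 15-30 ms), dual-stimulus
#' interference starting at 150 ms, and an ipsilateral response that is a
#' rank-reduced, attenuated copy of the contralateral one.
#'
#' @param n_participants number of simulated participants.
#' @param n_single_sequences single-peripheral sequences per participant.
#' @param n_dual_sequences dual-peripheral sequences per participant.
#' @param sample_rate sampling rate in Hz (fixed at 1000; 1-ms resolution).
#' @param epoch_window epoch limits in ms relative to stimulus onset.
#' @param contra_onset latency (ms) at which the contralateral response begins.
#' @param transfer_delay interhemispheric transfer delay Delta in ms (>= 0).
#' @param retention fraction rho in [0,1] of latent pattern dimensions carried
#'   to the ipsilateral hemisphere (rank reduction of the transferred copy).
#' @param ipsi_gain amplitude gain gamma in (0,1] of the ipsilateral copy.
#' @param interference_onset ms after which dual-condition amplitudes are
#'   attenuated.
#' @param interference_attenuation multiplicative attenuation beta in (0,1]
#'   applied in dual trials after `interference_onset` (1 = no interference).
#' @param snr ratio of signal RMS to noise RMS on cluster channels within
#'   0-500 ms; `snr = 0` produces pure-noise epochs.
#' @param pattern_dim latent pattern components per stimulus (<= channels per
#'   cluster).
#' @param n_channels_per_cluster electrodes per hemisphere cluster.
#' @param noise_autocorr AR(1) coefficient of the additive noise, in [0,1).
#' @param kernel_width width in ms of the half-cosine response kernel.
#' @param w_image,w_concept nonnegative weights of shared modality-level and
#'   concept-level components mixed into each stimulus's latent pattern
#'   (0 = fully stimulus-unique patterns). Nonzero values inject structure
#'   that image/concept model RDMs can explain.
#' @param seed integer seed governing every random draw of the generator.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 20,
                              n_single_sequences = 24,
                              n_dual_sequences = 12,
                              sample_rate = 1000,
                              epoch_window = c(-100, 800),
                              contra_onset = 80,
                              transfer_delay = 20,
                              retention = 0.5,
                              ipsi_gain = 0.6,
                              interference_onset = 150,
                              interference_attenuation = 0.7,
                              snr = 0.2,
                              pattern_dim = 6,
                              n_channels_per_cluster = 6,
                              noise_autocorr = 0.9,
                              kernel_width = 100,
                              w_image = 0,
                              w_concept = 0,
                              seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              n_single_sequences = as.integer(n_single_sequences),
              n_dual_sequences = as.integer(n_dual_sequences),
              sample_rate = sample_rate,
              epoch_window = as.numeric(epoch_window),
              contra_onset = contra_onset,
              transfer_delay = transfer_delay,
              retention = retention,
              ipsi_gain = ipsi_gain,
              interference_onset = interference_onset,
              interference_attenuation = interference_attenuation,
              snr = snr,
              pattern_dim = as.integer(pattern_dim),
              n_channels_per_cluster = as.integer(n_channels_per_cluster),
              noise_autocorr = noise_autocorr,
              kernel_width = kernel_width,
              w_image = w_image,
              w_concept = w_concept,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$n_participants >= 1,
            cfg$n_single_sequences >= 0,
            cfg$n_dual_sequences >= 0,
            cfg$sample_rate == 1000,
            length(cfg$epoch_window) == 2,
            cfg$epoch_window[1] < 0, cfg$epoch_window[2] > 0,
            cfg$contra_onset >= 0,
            cfg$transfer_delay >= 0,
            cfg$retention >= 0, cfg$retention <= 1,
            cfg$ipsi_gain > 0, cfg$ipsi_gain <= 1,
            cfg$interference_attenuation > 0, cfg$interference_attenuation <= 1,
            cfg$snr >= 0,
            cfg$pattern_dim >= 1,
            cfg$pattern_dim <= cfg$n_channels_per_cluster,
            cfg$n_channels_per_cluster >= 1,
            cfg$noise_autocorr >= 0, cfg$noise_autocorr < 1,
            cfg$kernel_width > 0,
            cfg$w_image >= 0, cfg$w_concept >= 0)
  if (cfg$contra_onset + cfg$transfer_delay >= cfg$epoch_window[2])
    stop("contra_onset + transfer_delay must fall before the epoch end")
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf("  %d participants; %d single + %d dual sequences\n",
              x$n_participants, x$n_single_sequences, x$n_dual_sequences))
  cat(sprintf("  epochs %d..%d ms @ %g Hz; contra onset %g ms, transfer delay %g ms\n",
              x$epoch_window[1], x$epoch_window[2], x$sample_rate,
              x$contra_onset, x$transfer_delay))
  cat(sprintf("  retention %.2f, ipsi gain %.2f, interference %s%g ms x %.2f\n",
              x$retention, x$ipsi_gain, ">", x$interference_onset,
              x$interference_attenuation))
  cat(sprintf("  snr %.3g, AR(1) %.2f, seed %d\n",
              x$snr, x$noise_autocorr, x$seed))
  invisible(x)
}
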