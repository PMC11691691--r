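#' Generate the lateralized rapid-presentation trial design
#'
#' Builds the full trial table for every participant and sequence. Each
#' single-peripheral sequence presents every image stimulus four times (two
#' in each hemifield) and every word stimulus eight times (four per
#' hemifield) -- words are doubled because each label appears in two case
#' variants of the same typeface, and the decoding stage later subsamples
#' them back to the image count. Each dual-peripheral sequence pairs an
#' independently shuffled left-hemifield stream with a right-hemifield stream
#' (same per-stimulus counts per side), one stimulus to each hemifield on
#' every trial. Trials are 200 ms apart (100 ms on, 100 ms off) and ordered
#' randomly within a sequence.
#'
#' With the default 36-stimulus set this yields 192 trials per sequence and,
#' over 24 single sequences, 48 presentations of each image stimulus per
#' hemifield.
#'
#' @param config a [simulation_config()].
#' @param stimuli a [stimulus_set()].
#' @return data.frame of class `trial_table` with columns `participant`,
#'   `condition` ("single"/"dual"), `sequence_index`, `trial_index`,
#'   `lvf_stimulus`, `rvf_stimulus` (stimulus id or NA), `onset_time` (ms).
#' @export
generate_design <- function(config, stimuli = stimulus_set()) {
  stopifnot(inherits(config, "simulation_config"), inherits(stimuli, "stimulus_set"))
  img_ids <- stimuli$stimulus_id[stimuli$modality == "image"]
  word_ids <- stimuli$stimulus_id[stimuli$modality == "word"]
  # per-sequence, per-hemifield presentation counts
  side_stream <- c(rep(img_ids, each = 2L), rep(word_ids, each = 4L))
  n_trials_single <- 2L * length(side_stream)

  with_seed(derive_seed(config$seed, 101L), {
    out <- vector("list", config$n_participants * 2L)
    k <- 0L
    for (p in seq_len(config$n_participants)) {
      if (config$n_single_sequences > 0) {
        seqs <- lapply(seq_len(config$n_single_sequences), function(s) {
          lvf <- c(side_stream, rep(NA_integer_, length(side_stream)))
          rvf <- c(rep(NA_integer_, length(side_stream)), side_stream)
          ord <- sample.int(n_trials_single)
          data.frame(participant = p, condition = "single", sequence_index = s,
                     trial_index = seq_len(n_trials_single),
                     lvf_stimulus = lvf[ord], rvf_stimulus = rvf[ord])
        })
        k <- k + 1L
        out[[k]] <- do.call(rbind, seqs)
      }
      if (config$n_dual_sequences > 0) {
        seqs <- lapply(seq_len(config$n_dual_sequences), function(s) {
          lvf <- rep(side_stream, 2L)[sample.int(n_trials_single)]
          rvf <- rep(side_stream, 2L)[sample.int(n_trials_single)]
          data.frame(participant = p, condition = "dual", sequence_index = s,
                     trial_index = seq_len(n_trials_single),
                     lvf_stimulus = lvf, rvf_stimulus = rvf)
        })
        k <- k + 1L
        out[[k]] <- do.call(rbind, seqs)
      }
    }
    trials <- do.call(rbind, out[seq_len(k)])
    trials$onset_time <- (trials$trial_index - 1L) * 200
    rownames(trials) <- NULL
    class(trials) <- c("trial_table", "data.frame")
    trials
  })
}
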