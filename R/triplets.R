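#' Simulate triplet odd-one-out responses
#'
#' Generates behavioral responses for the triplet similarity task: on each
#' trial three distinct stimuli are drawn uniformly, and the odd one out is
#' chosen by a Luce (softmax) rule over each stimulus's summed latent
#' dissimilarity to the other two. The latent dissimilarity matrix is a
#' nonnegative weighted sum of model RDMs; `decision_noise` is the softmax
#' temperature (as it tends to 0 the choice becomes the deterministic argmax).
#'
#' @param latent_rdms list of square dissimilarity matrices over the same
#'   stimulus set (e.g. from [build_model_rdms()]).
#' @param weights nonnegative weight per matrix.
#' @param n_participants number of simulated raters.
#' @param n_trials trials per participant (the emulated experiments used 400).
#' @param decision_noise positive softmax temperature.
#' @param seed integer seed.
#' @return data.frame of class `triplet_responses` with columns
#'   `participant`, `trial`, `stim_a`, `stim_b`, `stim_c`,
#'   `chosen` ("a"/"b"/"c").
#' @export
generate_triplet_responses <- function(latent_rdms, weights = rep(1, length(latent_rdms)),
                                       n_participants = 21, n_trials = 400,
                                       decision_noise = 0.1, seed = 1L) {
  stopifnot(length(latent_rdms) >= 1, length(weights) == length(latent_rdms),
            all(weights >= 0), decision_noise > 0,
            n_participants >= 1, n_trials >= 1)
  n <- nrow(latent_rdms[[1]])
  if (n < 3) stop("need at least 3 stimuli for a triplet task")
  D <- matrix(0, n, n)
  for (k in seq_along(latent_rdms)) {
    m <- as.matrix(latent_rdms[[k]])
    stopifnot(nrow(m) == n, ncol(m) == n)
    m[is.na(m)] <- 0
    D <- D + weights[k] * m
  }

  n_total <- n_participants * n_trials
  with_seed(seed, {
    trip <- t(replicate(n_total, sample.int(n, 3)))
    v <- cbind(D[trip[, c(1, 2)]] + D[trip[, c(1, 3)]],
               D[trip[, c(2, 1)]] + D[trip[, c(2, 3)]],
               D[trip[, c(3, 1)]] + D[trip[, c(3, 2)]])
    z <- v / decision_noise
    z <- z - apply(z, 1, max)
    pr <- exp(z)
    pr <- pr / rowSums(pr)
    u <- runif(n_total)
    pick <- 1L + (u > pr[, 1]) + (u > pr[, 1] + pr[, 2])
    out <- data.frame(participant = rep(seq_len(n_participants), each = n_trials),
                      trial = rep(seq_len(n_trials), n_participants),
                      stim_a = trip[, 1], stim_b = trip[, 2], stim_c = trip[, 3],
                      chosen = c("a", "b", "c")[pick],
                      stringsAsFactors = FALSE)
    class(out) <- c("triplet_responses", "data.frame")
    out
  })
}
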