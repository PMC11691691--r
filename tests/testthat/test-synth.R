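test_that("stimulus set has the full factorial composition", {
  stim <- stimulus_set()
  expect_equal(nrow(stim), 36)
  expect_equal(sum(stim$modality == "image"), 24)
  expect_equal(sum(stim$modality == "word"), 12)
  expect_equal(anyDuplicated(stim[, c("modality", "concept", "exemplar")]), 0L)
  expect_equal(sort(unique(stim$concept)),
               sort(c("bird", "fish", "tree", "boat", "face", "tool")))
})

test_that("design repeat schedule holds exactly for any seed", {
  stim <- stimulus_set()
  img <- stim$stimulus_id[stim$modality == "image"]
  wrd <- stim$stimulus_id[stim$modality == "word"]
  for (seed in c(2, 9)) {
    cfg <- simulation_config(n_participants = 1, n_single_sequences = 2,
                             n_dual_sequences = 1, seed = seed)
    des <- generate_design(cfg, stim)
    for (s in 1:2) {
      sq <- des[des$condition == "single" & des$sequence_index == s, ]
      expect_equal(nrow(sq), 192)
      # single trials carry exactly one stimulus
      expect_true(all(xor(is.na(sq$lvf_stimulus), is.na(sq$rvf_stimulus))))
      expect_true(all(table(factor(sq$lvf_stimulus, levels = img)) == 2))
      expect_true(all(table(factor(sq$rvf_stimulus, levels = img)) == 2))
      expect_true(all(table(factor(sq$lvf_stimulus, levels = wrd)) == 4))
      expect_true(all(table(factor(sq$rvf_stimulus, levels = wrd)) == 4))
    }
    dq <- des[des$condition == "dual", ]
    expect_equal(nrow(dq), 192)
    expect_true(all(!is.na(dq$lvf_stimulus) & !is.na(dq$rvf_stimulus)))
    expect_true(all(table(factor(dq$lvf_stimulus, levels = img)) == 4))
    expect_true(all(table(factor(dq$rvf_stimulus, levels = wrd)) == 8))
    expect_true(all(diff(dq$onset_time[order(dq$trial_index)]) == 200))
  }
})

test_that("single-sequence word counts follow the per-sequence rule", {
  cfg <- simulation_config(n_participants = 1, n_single_sequences = 1,
                           n_dual_sequences = 0, seed = 4)
  stim <- stimulus_set()
  des <- generate_design(cfg, stim)
  w <- stim$stimulus_id[stim$modality == "word"][1]
  expect_equal(sum(des$lvf_stimulus == w, na.rm = TRUE), 4)
})

test_that("design and epochs are bit-identical for identical config and seed", {
  cfg <- mini_config(n_single_sequences = 1, snr = 0.5, seed = 42)
  stim <- mini_stimuli()
  d1 <- generate_design(cfg, stim)
  d2 <- generate_design(cfg, stim)
  expect_identical(d1, d2)
  e1 <- generate_epochs(cfg, d1, stim)
  e2 <- generate_epochs(cfg, d1, stim)
  expect_identical(e1$data, e2$data)
  cfg2 <- mini_config(n_single_sequences = 1, snr = 0.5, seed = 43)
  expect_false(identical(generate_design(cfg2, stim), d1))
})

test_that("epoch geometry and channel clusters are well formed", {
  cfg <- mini_config(n_single_sequences = 1, seed = 6)
  stim <- mini_stimuli()
  ep <- generate_epochs(cfg, generate_design(cfg, stim), stim)
  expect_equal(length(ep$time), 901)
  expect_equal(range(ep$time), c(-100, 800))
  expect_equal(dim(ep$data)[1], nrow(ep$trials))
  expect_equal(dim(ep$data)[2], nrow(ep$channels))
  expect_setequal(unique(ep$channels$cluster), c("left", "right", "other"))
  expect_equal(sum(ep$channels$cluster == "left"), 6)
  expect_true(all(electrode_clusters()$left %in% ep$channels$name))
})

test_that("noise AR(1) coefficient is recovered from noise-only epochs", {
  cfg <- mini_config(n_single_sequences = 2, snr = 0, noise_autocorr = 0.6,
                     seed = 8)
  stim <- mini_stimuli()
  ep <- generate_epochs(cfg, generate_design(cfg, stim), stim)
  x0 <- as.vector(ep$data[, , -dim(ep$data)[3]])
  x1 <- as.vector(ep$data[, , -1])
  expect_gt(length(x0), 1e5)
  expect_lt(abs(cor(x0, x1) - 0.6), 0.05)
})

test_that("a transfer delay overrunning the epoch is rejected", {
  expect_error(simulation_config(contra_onset = 700, transfer_delay = 150),
               "epoch end")
})

test_that("triplet pair coding marks the odd one out as dissimilar", {
  resp <- data.frame(participant = 1, trial = 1, stim_a = 1, stim_b = 2,
                     stim_c = 3, chosen = "a")
  rdm <- build_rdm_from_triplets(resp, n_stimuli = 3)
  expect_equal(rdm$values[2, 1], 1)
  expect_equal(rdm$values[3, 1], 1)
  expect_equal(rdm$values[3, 2], 0)
  # opposite choices over the same triplet average to 0.5
  resp2 <- rbind(resp, transform(resp, trial = 2, chosen = "b"))
  rdm2 <- build_rdm_from_triplets(resp2, n_stimuli = 3)
  expect_equal(rdm2$values[2, 1], 1)     # both trials mark (1,2) dissimilar
  expect_equal(rdm2$values[3, 1], 0.5)
  expect_equal(rdm2$values[3, 2], 0.5)
})

test_that("uniform latent dissimilarity drives RDM cells to 2/3", {
  # analytic expectation: with all-equal dissimilarities each pair member is
  # chosen with total probability 2/3, so every cell converges to 2/3
  flat <- matrix(1, 8, 8)
  resp <- generate_triplet_responses(list(flat), n_participants = 1,
                                     n_trials = 50000, decision_noise = 1,
                                     seed = 13)
  rdm <- build_rdm_from_triplets(resp, n_stimuli = 8)
  cells <- lower_tri_values(rdm$values)
  expect_equal(rdm$n_unobserved, 0)
  expect_true(all(abs(cells - 2 / 3) < 0.03))
})

test_that("low-noise triplet responses recover the generating model RDM", {
  set.seed(31)
  n <- 8
  D <- matrix(0, n, n)
  D[lower.tri(D)] <- runif(sum(lower.tri(D)), 0.1, 1)
  D <- D + t(D)
  resp <- generate_triplet_responses(list(D), n_participants = 1,
                                     n_trials = 50000,
                                     decision_noise = 0.05, seed = 17)
  est <- build_rdm_from_triplets(resp, n_stimuli = n)
  expect_gt(correlate_rdms(est$values, D)$rho, 0.9)
})

test_that("triplet estimator matches the closed-form Luce choice probabilities", {
  # E[cell(a,b)] = mean over third stimuli c of P(choose a) + P(choose b)
  set.seed(5)
  n <- 6
  D <- matrix(0, n, n)
  D[lower.tri(D)] <- runif(sum(lower.tri(D)), 0, 1)
  D <- D + t(D)
  for (tau in c(0.2, 0.5, 1)) {
    expected <- matrix(NA_real_, n, n)
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      others <- setdiff(1:n, c(a, b))
      p_ab <- vapply(others, function(cc) {
        v <- c(D[a, b] + D[a, cc], D[b, a] + D[b, cc], D[cc, a] + D[cc, b]) / tau
        pr <- exp(v - max(v))
        pr <- pr / sum(pr)
        pr[1] + pr[2]
      }, numeric(1))
      expected[a, b] <- expected[b, a] <- mean(p_ab)
    }
    resp <- generate_triplet_responses(list(D), n_participants = 1,
                                       n_trials = 60000, decision_noise = tau,
                                       seed = 100 + round(10 * tau))
    est <- build_rdm_from_triplets(resp, n_stimuli = n)
    dev <- abs(lower_tri_values(est$values) - lower_tri_values(expected))
    expect_lt(max(dev), 0.025)
  }
})

test_that("ipsilateral decodability is non-decreasing in retention and gain", {
  stim <- mini_stimuli()
  win <- c(50, 350)
  ipsi_mean <- function(retention, ipsi_gain) {
    cfg <- mini_config(n_single_sequences = 6, snr = 1, transfer_delay = 10,
                       retention = retention, ipsi_gain = ipsi_gain, seed = 77)
    ep <- generate_epochs(cfg, generate_design(cfg, stim), stim)
    rs <- pairwise_decode(ep, "right", "single", "RVF", n_folds = 6,
                          time_window = win)
    mean(mean_accuracy(rs)$values)
  }
  rho_acc <- vapply(c(1 / 6, 0.5, 1), ipsi_mean, numeric(1), ipsi_gain = 1)
  expect_true(all(diff(rho_acc) > -0.01))
  expect_gt(rho_acc[3], rho_acc[1])
  gain_acc <- vapply(c(0.3, 0.6, 1), function(g) ipsi_mean(1, g), numeric(1))
  expect_true(all(diff(gain_acc) > -0.01))
  expect_gt(gain_acc[3], gain_acc[1])
})
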