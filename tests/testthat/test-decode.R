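# helper: hand-built epoch_set around a trials x channels x time array
make_epochs <- function(data, stim, seqs, condition = "single",
                        hemifield = "RVF", n_other = 0) {
  n_ch <- dim(data)[2]
  cl <- electrode_clusters(n_ch - n_other)
  channels <- data.frame(name = c(cl$left[seq_len(n_ch - n_other)],
                                  rep("Oz", n_other)),
                         cluster = c(rep("left", n_ch - n_other),
                                     rep("other", n_other)))
  trials <- data.frame(participant = 1, condition = condition,
                       sequence_index = seqs,
                       trial_index = seq_along(stim),
                       lvf_stimulus = if (hemifield == "LVF") stim else NA_integer_,
                       rvf_stimulus = if (hemifield == "RVF") stim else NA_integer_,
                       onset_time = 0)
  structure(list(data = data, trials = trials, channels = channels,
                 time = seq_len(dim(data)[3])),
            class = "epoch_set")
}

# independent R transcription of the decoder's discriminant rule
r_lda_accuracy <- function(x, y, folds, shrinkage = 0) {
  correct <- 0; total <- 0
  for (f in unique(folds)) {
    tr <- folds != f
    m0 <- colMeans(x[tr & y == 0, , drop = FALSE])
    m1 <- colMeans(x[tr & y == 1, , drop = FALSE])
    z <- rbind(sweep(x[tr & y == 0, , drop = FALSE], 2, m0),
               sweep(x[tr & y == 1, , drop = FALSE], 2, m1))
    S <- crossprod(z) / nrow(z)
    mu <- mean(diag(S))
    Sig <- (1 - shrinkage) * S
    diag(Sig) <- diag(Sig) + shrinkage * mu + 1e-12 * ifelse(mu > 0, mu, 1)
    w <- solve(Sig, m0 - m1)
    thr <- sum(w * (m0 + m1) / 2)
    sc <- x[!tr, , drop = FALSE] %*% w - thr
    pred <- ifelse(sc >= 0, 0, 1)
    correct <- correct + sum(pred == y[!tr])
    total <- total + sum(!tr)
  }
  correct / total
}

test_that("36 stimuli enumerate 630 unique pair contrasts", {
  pairs <- stim_pairs(stimulus_set()$stimulus_id)
  expect_equal(nrow(pairs), 630)
  expect_equal(anyDuplicated(t(apply(pairs, 1, sort))), 0L)
})

test_that("word balancing keeps exactly n_keep presentations, images untouched", {
  stim <- stimulus_set()
  cfg <- simulation_config(n_participants = 1, n_single_sequences = 24,
                           n_dual_sequences = 0, seed = 3)
  des <- generate_design(cfg, stim)
  bal <- balance_word_trials(des, stim, n_keep = 48, seed = 5)
  wrd <- stim$stimulus_id[stim$modality == "word"]
  img <- stim$stimulus_id[stim$modality == "image"]
  for (col in c("lvf_stimulus", "rvf_stimulus")) {
    expect_true(all(table(factor(bal[[col]], levels = wrd)) == 48))
    expect_true(all(table(factor(bal[[col]], levels = img)) == 48))
  }
  # stratification: 96 over 24 sequences -> exactly 2 kept per sequence
  w1 <- wrd[1]
  per_seq <- table(bal$sequence_index[!is.na(bal$lvf_stimulus) &
                                        bal$lvf_stimulus == w1])
  expect_true(all(per_seq == 2))
  # already balanced input is returned unchanged
  expect_identical(balance_word_trials(bal, stim, n_keep = 48, seed = 9), bal)
  # one presentation short of n_keep errors, naming the stimulus
  broken <- bal
  broken$lvf_stimulus[which(broken$lvf_stimulus == w1)[1]] <- NA_integer_
  expect_error(balance_word_trials(broken, stim, n_keep = 48, seed = 5),
               paste0("stimulus ", w1))
})

test_that("decoder matches an independent Fisher-discriminant transcription", {
  set.seed(11)
  for (inst in 1:10) {
    n_per <- 12
    x <- array(rnorm(2 * n_per * 2 * 3), dim = c(2 * n_per, 2, 3))
    sep <- runif(1, 0, 2)
    x[1:n_per, 1, ] <- x[1:n_per, 1, ] + sep
    stim <- rep(c(1L, 2L), each = n_per)
    seqs <- rep(rep(1:4, each = 3), 2)
    ep <- make_epochs(x, stim, seqs)
    rs <- pairwise_decode(ep, "left", "single", "RVF", n_folds = 4,
                          shrinkage = 0)
    for (t in 1:3) {
      ref <- r_lda_accuracy(x[, , t], as.numeric(stim == 2),
                            (seqs - 1) %% 4)
      expect_equal(rs$values[2, 1, t], ref, tolerance = 1e-12)
    }
  }
})

test_that("well-separated spherical classes match a nearest-centroid oracle", {
  set.seed(21)
  n_per <- 20
  x <- array(rnorm(2 * n_per * 4 * 2), dim = c(2 * n_per, 4, 2))
  x[(n_per + 1):(2 * n_per), 1, ] <- x[(n_per + 1):(2 * n_per), 1, ] + 3
  stim <- rep(c(1L, 2L), each = n_per)
  seqs <- rep(rep(1:4, each = 5), 2)
  fold <- (seqs - 1) %% 4
  ep <- make_epochs(x, stim, seqs)
  rs <- pairwise_decode(ep, "left", "single", "RVF", n_folds = 4)
  for (t in 1:2) {
    correct <- 0
    for (f in 0:3) {
      m1 <- colMeans(x[stim == 1 & fold != f, , t])
      m2 <- colMeans(x[stim == 2 & fold != f, , t])
      test <- which(fold == f)
      d1 <- colSums((t(x[test, , t]) - m1)^2)
      d2 <- colSums((t(x[test, , t]) - m2)^2)
      pred <- ifelse(d1 <= d2, 1, 2)
      correct <- correct + sum(pred == stim[test])
    }
    expect_lt(abs(rs$values[2, 1, t] - correct / (2 * n_per)), 0.01 + 1e-12)
  }
})

test_that("identical class distributions decode at chance", {
  set.seed(33)
  x <- array(rnorm(48 * 3 * 20), dim = c(48, 3, 20))
  stim <- rep(c(1L, 2L), each = 24)
  seqs <- rep(rep(1:4, each = 6), 2)
  ep <- make_epochs(x, stim, seqs)
  rs <- pairwise_decode(ep, "left", "single", "RVF", n_folds = 4)
  expect_lt(abs(mean(rs$values[2, 1, ]) - 0.5), 0.08)
  expect_true(all(rs$values >= 0 & rs$values <= 1, na.rm = TRUE))
})

test_that("results are invariant to trial order within folds", {
  set.seed(44)
  x <- array(rnorm(24 * 2 * 4), dim = c(24, 2, 4))
  stim <- rep(c(1L, 2L), each = 12)
  seqs <- rep(rep(1:3, each = 4), 2)
  ep <- make_epochs(x, stim, seqs)
  r1 <- pairwise_decode(ep, "left", "single", "RVF", n_folds = 3)
  perm <- sample(24)
  ep2 <- make_epochs(x[perm, , , drop = FALSE], stim[perm], seqs[perm])
  r2 <- pairwise_decode(ep2, "left", "single", "RVF", n_folds = 3)
  expect_equal(r1$values, r2$values, tolerance = 1e-12)
})

test_that("decoding preconditions raise informative errors", {
  set.seed(7)
  x <- array(rnorm(12 * 2 * 2), dim = c(12, 2, 2))
  stim <- rep(c(1L, 2L), each = 6)
  seqs <- rep(1:3, 4)
  ep <- make_epochs(x, stim, seqs)
  expect_error(pairwise_decode(ep, "left", "single", "RVF", n_folds = 2),
               "does not divide")
  expect_error(pairwise_decode(ep, "right", "single", "RVF", n_folds = 3),
               "missing")
  # a stimulus absent from one fold
  stim2 <- stim
  stim2[seqs == 2 & stim == 2] <- 1L
  ep2 <- make_epochs(x, stim2, seqs)
  expect_error(pairwise_decode(ep2, "left", "single", "RVF", n_folds = 3),
               "absent from fold")
})

test_that("mean accuracy averages the unique cells", {
  v <- array(0.5, dim = c(3, 3, 2))
  rs <- rdm_series(v)
  expect_equal(unname(mean_accuracy(rs)$values), c(0.5, 0.5))
  v2 <- array(0, dim = c(4, 4, 1))
  lt <- lower.tri(v2[, , 1])
  m <- matrix(0, 4, 4)
  m[lt] <- rep(c(0.4, 0.6), 3)
  v2[, , 1] <- m + t(m)
  expect_equal(unname(mean_accuracy(rdm_series(v2))$values), 0.5)
})

test_that("contra/ipsi collapsing averages the right combinations", {
  base <- list(left_LVF = 0.5, left_RVF = 0.6, right_LVF = 0.5, right_RVF = 0.4)
  out <- collapse_contra_ipsi(base)
  expect_equal(out$contralateral, 0.55)
  expect_equal(out$ipsilateral, 0.45)
  same <- list(left_LVF = 1:3, left_RVF = 1:3, right_LVF = 1:3, right_RVF = 1:3)
  expect_equal(collapse_contra_ipsi(same)$contralateral, 1:3)
  expect_error(collapse_contra_ipsi(base[-1]), "left_LVF")
})
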