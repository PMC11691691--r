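test_that("self-correlation of an RDM series gives a unit diagonal", {
  a <- random_rdm_series(8, 10, seed = 1, split = "odd")
  b <- a
  b$split <- "even"
  tg <- crosscorrelate_timegen(a, b)
  expect_equal(unname(diag(tg$values)), rep(1, 10))
})

test_that("zero-variance time points yield undefined correlations", {
  a <- random_rdm_series(6, 5, seed = 2, split = "odd")
  flat <- rdm_series(array(0.5, dim = c(6, 6, 5)), split = "even")
  tg <- crosscorrelate_timegen(a, flat)
  expect_true(all(is.na(tg$values)))
})

test_that("Spearman surface is invariant to monotone transforms", {
  a <- random_rdm_series(8, 6, seed = 3, split = "odd")
  b <- random_rdm_series(8, 6, seed = 4, split = "even")
  tg1 <- crosscorrelate_timegen(a, b)
  b2 <- b
  b2$values <- exp(3 * b2$values)   # strictly increasing transform
  tg2 <- crosscorrelate_timegen(a, b2)
  expect_equal(tg1$values, tg2$values, tolerance = 1e-12)
})

test_that("both cross-split pairings are averaged", {
  ao <- random_rdm_series(6, 4, seed = 5, split = "odd")
  be <- random_rdm_series(6, 4, seed = 6, split = "even")
  ae <- random_rdm_series(6, 4, seed = 7, split = "even")
  bo <- random_rdm_series(6, 4, seed = 8, split = "odd")
  m1 <- crosscorrelate_timegen(ao, be)$values
  m2 <- crosscorrelate_timegen(ae, bo)$values
  m12 <- crosscorrelate_timegen(ao, be, ae, bo)$values
  expect_equal(m12, (m1 + m2) / 2, tolerance = 1e-12)
})

test_that("delay profile picks out a constructed diagonal offset", {
  t_ax <- 0:100
  vals <- matrix(0, 101, 101)
  for (i in seq_along(t_ax)) {
    j <- i + 20
    if (j <= 101) vals[i, j] <- 1
  }
  tg <- structure(list(values = vals, time_a = t_ax, time_b = t_ax,
                       condition = "single", hemisphere_a = "left",
                       hemisphere_b = "right"),
                  class = "timegen_matrix")
  prof <- delay_profile(tg, delays = -50:50, window = c(0, 100))
  expect_equal(prof$delays[which.max(prof$values)], 20L)
  # a symmetric surface gives a symmetric profile
  sym <- tg
  sym$values <- vals + t(vals)
  ps <- delay_profile(sym, delays = -50:50, window = c(0, 100))
  expect_equal(ps$values, rev(ps$values), tolerance = 1e-12)
})

test_that("asymmetry test favors the null for symmetric profiles", {
  # +d/-d differences have exactly zero mean across participants (paired
  # +/- perturbations) but nonzero variance: the t statistic is 0 at every
  # offset, so the interval null wins decisively at n = 20
  set.seed(9)
  delays <- -30:30
  bhalf <- rnorm(30, 0.2, 0.05)
  base <- c(rev(bhalf), rnorm(1, 0.2, 0.05), bhalf)  # symmetric about d = 0
  wob <- runif(30, 0.01, 0.03)
  profs <- lapply(1:20, function(p) {
    s <- if (p <= 10) 1 else -1
    v <- base
    v[32:61] <- v[32:61] + s * wob        # +d side
    v[30:1] <- v[30:1] - s * wob          # -d side, mirrored order
    structure(list(delays = as.integer(delays), values = v),
              class = "delay_profile")
  })
  res <- asymmetry_test(profs)
  expect_equal(nrow(res), 30)
  expect_true(all(res$bf < 1 / 3))
  expect_error(asymmetry_test(profs[1]), "2 participants")
})

test_that("asymmetry test detects a strong contralateral-lead band", {
  set.seed(10)
  delays <- -40:40
  profs <- lapply(1:20, function(p) {
    v <- rnorm(81, 0.1, 0.02)
    names(v) <- delays
    band <- as.character(14:38)
    v[band] <- v[band] + 0.15 + rnorm(25, 0, 0.02)  # effect size ~ 1.5+
    structure(list(delays = as.integer(delays), values = unname(v)),
              class = "delay_profile")
  })
  res <- asymmetry_test(profs)
  in_band <- res$abs_delay >= 14 & res$abs_delay <= 38
  expect_true(all(res$bf[in_band] > 10))
})

test_that("within/across consistency behaves under known structure", {
  # identical odd/even series: within = 1
  mk <- function(seed, split) random_rdm_series(6, 5, seed = seed, split = split)
  rdms <- list()
  for (h in c("left", "right")) for (hf in c("LVF", "RVF")) {
    base <- mk(match(h, c("left", "right")) * 10 + match(hf, c("LVF", "RVF")),
               "odd")
    even <- base
    even$split <- "even"
    rdms[[paste(h, hf, "odd", sep = "_")]] <- base
    rdms[[paste(h, hf, "even", sep = "_")]] <- even
  }
  out <- consistency_within_across(rdms)
  expect_equal(unname(out$within_contra), rep(1, 5))
  expect_equal(unname(out$within_ipsi), rep(1, 5))
  # independent random hemispheres: across ~ 0 on average
  set.seed(12)
  rdms2 <- list()
  s <- 0
  for (h in c("left", "right")) for (hf in c("LVF", "RVF"))
    for (sp in c("odd", "even")) {
      s <- s + 1
      rdms2[[paste(h, hf, sp, sep = "_")]] <- random_rdm_series(12, 40,
                                                                seed = 500 + s,
                                                                split = sp)
    }
  out2 <- consistency_within_across(rdms2)
  expect_lt(abs(mean(out2$across)), 0.1)
})

test_that("across-hemisphere correlation respects the split-half noise ceiling", {
  # shared latent structure + hemisphere-specific distortion + split noise:
  # across <= sqrt(within_L * within_R) + sampling tolerance
  n_viol <- 0
  for (seed in 1:10) {
    set.seed(700 + seed)
    n <- 12; T <- 20
    lt_n <- choose(n, 2)
    latent <- matrix(rnorm(lt_n * T), lt_n, T)
    ipsi_latent <- 0.7 * latent + 0.7 * matrix(rnorm(lt_n * T), lt_n, T)
    mk <- function(base, sd, split) {
      vals <- array(0, dim = c(n, n, T))
      for (t in 1:T) {
        m <- matrix(0, n, n)
        m[lower.tri(m)] <- base[, t] + rnorm(lt_n, 0, sd)
        vals[, , t] <- m + t(m)
      }
      rdm_series(vals, split = split)
    }
    lo <- mk(latent, 0.8, "odd"); le <- mk(latent, 0.8, "even")
    ro <- mk(ipsi_latent, 0.8, "odd"); re <- mk(ipsi_latent, 0.8, "even")
    within_l <- diag(crosscorrelate_timegen(lo, le)$values)
    within_r <- diag(crosscorrelate_timegen(ro, re)$values)
    across <- diag(crosscorrelate_timegen(lo, re, le, ro)$values)
    ceiling_ok <- across <= sqrt(pmax(within_l * within_r, 0)) + 0.25
    n_viol <- n_viol + sum(!ceiling_ok)
  }
  expect_lt(n_viol / (10 * 20), 0.05)
})
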