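# Shared fixtures and independent oracles for the test suite.

# Reduced 12-stimulus set (8 images + 4 words over 2 concepts): keeps both
# modality and concept structure while staying fast to decode.
mini_stimuli <- function() stimulus_set(concepts = c("bird", "fish"))

# A small single-condition simulation: 12 sequences so that 12-fold (all)
# and 6-fold (odd/even half) decoding both divide the sequence count.
mini_config <- function(n_single_sequences = 12, ..., seed = 1) {
  simulation_config(n_participants = 1,
                    n_single_sequences = n_single_sequences,
                    n_dual_sequences = 0, seed = seed, ...)
}

# Random symmetric RDM stack (pairs iid normal), as an rdm_series.
random_rdm_series <- function(n_stim, n_time, seed, split = "all",
                              mean = 0.5, sd = 0.05) {
  set.seed(seed)
  vals <- array(0, dim = c(n_stim, n_stim, n_time))
  lt <- lower.tri(matrix(0, n_stim, n_stim))
  for (t in seq_len(n_time)) {
    m <- matrix(0, n_stim, n_stim)
    m[lt] <- rnorm(sum(lt), mean, sd)
    vals[, , t] <- m + t(m)
  }
  rdm_series(vals, split = split)
}

# Log likelihood of an observed t statistic at noncentrality ncp, written
# for the oracle below directly from the scale-mixture definition
# T = (Z + ncp)/sqrt(V/df): f(t) = Int phi(t u - ncp) u f_U(u) du with
# U = sqrt(V/df). 101-node Simpson rule bracketing the integrand's mode.
# (R's dt(ncp=) loses all precision in far tails, so the oracle cannot
# lean on it; the in-package evaluator is checked against dt separately,
# in the regime where dt is accurate.)
oracle_loglik <- function(tstat, df, ncp) {
  K <- 101L
  a <- tstat^2 + df
  u0 <- (tstat * ncp + sqrt(tstat^2 * ncp^2 + 4 * df * a)) / (2 * a)
  sdu <- 1 / sqrt(tstat^2 + df / u0^2 + df)
  lo <- pmax(u0 - 9 * sdu, u0 * 1e-8)
  h <- (u0 + 9 * sdu - lo) / (K - 1)
  u <- matrix(lo, length(ncp), K) + outer(h, 0:(K - 1))
  lg <- dnorm(tstat * u - ncp, log = TRUE) + 2 * log(u) + log(2 * df) +
    dchisq(df * u^2, df, log = TRUE)
  m <- apply(lg, 1, max)
  wts <- c(1, rep(c(4, 2), (K - 3) / 2), 4, 1)
  m + log(as.vector(exp(lg - m) %*% wts) * h / 3)
}

# Independent fine-grid oracle for the JZS interval-null Bayes factor:
# trapezoidal integration over a 1e5-node effect-size grid of the
# likelihood against the truncated Cauchy prior renormalized on each
# region, carried in log space. Independent of the package's adaptive
# piecewise integrator.
bf_oracle <- function(samples, spec, n_nodes = 1e5) {
  x <- samples - spec$mu0
  n <- length(x)
  tstat <- mean(x) / (sd(x) / sqrt(n))
  df <- n - 1
  r <- spec$prior_scale
  lo_n <- spec$null_interval[1]
  hi_n <- spec$null_interval[2]
  d_hat <- tstat / sqrt(n)
  se <- 1 / sqrt(n)
  up_bound <- max(d_hat + 12 * se, hi_n + 3)
  dn_bound <- min(d_hat - 12 * se, lo_n - 3)
  # log marginal over [lo, hi], prior renormalized on [mass_lo, mass_hi]
  log_marg <- function(lo, hi, mass_lo, mass_hi) {
    g <- seq(lo, hi, length.out = n_nodes)
    lw <- numeric(n_nodes)
    for (i in seq(1, n_nodes, by = 10000)) {
      j <- min(i + 9999, n_nodes)
      lw[i:j] <- oracle_loglik(tstat, df, g[i:j] * sqrt(n)) +
        dcauchy(g[i:j], 0, r, log = TRUE)
    }
    m <- max(lw)
    v <- exp(lw - m)
    prior_mass <- pcauchy(mass_hi, 0, r) - pcauchy(mass_lo, 0, r)
    m + log(sum((v[-1] + v[-n_nodes]) / 2) * (g[2] - g[1]) / prior_mass)
  }
  lm_null <- log_marg(lo_n, hi_n, lo_n, hi_n)
  lm_alt <- switch(spec$direction,
    greater = log_marg(hi_n, up_bound, hi_n, Inf),
    less = log_marg(dn_bound, lo_n, -Inf, lo_n),
    two_sided = {
      w_up <- 1 - pcauchy(hi_n, 0, r)
      w_dn <- pcauchy(lo_n, 0, r)
      up <- log_marg(hi_n, up_bound, hi_n, Inf)
      dn <- log_marg(dn_bound, lo_n, -Inf, lo_n)
      m <- max(up, dn)
      m + log((exp(up - m) * w_up + exp(dn - m) * w_dn) / (w_up + w_dn))
    })
  exp(lm_alt - lm_null)
}
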