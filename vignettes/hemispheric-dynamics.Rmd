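---
title: "Hemispheric dynamics of visual object coding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemispheric dynamics of visual object coding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemidyn)
```

## The scientific problem

Visual input from one hemifield projects first to the contralateral
hemisphere; the ipsilateral hemisphere receives the same information only
via interhemispheric transfer, with a delay on the order of 10–30 ms and a
possible loss of detail. `hemidyn` implements a complete analysis chain for
studying this process with time-resolved EEG decoding:

1. **Pairwise decoding** of stimulus identity from hemisphere-specific
   electrode clusters, per 1-ms time point, giving a time-resolved
   representational dissimilarity matrix (RDM) per hemisphere.
2. **Time-generalized RSA** across hemispheres: correlating the RDM of one
   hemisphere at time $t_a$ with the other at $t_b$ for all $(t_a, t_b)$,
   from which an interhemispheric **delay profile** and its asymmetry are
   estimated.
3. **Behavioral grounding**: RDMs estimated from triplet odd-one-out
   judgments, compared to binary image (modality) and concept models.
4. **Commonality analysis**: partitioning neural RDM variance into parts
   unique to each behavioral model and shared between them.
5. **Bayesian inference**: interval-null Jeffreys–Zellner–Siow (JZS) Bayes
   factors over time, onset detection by sustained evidence, and
   leave-two-out jackknife confidence intervals.

Because no real recordings ship with the package, a synthetic generator
produces epoched EEG-like data and behavioral responses with *known* ground
truth (injected transfer delay, information loss, interference, and latent
model structure), so that every downstream stage can be validated by
parameter recovery.

## The experimental design being emulated

The generator reproduces a lateralized rapid serial visual presentation
design: 36 stimuli (24 object images, 6 concepts x 4 exemplars, plus 12
word labels, 6 concepts x 2 case variants), epochs of −100..800 ms at
1000 Hz, trials 200 ms apart (100 ms on, 100 ms off). Single-peripheral
sequences show one stimulus per trial (images 2x per hemifield per
sequence, words 4x — words appear twice as often because two case variants
share a typeface, and are subsampled back at analysis time); dual
sequences pair independent left/right streams. The default experiment has
20 participants, 24 single and 12 dual sequences, giving 192 trials per
sequence and 48 presentations per image stimulus per hemifield —
`balance_word_trials()` subsamples words to the same 48, stratified evenly
over sequences.

## The signal model of the generator

Each stimulus $s$ presented in hemifield $h$ has a latent pattern
$p_{h,s} \in \mathbb{R}^d$ (default $d = 6$). The cluster contralateral to
$h$ receives $A_c\,p_{h,s}\,k(t - t_0)$, where $A_c$ is a
participant-specific random orthonormal channel map (a stable topography)
and $k$ is a half-cosine bump of width 100 ms starting at
$t_0 = 80$ ms. The ipsilateral cluster receives a **rank-reduced copy**:
only the first $\lceil \rho d \rceil$ latent components survive transfer
(retention $\rho$, default 0.5), scaled by the gain $\gamma$ (default 0.6)
and delayed by the transfer delay $\Delta$ (default 20 ms, matching
published interhemispheric estimates of roughly 15–30 ms). In dual trials
both hemifields' stimuli contribute, and all pattern amplitude after
150 ms is multiplied by an interference factor $\beta$ (default 0.7) —
interference spares the first processing stage, as observed empirically.
Additive AR(1) Gaussian noise (coefficient 0.9, a typical single-trial EEG
autocorrelation at 1 kHz) is scaled so that the RMS signal-to-noise ratio
on cluster channels within 0–500 ms equals `snr`; `snr = 0` switches the
signal off entirely, which is the package's null model.

Two optional weights, `w_image` and `w_concept`, mix shared modality-level
and concept-level components into the latent patterns. With
`w_image > 0`, same-modality stimulus pairs become harder to discriminate,
so the neural RDM acquires structure that the image model explains — the
hook used to validate the behavioral-relevance analyses by injection.

Free parameters the emulated study does not constrain (kernel shape and
width, $\gamma$, $\rho$, $\beta$, the AR coefficient, `snr`) were fixed
once at the defaults above on physiological plausibility grounds. What the
generator does **not** emulate: realistic head geometry and volume
conduction, eye movements and artifacts, overlapping responses from the
5 Hz stimulation (epochs are generated independently), and the
target-detection task. Passing recovery tests therefore demonstrates the
correctness of the analysis chain, not the realism of the forward model.

## Decoding

`pairwise_decode()` trains, for every unordered stimulus pair, every fold
and every 1-ms sample, a two-class linear discriminant on the 6-channel
pattern of one cluster. Folds contain whole trial sequences
(round-robin over the ordered sequences of the chosen split), so training
and test data never share a sequence; 12 folds for the full design, 6
within an odd/even half. The shared covariance uses Ledoit–Wolf analytic
shrinkage toward the scaled identity — with ~44 training trials and 6
channels, unregularized estimates are unstable; the shrinkage intensity is
data-driven per fit and can be overridden (`shrinkage = 0` disables it,
any fixed value in [0, 1] is accepted). Decisions on the boundary go
deterministically to the first class (lower stimulus id). No temporal
windowing or pseudo-trial averaging is applied: each sample stands alone.
Accuracies are pooled over folds, stored symmetrically, and averaged over
the `choose(36, 2) = 630` unique pairs by `mean_accuracy()`.

The inner loop (hundreds of thousands of small fits per call) is compiled
C++ with a hand-rolled Cholesky solve; the R surface handles selection,
fold assignment and validation.

## Time-generalized RSA and the delay profile

`crosscorrelate_timegen()` computes Spearman rank correlations (Pearson on
average-fractional ranks, standard tie handling) between the 630-cell
lower triangles of two hemispheres' RDMs at every pair of time points.
Correlations are always computed **across** split halves (odd vs even
sequences), and both cross pairings (odd-A x even-B, even-A x odd-B) are
averaged — symmetric and lower-variance than either direction alone.
Zero-variance triangles yield undefined cells, which are excluded (never
zero-filled, which would bias delay profiles toward zero).

`delay_profile()` averages the surface along off-center diagonals for
delays −100..100 ms over reference times 0–500 ms (both configurable).
With rows = contralateral time, a positive-delay peak means contralateral
structure precedes ipsilateral structure. `asymmetry_test()` compares
+d against −d per participant with a directional interval-null Bayes
factor. Contra/ipsi collapsing happens at the correlation (output) level,
after each hemisphere x hemifield cell is computed.

`consistency_within_across()` contrasts the within-hemisphere split-half
correlation (a noise ceiling) with the across-hemisphere correlation; an
across value at the ipsilateral ceiling while below the contralateral one
is the signature of the ipsilateral structure being a subset of the
contralateral structure.

## Behavior: triplets, models, and dependent correlations

In the triplet odd-one-out task, the chosen stimulus is coded 1
(dissimilar) against each of the other two and the remaining pair 0; a
pair's dissimilarity is the mean code over all trials of all participants
in which the two stimuli co-occurred (never-observed pairs stay undefined
and propagate as missing). The synthetic responder samples triplets
uniformly and chooses by a Luce (softmax) rule over summed latent
dissimilarities; as its temperature tends to zero, choices become
deterministic, and with all-equal dissimilarities every cell converges to
2/3 — both facts are exploited as test oracles.

The two binary stimulus models code a pair as similar when it shares
modality (image model) or concept (concept model). Whether a neural RDM
tracks one behavioral task more than another is tested with Steiger's z
for two dependent correlations sharing one variable, treating the 630
pairs as the sample size (the RDM cells are not independent; the z is
interpreted as a descriptive convention, and permutation p-values over
stimulus labels are available in `correlate_rdms()` where calibrated
inference matters).

## Commonality analysis

`variance_partition()` regresses the neural cells on both models together
and on each alone (OLS with intercept, computed by projection on an
orthonormalized design), and partitions
$R^2_{\text{full}}$ into
$\text{unique}_\text{image} = R^2_{\text{full}} - R^2_{\text{concept}}$,
$\text{unique}_\text{concept} = R^2_{\text{full}} - R^2_{\text{image}}$, and
$\text{common} = R^2_{\text{image}} + R^2_{\text{concept}} - R^2_{\text{full}}$.
The three parts sum to $R^2_{\text{full}}$ identically (asserted to
1e-10 in the tests); negative commonality, possible with suppressor
structure, is reported as-is. The permutation null re-labels the 36
stimuli (joint row/column permutation — cell-wise shuffling would break
RDM geometry and inflate false positives), shares one permutation across
time points within a repetition (preserving the temporal dependence of
the null), and uses add-one p-values: with 1000 permutations, exceeding
all of them means p = 1/1001 < 0.001.

## Bayes factors, onsets, and jackknife CIs

`jzs_interval_bf()` computes a one-sample interval-null Bayes factor: the
likelihood of the observed t statistic under effect size $\delta$ is the
noncentral-t density at noncentrality $\delta\sqrt{n}$; the prior is a
Cauchy with scale 0.707 renormalized on each region; the null region is
$\delta \in [-0.5, 0.5]$ and the alternative is the region beyond it on
the tested side (one tail for directional tests, both for two-sided).
Above-chance decoding and positive correlations are tested directionally
("greater"); condition differences two-sided.

Two numerical choices matter. First, R's `dt(ncp =)` loses precision
catastrophically in far tails (it can return `-Inf` or wrong finite
values), so the likelihood is evaluated through the scale-mixture
representation $T = (Z + \delta\sqrt{n})/\sqrt{V/\nu}$, integrated in log
space by a Simpson rule bracketed around the integrand's analytic mode;
this matches `dt` to ~1e-9 where `dt` is reliable and stays accurate far
beyond it (validated against 40-digit arithmetic during development).
Second, the marginal over $\delta$ uses adaptive piecewise quadrature with
breakpoints at the likelihood peak and a dense-trapezoid fallback for
segments the adaptive rule rejects; the test suite checks agreement with
an independent 1e5-node fine-grid integration to 1e-4 relative.

Onsets are the first time point (at or after 0 ms) opening a run of at
least 10 consecutive 1-ms samples with BF > 10 — a conservative
sustained-evidence rule; an absent run yields `NA`, never the epoch end.
`jackknife_ci()` recomputes onset/peak statistics over all
`choose(n, 2) = 190` (for n = 20) leave-two-out subsamples, each passing
through the full group-mean → BF → statistic chain, and reports the
2.5th/97.5th percentiles.

## Problem sizes used for validation

The packaged tests and the acceptance script validate on reduced but
structurally faithful configurations chosen once: a 12-stimulus set (two
concepts, preserving the image/word composition), 8–12 sequences, 4–6
participants, and 10 simulation seeds for calibration claims. Null
calibration uses `snr = 0` (grand-mean pairwise accuracy must sit within
[0.49, 0.51]); delay recovery injects $\Delta \in \{10, 20, 40\}$ ms at
high snr with $\rho = \gamma = 1$ and requires the group delay-profile
argmax within ±3 ms plus asymmetry BF > 10 at the matching offset; the
commonality validation runs at `snr = 0.3` — chosen so peak accuracies sit
in the mid-90s rather than at ceiling, where RDM variance (and hence model
structure) would be compressed — with `w_image = 1`, and requires the
unique-image component to beat all 200 permutations across the evoked
window. Null-rate calibration of the exceeds-all-permutations flag is done
directly on random RDM series, since the permutation machinery operates on
RDMs.

## Known limitations

* The generator's linear, noise-additive signal model cannot probe
  robustness to artifacts, volume conduction, or overlapping evoked
  responses.
* Steiger's z on RDM cells inherits the field convention of treating 630
  non-independent cells as the sample size.
* The delay profile assumes a single dominant transfer delay; multimodal
  transfer would be summarized by its strongest ridge.
* `import_epochs()` reads only the package's native container; data from
  acquisition toolchains must be converted upstream.

## A minimal run

```{r example, eval = FALSE}
cfg <- run_config(
  simulation = simulation_config(n_participants = 4, n_single_sequences = 8,
                                 n_dual_sequences = 0, snr = 0.5, seed = 1),
  conditions = "single", hemifields = "RVF", n_folds = 8,
  n_keep_words = NULL, time_window = c(-20, 620),
  n_permutations = 200, stages = c("decode", "rsa", "commonality"),
  out_dir = "hemidyn-out", seed = 1)
manifest <- run_pipeline(cfg, stimulus_set(concepts = c("bird", "fish")))
manifest$n_pair_contrasts      # 66 for the 12-stimulus set
manifest$rsa$single_RVF$asymmetry
```
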