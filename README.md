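# hemidyn

Time-resolved analysis of how visual object information is represented
within, and shared across, the two cerebral hemispheres — for EEG
researchers studying lateralized vision, interhemispheric transfer, and
the behavioral relevance of neural representational structure.

A stimulus flashed in one visual hemifield reaches the contralateral
hemisphere first; the ipsilateral hemisphere sees a delayed, possibly
degraded copy. `hemidyn` quantifies this process end to end:

- **Pairwise MVPA decoding**: for every pair of the 36 stimuli
  (630 contrasts), a regularized linear discriminant (Ledoit–Wolf
  shrinkage, sequence-wise 12-fold cross-validation) decodes stimulus
  identity from a six-electrode occipito-temporal cluster per hemisphere
  at every 1-ms sample, yielding neural representational dissimilarity
  matrices (RDMs) over time.
- **Interhemispheric time × time RSA**: split-half Spearman correlation of
  the two hemispheres' RDM triangles for all time-point pairs; averaging
  off-center diagonals gives a delay profile whose peak estimates the
  interhemispheric transfer delay Δ, and a directional interval-null Bayes
  factor tests the "contralateral leads" asymmetry at each offset.
- **Behavioral RDMs** from triplet odd-one-out judgments (chosen stimulus
  coded dissimilar from the other two; cell = mean code over co-occurring
  trials), binary image/concept stimulus models, Steiger's z for dependent
  correlations, and neural–behavior correlation time courses.
- **Commonality analysis**: OLS variance partitioning of neural RDM cells
  into `unique_image = R²_full − R²_concept`,
  `unique_concept = R²_full − R²_image`, and
  `common = R²_image + R²_concept − R²_full`, with a stimulus-label
  permutation null (exceeding all 1000 permutations ⇒ p < 0.001).
- **JZS interval-null Bayes factors** (Cauchy prior, scale 0.707; null
  interval of effect sizes −0.5..0.5), sustained-evidence onset detection
  (first run of ≥10 consecutive ms with BF > 10), and leave-two-out
  jackknife confidence intervals (190 subsamples for n = 20).

Because real recordings are not bundled, the package ships a first-class
synthetic generator that emulates the lateralized rapid-presentation
design (192-trial sequences; image stimuli 2× per hemifield per sequence,
words 4× with analysis-time subsampling; epochs −100..800 ms at 1 kHz)
and injects *known* ground truth — transfer delay, ipsilateral information
loss, dual-stimulus interference, and latent model structure — so every
stage is validated by parameter recovery. See the methods vignette
(`vignettes/hemispheric-dynamics.Rmd`) for the model and all numerical
choices.

## Worked example

Simulate one participant of a reduced 12-stimulus experiment and measure
the contralateral advantage:

```r
library(hemidyn)
stim <- stimulus_set(concepts = c("bird", "fish"))   # 8 images + 4 words
cfg <- simulation_config(n_participants = 1, n_single_sequences = 8,
                         n_dual_sequences = 0, snr = 0.4, seed = 7)
epochs <- generate_epochs(cfg, generate_design(cfg, stim), stim)

contra <- pairwise_decode(epochs, "left",  "single", "RVF", n_folds = 8)
ipsi   <- pairwise_decode(epochs, "right", "single", "RVF", n_folds = 8)
acc_c <- mean_accuracy(contra); acc_i <- mean_accuracy(ipsi)
```

This prints (numbers from the code above, seed 7):

```
peak contra accuracy 0.992 at 126 ms; ipsi 0.855 at 150 ms
```

The right-hemifield stimulus is decoded earlier and better from the left
(contralateral) cluster; the right (ipsilateral) cluster peaks ~24 ms
later and lower, reflecting the generator's 20-ms transfer delay, 0.6
gain, and 0.5 retention. Recovering the delay explicitly from the
time-generalized RSA (high snr, full retention so the ridge is sharp):

```r
cfg2 <- simulation_config(n_participants = 1, n_single_sequences = 8,
                          n_dual_sequences = 0, snr = 1, transfer_delay = 20,
                          retention = 1, ipsi_gain = 1, seed = 7)
ep2 <- generate_epochs(cfg2, generate_design(cfg2, stim), stim)
rd <- list()
for (h in c("left", "right")) for (sp in c("odd", "even"))
  rd[[paste(h, sp, sep = "_")]] <- pairwise_decode(ep2, h, "single", "RVF",
                                                   n_folds = 4, split = sp,
                                                   time_window = c(-20, 620))
tg <- crosscorrelate_timegen(rd$left_odd, rd$right_even,
                             rd$left_even, rd$right_odd)
prof <- delay_profile(tg)
prof$delays[which.max(prof$values)]
#> delay-profile argmax: 19 ms   (true transfer delay: 20 ms)
```

`run_pipeline(run_config(...))` chains all stages (simulate → decode →
RSA → behavior → commonality → onsets) and writes CSV outputs under a
config-hash-stamped run directory.

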