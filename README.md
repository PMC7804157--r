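# autotap

Kinematic analysis of automatic finger-tapping trajectories: does paying
attention to a well-practiced movement change it?

`autotap` implements, as a tested R package plus a small set of analysis
scripts, the full pipeline from raw video-derived hand-keypoint
trajectories (17 points at 60 Hz) to three families of outcome measures
for four attentional conditions (attention away from movement, on the
whole tapping sequence, on the index finger, on the middle finger):

* **Temporal coherence of tapping.** A from-scratch Morlet
  wavelet-transform-coherence (WTC) engine produces time-by-frequency
  coherence maps with cone-of-influence masking. The participant's tapping
  rate is the peak of the pooled inter-trial coherence spectrum; the
  full-width-at-half-maximum band around it defines the frequency range of
  interest; mean inter-finger coherence (6 fingertip pairs per trial) and
  inter-trial coherence (same fingertip across trial pairs) quantify
  movement automaticity,

      R^2(t,s) = |S(W_xy / s)|^2 / ( S(|W_x|^2 / s) * S(|W_y|^2 / s) ),

  with `S` the Gaussian-in-time, boxcar-across-scale smoothing operator.
* **Tapping amplitude.** Each fingertip's trajectory is band-passed into
  the band of interest, its analytic-signal magnitude averaged over the
  range of interest (frames `fs .. round(d*fs)` after the initiation beep:
  344 points for 6.71 s trials, 609 for 11.14 s), giving the amplitude `A`
  and the attentional modulation index

      I_A = A_attention / A_reference - 1

  (positive = facilitation of the attended finger, negative = inhibition).
* **Pattern decoding.** WTC between every pair of the 14 tapping-finger
  keypoints (choose(14,2) = 91 pairs x 40 frequencies), PCA to 80
  components, a trial-aligned six-way dataset split, 60-point sliding
  windows stepped by 4, and an RBF-SVM (gamma = 0.014) under six-fold
  cross-validation; chance is 0.25 for four conditions.

Because the underlying human data set is not publicly deposited, the
package ships a first-class synthetic trajectory generator
(`sim_config()`, `generate_session()`) that emulates the data's assumed
structure — participant-specific tapping rates (3.07–8.43 Hz), fixed
inter-finger phase lags, condition-dependent amplitude gains and per-cycle
phase jitter, postural drift, tremor, tracking noise and outlier spikes —
with full ground truth, so every stage is validated by parameter recovery.
Repeated-measures ANOVA (partial eta-squared), paired/one-sample t-tests
(Cohen's d) and Pearson correlation complete the group-level analyses.

Audience: motor-control and attention researchers analyzing pose-estimation
keypoint output from repetitive-movement experiments, and anyone needing a
tested R implementation of wavelet transform coherence.

## Worked example

```r
library(autotap)

# one simulated participant: 4 conditions x 6 short trials, default
# attentional effects implanted (attended finger gain 1.2, jitter 0.40)
tc <- default_trial_counts(); tc[, "short"] <- 6L; tc[, "long"] <- 0L
ses <- generate_session(sim_config(trial_counts = tc, seed = 23), "demo")
pt  <- preprocess_trials(ses$trials)

band <- participant_band(pt)
band
#> <band_of_interest> tapping rate 6.271 Hz, FWHM band [4.139, 9.726] Hz
ses$ground_truth$rate[1]   # implanted participant rate
#> [1] 5.929981

subset(amplitude_table(pt, band),
       finger == "index" & condition != "reference")
#>    finger        condition         A        I_A
#> 5   index sequence_focused 11.154151  0.1215602
#> 9   index    index_focused 11.425758  0.1488705
#> 13  index   middle_focused  8.959571 -0.0991069
```

The estimated tapping rate lands within one grid step of the implanted
5.93 Hz, and the index fingertip's modulation index recovers the implanted
structure: facilitation when the index finger (gain 1.2) or the sequence
(gain 1.15) is attended, inhibition (gain 0.9) when the middle finger is
attended. (`A` is in pixels; `I_A` is dimensionless; recovered `I_A`
magnitudes sit a little below the implanted gain offsets because in-band
tremor and tracking noise enter both amplitudes.)

The numbered scripts under `analysis/` run the same stages over a small
simulated participant pool and write delimited tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # 8 participants, raw trajectory files
Rscript analysis/02_preprocess.R  # QC table
Rscript analysis/03_coherence.R   # bands, coherence by condition, rm-ANOVA
Rscript analysis/04_amplitude.R   # amplitude, I_A t-tests, two-way ANOVA
Rscript analysis/05_decode.R      # per-participant decoding, test vs chance
```

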