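# hearsim

Binaural beamforming, time-frequency enhancement and simulated
speech-reception-threshold (SRT) experiments for behind-the-ear hearing
aids.

Listeners with hearing loss need a substantially better signal-to-noise
ratio than normally-hearing listeners to understand speech in noisy,
reverberant places such as classrooms.  A pair of behind-the-ear hearing
aids carries four microphones (front and back on each ear), enough for
directional filtering; the open question is how to combine spatial
filtering with single-channel time-frequency (TF) enhancement without
destroying the interaural cues that make binaural hearing work.
`hearsim` implements and evaluates that processing chain end to end for
researchers in hearing science and speech enhancement:

* **MVDR beamforming** designed from calibration recordings, in two
  configurations — *binaural* (BN: one four-microphone beamformer per
  ear) and *bilateral* (BL: an independent two-microphone beamformer per
  ear).  Per frequency bin, the weights are
  `w = R⁻¹d / (dᴴR⁻¹d)`, minimising the output noise power `wᴴRw`
  subject to the distortionless constraint `wᴴd = 1`, where `R` is the
  noise spatial covariance and `d` the relative transfer function of the
  target normalised at the reference microphone (LF for the left output,
  RF for the right).
* **Three TF enhancement regimes** on a shared 16-ms / 75%-overlap STFT
  grid (129 bins × 4-ms cells at 16 kHz): a *mask-informed* log-MMSE
  enhancer (trainable cochleagram-based mask estimator, two-component
  zero-mean complex-Gaussian speech prior), a *Wiener* gain
  `g = (|Y|² − λ_N)/|Y|²` with speech-presence-probability noise
  tracking, and a per-band modulation-domain *Kalman* amplitude filter.
  Left and right gains are linked by the per-cell maximum and applied
  identically to both ears, preserving interaural cues by construction.
* **A synthetic scene generator** standing in for measured impulse
  responses: rigid-sphere head model with fractional delays and head
  shadow, speech-shaped and babble noise, reverberant tails with
  controlled T60 and interaural coherence, a slow four-microphone AGC,
  and the asymmetric 65-dB-SPL level rules for setting trial SNRs.
* **Simulated psychophysics**: NAL-R hearing-loss compensation from
  audiograms, logistic simulated listeners, the asymmetric adaptive
  staircase (steps +3/+2/+1/−1/−2/−3 dB for 0–5 correct keywords of 5),
  SRT estimation as the mean of SNRs from sentence 5 through the
  hypothetical 11th, and spatial release from masking
  `SRM = SRT(co-located) − SRT(separated)`.

## Worked example

Build an anechoic scene (target at 0°, speech-shaped noise at 60°, 0 dB
SNR), design a binaural MVDR from matched calibration recordings, and
compare oracle output SNRs; then run one adaptive SRT track on a
simulated listener.

```r
library(hearsim)

scene <- scene_spec(target_azimuth = 0, noise_azimuth = 60, t60 = 0, seed = 1)
parts <- build_scene_trial(scene, snr_db = 0, seed = 1, duration_s = 1.5)

des  <- design_beamformer(parts$cal_target, parts$cal_noise, "bn")
none <- design_beamformer(parts$cal_target, parts$cal_noise, "none")
outs <- apply_beamforming(parts$trial$mics, des)
enh  <- enhance(outs$L, outs$R, outs$M, "wiener")   # enhanced LE/RE waveforms

max(oracle_output_snr(parts$trial, none))   # unprocessed better ear
max(oracle_output_snr(parts$trial, des))    # binaural MVDR

tr <- run_track(listener_model(true_srt = -12, slope = 0.15),
                start_snr = -4, seed = 1)
tr$snr_sequence
tr$srt
srm(-3.9, -12.9)
```

Output:

```
unprocessed better-ear SNR:  -4.1 dB
binaural MVDR output SNR:    17.2 dB
staircase SNRs: -4 -7 -10 -12 -14 -11 -10 -9 -11 -12 -10
SRT estimate: -11.00 dB
SRM from printed SRTs: 9.0 dB
```

The beamformer lifts the oracle SNR of the spatially separated masker by
some 21 dB (the trial-wide measure includes the masker-only lead and lag,
so the unprocessed figure sits below the nominal 0 dB).  The staircase
converges around the listener's true SRT of −12 dB, and the SRT estimate
averages the SNRs from the fifth presentation onward including the
hypothetical 11th.

A command-line front end wraps the same functions:

```sh
Rscript scripts/hearsim.R synthesize --scene anechoic --azimuth 60 --snr 0 --seed 3 --out demo
Rscript scripts/hearsim.R process --config bn --enhance wiener \
    --cal-target demo_cal_target.wav --cal-noise demo_cal_noise.wav \
    --in demo_mix.wav --out demo_out.wav
Rscript scripts/hearsim.R track --true-srt -10 --seed 2
Rscript scripts/hearsim.R experiment --listeners 8 --seed 2 --out exp.csv
```

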