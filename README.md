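# eventconn

Event-coupling functional connectivity for interictal intracranial EEG.

Depth-electrode (iEEG) recordings from epilepsy surgery candidates carry
network structure even between seizures: contacts inside the seizure-onset
zone (SOZ) tend to be more strongly coupled with each other than contacts
outside it, and how cleanly that structure is organized relates to surgical
outcome. `eventconn` implements a complete, tested pipeline for measuring
that coupling from the *timing of band-limited oscillatory events*, for
researchers analyzing multichannel interictal iEEG with per-contact
anatomical metadata.

## The method

For each band — theta (4–8 Hz), low gamma (30–55 Hz), high gamma
(65–95 Hz; 55–65 Hz is never analyzed to avoid mains contamination) — the
band-passed signal's local amplitude maxima form an event train per
channel. For a channel pair, all event lags within ±T (T = ⌈1000/f_min⌉ ms)
are binned at 2 ms into a peri-event histogram, and its Shannon entropy

    S = −Σ p_i ln p_i,   S_max = ln N

is normalized into a connectivity index

    h = (S_max − S) / S_max ∈ [0, 1],

with h = 1 for a perfectly peaked lag distribution (fully coupled) and
h = 0 for a uniform one (uncoupled). Indices are computed in non-overlapping
windows (300/60/30 s for θ/Lγ/Hγ), validity-masked (≥30 lag observations
per bin), and averaged into a symmetric channels × channels matrix.

Around the core metric the package provides:

* preprocessing — rational resampling to 1 kHz with anti-aliasing, zero-phase
  60 Hz notch, zero-phase FIR band-pass (`resample_to_1khz`, `notch_60hz`,
  `bandpass`);
* interictal spike detection by spectral whitening plus robust thresholding,
  and pairwise spike-coupling rates r_ij = (n_i + n_j)/duration
  (`whiten`, `detect_spikes`, `spike_coupling_matrix`);
* inter-contact Euclidean distances (MNI mm) and the exponential
  distance-decay fit s = A·e^(−τd) (`distance_matrix`, `fit_decay`);
* SOZ (inside/outside/between) and regional (M-M … E-E) network labeling
  into a long-format pair table (`build_pair_table`);
* a mixed-effects statistics stage — random patient intercept, REML,
  marginal-mean contrasts with Bonferroni correction (`fit_mixed_model`,
  `marginal_contrasts`), plus rank tests, Cohen's d, Pearson correlation;
* a seeded synthetic-data generator producing coupled oscillatory event
  trains (parent Poisson processes, copy probability ρ, jitter σ, optional
  ρ = A·e^(−τd) distance rule), rendered recordings with pink noise and
  injected spikes, and ground truth for recovery testing (`synth_config`,
  `simulate_recording`, `make_study`);
* an end-to-end orchestrator writing all artifacts plus a reproducible run
  manifest (`run_pipeline`), and a thin CLI at `inst/scripts/eventconn.R`.

## Worked example

Two synthetic patients — one seizure-free (SF) with boosted coupling inside
the SOZ, one not seizure-free (NSF) with the boost in a non-SOZ subset —
pushed through the full pipeline:

```r
library(eventconn)
study <- make_study(n_patients = 2, n_channels = 6, duration_s = 60, seed = 7)
cfg <- run_config(bands = default_bands()[c("low_gamma", "high_gamma")],
                  out_dir = file.path(tempdir(), "demo"), seed = 7)
res <- run_pipeline(study, cfg)

res$connectivity$P01$high_gamma
#> <connectivity_matrix> band high_gamma: 6 channels; mean h = 0.0024 (15/15 pairs valid)

head(res$pair_table[, c("patient", "channel_i", "channel_j", "h_high_gamma",
                        "distance_mm", "zone_pair", "outcome")], 4)
#> # A tibble: 4 × 7
#>   patient channel_i channel_j h_high_gamma distance_mm zone_pair outcome
#> 1 P01     D01       D02            0.00905           4 inside    SF
#> 2 P01     D01       D03            0.00533           8 inside    SF
#> 3 P01     D01       D04            0.00110          12 between   SF
#> 4 P01     D01       D05            0.00130          16 between   SF

aggregate(h_high_gamma ~ zone_pair + outcome, data = res$pair_table, mean)
#>   zone_pair outcome h_high_gamma
#> 1   between     NSF 0.0009798812
#> 2    inside     NSF 0.0015600258
#> 3   outside     NSF 0.0104861635
#> 4   between      SF 0.0008260771
#> 5    inside      SF 0.0082902061
#> 6   outside      SF 0.0011323975
```

The SF patient's inside-SOZ pairs are roughly seven times more coupled than
its outside pairs (0.0083 vs 0.0011), while the NSF patient's elevated
coupling sits outside the SOZ (0.0105 vs 0.0016) — exactly the injected
network structure, recovered from the rendered signals. The per-patient
distance-decay fits land in `res$decay_fits` (A, τ per band), and
`res$stats` holds the mixed-model contrasts when at least two patients and
both outcome groups are present. Absolute h values are small because the
index responds conservatively to coupling on dense event trains; it is the
contrast structure that carries the signal (see the methods vignette).

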