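---
title: "Event-coupling connectivity for interictal iEEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-coupling connectivity for interictal iEEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eventconn)
```

## The model

`eventconn` quantifies functional coupling between pairs of intracranial EEG
contacts from the timing of band-limited oscillatory events rather than from
amplitude or phase. For each analysis band — theta (4–8 Hz), low gamma
(30–55 Hz) and high gamma (65–95 Hz) — the band-passed signal's local
amplitude maxima are treated as a point process. For a channel pair
$(x, y)$, every event on $x$ is compared with every event on $y$ inside a lag
window $[-T, T)$ and the lags are collected into a peri-event histogram with
2 ms bins, the lag resolution a 1 kHz signal supports. The histogram's
Shannon entropy

$$S = -\sum_{i=1}^{N} p_i \ln p_i, \qquad S_{max} = \ln N,$$

measures how concentrated the lag distribution is, and the connectivity
index

$$h = \frac{S_{max} - S}{S_{max}} \in [0, 1]$$

is 1 when all lag mass falls in one bin (a fixed lead/lag relationship,
fully coupled) and 0 for a uniform lag distribution (no temporal
relationship). The lag half-width is tied to the band: $T = \lceil 1000 /
f_{min}\rceil$ ms, one period of the slowest oscillation in the band, giving
34 ms and 34 bins for low gamma, 16 ms and 16 bins for high gamma, 250 ms
and 250 bins for theta.

A histogram is considered statistically valid when it holds at least 30
observations per bin on average. At the band's mean event frequency
$(f_{min}+f_{max})/2$ this dictates the minimum recording length — 24 s for
low gamma — and motivates the analysis window lengths $L$ of 30 s (high
gamma), 60 s (low gamma) and 300 s (theta). The recording is cut into
$M = \lfloor \mathrm{duration} / L \rfloor$ non-overlapping windows; $h$ is
computed once per unordered pair per window, assigned symmetrically, and
averaged over the windows that pass the validity criterion. Pair-windows
that fail it are excluded from the mean rather than zero-filled, and pairs
with no valid window propagate as missing values.

Note that the theta design is internally infeasible: 250 bins × 30 events
≈ 1250 s of events at 6 Hz, more than one 300 s window can supply.
`band_spec()` therefore carries a `feasible` flag and the validity criterion
is reported, not silently enforced; theta results should be read with the
flag in mind.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| bin width | 2 | ms | two-sample resolution at 1 kHz |
| $T$ | $\lceil 1000/f_{min} \rceil$ | ms | one period of the slowest band component |
| $L$ | 300 / 60 / 30 | s | theta / low-gamma / high-gamma window |
| events per bin | 30 | — | histogram validity threshold |
| event threshold | 0.1 | µV | minimum exceedance over both neighbours |
| spike z | 6 | robust z | detector operating point |
| spike refractory | 50 | ms | one detection per transient |
| mains guard | 55–65 | Hz | never analyzed, 60 Hz contamination |

The event detector uses neighbor-exceedance semantics: a sample is an event
iff it exceeds *both* adjacent samples by at least the threshold. This is
the "Threshold" convention of classical peak finders, not a minimum absolute
height, which makes the 0.1 µV default meaningful only on µV-scaled input —
hence the amplitude scale option at load time.

## Preprocessing

Recordings are harmonized to 1 kHz by rational-ratio polyphase resampling.
When down-sampling, the anti-aliasing low-pass sits at 0.9× the output
Nyquist (450 Hz); when up-sampling, the imaging filter's −6 dB point sits at
the input Nyquist so that all content the original recording could represent
is preserved. Mains interference is removed with a narrow (4 Hz wide)
zero-phase band-stop at 60 Hz (configurable for 50 Hz systems), implemented
as a forward–backward IIR with reflection padding: the notch needs a deep
null with a short transient, which a FIR of practical length cannot give.
Band-passing uses windowed-sinc (Hamming) FIR filters with transition width
`max(2 Hz, 20% of the lower edge)`, applied with exact group-delay
compensation. Zero phase matters throughout: the lag histograms are
phase-sensitive, and any differential filter delay between channels would
masquerade as lead/lag structure.

Interictal segment selection (quiet wakefulness, >24 h post-implant, ≥6 h
before the next seizure, pre-taper) is a metadata filter over segment
annotations; nothing is inferred from the signal. Channels fully in white
matter or marked noisy are dropped at load using the metadata flags.

## Interictal spikes

Spikes are detected by spectral whitening: the amplitude spectrum is divided
by its median-smoothed envelope (a robust flattening that ignores narrow
peaks), the phase is kept, and the series is band-limited to 150 Hz, above
which spikes carry essentially no energy. Candidate spikes are strict local
maxima of the absolute whitened signal with robust z ≥ 6 (median/MAD of the
whitened series), kept greedily by descending amplitude under a 50 ms
refractory period. The thresholds are configurable because the original
workflow relied on visual confirmation; the defaults are set so that pure
pink noise yields well under one false detection per ten minutes while
transients at 8× the noise SD are recovered essentially completely.

The spike-coupling rate for a pair is $(n_i + n_j) / \mathrm{duration}$ in
events per second; a per-minute option exists because both conventions
appear in practice. This matrix is rank-one-plus-diagonal by construction
($r_{ij} + r_{kl} = r_{il} + r_{kj}$ exactly), which the tests exploit.

## Distance decay and network labels

Inter-contact distances are Euclidean in MNI millimetres. Connectivity
versus distance is summarized per patient and band by the exponential decay
$s = A e^{-\tau d}$, fitted by Levenberg–Marquardt least squares on all
valid pairs, unweighted, with $\tau \ge 0$, starting from a log-domain
linear fit. If the exponential cannot beat the best constant model the
constant model is returned, so the fit residual never exceeds the constant
baseline. Whether to fit raw pairs or binned means is genuinely open; raw
pairs are the simplest faithful reading of "fitted to the connectivity
strength as a function of distance".

Channel pairs are labeled *inside* (both contacts in the seizure-onset
zone), *outside* (neither) or *between*, and by regional network M-M, M-L,
M-E, L-L, L-E, E-E with the canonical order mesial < lateral <
extratemporal. Ipsilateral and contralateral non-SOZ contacts are pooled by
default, with a split option, mirroring the pilot finding that laterality
made no difference.

## Group statistics

Because a pair's zone label and its regional network are not nested,
statistics operate on individual non-averaged pair records. The model is a
linear mixed model: connectivity index as response; zone, region network and
surgical outcome as fixed factors (full factorial among those entered);
spike-coupling rate and distance as covariates; a random intercept per
patient; REML estimation with Satterthwaite degrees of freedom. Random
slopes are deliberately omitted — the design statement is a random intercept
per subject. Group differences are differences of estimated marginal means
with Bonferroni correction over each reported contrast family; the family is
all pairwise contrasts within a factor (optionally within levels of a
conditioning factor), since no finer definition is available. An optional
log or rank transform of the response stands in for the unspecified
"transformation to normality"; none is applied by default. Rank tests
(two-sided Wilcoxon rank-sum), Cohen's d on pooled SD, and Pearson
correlations cover the simpler comparisons.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes, not
the biophysics. Each coupled pair owns a parent Poisson process; each
channel copies each parent event independently with probability $\rho$ and
adds Gaussian jitter (SD $\sigma$ per channel, so pairwise lag SD is
$\sigma\sqrt{2}$); independent Poisson background tops every channel up to
the band's target event rate, which defaults to the band's mean frequency —
the same rate the minimum-duration arithmetic assumes. Coupling can follow
an explicit pair list or the distance rule $\rho = A e^{-\tau d}$ over the
contact geometry (default: one linear depth electrode, 4 mm contact
spacing). Events render as 3-cycle Hann-windowed bursts at the band center
frequency (20 µV), spikes as ~70 ms biphasic transients (8× noise SD), over
1/f ("pink") background noise (10 µV SD). All randomness derives from one
seed; a fixed seed reproduces recordings byte-for-byte.

Multi-patient studies encode the hypothesized epileptic-network structure:
seizure-free patients get boosted coupling among SOZ contacts, not-seizure-
free patients among a designated non-SOZ subset, so the inside-vs-outside
contrast separates the groups. A separate table-level simulator
(`simulate_pair_table()`) generates statistics-stage input directly with
known injected effects for parameter-recovery and type-I-error testing.

What the generator does *not* emulate: non-stationarity, sleep/wake
transitions, volume conduction, electrode drift, correlated noise across
contacts, or realistic spike morphology variability. Passing recovery tests
therefore demonstrates correctness of the estimator chain under the model's
own assumptions, not clinical validity on patient recordings.

## Numerical choices and degenerate inputs

Histogram bins are half-open $[l, l+2)$ with $-T$ included and $+T$
excluded; all event pairs in range count, not nearest neighbours only
(standard cross-correlogram; "each local maxima"). $h$ is computed once per
unordered pair — computing both directions could differ at bin boundaries,
and symmetry is asserted by the method. Empty histograms have undefined
entropy and surface as missing values, never as zeros. Entropy uses the
convention $0 \ln 0 = 0$ and is clamped to $[0, \ln N]$ against
floating-point drift. The decay fit guards against divergence by falling
back to the constant model. EDF output quantizes to 16 bits over a
per-channel symmetric physical range written to the header at the exact
precision used for scaling, so a round trip errs by at most range/65536 per
sample.

One known property of the index deserves emphasis: around a uniform lag
distribution the entropy is stationary, so $h$ responds *quadratically* to
small amounts of added coincidence mass. Consequences: (1) independent
trains show a positive finite-sample floor that shrinks as the total count
grows (the null-calibration tests measure this); and (2) when coupling
probability decays exponentially with distance, the h-versus-distance decay
constant is systematically steeper than the coupling decay constant — with
independent per-channel copying the coincidence mass itself scales as
$\rho^2$, compounding the effect. The end-to-end recovery test in the
acceptance suite measures this bias rather than hiding it; on the default
study conditions the fitted $\tau$ overshoots the generator's coupling
$\tau$ by roughly a third. Comparisons of $\tau$ *across* bands or groups
fitted on the same index remain meaningful; reading the fitted $\tau$ as the
coupling-probability decay rate does not.

## Problem sizes

The test and acceptance suites run on deliberately small configurations:
pairwise recovery uses 60 s two-channel event trains over 20 seeds per
condition; the end-to-end decay study uses 12 contacts × 120 s; the
statistics stage uses 20–40 synthetic patients for recovery and 200
six-patient replicates for type-I error; spike round-trips use 10 min of
signal. These sizes make every reported property a few-minute computation
while keeping Monte-Carlo error well inside the asserted tolerances.

## Limitations

* Only undirected, time-averaged coupling: no directed/causal metrics, no
  sliding-window dynamics.
* The theta band's validity criterion cannot be met at the stated window
  length; theta indices rest on fewer counts per bin than the gamma bands.
* Euclidean distance ignores anatomy; the decay model is a summary, not a
  mechanism.
* The entropy index's nonlinear response to coupling strength (above) means
  $h$ is an ordinal, not a calibrated, measure of coupling probability.
* The FIR order and the exact resampler and spike-whitening recipes of the
  original workflow are not recoverable; the implementations here are
  standard designs satisfying the stated contracts.
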