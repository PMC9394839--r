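---
title: "Methods: real-time spindle detection and closed-loop evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: real-time spindle detection and closed-loop evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spindleloop)
```

## The problem

Sleep spindles are transient 12--16 Hz EEG oscillations lasting 0.5--2.5 s,
prominent in NREM sleep and implicated in memory consolidation. Closed-loop
auditory stimulation experiments need to detect a spindle *while it is still
unfolding* and deliver a stimulus inside its duration. That rules out the
window-based spectral heuristics used for offline scoring: an online detector
sees only the past, must run within a few tens of milliseconds per decision
on modest hardware, and every stage in front of it adds delay that the
stimulus inherits.

`spindleloop` implements such a detection chain end to end at desk scale:
synthetic consensus-scored EEG, streaming preprocessing with exact delay
bookkeeping, a small convolutional-recurrent detector with time-dilation,
training and subject-wise evaluation, Pareto-front architecture search, and a
stimulation policy scored at the event level.

## Synthetic recordings

Access-controlled consensus-annotated sleep archives cannot ship with a
package, so every stage here is exercised against a seeded generator
(`generate_recording()`) that emulates the *statistics that matter to the
pipeline*, not sleep physiology:

* background: $1/f$ spectrally-shaped Gaussian noise (default exponent 1,
  RMS 10 µV), with an optional 50/60 Hz mains sinusoid;
* events: sinusoidal bursts with a Hann amplitude envelope, per-event
  frequency uniform on 12--16 Hz, duration uniform on 0.5--2.5 s, peak
  amplitude log-normal (median 30 µV for the *younger* cohort profile,
  15 µV for *older*, log-sd 0.2);
* rate: the default 2 events/min × 1.5 s mean duration puts ≈5% of samples
  inside spindles, the strong class imbalance that motivates oversampling.
  The older profile uses 1.4 events/min, reflecting fewer and weaker
  spindles in older adults. The event *count* is deterministic
  (`round(rate · duration / 60)`) and placement is random with a guaranteed
  400 ms inter-event gap, so the refractory logic downstream is exercised
  while the configured base rate concentrates tightly;
* annotation: `n_experts` (default 5) virtual annotators each mark an event
  with probability logistic in log(amplitude/noise-RMS) — the log form makes
  a zero-amplitude event have probability exactly zero. The per-sample score
  is the fraction of experts marking, held over the event; binary labels are
  derived from that score by the same thresholding/post-processing chain
  used for real consensus scores.

What the generator does **not** model: sleep stages, slow-oscillation
coupling, artifacts (eye blinks, EMG), inter-subject spectral variability.
A detector that excels here has demonstrated that the pipeline and training
machinery work; it says nothing about performance on real polysomnography.

## Preprocessing

Signals are acquired at 500 Hz, decimated to 250 Hz (anti-alias FIR, cutoff
100 Hz, keep every second sample), optionally notch-filtered (order-20
linear-phase band-stop at mains ± 5 Hz, applied *before* the branch split so
both branches stay delay-matched), and processed by two causal branches:

* **cleaned branch** — order-20 linear-phase band-pass 0.5--30 Hz, then
  online standardization: $\mu_n = (1-\alpha_\mu)\mu_{n-1} + \alpha_\mu x_n$,
  $v_n = (1-\alpha_\sigma)v_{n-1} + \alpha_\sigma (x_n-\mu_n)^2$, output
  $(x_n-\mu_n)/\sqrt{v_n+\varepsilon}$ with $\alpha_\mu = 0.1$,
  $\alpha_\sigma = 0.001$. Subtracting the fast running mean acts as a
  high-pass whose −3 dB point sits near 4.7 Hz at 250 Hz, so everything
  below 4 Hz is attenuated by more than 3 dB;
* **envelope branch** — order-20 band-pass 12--16 Hz, standardization with
  $\alpha_\mu = \alpha_\sigma = 0.001$, squaring, and EMA smoothing with
  $\alpha = 0.01$.

Numerical choices: the variance update uses the post-update mean
(Welford-flavoured EMA; the alternative orderings differ only at third
order in $\alpha$); $\varepsilon = 10^{-8}$ floors the variance; the
standardizer state is initialized at the first sample with $\mu = x_1$,
$v = 1$ to avoid start-up spikes; FIR design is windowed-sinc (Hamming) via
`signal::fir1()`, whose even-order symmetric taps give an *exactly*
integer group delay of `order/2` samples — 10 samples = 40 ms per branch at
250 Hz, identical in both branches. This constant is part of the delay
budget (`delay_budget()`: 40 ms filters + 20 ms forward pass + 4 ms
stimulus output = 64 ms) added to every trigger time.

Two properties are load-bearing and tested bit-exactly: *chunk
transparency* (processing any chunking of the stream equals processing it
whole, because each stage carries exact state and performs identical
floating-point operations in the same order) and *causality*.

A limitation worth stating: a 21-tap FIR at 250 Hz spans 84 ms — less than
one cycle at 5 Hz — so the envelope branch's rejection of low-frequency
oscillations is modest (≈2 dB at 5 Hz), and its standardizer renormalizes
any *steady* tone toward unit variance. The envelope is therefore a
*transient burst* indicator relative to the adapted background, not a
narrowband power meter; the tests assert exactly that property.

## Labels

Consensus scores in $[0,1]$ become binary spindle labels by thresholding
(0.2 for the younger cohort, 0.35 for the older), then merging intervals
separated by less than 0.1 s and discarding intervals shorter than 0.3 s or
longer than 2.5 s. The merge sentence of the underlying protocol is
ambiguous about whether both neighbours must be short; the default merges on
the gap alone (the simplest reading that is idempotent), and the stricter
reading is available as `label_config(strict_merge = TRUE)`. The pipeline
order is binarize → merge → length-filter, matching the order in which the
rules are stated.

## Detector

A sliding window of the cleaned signal (and optionally the envelope) feeds a
small 1-D CNN (conv → ReLU → max-pool blocks) whose flattened features drive
a GRU; a scalar head produces either a sigmoid probability (classifier) or a
clipped linear score (regressor). Defaults: 54-sample (216 ms) window,
stride 5 samples (20 ms, matching the per-forward-pass hardware budget),
conv blocks (8ch k7 p2, 16ch k5 p2), GRU width 32 — about 19.4k trainable
parameters, the same size class as the ~25k-parameter reference designs for
embedded inference. The window length is a searchable hyperparameter, since
it is an architecture choice with no single canonical value.

**Time dilation.** `dilation_k` (default 8) decoupled replicas of the GRU
state are used round-robin: replica `step mod k` processes the current
window. Each replica therefore sees every k-th window — an effective stride
of 160 ms — extending temporal context by a factor k at zero parameter
cost. The implementation satisfies an exact equivalence, which the tests
check to machine precision: a dilation-k model over a window stream is
identical to k independent copies of the undilated network run over the k
interleaved substreams. The reported output at each step is that of the
replica updated at that step (the most recently updated one).

Warm-up outputs (before a replica has seen a window) are defined — the head
applied to the zero state — rather than suppressed; downstream consumers
can gate on time instead.

Weights initialize with the standard fan-in-scaled uniform scheme from a
seeded RNG; builds are deterministic in `(config, seed)`. Checkpoints are
JSON text: config + flat weight vector with `%.17g` formatting, which
round-trips doubles exactly.

## Training

Classifiers optimize binary cross-entropy against the binary labels;
regressors optimize mean squared error against the raw scores (predicting
the consensus *before* post-processing). With ~5% positives, classifier
batches are rebalanced by oversampling — each batch slot is positive with
probability ½, drawn with replacement — while regressors train on the
natural distribution (rebalancing consistently hurt score regression in the
underlying study, and is off by default for regressors here).

The GRU is trained by truncated backpropagation through sequences of
`seq_len = 8` windows spaced `dilation_k × stride` samples apart — exactly
the substream one virtual network sees — with the loss on the final window.
Two details matter:

* **state burn-in** (`burn_in = 8`): each training sequence is preceded by
  8 forward-only windows that warm the recurrent state into its mid-stream
  regime. Without this, the network trains against the zero-state
  transient, and its inference-time behaviour (state accumulated over
  minutes) drifts badly — we observed event-level f1 collapse when training
  longer without burn-in;
* the optimizer is Adam (lr $10^{-3}$, standard moments), with a fixed
  number of gradient steps; training is deterministic given the seed and
  batch order, and a non-finite loss aborts with diagnostics.

The operating threshold is *not* 0.5: under 50/50 oversampling the
classifier's output is calibrated to the balanced distribution, so the
event-level optimum lies high (typically 0.85--0.95 on the synthetic
conditions; the reference system reports 0.84 on real data). The threshold
sweep in `threshold_sweep()` is the intended way to pick the operating
point.

**Protocol.** `selection_protocol()` implements subject-wise evaluation:
shuffle subjects (default 10 times), hold out 10% for validation and 10%
for test (floor, minimum one subject), train 3 models per split differing
only by seed, select by validation f1, report test metrics per cohort and
overall as mean (sd) over shuffles. Subjects never leak across sets. The
ablations of the underlying study (input duplication, dilation removal,
phase-restricted training, regressor-as-classifier) are all expressible
through `detector_config()`/`train_config()` alone.

## Architecture search

`run_search()` explores detector configurations under two costs: hardware
(exact trainable-parameter count, free via `count_parameters()`) and
software (1 − f1 after training, expensive). It maintains the streamed
Pareto front (verified against a quadratic filter), guides proposals with a
linear-regression surrogate over scaled/one-hot encoded configurations
(falling back to the history mean, then to a 0.5 prior), and uses ε-greedy
acquisition (default ε = 0.2, 16 candidates per greedy draw). Rounds of
`n_workers` proposals emulate parallel workers; per-evaluation seeds are
fixed at proposal time, failed trainings are logged and skipped, and the
final selection is the front member with minimal software cost. The exact
acquisition strategy of the original large-scale search is not public; the
ε-greedy rule is this package's documented choice, isolated behind
`propose()` so alternatives can be swapped.

## Closed-loop evaluation

`run_policy()` emits a stimulus at the first threshold crossing of a
detection episode (crossing means output strictly above threshold; episode
end means falling back to or below it — a hysteresis margin exists in the
config but is off by default). After an episode ends, a 400 ms refractory
timer runs; an episode re-starting inside it is treated as the same spindle:
no stimulus, and the timer restarts at the new episode's end. Stimulus times
include the 64 ms constant budget; the refractory timer is anchored at
*detection* end, since label ends are unknowable online.

`score_stimulation()` applies the event-level definitions: the first
stimulus landing inside a labeled interval is that event's TP (at most one);
every other stimulus — including one arriving *before* an onset — is an FP;
an event with no in-interval stimulus is an FN. Delays record the closest
stimulus relative to each onset, negatives retained. Note that the TP rule
is purely interval-based: a stimulus triggered by one spindle but landing in
another is the latter's TP.

One property that is *not* a theorem: "stimulus count never increases with
threshold". Under the refractory rule, a higher threshold can split one
episode into two separated by more than 400 ms and so *add* a stimulus. The
property holds for unimodal episodes, which is how it is tested; on real
detector outputs it is a strong tendency, not a guarantee.

## Problem sizes and what the tests show

The test suite runs the full chain on a seeded 30-minute synthetic recording
at the 5% base rate: preprocessing, classifier training (800 Adam steps,
batch 64), replay, threshold sweep, and event scoring — about two minutes of
compute. On these conditions the trained detector's event-level f1 at the
swept threshold exceeds 0.8 and beats a fixed band-power baseline
(envelope > 2× adapted background), and the delay distribution shifts right
as the threshold rises. These are sanity properties of the machinery under
controlled conditions; absolute scores on consensus-annotated human data
cannot be reproduced without that data and are deliberately out of scope.
Shorter fixtures (tens of seconds, toy architectures of a few hundred
parameters) back the unit tests; the analytic checks (40 ms branch delay,
≥4 Hz standardizer cutoff, parameter-count arithmetic) are exact.

## Known limitations

* Pure-R implementation: training throughput (~10 gradient steps/s at the
  default size) suits desk-scale experiments, not large-scale searches.
* The EDF writer emits 16-bit EDF with 1 s records and zero-pads the final
  record; reading a padded file returns the padded length.
* The generator's expert model has no inter-rater bias structure — experts
  are exchangeable given the event amplitude.
* No artifact rejection or adaptive notch; recordings are assumed clean
  apart from stationary mains hum.
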