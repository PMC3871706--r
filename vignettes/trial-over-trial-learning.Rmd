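---
title: "A cerebellar circuit model of trial-over-trial learning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cerebellar circuit model of trial-over-trial learning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Floccular Purkinje cells fire two kinds of spikes: high-rate simple spikes
(SS) driven through the mossy-fiber pathway, and rare complex spikes (CS)
triggered by climbing fibers from the inferior olive (IO). During pursuit
learning, two trial-level phenomena intertwine:

* **trial-over-trial depression** — a CS evoked by an off-direction
  instruction on one trial is followed by a few spikes/s less SS firing on
  the next trial;
* **same-trial facilitation** — a trial on which a cell happens to fire
  faster at instruction time is also more likely to show a CS later in that
  trial, consistent with a disynaptic Purkinje-cell → deep-cerebellar-nucleus
  → inferior-olive loop (two inhibitory synapses, so more SS firing
  disinhibits the olive).

Because the two effects contaminate each other in raw pair averages, the
analyses here tag consecutive trials by their binary CS pattern and compare
codes in which one effect is held fixed. `cerelearn` implements both the
generative circuit model that reproduces these signatures and the tagging
statistics, so each can be validated against the other.

## The generative model

Time is represented only as the progression from trial to trial; each trial
yields one scalar SS rate per cell, one Boolean CS per cell, and one
behavioural scalar. Per trial $j$:

1. **Rates.** $SS_{ij} = (1-R_{nn})\,\alpha_{ij} + R_{nn}\,\beta_j + w_{ij}$,
   with $\alpha_{ij}$ drawn independently per cell and $\beta_j$ once per
   trial, both $\mathcal N(100, 18)$ spikes/s, and $w_{ij} \le 0$ the
   plasticity offset. The implied pairwise across-trial correlation is
   $R_{nn}^2 / ((1-R_{nn})^2 + R_{nn}^2)$, which the test suite checks against
   brute-force simulation for $R_{nn} \in \{0, 0.3, 0.5, 1\}$; at the default
   $R_{nn}=0.3$ it is $0.09/0.58 \approx 0.155$.
2. **Olive drive.** $IN_{kj}$ is the mean rate of a contiguous block of
   `pool_size` cells assigned to olive neuron $k$ (blocks wrap modulo the
   population size when they would overrun it).
3. **CS probability.** Off-direction instructions:
   $P_{kj} = 0.1 + 0.5/(1+e^{-0.3(IN_{kj}-100)})$, strictly inside
   $(0.1, 0.6)$ and monotone in the drive. On-direction instructions never
   evoke a CS. With the feedback ablated, every olive neuron sees the
   constant midpoint drive instead, which freezes $P$ at 0.35.
4. **CS sampling.** Olive neuron $k$ fires iff $R_{CS}\,\delta_{kj} < P_{kj}$
   with independent $\delta_{kj}\sim U(0,1)$ and a single
   $R_{CS}\sim\mathcal N(1, 0.4)$ shared by all olive neurons on the trial.
   The shared gain is what synchronises CS occurrence across the population:
   fixing $R_{CS}=1$ leaves every olive neuron an independent
   Bernoulli($P_k$). Each olive neuron's response is copied to its block of
   10 Purkinje cells ($k = \lceil i / 10 \rceil$).
5. **Plasticity.** A CS on trial $t$ contributes $-5$ spikes/s on trial
   $t{+}1$ and $-2.5$ on $t{+}2$, then exactly 0. Overlapping kernels from CS
   on successive trials sum (the simplest composition consistent with a
   fixed decay schedule); a `reset` mode that restarts the kernel is
   available behind `plasticity_mode`.
6. **Behaviour.** Eye velocity is `ev_gain * (rate_mean − population mean)`:
   depressed firing maps to positive learned velocity along the instruction
   direction. `ev_gain = 0.1` puts full-model learned deflections at
   $O(0.1)$ units.

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `n_pc`, `n_io`, `divergence` | 1000, 100, 10 | counts | circuit size; `n_pc = n_io × divergence` |
| `rate_mean`, `rate_sd` | 100, 18 | spikes/s | component distribution of SS firing |
| `r_nn` | 0.3 | — | shared-noise weight; sets the ≈0.16 SS correlation |
| `pool_size` | 20 | cells | olive fan-in *N* (1 / 20 / 1000 in the fan-in ablations) |
| sigmoid base/amplitude/slope/midpoint | 0.1, 0.5, 0.3, 100 | prob, prob, 1/(spikes/s), spikes/s | drive → CS-probability mapping |
| `rcs_sd` | 0.4 | — | spread of the shared CS gain; sets CS synchrony |
| `plasticity_amplitude`, `plasticity_decay_step` | 5, 2.5 | spikes/s | depression kernel (−5, −2.5) |
| `n_trials`, `p_off` | 800, 0.5 | — | session length and instruction mix |

Two points were genuinely open and are resolved as explicit choices:

* **Olive fan-in of the reference model.** Only the 1/20/1000 variants are
  named; the middle value 20 is the default because the ablations show the
  pair statistics depend only weakly on fan-in, and it keeps the drive
  variance between the two extremes.
* **Marginal SD of SS firing.** The mixture as written has marginal sd
  $18\sqrt{(1-R_{nn})^2+R_{nn}^2} \approx 13.7$ spikes/s, not 18. The model
  implements the mixture verbatim (the tests assert 13.7); setting
  `renormalize_sd = TRUE` rescales the mixture so the marginal sd is exactly
  `rate_sd` for users who prefer to pin the observable sd instead.

### Numerical choices and degenerate inputs

* `R_CS` can go non-positive (≈0.6% of draws at sd 0.4); it is clipped at 0,
  which makes a CS certain on those trials and preserves the monotone
  "smaller gain → more synchronous firing" semantics.
* Rate draws below 0 (probability ~1e−8 per draw at defaults, more under
  heavy depression) are clipped at 0 and counted in the session's
  `n_clipped`.
* Pool blocks wrap modulo `n_pc`; with the defaults (100 × 20 over 1000
  cells) the assignment covers each cell exactly twice.
* A degenerate rate distribution (sd = 0) aborts the tercile analysis naming
  the offending cell; empty eligible pair sets warn and return empty
  tibbles rather than fabricating zeros; pair codes with no members are
  reported as missing (`n_pairs = 0`, `NA` means), not as zero effects.
* Sessions are bit-exactly reproducible from `(config, seed)`; the ablation
  suite derives one child seed per (variant, run) from its master seed and
  logs all of them.

## The trial-sequence statistics

All analyses consume a tidy per-trial table (`trial`, `direction`,
`cs_flag`, `ss_value`, optional `behavior_value`, optional `cell`) — either
`as_trial_summary()` of a simulated session (for which fast matrix-backed
methods exist and are tested for exact agreement with the data-frame path)
or window-averaged spike data.

* **Pairs** (`tag_pairs`, `pair_differences`). Sliding pairs whose first
  trial is off-direction, coded by CS occurrence. Averages are taken within
  cells first, then across cells. The plasticity estimate is
  `mean d('0-0') − mean d('1-1')`: both codes have matching CS status on the
  two trials, so same-trial facilitation cancels and the configured
  5 spikes/s kernel is recovered (typically 5.3–5.7 across 20 sessions; the
  small excess over 5 reflects selection effects — e.g. `'1-1'` test trials
  must be off-direction while `'0-0'` test trials need not be). Whether the
  test trial must be off-direction is a flag (`require_test_off`), off by
  default; the independence test always enforces it.
* **Trios** (`trio_position_means`). Consecutive trials with the first two
  off-direction, coded by three CS flags. `'0-0-0'` trios are flat across
  positions; `'0-0-1'` versus `'0-0-0'` isolates same-trial facilitation
  with CS history matched.
* **Terciles** (`facilitation_terciles`). Per cell, trials are trisected at
  the mean ± 0.44 sd of the rate (equal occupancy under normality,
  $\Phi(-0.44)\approx 0.33$), CS probability is computed per segment, and a
  line through the three (mean rate, CS probability) points gives the
  facilitation slope, ≈0.004 probability per spike/s in the full model
  (printed reference ≈0.005). Trisection is per cell, then pooled.
* **Independence** (`independence_test`). Over consecutive off-off pairs,
  observed `P('1-1')` versus the independence prediction `p²` from the
  marginal CS probability, with a paired t-test across cells or runs. The
  model shows a small, consistent deficit (CS → depression → lower next-trial
  CS probability). The complementary `'1-0'` excess is smaller than
  per-session noise and only visible on average.
* **Dispersion.** Bootstrap percentile CIs (1000 seeded resamples by
  default). The resampling unit is the cell when several cells are present —
  matching the average-within-then-across-cells estimator — otherwise the
  individual pair. Paired t and Wilcoxon tests are both reported. Note that
  cells within one session share trials, so across-cell tests overstate
  independence; across-run comparisons are the conservative route.

## The ablation suite

`run_ablation_suite()` reruns named variants (`FULL`, `NO_plast`,
`NO_SStoCS`, `SS_r0`, `CS_r0`, `SSCS_r0`, `F1`, `F20`, `F1000`) 20 times
each. "Amplitude" is not uniquely defined for scalar-per-trial output; it is
implemented as the per-code mean trial-over-trial change (`d_ss`,
`d_behavior`), the model's only scalar. The characteristic pattern, asserted
by the test suite: removing plasticity abolishes the `'0-0'` − `'1-1'`
contrast; removing both neuron–neuron correlations collapses the behavioural
contrast while leaving the per-cell contrast intact (population averaging
cancels uncorrelated CS-linked changes); fan-in barely matters.

## The spike-level layer

`generate_spike_trains()` emulates a recorded unit: simple spikes from an
inhomogeneous gamma-renewal process (shape 4 by default — Purkinje-like
regularity; shape 1 gives Poisson), CS events as spontaneous
Bernoulli(0.09) per 100-ms bin plus an evoked event uniform in 75–175 ms
after off-direction instructions. Processing conventions:

* **Reciprocal-interval rate**: 1000/ISI on the half-open interval
  $(t_1, t_2]$ between consecutive spikes, zero outside the first/last spike
  (the boundary behaviour is not standardised anywhere; this rule is
  isolated in one function).
* **Windows**: SS scalar = mean rate over [−50, +50] ms around instruction
  onset; CS flag = any CS in [75, 175) ms (half-open, so boundary events are
  unambiguous).
* **Histograms**: probability of ≥1 CS per 100-ms bin (a probability, not an
  expected count).
* **Screening**: `group1` iff evoked probability > 3× spontaneous; `group2`
  iff < 0.2 and ≤ 3× spontaneous; the boundary case (≥ 0.2 but ≤ 3×) is
  retained as `group1`.

A 100-ms window over ~10 spikes has renewal noise of CV ≈ 0.16, so
spike-level summaries track the generating scalars strongly but not
perfectly; the end-to-end test asserts matched CS codes and correlated (not
identical) rate differences, and mean-rate recovery within 5% at 200 trials.

### What the generator does and does not emulate

It reproduces per-trial rate statistics, sparse CS timing, and the analysis
conventions — enough to validate the processing chain end to end. It does
not model within-trial rate dynamics (pursuit onset transients, direction
tuning), recording artefacts (sorting errors, lost isolation), slow
nonstationarities, or the empirical CS-SS coupling; passing tests therefore
certify the pipeline's arithmetic on realistic input, not fidelity to any
particular recorded dataset, and the monkeys' empirical values (segment
rates 66/84/103 spikes/s, observed 0.11 vs 0.12 independence) are reference
shapes, not targets.

## Problem sizes and runtime

The checked-in checks simulate the reference scale where the claim demands
it (1000 cells × 800 trials: one session for the SS correlation, 2–10 for CS
synchrony and the facilitation slope, 20 for plasticity recovery and the
independence-deficit count, 5 runs × 6 variants for the ablation pattern)
and a 60–200-cell circuit elsewhere; the full suite runs in about a minute.

## Known limitations

* Scalar trials only; no millisecond-resolved traces, no explicit DCN units
  (the disynaptic path is collapsed into the pooled-drive sigmoid).
* The CS synchrony produced by the shared-gain mechanism at its stated
  parameters averages ≈0.22, at the low edge of the ≈0.25 population value
  it is meant to capture; no parameter was adjusted to close the gap.
* Across-cell significance tests within a single session inherit the cells'
  shared trial structure; prefer across-session replication for inference.
* The model does not attempt the empirical absence of facilitation at
  on-direction instruction offsets, nor multi-block long-term learning, nor
  any dependence on the instruction-test interval.
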