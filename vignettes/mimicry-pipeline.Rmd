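---
title: "Quantifying facial mimicry from AU time series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying facial mimicry from AU time series: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aumimic)
```

## The measurement problem

When people watch an emotional facial expression they often produce a faint,
involuntary echo of it — *spontaneous facial mimicry* — and they can also copy
it deliberately when asked — *instructed facial mimicry*. Both behaviors can be
read off automated FACS Action Unit (AU) intensity estimates: per video frame,
nine AU channels (AU1, AU2, AU4, AU6, AU12, AU15, AU20, AU25, AU26) graded into
six ordinal categories, neutral (0) through maximum (5), at 30 fps.

The two behaviors need different instruments. Spontaneous mimicry is weak and
does not track the stimulus dynamics, so the question is binary: did the
expression-specific AU pattern activate at all, and when? Instructed mimicry is
strong and explicitly imitative, so the question is one of *accuracy*: how
closely does the produced AU trajectory follow the observed one? This package
implements both instruments, the snippet validity rules around them, the
mixed-design statistical stage on top, and a seeded synthetic-cohort generator
that makes the whole chain testable end to end.

## Spontaneous mimicry: windowed pattern detection

A 5-s stimulus snippet is scored in two post-onset windows:

* **RFR** (rapid facial reactions): 0–1000 ms, frames 0–29 — subperceptual
  muscle responses;
* **CFR** (controlled facial reactions): 1000–5000 ms, frames 30–149 — slower,
  more deliberate responses.

A snippet counts as mimicked in a window when the AU set of the stimulus
emotion is simultaneously active for at least **3 consecutive frames**
(100 ms — about the shortest time a facial muscle takes to move) within that
window. Activation is binarized at the trace category (intensity ≥ 1):
spontaneous mimicry is expected to be low-intensity, so intensity carries no
weight beyond presence. The emotion→AU map (`emotion_patterns()`) reads
alternatives disjunctively and combinations conjunctively, e.g. happiness is
AU6, *or* AU12, *or* AU6 + AU12; fear is AU20 *or* AU1 + AU2 + AU4. The fear
row is read as those two alternatives by analogy with the other rows; the table
is an ordinary R object, so an analyst can override it.

Two points the source procedure leaves open were fixed as follows:

* **Straddling runs.** A run crossing the 1000 ms boundary is evaluated per
  window independently: it triggers a window only if at least 3 of its
  consecutive frames fall inside *that* window. This is the least arbitrary
  reading — neither window can be triggered by frames it does not contain.
* **Raw vs filtered detection.** Detection defaults to the raw ordinal series.
  Binarizing at "any activity" is a statement about the detector's categories,
  not about a smoothed estimate; `spontaneous_outcomes(smooth_window = 10)`
  switches to thresholding the filtered series (0.5 is then the natural
  threshold) for sensitivity analyses.

Per participant and embodiment, the rate is mimicked trials over *valid*
snippets, and a block (participant × embodiment) with more than half of its
snippets missing is excluded entirely — a block that sparse is judged
unreliable as a whole. "Half" is evaluated against the nominal block size of
12 by default (`nominal_n` switches to the observed count). The boundary is
strict: 7 of 12 missing drops the block, 6 of 12 keeps the survivors.

## Instructed mimicry: cross-recurrence quantification

Accuracy of a deliberate copy is quantified by comparing the participant's AU
trajectory $\vec{f_1}$ (N frames) with the agent's $\vec{f_2}$ (M frames)
through a cross-recurrence plot

$$CR_{i,j} = \Theta\!\left(\epsilon - \lVert \vec{f_1}(i) - \vec{f_2}(j)
\rVert_1\right),$$

a binary N × M matrix marking the frame pairs at which the two faces occupy
the same region of AU space. Defaults: Manhattan norm, threshold
$\epsilon = 2$ on the ordinal scale with a *strict* inequality (distance
exactly 2 is not a match; an inclusive mode exists for comparability with
standard CRQA software), and the feature vector restricted to the stimulus
emotion's AU set (1–4 channels — the union of its pattern alternatives).
The channel policy is explicit because a fixed 3-channel convention cannot be
reconstructed from the source; `channel_policy = "all"` uses all nine
channels, and $\epsilon$ can be reconsidered relative to the dimension when
doing so.

From the diagonal structure of the plot:

* **cRR** — percent recurrent entries, $100 \cdot \sum CR_{i,j} / (N M)$
  (the matrix's actual size, so rectangular plots after trimming are handled);
* **P(l)** — histogram of maximal diagonal run lengths (isolated points are
  lines of length 1; border-touching runs count at visible length);
* **L** — mean length of lines at least $l_{min} = 8$ samples (≈ 250 ms);
* **L\_max** — the longest diagonal line;
* **DET** — recurrent points on long lines as a share of all recurrent points
  ($\sum_{l \ge l_{min}} l P(l) / \sum_l l P(l)$, in [0, 1]).

DET also exists in an `as_printed` variant dividing by the number of *lines*
($\sum_l P(l)$), which can exceed 1. Published magnitudes in this literature
are sometimes only consistent with that variant, so it is kept behind
`det_variant`; the normalized form is the default because it is the one that
is a proportion. No Theiler window is applied: the two series come from
different systems (participant and agent), so the main diagonal carries lag-0
signal rather than trivial self-recurrence.

Degenerate plots are flagged, not faked: an empty recurrence set reports all
measures as 0 with `empty = TRUE`, and absence of lines reaching $l_{min}$
reports `l_mean = 0` with `lines_ge_lmin = 0`.

Before CRQA, both series pass a centered moving-average filter of 10 samples,
and the participant snippet loses its 1-s cut buffers (30 frames each end).
The even window spans frames $[t-5, t+4]$ — a fixed, documented convention —
and shrinks at the edges rather than padding, so no data are invented at
snippet boundaries. Instructed blocks retaining 5 or fewer valid snippets are
excluded (6 survive).

## The statistical stage

The cohort table is participant × embodiment with one column per dependent
variable (RFR/CFR rates, mean cRR/L/L\_max/DET, questionnaire scale means).
On it:

* `mixed_anova_3x3()` — humanlikeness (between) × artificial embodiment
  (within), via the standard mixed-design sum-of-squares decomposition
  (`stats::aov` with an `Error(subject)` stratum), uncorrected degrees of
  freedom (no sphericity correction by default, matching the reporting
  convention mirrored here), partial $\eta^2$ per effect, listwise deletion of
  participants with missing cells, and a refusal below 2 complete participants
  per group. The test suite checks it against an independently coded
  balanced-design SS oracle.
* `mixed_anova_2x3_artificiality()` — collapses the three artificial
  embodiments to their per-participant mean and contrasts it with the human
  control.
* `bonferroni_posthoc()` — all pairwise comparisons of a factor (paired t
  tests on participant for within factors), p times the number of pairs,
  capped at 1. Pairwise error terms are used rather than a pooled one; with
  three levels the choice is small and the pairwise form is robust to
  heterogeneous pair variances.
* `simple_regression()` — standardized OLS pooled over participant ×
  embodiment rows, reporting $\beta$, $t$, $df = n - 2$, $p$, $r^2 = \beta^2$.
  Pooling ignores within-participant clustering deliberately, to mirror the
  analysis convention this package reproduces; zero-variance inputs are
  flagged (`defined = FALSE`), never silently zeroed.

## What the synthetic cohort emulates

No raw data from the motivating study exist to re-analyze, so the generator
produces a cohort with the same design skeleton and *known* ground truth:
45 participants (15 per humanlikeness group), four embodiments (virtual agent,
physical robot, video-recorded robot, video-recorded human), two phases, and
12 snippets (2 × 6 emotions) per embodiment and phase — 48 per participant per
phase — with no emotion repeated back to back within a block.

Stimuli are onset–apex–offset ramps: 1 s rise, 3 s hold, 1 s decay at peak
intensity 4 on the emotion's AU set (the 5-s total is fixed by design; the
1/3/1 split is this package's assumption, configurable in
`expression_template()`). Responses:

* *Spontaneous*: with probability `p_mimic_rfr` / `p_mimic_cfr` per window, a
  subtle injection (peak 1–2, duration 3–15 frames) of the emotion's first
  pattern alternative, starting at a uniform latency inside the window;
  1-frame flicker noise at rate 0.01 per frame and channel; defaults for the
  probabilities (0.53–0.66 RFR and 0.66–0.74 CFR for artificial agents, 0.84 /
  0.79 for the human) and for snippet-level occlusion (0.18 spontaneous, 0.09
  instructed) sit at the magnitudes the emulated study reports. A
  per-participant propensity shift (SD 0.12, chosen so participant-level rate
  dispersion lands near the reported 0.15–0.19 once binomial noise is added)
  makes individual differences — and hence the regression stage — non-trivial.
* *Instructed*: the stimulus trajectory delayed by a sampled lag (0–10
  frames), scaled by a gain around 1 (SD 0.15), plus Gaussian noise (SD 0.3),
  re-quantized to the ordinal scale by round-half-away-from-zero and clipping
  — keeping synthetic data on the detector's output scale — then padded with
  the 1-s buffers the preprocessing stage removes. Setting lag 0 / gain 1 /
  noise 0 reproduces the stimulus exactly.
* *Questionnaires*: eight 5-point scale means, each a signed coupling times
  the standardized participant × embodiment latent mimicry propensity plus
  noise, clipped to [1, 5].

Every snippet is generated under its own recorded RNG seed, so the ground
truth record reconstructs any response series exactly, and a fixed master seed
makes cohort files byte-identical across runs.

What the generator does **not** emulate — and what passing tests therefore do
not establish about real data: detector error structure (real AU estimates
have correlated, intensity-dependent noise, not i.i.d. flicker),
valence-congruent or inverse mimicry, frame-level dropout (occlusion is
snippet-level, matching the exclusion unit of the emulated procedure),
habituation or order effects, and any coupling between emotion recognizability
and mimicry. Synthetic instructed copies are also far more regular than real
ones: cohort-level cRR around 45% and DET near 0.9 at the default noise,
versus ~13% and lower line structure in comparable human data. The fidelity
knobs (`instructed_noise_sd`, `instructed_gain_sd`, `instructed_lag_frames`)
move the synthetic regime toward realism but were fixed once as a clean,
analyzable default rather than calibrated to any published table.

One interaction worth knowing: after the 10-sample smoothing, cRR is nearly
flat in the additive-noise level (the filter cancels most of it, while
re-quantization of noise adds baseline activity), whereas L and L_max degrade
monotonically. On raw, unsmoothed copies cRR does fall monotonically with
noise. Qualitative noise-response checks therefore target the line-based
measures at the pipeline level and cRR at the generator level.

## Numerical and testing choices

* Windows at 30 fps: RFR = frames 0–29 (onset time in [0, 1000) ms), CFR =
  frames 30–149 (closed upper bound; the snippet ends first).
* Re-quantization rounds half away from zero (so 2.5 → 3), then clips to
  [0, 5]; `round()`'s round-half-even would bias ramp midpoints downward.
* The trial order within a block is found by rejection sampling over
  permutations of the 12 items; for 2 copies of 6 labels a non-repeating
  order is abundant, so this is fast and exactly uniform over valid orders.
* Monte-Carlo test scales: the CRQA implementation is checked exactly against
  a brute-force diagonal-scan oracle on 500 random pairs (length ≤ 40, up to
  4 channels); detection against an exhaustive run scan on 1000 masks;
  type-I calibration of the simulate→analyze loop on 1000 replicates of a
  12-participant, 3-embodiment, zero-effect cohort; power and
  coupling-sign recovery on 100 replicates at the full n = 45. These sizes
  give Monte-Carlo standard errors well inside the asserted bands while
  keeping the suite quick.
* A fully recurrent 150 × 150 plot has DET(normalized)
  $= (N^2 - 56)/N^2 \approx 0.9975$, not 1: the 14 corner diagonals are
  shorter than $l_{min}$. DET reaches exactly 1 at $l_{min} = 1$. The tests
  assert the exact value.

## Worked example

```{r example, eval = FALSE}
co <- generate_cohort(cohort_config(), seed = 1)
out <- run_cohort_pipeline(co)

aggregate(rate ~ embodiment + window, out$rates, mean)
head(out$crqa)
out$anova_3x3$rate_cfr
bonferroni_posthoc(out$table[out$table$embodiment != "video_human", ],
                   "rate_cfr", "embodiment")
```

## Known limitations

* The mixed ANOVA uses `aov`'s sequential sums of squares; with the listwise-
  complete, (near-)balanced designs produced here this coincides with the
  usual reporting, but heavily unbalanced real tables would need a Type-III
  route.
* No sphericity correction by default (a Greenhouse–Geisser flag would be the
  natural extension); with three within levels the distortion is bounded.
* CRQA here is diagonal-line only: no laminarity/trapping time, no
  embedding-delay reconstruction, no windowed variant.
* The regression stage inherits the pooled-observation convention and its
  optimistic degrees of freedom; a clustered-robust option would be the
  methodologically cleaner default for new studies.
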