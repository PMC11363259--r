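---
title: "Methods: workflow segmentation, OPIs and the case simulator"
author: "opiflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: workflow segmentation, OPIs and the case simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opiflow)
```

This vignette documents the modelling decisions behind `opiflow`: how
annotated robot-assisted hysterectomy (rTLH) cases are represented, how
objective performance indicators (OPIs) and workflow statistics are
defined, which statistical tests are used and why, and what the synthetic
case generator does — and does not — emulate.

## The annotation model and the 2-second gap rule

A case is annotated against a card of 11 functional steps. Six steps are
*paired* (performed once per side; the side is part of the step label) and
the first four are *optional* (adhesiolysis and adnexal dissections that
depend on the indication). Times are seconds from camera insertion, as
non-negative floats; the model carries no absolute timestamps. Input times
are assumed already re-based to camera insertion.

Three conventions resolve raw annotations into a canonical timeline:

* **Gap threshold (`gap_threshold_s`, default 2 s).** An inter-segment
  interval strictly greater than the threshold is an annotated *gap*;
  an interval up to **and including** 2.0 s counts as an immediate step
  change. The inclusive reading is the only testable interpretation of a
  change happening "within" 2 seconds, and it makes the rule a total
  decision procedure on any input.
* **Same-step merging.** Consecutive segments with an identical label
  separated by at most the threshold are one continuous step and are merged
  transitively before gaps are computed. Identical labels across a true gap
  are *not* merged: they are step resumptions and later produce
  self-transitions and switch counts.
* **Half-open intervals.** Segments cover `[start, end)`. A segment may
  start exactly where its predecessor ends, and an event sitting on a
  shared boundary is counted exactly once.

Sub-threshold intervals (between 0 and 2 s) are assigned to *neither*
neighboring step: step time is what the annotator marked, nothing more. The
same applies to events: an event inside a gap or a sub-threshold interval
is retained in the stream but counted in no step. These two choices give
exact conservation laws — segment time + gap time + sub-threshold time
equals the annotated span, and in-step event counts + out-of-step events
equal the stream size — which the test-suite checks on every simulated
cohort.

Overlapping segments are rejected outright. Whether a human annotator could
ever mark overlapping steps is unknowable from summary reports; forbidding
overlap keeps every downstream definition (durations, sequences, fractional
order) single-valued.

## OPIs

Five event kinds are modelled: camera movement, energy activation, and
clutch presses (left, right, both hands). Events are instantaneous onsets;
if a recorder reports continuous activations they must be reduced to onsets
upstream — the package deliberately exposes no debouncing, because no
defensible debounce window can be chosen without access to raw kinematics.
Kinematic indicators (path lengths, velocities) are out of scope.

Per step and case, `compute_case_opi()` reports occurrences, summed
duration and per-kind counts, with `clutch_total` the sum of the three
clutch kinds. Left/right variants of paired steps are collapsed into one
row by default (`collapse_sides = TRUE`), matching how step-level OPIs are
usually reported; the collapsed row equals the sum of the side rows, which
is tested as an invariant. Cohort summaries report mean, sample (n − 1)
standard deviation and n; a single-case group has no defined SD and reports
`NA` rather than 0.

## Workflow statistics

The *functional sequence* of a case is its merged segment labels in time
order with a START pseudo-state prepended. There is no END pseudo-state:
terminal steps simply have an all-zero transition row, which row
normalization leaves at zero rather than inventing mass.

Transition counts pool adjacent pairs over all cases (per-surgeon matrices
are obtained by passing per-surgeon timeline subsets). Labels below the
occurrence threshold are deleted before pairing, splicing their neighbors
together; with the default `min_occurrences = 3`, a step observed only
twice in a cohort is excluded — the precedent being an adnexal step seen
only once per side in a single case, too rare for a meaningful transition
estimate.

The *median fractional step order* places segment `k` of `m` (1-based,
gaps excluded, after merging) at `k/m` and takes the per-label median over
all occurrences in all cases. All occurrences contribute, not only the
first: a median over the occurrence distribution is what makes interrupted
and revisited steps sort sensibly. Axis ordering for the transition heatmap
sorts labels by this median, except that the right and left variants of a
paired step are forced adjacent with right first — a fixed convention that
keeps matrices comparable across cohorts whose side preferences differ.
Where the two sides' medians differ, the pair sorts at the earlier of the
two, and ties fall back to card order.

Row-stochastic normalization is used for the probability matrix (each
non-terminal row sums to 1 within 1e-12). A global normalization would
confound step frequency with transition preference; row normalization is
the standard Markov-chain estimate and is validated in the tests by
recovering a known chain's matrix from 500 simulated sequences to within
0.05 maximum absolute error.

## Statistical comparisons

Comparisons use the two-sided two-sample Student's t test, pooled-variance
by default with `df = n₁ + n₂ − 2`; Welch is available via
`method = "welch"`. Pooled is the default because it is what reproduces the
published surgeon contrast for camera movement during colpotomy (p = 0.0336,
printing as 0.03) from its summary statistics; Welch gives 0.039 → 0.04.
Step comparisons are *unpaired* even though both steps come from the same
cases: the package mirrors the `mean ± SD` presentation of the source
comparisons, and an unpaired test is the only one computable from such
summaries. The summary-statistic route (`ttest_from_summary`) and the raw
route (`ttest_raw`, which delegates to `stats::t.test`) are held to agree
to 1e-10 in the tests.

Degenerate inputs are defined, not left to error paths deep in the
arithmetic: two groups with zero variance and equal means give `t = 0,
p = 1`; zero variance with unequal means is an explicit error (the
statistic is infinite); every group needs `n ≥ 2`. P-values print to three
decimals with `<0.001` below that, the clinical reporting convention.

Five published p-values for these data (0.051, 0.28, 0.25, 0.32, 0.09)
cannot be reproduced from their own printed summaries under either the
pooled or the Welch test; `check_printed_p()` exists to flag exactly this
situation. The package asserts that they are discordant and does not
attempt to match them — whatever produced them (a different data subset, a
one-sided test, a transcription issue) is not recoverable from the printed
record.

## The case simulator

The generator is a semi-Markov process over the annotation card:

1. **Step plan.** Card order; optional steps included with per-step
   probabilities; paired steps emit the surgeon's starting side first;
   a reversal variant swaps uterus removal behind cuff closure (vaginal
   morcellation).
2. **Durations.** Per-step lognormal, moment-matched to a target mean and
   SD. Lognormal is a standard minimal-assumption choice for positive
   skewed task times; only the first two moments are calibrated, since only
   means and SDs are published.
3. **Interruptions.** With a per-step probability the step splits into two
   occurrences (uniform 35–65% split) around a gap, generating the
   self-transitions and switch counts real timelines show.
4. **Transitions.** With probability `gap_prob` an inter-step gap is drawn
   from a lognormal truncated below at 2 s (so it survives timeline
   resolution); otherwise the interval is uniform on [0, 2] s.
5. **Events.** Within each segment, each kind's count is
   Poisson(rate × duration) with uniform timestamps; gaps carry no events,
   consistent with OPIs being defined only inside steps.

### Calibration

Published values fix, for both default profiles: colpotomy duration
(mean 281.1 s, SD 83.7), cuff-closure duration (677.5 s, SD 81.0), and the
index-step event rates as published mean counts divided by the published
mean duration — camera 35.3/281.1 ≈ 0.126/s (A) vs 18.3/281.1 ≈ 0.065/s
(B) and energy 35.3/281.1 (A) vs 41.0/281.1 (B) during colpotomy (pooling
to ≈ 38.2/281.1 ≈ 0.136/s), camera 0.032 (A) vs 0.022 (B) and energy
0.0063 (A) vs 0.0123 (B) during cuff closure (pooling to ≈ 0.0093/s), and
clutch totals 7.3 vs 2.7 (colpotomy) and 9.0 vs 6.3 (cuff closure) over
the respective durations, split 45/45/10% across left/right/both. Surgeon A
starts paired steps on the left, B on the right; B's reversal probability
is 1/3 (one of that surgeon's three cases).

Values not published are fixed once at magnitudes plausible for an
experienced surgeon and are not study targets: dissection-step durations of
90–240 s (means) with generous SDs, camera/energy rates of 0.04–0.12
events/s for non-index steps, optional-step inclusion of 0.5 / 0.85 / 0.15
/ 0.5 for adhesiolysis, tube, IP-ligament and utero-ovarian dissection
(the IP value reflecting a step seen in one case in six), interruption
probabilities of 0.12 (0.15 for colpotomy, 0.35 for cuff closure, the one
step that repeatedly self-resumes), `gap_prob = 0.6` and gap lengths
lognormal with mean ≈ 45 s. Total simulated case time lands in the
published 65–103 min range.

### Determinism and seeds

Every simulation is a pure function of its integer seed. Cohorts derive
per-case seeds as `master_seed + case_index`, so extending a cohort
preserves existing cases; tabular outputs of the orchestration layer are
byte-stable across reruns, while figures are best-effort renderings and
carry no bit-stability contract.

### What the simulator does not emulate

Calibration matches first moments only: real duration and count
distributions, correlations between metrics within a case, patient-factor
effects (BMI, uterus weight), annotator disagreement, and overdispersed or
bursty event processes are all absent. Gamma durations or negative-binomial
counts would be natural extension points but are not defaults — with six
real cases behind the published summaries there is nothing to fit them to.
Passing tests therefore demonstrate internal consistency and faithful
first-moment calibration, not that real recorder data would behave this
way.

## Verification choices and problem sizes

The suite checks the gap rule against an independently written brute-force
adjacent-pair reference on 1,000 random integer-time segment lists;
conservation laws on a 50-case cohort; Poisson-rate recovery on 200 cases
per profile (each per-step estimate computed as total count over total step
time, cohort-wide for rates shared by both profiles and per profile for the
index steps where they differ — the granularity at which each rate is
defined); duration calibration of colpotomy to within 5%; transition
structure preservation over 500 simulated sequences; the pooled test's
type-I error over 2,000 null pairs at n = 3/group (accepted band
0.03–0.07); and a 100-replicate replay of the 3 + 3 study design, requiring
the duration and energy step contrasts to reach significance and the
surgeon camera contrast to point the calibrated way (A above B) in at
least 80% of replicates. At n = 3 per group the camera contrast has only
moderate power under this generator — Poisson counts on variable durations
are noisier than the published per-surgeon SDs — so direction, not
significance, is the replicated claim for that contrast.

## Known limitations

* The annotation card is rTLH-specific; other procedures need their own
  card file, which the loaders accept but for which no calibrated profiles
  ship.
* Event streams must arrive as discrete onsets; there is no raw-signal
  ingestion.
* Transition matrices pool all supplied cases; uncertainty on individual
  transition probabilities is not quantified (six real cases would give
  very wide intervals).
* No multiple-testing correction is applied, matching the source
  presentation of per-comparison p-values; users running many comparisons
  should adjust externally.
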