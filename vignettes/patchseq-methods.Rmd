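---
title: "Models and methods behind PatchSeqKit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind PatchSeqKit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PatchSeqKit)
```

# The problem

Patch-seq records a neuron's intrinsic electrophysiology, extracts its mRNA
(ideally with the nucleus) for RNA-seq, and recovers its morphology from a
biocytin fill — three fragile measurements from one cell. At scale, the
difference between a usable and an unusable dataset is almost entirely
quality control: rejecting unstable sweeps while the cell is still on the
rig, scoring each transcriptome against a dissociated-cell reference, and
quantifying how confidently each cell maps onto a reference taxonomy.
PatchSeqKit implements that computational core, together with seeded
synthetic generators so every stage can be exercised and validated without
any external download.

# Sweep quality control

A current-clamp sweep is accepted only if its pre-stimulus baseline is
stable and its membrane potential returns to baseline after the stimulus.

**Baseline** (`evaluateBaseline()`). Over the 500 ms window preceding the
first stimulus epoch, three criteria are evaluated:

* the mean resting membrane potential must lie within 1 mV of the target
  (`rmpTolerance`, inclusive — so the largest passing offset is exactly the
  stated tolerance);
* a *short-window* RMS metric — the maximum, over non-overlapping 1.5 ms
  sub-windows, of the RMS of the mean-subtracted voltage — must be strictly
  below 0.07 mV (high-frequency noise);
* a *long-window* RMS metric — the RMS of the mean-subtracted voltage over
  the full window — must be strictly below 0.5 mV (patch instability).

The split into a maximum over sub-windows versus one full-window value is a
design choice: the two published constants are described only as short- and
long-window noise bounds, and taking the maximum over sub-windows makes the
short metric sensitive to a brief transient that a single 500 ms RMS would
average away. Both window lengths and bounds are configurable in
`qcConfig()`.

**Recovery** (`evaluateRecovery()`). After an enforced 500 ms minimal
recovery period the RMP is assayed in consecutive 500 ms windows; the first
window that meets all three baseline criteria completes the sweep (its end
time is the reported `pass_time`), and a sweep that has not recovered within
10 s of stimulus end fails. `pass_time` is therefore always
`stimEnd + 0.5 + 0.5k` seconds.

**Autobias** (`autobiasStep()`). Between sweeps the bias current is
corrected by Ohm's law on the input resistance,
`dI = (target - measured) / R_input`, clipped to `maxBiasStep` (default
50 pA). The controller gain is a design choice — only the corrective
behavior is prescribed — and one exact step is what a test can verify.

**Stimulus sets** (`runStimulusSet()`). Failed sweeps are repeated; the set
aborts exactly when the remaining required passes plus accumulated failures
exceed the total allotment. The allotment is `required + maxRepeats` with
`maxRepeats = required` by default, i.e. twice the set size, which is the
weakest allotment under which the published abort sentence is exact. A
failing recovery counts as one failed sweep. During a ramp (default
25 pA/s), spikes are detected online and the stimulus is terminated at the
fifth spike (`rampSpikeLimit`), with recording continuing through recovery;
the engine emulates online termination by truncating the ramp epoch at the
limiting spike's time and re-acquiring from the deterministic responder.

**Inclusion rules** (`sweepInclusion()`, `cellInclusion()`). Strict
inequalities per the published wording: bridge balance and access resistance
below 20 MOhm *and* below 15% of the input resistance; pre-break-in seal
above 1 GOhm; bias current within +/-100 pA (the "0 +/- 100 pA" phrasing is
read as an inclusive bound on the magnitude).

**Online spike detection** (`detectSpikesOnline()`). The derivative is
smoothed with a *causal* 5-sample boxcar (an online detector cannot look
ahead); events are local maxima of the smoothed derivative above the
20 mV/ms threshold rather than raw upward crossings, because crossing counts
are not monotone in the threshold (a double-peaked excursion can split),
while excursion maxima guarantee that raising the threshold selects a subset
of events. The offline detector (below) uses a centered boxcar instead; the
two smoothers are deliberately different and both widths are configurable.

# Action-potential features

`detectAPs()` marks candidate events where the centered-boxcar-smoothed
dV/dt exceeds 20 mV/ms, locates each peak within 5 ms, and then applies the
refinement filters: threshold-to-peak height at least 2 mV, threshold-to-peak
time at most 5 ms, absolute peak at least -30 mV. The filter names are
prescribed; the default values follow the conventions of the standard
intracellular feature-extraction toolchain and are configurable in
`apParams()`. The AP threshold is refined to the last sample before the peak
at which the smoothed dV/dt rises through 5% of the average maximal dV/dt
across the sweep's APs; the average is taken per sweep (per-cell averaging is
a plausible alternative reading and can be emulated by passing a fixed
`avgMaxDvdt` to `refineThreshold()`). Because the rule is a ratio it is
invariant to scaling the trace. Width is measured at half of
(peak - threshold) with linear interpolation; upstroke/downstroke are the
extreme smoothed derivatives on the rising and falling limbs.

`buildFeatureMatrix()` assembles six feature categories per cell from
long-square sweeps on an amplitude grid: (a) the first-AP waveform of the
lowest suprathreshold step in a threshold -1 ms to +4 ms window resampled to
250 points, (b) its derivative, (c) trough-to-next-threshold interspike
segments resampled to 100 points and averaged, (d) instantaneous firing rate
in 20 ms bins (50 per 1 s step) at rheobase, +40 and +80 pA, normalized to
the per-step maximum, (e) mean voltage in 10 ms bins (100 per step) at -10,
-50 and -90 pA concatenated to length 300, and (f) the largest
hyperpolarizing step min/baseline-normalized to [0, 1]. Rheobase is the
lowest tested amplitude eliciting at least one AP. A missing amplitude is
filled with the arithmetic mean of the flanking available sweeps' binned
features (one-sided copy at the grid edge); a cell with no suprathreshold or
no subthreshold sweep is dropped and reported. The AP window, resampling
lengths and bin counts are not published constants; the values above are the
package defaults and are stated in `featureConfig()`.

`sparsePCA()` runs per category: soft-thresholded power iteration with
projection deflation (penalty expressed as a fraction of the largest
absolute loading; at 0 the procedure is ordinary PCA and is tested against
`prcomp`). Because sparse components are not orthogonal, explained variance
is *adjusted* via the QR decomposition of the projected data — the standard
correction — and components with adjusted explained variance above 1%
(`retention`) are kept, z-scored and concatenated. The total number of kept
components is data-dependent by construction; no attempt is made to
reproduce any particular published component count.

# Transcriptomic quality scores

Markers are selected per class from the reference
(`selectMarkers()`, default 50 per class): genes are ranked by
(mean in class - max mean elsewhere) x (detection fraction in class - max
detection elsewhere) in log2(CPM+1) space, a gene may serve only the class
where it scores highest, ties break lexicographically, and genes depleted in
both factors are excluded (two negative factors must not make a positive
score). All scores work in log2(CPM+1) space throughout.

For a cell, the per-class norm is its mean on-marker expression divided by
the class's reference summary — the median, over that class's reference
cells, of the per-cell mean on-marker expression. (The published phrase
"the same median expression" is ambiguous between a median of per-cell means
and a mean of per-gene medians; the median of per-cell means makes reference
cells self-normalize to a within-class median of exactly 1, which is the
property the score relies on.) The **NMS** is the maximum norm over classes,
the assigned class its argmax; a cell passes at NMS >= 0.4, boundary
inclusive. The **contamination score** is the sum of norms over the assigned
class's off-classes — by default every other class, which is the literal
published definition; a narrower off-set (e.g. non-neuronal subclasses plus
the opposite neuronal class) can be supplied via `MarkerSets`. Norms are not
clipped before summation. The **quality score** is the Spearman correlation
between the cell's marker-union vector and the best-matching type profile
within the assigned class ("correlation" is unqualified in the source; a
rank correlation is robust to the strong mean-variance relation of
log-expression).

# Taxonomy mapping and consistency

`mapCellOnce()` descends the tree from the root, choosing at each node the
child whose cluster mean profile (over that node's branch markers) has the
highest Pearson correlation with the cell; ties go to the first declared
child, and a degenerate correlation (constant vector) counts as no
correlation. `bootstrapMap()` repeats the descent 100 times, resampling 70%
of reference cells (stratified within each leaf type, so no cluster can
empty) and 70% of each node's markers in every iteration; the probability of
a leaf is the fraction of descents ending there. The published procedure
("100 bootstrapped iterations at each branch point") is implemented as 100
full root-to-leaf descents with per-descent resampling — the probability
semantics are equivalent, and full descents keep each iteration an
independent draw.

`referenceProbabilityMatrix()` maps every reference cell the same way and
averages probability vectors within each type; its rows record the expected
mapping ambiguity among biologically close types. `classifyConsistency()`
then applies, in order: KL divergence (epsilon-smoothed at 1e-6,
renormalized, natural log) between the cell's probabilities and the assigned
type's reference row — above 2 nats the cell is *inconsistent*; Pearson
correlation between the cell and the assigned type's mean profile over the
branch markers along the assigned path — below 0.5, *inconsistent*; then
*highly consistent* iff the top-two probability sum exceeds 70% **and** the
top1/top2 ratio exceeds 2 (both strict, per "exceeded"/"more than"; a zero
second probability counts as an infinite ratio); otherwise *moderately
consistent*. The reference distribution per type is aggregated by mean
(median is a one-line change); the per-type mean is the natural analogue of
"the reference mapping probability distribution" of a type.

# Outcome analysis

`rocAuc()` computes the empirical ROC over all thresholds with tied scores
grouped into single steps and the AUC by trapezoid, which equals the
Mann-Whitney concordant-pair probability with ties counted half; the
direction of each analysis (e.g. higher end pipette resistance predicts
good morphology; higher NMS predicts consistent mapping) is always explicit,
never inferred. `operatingPoint()` reports, at a cutoff, the fraction of
failed-outcome cells excluded and of good-outcome cells lost. Group-level
comparisons are delegated to `stats::t.test()` via `compareGroups()`.

# What the synthetic generators emulate — and what they do not

`makeReference()` plants disjoint marker blocks on a near-dropout baseline
(class markers shared across a class's types, type markers per leaf — the
latter an extension beyond class blocks, without which leaf types would be
unresolvable at the class branch point). Counts are drawn negative-binomially
around log-normally jittered means, CPM-normalized and log2(x+1)-transformed,
so reference cells satisfy the CPM-sum invariant exactly. Default study
conditions: 4 classes (one glial) x 2 types, 1000 genes, 50 class markers at
+4 log2 units, 30 cells per type, noise SD 0.3 — a desk-scale analogue, not
a reproduction of any real taxonomy's scale or gene identities.

`makePatchseqCells()` forms each cell as
`qualityFactor x typeCPM + contaminationFraction x gliaCPM` in linear CPM
space (contaminating RNA is additive material), optional log-normal noise,
then log2(x+1) — **without** re-normalizing the sum to one million. This is
deliberate: re-normalization would cancel the quality factor exactly, and
the empirical signature of a low-quality extraction is precisely that fewer
genes are detected overall. The quality factor is a stand-in for the
unknown dropout process of real Patch-seq extractions: it scales all
transcripts uniformly, whereas real degradation is length- and
abundance-biased. Passing tests therefore demonstrate that the scores
recover *planted* structure under this mixture model, not that they are
calibrated on real data.

`makeSweep()` integrates the first-order membrane equation exactly on the
sampling grid and pastes a piecewise-linear AP template at threshold
crossings; the template's peak dV/dt is an explicit parameter, so detector
boundaries can be located exactly. Noise is additive measurement noise
applied after integration — spike timing stays deterministic and the
closed-form oracles (steady-state deflection, ramp crossing time) are exact.
Real spike initiation dynamics, adaptation and channel noise are outside
the model.

`makeMetadata()` draws log-normal end-pipette-resistance distributions whose
analytic AUC between failed and good morphology equals the requested target
(AUC is invariant under the exp transform; a target of 1 switches to
disjoint uniform supports, since two normals always overlap).

All generators are pure functions of their seed; one master seed is split
into per-component streams with `childSeed()`.

# Numerical conventions and degenerate inputs

* Boundary conventions: RMP tolerance inclusive; RMS, resistance-fraction
  and seal criteria strict; NMS cutoff inclusive; KL, correlation, top-two
  and ratio thresholds strict.
* Derivatives: central differences; centered boxcar offline, causal boxcar
  online; both default to 5 samples.
* An all-zero expression vector scores NMS = 0, contamination = 0, fails.
* A class with zero reference median is excluded from scoring with a
  warning; a flat trace segment that prevents a half-height crossing flags
  the width as missing; a subsample that would empty a cluster is prevented
  by stratified resampling.
* KL smoothing floor 1e-6 with renormalization; natural-log units.
* Sparse-PCA sign convention: the largest-magnitude loading is positive;
  initialization is the dominant column of the Gram matrix, so results are
  deterministic without a seed.

# Problem sizes

The test suite and the boundary analyses run on small synthetic instances
chosen to keep every oracle exact: references of 3-4 classes x 2 types with
600-1000 genes, 500 cells per group for the NMS separation analysis,
100-iteration bootstraps, and sweeps of 1-7 s at 5-10 kHz (500 kHz only for
the threshold-ratio analysis, where discretization error must stay below a
tenth of a percentage point). These sizes are the package's validation
conditions; the implementations themselves are vectorized over cells and
have no built-in limits.

# Known limitations

* The quality factor and contamination mixture are idealizations; no
  sequencing-read or length-bias simulation is attempted.
* The consistency classification depends on a reference probability matrix
  estimated by bootstrap; with few reference cells its rows are themselves
  noisy.
* The membrane model is passive-plus-template: it cannot produce bursting,
  adaptation or depolarization block, so feature categories (c) and (d) are
  exercised on stereotyped trains only.
* Dataset-level published figures (pass rates, dataset AUCs, component
  counts, operating points) are properties of a specific large dataset and
  are out of scope; the package validates behavioral boundaries and
  planted-structure recovery instead.
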