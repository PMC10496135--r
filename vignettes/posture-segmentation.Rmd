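---
title: "Posture segmentation of 3D pose-tracking data: methods and design"
author: "PostureSeg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Posture segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PostureSeg)
```

## The problem

Markerless pose estimation (DeepLabCut and kin) turns video of a freely
moving mouse into per-frame coordinates of tracked body parts. Turning those
coordinates into an interpretable behavioral readout still requires a
segmentation step: which frames belong to which posture, and which postures
recur across animals? PostureSeg implements a deliberately simple,
fully unsupervised three-step pipeline for that task, operating only on the
vertical (z) coordinate of six bodily hotspots — nose, eyes, neck, mid back,
lower back, tail attachment — whose relative elevations change sharply
between behavioral states such as locomotion, rearing, and defensive
hunching.

## The model

### Features: signed pairwise height differences

For each frame the six z coordinates are reduced to the 15 signed
differences $d_{ij} = z_i - z_j$ over all hotspot pairs $i < j$ in canonical
order. Two properties motivate this choice:

* **Body-size invariance.** A constant offset added to all hotspots (a
  larger animal, a higher arena floor) cancels exactly in every difference.
  This is tested to $10^{-12}$ in the suite.
* **Sign carries signal.** Whether the nose sits above or below the tail
  attachment distinguishes rearing from digging; absolute values would
  conflate them. The sign is therefore retained (an `absolute = TRUE` mode
  exists for comparison).

Frames where any hotspot failed to track are kept in the timeline — frame
indices must stay aligned across sessions — but flagged, excluded from
clustering, and labeled with the sentinel 0 ("unassigned") throughout.

Note the features are *invariant* to body size only in the additive sense;
a multiplicative size effect (longer limbs stretching all differences) is
not removed, and no further normalization is applied by design.

### Step 1: postures per subject

All sessions of one subject are concatenated (posture identity should not
depend on session) and the N×15 feature matrix is clustered by k-means with
an elbow criterion: for each candidate $k = 1 \dots k_{max}$ the engine
keeps the best of $r$ k-means++ restarts, and the chosen $k$ is the smallest
whose explained-variance fraction

$$V(k) = 1 - \frac{WCSS(k)}{WCSS(1)}$$

reaches the cutoff. Postures are renumbered by descending frame count, so
posture 1 is always the subject's most frequent one.

Engine details that matter for reproducibility:

* initialization is k-means++ drawn from R's RNG, so a seed fixes the
  entire fit;
* assignment ties break to the lowest cluster index, and empty clusters
  retain their previous center — both deterministic rules;
* Lloyd iteration stops when assignments are stable, when the relative
  WCSS improvement falls below $10^{-8}$, or at `maxIter`.

Defaults (`clusteringConfig()`): $k_{max} = 20$, cutoff $0.95$, $r = 10$
replicates, `maxIter` 300. The cutoff is the load-bearing choice: 0.95
means "stop adding postures once they explain 95% of postural variance".
On well-separated synthetic data $V$ jumps from roughly 0.87–0.90 at one
cluster below the planted number to roughly 0.97 at the planted number, so
values between about 0.92 and 0.96 behave identically; 0.95 is used
throughout.

### Step 2: behavioral modules across subjects

Posture centroids (the per-posture mean feature vectors) of all subjects
are pooled and clustered again with the same engine at a fixed $k$, chosen
by the user or by the rule $k = \min_s(P_s) + 1$ — one more module than the
smallest per-subject posture count, giving every subject's postures room to
separate while still forcing cross-subject matching. Centroids enter
unweighted (each posture is one row regardless of how many frames support
it); a `weighted = TRUE` mode replicates rows by frame count. Two postures
of the same subject may land in the same module — that is a legitimate
merge of near-duplicate postures, and it is logged. Modules are renumbered
by descending total frame count across the cohort.

### Step 3: frame labeling and frequencies

Every frame's posture label is translated to its module through the
(subject, posture) → module map; the sentinel propagates. Output is one
labeled file per original tracking file plus a per-subject frequency table
(modules × sessions) whose columns sum to the session frame counts — an
"unassigned" row appears only when missing frames exist, so files from
fully tracked data remain comparable to older layouts.

## Analytics

**Bouts.** A bout is a maximal run of consecutive frames with the same
module label; run-length encoding is per session (bouts never span
recordings). Durations convert to milliseconds as $n \cdot 1000 / fps$ (40
ms per frame at 25 fps). The short-bout percentage is frame-weighted:
$\sum_{\text{bouts} < T} \text{len} \times 100 / \sum \text{len}$, with
$T = 3$ frames (120 ms) as default threshold. Sentinel bouts are excluded
from bout statistics by default (`includeUnassigned` overrides); they are
*included* in frequency tables, which count every frame.

**Session normalization.** Stimulus-evoked change of module $m$ in test
session with count $a$ against reference count $b$ is $(a-b)/(a+b) \in
[-1, 1]$, antisymmetric and invariant to rescaling all counts. The $0/0$
case is defined as 0, keeping heatmaps finite; stored values are fractions,
percent is presentation only.

**Ethogram correlation.** Pearson product–moment correlation across
subjects between time per module and time per manually scored category,
with two-sided t-distribution p-values via `stats::cor.test`. Frames and
seconds give identical r at fixed fps, so either unit is accepted. A
constant vector yields a flagged `NA` — never a silent zero.

## The synthetic cohort generator

`simulateCohort()` emulates the upstream data source so the whole pipeline
can be validated against known ground truth: per subject, a semi-Markov
process switches among a subject-specific subset (≥ `minExpressed`, size
drawn uniformly) of A planted archetypes, with geometric dwell times (mean
10 frames by default — long enough that bouts are visible, short enough
that a 4500-frame session holds hundreds of them), per-subject additive
body-size offsets (s.d. 1), i.i.d. Gaussian tracking noise per hotspot
(s.d. 0.5), and whole-frame dropouts at rate 0.01. Defaults are 12 subjects
× 5 sessions × 4500 frames at 25 fps, a cohort size typical of a
multi-session stimulation experiment.

**What the archetypes are and are not.** The nine default profiles carry
coarse postural motifs (nose-high, mid-back-apex, tail-high, …) but are
*stylized*: they were spread by repulsion on the sphere of centered shape
vectors to be near-equidistant in feature space (pairwise distances 18–30
units against a per-feature noise s.d. of about 0.7). Strictly anatomical
profiles cluster along a few shape directions — two rearing variants are
nearly parallel — and no variance-ratio criterion can split nearly parallel
archetypes; a fixture whose ground truth is unrecoverable in principle
would test nothing. Consequently, passing the planted-recovery tests shows
the pipeline is correct and deterministic on separable data; it does not
show that real mouse postures are this separable. On real data the elbow's
$k$ reflects a bias–variance trade-off, not a discrete truth.

Other things the generator does not emulate: autocorrelated tracking noise,
partial-body dropouts, slow drift, x/y kinematics, and any dependence of
dwell time on posture identity.

## Numerical and degenerate-input choices

* WCSS(1) = 0 (all frames identical) short-circuits the elbow to $k = 1$.
* `kMax` is clamped to the number of distinct feature rows, with a message.
* In k-means++, if all remaining squared distances are zero the next
  center is the first unused point — deterministic.
* Centroids are recomputed as plain means of member rows after
  relabeling, so the definitional invariant (centroid p = mean of rows
  labeled p) holds to ~1e-16 rather than inheriting Lloyd's last update.
* Natural sorting (digit runs zero-padded, C collation) fixes session
  order across platforms; file modification times are never consulted.
* Output CSVs are headerless numeric (the convention of the desktop
  MATLAB-style pipelines this layout follows); the frequency file alone
  carries a header row to preserve session labels through a round trip.
  Missing values are written as NaN.

## Problem sizes used by the test suite

Unit tests run on cohorts of 2–4 subjects with sessions of a few hundred
frames; the cohort-scale recovery test runs the full default geometry (12 ×
5 × 4500 frames, ~1.6 M tracked frames) through all three steps and asks
for adjusted Rand index ≥ 0.9 against the planted labels and exactly the
planted number of modules under the MIN+1 rule. The acceptance script uses
12 subjects × 2 × 1200 frames, which is ample for the module-count rule it
evaluates.

## Known limitations

* Only z is consumed; behaviors distinguished by horizontal kinematics
  (e.g. locomotion speed) fold into the same modules.
* k-means partitions are spherical in feature space; elongated or nested
  posture manifolds will be split or merged.
* The MIN+1 rule is a heuristic; cohorts with one badly tracked subject
  (few postures) drag the module count down for everyone.
* DLC likelihood columns, if present, are ignored rather than thresholded
  (an explicit likelihood filter upstream is compatible with the reader,
  which only consumes z columns).
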