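---
title: "Dependency network analysis of ROI time series: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dependency network analysis of ROI time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depna)
```

## The problem

Standard functional-connectivity analysis of fMRI region-of-interest (ROI)
time series stops at symmetric pairwise correlations: it says which regions
co-fluctuate, not which regions *shape* the co-fluctuation of others.
Dependency network analysis (DepNA) addresses this with a simple,
correlation-native notion of influence: a node j is influential on the
connection between nodes i and k to the extent that removing j's linear
contribution (by partial correlation) weakens that connection. Ranking nodes
by their total influence yields a hierarchy of the network — which regions
are plausible drivers of information flow — that can be contrasted between
task conditions and correlated with behavior. The canonical application this
package emulates is a two-network design: a limbic "reactivity" sub-network
(amygdalae, mid-insulae, PAG, dACC) and a prefrontal-parietal "regulation"
sub-network (IFG, MiFG, SPL, pre-SMA, vmPFC), probed during low- versus
high-intensity emotional epochs of a naturalistic stimulus.

## The model

Let \(C\) be the Pearson correlation matrix of the \(N\) ROI time series in
one condition. For distinct nodes \(i, k, j\):

\[
PC(i,k \mid j) \;=\;
\frac{C(i,k) - C(i,j)\,C(k,j)}
     {\sqrt{\bigl[1 - C^2(i,j)\bigr]\bigl[1 - C^2(k,j)\bigr]}},
\qquad
d(i,k \mid j) \;=\; C(i,k) - PC(i,k \mid j).
\]

\(d(i,k|j)\) is the part of the i–k correlation attributable to j; it is
large only when j is a common cause or mediator of the pair. Negative values
(j *masks* a correlation) are reset to zero so that aggregation never sums
signed contributions against each other. The dependency matrix averages
over conditioned pairs,

\[
D(i,j) \;=\; \frac{1}{N-1}\sum_{k \ne j} d(i,k \mid j),
\]

and the **influencing degree** of node j is the column sum
\(\sum_{i \ne j} D(i,j)\): j's system-level out-influence. \(D\) is
non-negative and asymmetric — influence of j on i is not influence of i on
j. The \(k = i\) term is kept in the sum exactly as the definition is
written; it is identically zero, so it only fixes the normalizer at
\(N - 1\).

Three sub-network aggregates refine the picture (all exposed as
`influence_profile` schemes):

* **intra** — a member node's influence on connections inside its own
  sub-network;
* **inter, option 1** (`inter_within_other`) — a source-network node's
  influence on pairs entirely inside the other network;
* **inter, option 2** (`inter_between`) — its influence on pairs straddling
  the two networks (the conditioning node is excluded from its own pair
  slots).

Summing an inter profile over source nodes gives the total inter-network
influence of one network on the other.

Important caveat, inherited from the method itself: none of this is causal
inference. \(d\) detects shared linear variance; a node can "influence" a
pair through any common input, including unmodeled ones.

## Numerical and design choices

**Raw r versus Fisher z.** The partial-correlation formula is only
guaranteed well-defined for correlations in \([-1, 1]\); applied to raw
Pearson r it is exactly the correlation of the two residual series after
regressing out the conditioning node (a property the test suite asserts to
1e-10). Applying the same arithmetic to Fisher-z-transformed values — as the
method is sometimes described — can push denominator arguments
\(1 - z^2\) negative. The package therefore defaults to raw r, and offers
`transform = "fisher_z"` (denominator arguments floored at 1e-12, with a
warning) for literal reproduction. Pearson r is scale-invariant, so the
default per-epoch column z-scoring (`standardize_epochs`) is cosmetic but
keeps the z path stable.

**Intra-network computation.** The default recomputes the decomposition on
the sub-network's correlation sub-matrix alone, so the intra profile of a
sub-network equals the global pipeline run on that sub-matrix — a
self-contained sub-network quantity. The alternative
(`intra_mode = "masked_full"`) masks the full-network dependency matrix,
retaining whole-network conditioning; both are exposed because published
descriptions do not fix the convention.

**Pair normalization.** Inter-network scores are reported per contributing
(i, k) pair (`normalization = "mean"`) by default, with `"sum"` available.
Published magnitude tables for the different variants sit on visibly
different scales, so neither convention is asserted as canonical; the mean
keeps profiles comparable across differently sized networks.

**Degenerate inputs.** Constant columns and |r| = 1 conditioning
correlations are errors that name the offending ROI (a `clip` policy floors
the denominators instead). Zero-variance difference vectors in the paired
contrast are reported with an explicit `degenerate` flag rather than NaN.

## Epoch selection from continuous ratings

Continuous emotion ratings (10 Hz, a 21-degree scale in the emulated
design) are reduced to one low- and one high-intensity epoch by the printed
three-criterion search: equal length, group medians differing by Wilcoxon
signed-rank test at `alpha` (default 0.01), and maximal length, iterating
down from half the trace. At the largest passing length the pair maximizing
the group-median contrast is returned, with deterministic tie-breaks
(earliest high start, then earliest low start). Because exhaustive
sample-level enumeration is cubic in trace length, the search walks a
`step` grid (default one second — the resolution at which such windows are
reported); tests verify exhaustive-search agreement at `step = 1` on short
traces. The Wilcoxon pairing unit is per-subject window medians across
subjects (`pairing = "subjects"`), matching the "across subjects" reading;
`"timepoints"` pairs group-median samples by within-window position.
Windows map to volumes by `floor((t + lag) / TR)` with an optional
hemodynamic lag (default 0 s, as in the emulated analysis); 132-s windows
at TR 3 s give the canonical 44 volumes per condition.

## Group statistics

Per-node condition contrasts are two-tailed paired t-tests (df = n − 1)
with Benjamini–Hochberg adjustment over the node family (the family size
`m` is configurable for partially reported families). The edgewise graph
applies the same paired contrast to every dependency entry and keeps
directed edges j → i at p < 0.05, exported as BrainNet Viewer
`.node`/`.edge` text files and GraphML. Behavior correlations use the
low-minus-high influence difference, listwise deletion, and exclusion of
subjects more than 3 SD from the mean on either variable.

The spatial-specificity bootstrap compares an observed statistic with the
same statistic on size-matched random networks:
\(p = (\#\,\text{extreme} + 1)/(k + 1)\). As printed, the original formula
counts random values *smaller* than the observed one, which rewards
unremarkable findings; the surrounding text makes clear that specificity
means the observed value beats the random networks. The default therefore
counts values at least as extreme in the observed direction, and
`literal_eq5 = TRUE` reproduces the printed count (which is also the
rank-uniform variant used for the null-calibration test). Random networks
are drawn from a user-supplied candidate pool ([simulate_null_pool()] in
the synthetic setting); atlas-based gray-matter sampling is out of scope.

## The synthetic cohort generator

No public dataset accompanies the emulated design, so the generator is a
first-class module. Its defaults *are* the study conditions: 74 subjects,
the packaged 14-ROI two-network set, 44 volumes per condition at TR 3 s,
hub vmPFC. Influence is planted through a common-cause construction —
the hub carries a white Gaussian signal h, and every other node receives
\(\beta_{s,c}\,h\) plus a network-shared factor and private noise — because
\(d\) is by construction a common-cause detector. Condition couplings
default to 0.15 (low) and 0.45 (high).

The free parameters not fixed by the emulated design were chosen once as
realistic for TR-3s ROI data and are not tuned per analysis:
`subject_coupling_sd = 0.1` (between-subject coupling spread, giving
realistic subject-level variability in the planted effect),
`shared_factor_sd = 0.3` (moderate within-network shared variance, about a
tenth of the private noise variance `noise_sd = 1`), and a behavioral
latent `b = behavior_slope * (beta_low − beta_high) + noise` with
`behavior_slope = −1`, `behavior_noise_sd = 0.2`, so that behavior
correlates negatively with the low-minus-high hub influence at a moderate,
realistic effect size. The latent drives both the rating-trace high-plateau
amplitude (hence the AUC intensity index) and the discretized trait-anger
score. Rating traces are low-then-high step profiles with smoothed jitter
over the concatenated 264-s run, so the epoch search recovers the two
132-s condition blocks exactly.

What the generator does **not** emulate: hemodynamics (no balloon model,
no autocorrelation by default), head motion, physiological noise, spatial
structure, or missing behavioral data. Passing the planted-effect tests
therefore shows the *estimator chain* is correct and well calibrated under
the assumed statistical structure — not that real BOLD data satisfy that
structure.

## Validation scale and what the tests compute

The test suite validates at the emulated study scale where it matters:
oracle equivalence of the vectorized decomposition against a literal
triple-loop implementation (500 random matrices, N ≤ 8, 1e-12);
the residual-regression identity (100 datasets, 1e-10); type-I calibration
of the per-node paired contrast on 1000 i.i.d. Gaussian cohorts of
74 × 14 × 44 (per-node rejection rates within binomial 99% bounds of 0.05)
and rank-uniformity of the bootstrap p over 500 null runs; planted-hub
recovery with FDR survival over 20 seeded default cohorts plus monotonicity
in the coupling gap; the behavior-coupling sign over 100 cohorts; an
exhaustive-search cross-check of the epoch selection; and byte-identical
reproduction of the full pipeline bundle under a fixed seed.
`scripts/acceptance.R` recomputes the same quantities from scratch (400
null replicates there) and writes them as JSON.

## Limitations

* Influence is linear and correlation-based; nonlinear or lagged coupling
  is invisible, and no causal claim is licensed.
* Inputs must be fully preprocessed; the package provides only global-mean
  scaling and per-epoch standardization as signal utilities.
* Short epochs (T barely above N) make correlation — and therefore
  influence — estimates noisy; the containers warn below T = N + 2.
* The epoch search tests group medians; designs whose conditions differ in
  variance but not level will not separate.
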