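---
title: "Sequence-based scoring of acute gapmer neurotoxicity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-based scoring of acute gapmer neurotoxicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapmerTox)
```

## The problem

LNA-modified, phosphorothioate (PS) antisense oligonucleotide (ASO) gapmers
delivered by intracerebroventricular (ICV) bolus injection can produce acute,
hybridization-independent neurobehavioral side effects within minutes of
dosing. In vivo, severity is scored over five behavioral categories
(hyperactivity; decreased activity and arousal; motor dysfunction/ataxia;
abnormal posture and breathing; tremor/convulsions), each 0-4, summed to a
per-mouse total in 0-20 and averaged over a 4-6 mouse treatment group. In
vitro, the same liability manifests as a reduction of spontaneous,
AMPA-receptor-dependent calcium oscillations in neuronal cells, quantified on
a FLIPR plate reader as a percent-of-control oscillation score.

This package implements the computational layer connecting the two: sequence
feature extraction, a linear sequence score fitted to calcium-oscillation
data, tolerability classification, trace scoring, and a design procedure for
G-free negative-control gapmers.

## The model

For an ASO with nucleobase counts $n_A$, $n_T$, $n_C$, $n_G$ and a 3'
G-free stretch of $g_3$ nucleotides (consecutive non-G bases counted inward
from the 3' terminus), the calculated score is

$$\mathrm{score} = p_A n_A + p_T n_T + p_C n_C + p_G n_G + p_3 g_3 + I.$$

The six parameters are estimated by ordinary least squares against measured
calcium oscillation scores (`fitScoreModel()`, which delegates to the QR
solver in `stats::lm`). Higher scores predict safer ASOs. Per-term
significance uses the $t$ statistic on $n - 6$ residual degrees of freedom,
two-sided — a conventional choice; one-sided alternatives are not exposed.

Assumptions worth stating plainly:

* the score is linear in single-base counts and one positional feature;
  dinucleotide or trinucleotide expansions are deliberately out of scope
  (they add many parameters without a commensurate gain and invite
  overfitting at these panel sizes);
* LNA and DNA nucleotides are treated identically at the feature level —
  chemistry enters parsing and gap bookkeeping, not the score;
* calcium scores are used raw (uncapped) when fitting; capping extreme
  scores (e.g. at 200) is a display convention, available through the
  `cap` argument but off by default.

## Sequence representation

Gapmers are written 5'→3' in a case-annotated dialect: uppercase = LNA,
lowercase = DNA (`parseGapmer()` / `serializeGapmer()` are exact inverses).
Bases are stored as DNA letters (T, never U); base-analog chemistry such as
LNA-5-methylcytosine is not modeled because every downstream feature uses
four-letter base identity only. Positions are 1-based in user-facing
messages. Arbitrary per-position modification patterns are accepted, since
mixed-flank designs (e.g. `CcAAAtcttataataACtAC`) occur in practice.

## Tolerability classification

Group-mean tolerability scores are binned at 4, 7 and 18 into mild
`[0,4)`, moderate `[4,7)`, marked `[7,18]` and severe `(18,20]` classes.
The *binary* task labels an ASO acceptable when its score is **at or below
4**. The boundary score 4 therefore falls in the moderate severity bin yet
is still acceptable; the two conventions differ at that single point and
both are documented at `classifySeverity()` / `binaryLabel()`.

Classifier evaluation treats *toxic* as the positive class and
predicted-toxic as score ≤ cutoff:

* `rocCurve()` computes the AUC through the rank (Mann–Whitney) identity,
  ties counted one half — equal, by construction, to the probability that a
  random toxic ASO scores below a random acceptable one;
* `accuracyVsCutoff()` scans an integer grid (default 0-200, the
  calcium-score scale) and reports the accuracy-maximizing cutoff as the
  midpoint of the maximal plateau — the longest contiguous run of
  top-accuracy cutoffs, ties broken toward the first run. A midpoint is
  reported because top accuracy is typically flat over a score interval and
  any interior point is equally supported;
* `classificationReport()` reports confusion counts with accuracy,
  sensitivity, specificity, PPV and NPV; NPV — the fraction of
  predicted-safe ASOs that are truly safe — is the operationally relevant
  number when the score is used as a pipeline filter. Zero-denominator
  metrics are `NaN` with a warning rather than silently dropped.

## Calcium-trace scoring

`FliprTrace` objects hold 1 Hz fluorescence reads segmented by the plate
protocol (100 s baseline, 200 s post-addition, 300 s second read; lengths
configurable). The amplitude-threshold score gives each 1 s read in the
scored window one point when its signal increase exceeds 50% of the average
control spike amplitude; the summed count is converted to percent of the
mean control count, so untreated wells average 100 by construction.

Numerical conventions the protocol leaves open, fixed here for determinism:

* "signal increase" is fluorescence minus a per-trace baseline, estimated
  as the **median of the 100 s baseline segment** (a rolling-minimum
  alternative is available via `traceBaseline(method = "rolling_min")`);
* the scored window defaults to the 300 s second read, matching the window
  used to establish the control amplitude; the 200 s post-addition segment
  can be scored via the `segment` argument;
* peak counting (`countPeaks()`, used for the receptor-pharmacology arm)
  requires a local maximum with prominence ≥ 20% of the reference
  amplitude and ≥ 2 s separation — unstated in the protocol, needed for a
  deterministic count;
* spike detection in control wells ignores candidate maxima below 10% of
  the trace's own dynamic range, so flat traces raise an error instead of
  contributing noise-level "spikes".

Concentration–response data are fitted with the four-parameter logistic
$R(c) = \mathrm{bottom} + (\mathrm{top}-\mathrm{bottom})/(1 + (EC_{50}/c)^{h})$
by Levenberg–Marquardt least squares (`minpack.lm::nlsLM`). Initialization
is deterministic: top/bottom from the response extremes, $EC_{50}$ at the
geometric mean of the concentration range, and slope $\pm 1$ chosen from the
orientation of the response trend (for inhibition curves the fitted slope is
negative and the saturating plateau is `bottom`). Constant responses are
flagged degenerate ($EC_{50}$ unidentifiable) rather than fitted.

## Negative-control design

`designNegativeControls()` operationalizes the empirical finding that G
content (especially near the 3' end) raises, and A content lowers, acute
neurotoxic potential. Candidates are drawn by seeded rejection sampling over
$\{A, C, T\}$ at the configured lengths and LNA flank patterns, kept when
$|n_A - (n_T + n_C)| \le \delta$ (default $\delta = 4$, the loosest value
consistent with published designs of this type), then filtered by:

* no perfectly complementary window anywhere in the transcriptome;
* partially complementary windows — reverse-complement alignment with at
  most 2 Hamming mismatches, no gaps or bulges — in fewer than 0.1% of
  transcript records (`offtargetScreen()`, backed by
  `Biostrings::vcountPattern`; the denominator is transcript records, not
  windows);
* calculated score above 70.

Survivors are ranked by descending calculated score; ranking is this
package's policy, since "preference" among passing designs is not otherwise
an algorithm. RNA targets are stored as DNA letters with A↔T / C↔G
complementarity (U ≡ T). Transcripts shorter than the ASO contain no
window and count as non-binding rather than raising an error, so mixed
real transcriptomes remain usable.

## What the synthetic generator emulates — and what it does not

`generatorConfig()` fixes the simulated study conditions: panels of 1,645
training, 148 test and 19 validation ASOs tiled as reverse complements of
windows on a simulated 7,063 nt target pre-mRNA divided into 313 disjoint
regions; ASO lengths 14-20 nt with 3-9 LNA nucleotides split over two
flanks; calcium scores generated from a ground-truth linear model plus
Gaussian noise (sd 25), truncated at 0; and per-mouse tolerability totals
from the monotone decreasing link $20\,\mathrm{logistic}(-(ca - 70)/15)$
plus per-mouse noise (sd 2), decomposed into five category scores by random
composition, over 4-6 mice per group.

The default true coefficients $(p_A, p_T, p_C, p_G, p_3, I) =
(8, 3, 4, -6, 2, 50)$ are a calibration choice, not measured values: they
reproduce the qualitative pattern of fitted models (strongly negative G
weight; A contributing more than T or C; positive $g_3$ weight) and place a
typical tiled ASO near 100 on the percent-of-control scale, so that roughly
a third to two fifths of simulated ASOs fall in the moderate-to-severe
range and score cutoffs in the tens-to-low-hundreds are meaningful.
Tolerability is driven by each sequence's *noiseless* linear value, which
encodes the working hypothesis that the in-vivo liability follows the
underlying sequence effect rather than the assay's measurement noise; under
that structure a model fitted on a large noisy training screen de-noises
the assay, and the calculated score classifies tolerability better than the
raw measurement — the property the acceptance suite checks.

What the generator does **not** emulate: real target biology (no
knockdown efficacy, no region-specific sequence motifs beyond shared
windows), the true noise structure of the calcium assay (real noise is
unlikely to be homoscedastic Gaussian), dose dependence (a single dose
level is assumed), or any chemistry beyond the LNA/DNA flag. Passing tests
on generator output therefore validate the *machinery* — estimators,
classifiers, screens, file formats — under the stated statistical
structure; they are not evidence about any particular real panel.

## Problem sizes and determinism

The test suite exercises the estimators at the full simulated study scale
(1,645-ASO training panels; 200 Monte-Carlo refits for the standard-error
coverage check; exhaustive brute-force oracles for edit distance, AUC and
the off-target screen at small sizes), which keeps the default run under a
minute on a single core. Every stochastic component takes an explicit
seed, restores the caller's RNG state, and is bit-reproducible given the
seed; `scripts/acceptance.R` derives all of its seeds from its `--seed`
flag.

## Known limitations

* The fitted coefficients shipped by any given analysis are only as good
  as the calcium panel behind them; the package deliberately ships no
  trained coefficient values, only the fitting machinery and the published
  13-design negative-control panel for feature-level verification.
* Off-target screening is Hamming-only; gapped or bulged near-complements
  are not detected, consistent with the design procedure it implements.
* The tolerability link used for simulation is a convention; real
  calcium-to-behavior relationships around score ~100 are known to spread
  across severity classes, so simulated classification performance is an
  upper bound on what the structure alone can deliver.
* Calcium trace scoring assumes the 1 Hz protocol; instrument-native file
  formats are not parsed.
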