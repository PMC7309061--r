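---
title: "Scoring and classifying digitized neurocognitive test sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and classifying digitized neurocognitive test sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogscreen)
```

## The screening problem

Degenerative CNS disorders (Huntington's, Parkinson's, early dementia, mild
cognitive impairment) present with intertwined cognitive, motor, speech and
metabolic signs. `cogscreen` implements the computational core of a
self-administered, touch-screen screening battery: sixteen tasks (twelve
digitized from the SAGE cognitive examination plus finger tapping, spiral
tracing, voice recording and an energy-expenditure diary) are scored
automatically, condensed into a fixed 238-feature record per session, and a
hybrid ensemble classifies the record as healthy (class 0) or impaired
(class 1).

This vignette is the package's account of the methods: the models, the
tunable parameters and their defaults, the numerical choices, and what the
synthetic validation data can and cannot show.

## Geometric primitives

**Discrete Fréchet distance.** Drawn trajectories are point sequences, so
curve similarity uses the discrete Fréchet distance: the minimum over
monotone couplings of two sequences of the maximum pairwise Euclidean
distance, computed by the standard \(O(nm)\) dynamic program (in C++ via
Rcpp). Trajectories longer than 512 points are first resampled uniformly by
arc length; this bounds the quadratic cost while changing the distance by at
most the resampling gap. The implementation is tested against a brute-force
enumeration of all monotone couplings on curves of up to 7 points, and for
metric properties (symmetry, identity, triangle inequality) on random small
curves.

**Spiral reference.** The displayed Archimedean spiral is
\(r = \frac{s}{2\pi}\theta\) sampled uniformly in \(\theta\). Its
parameters are not dictated by the screening methodology, so the package
defaults are a deliberate choice: 3 turns, 256 sample points, and a spacing
argument the caller sizes to the device (the cohort generator uses 80 px
per turn around a 800 × 1000 px canvas). Counter-clockwise spirals are the
mirror image about the vertical axis through the center; screen coordinates
are Android-convention (origin top-left, y down).

**Percentage match.** The fraction of drawn points whose nearest reference
point lies within a radius. No radius is prescribed by the source
methodology; the default used by the cohort generator is 30 px (about 2% of
the canvas diagonal) and every scorer takes it as an argument.

**Parallel lines.** Edge slopes are total-least-squares line fits (first
principal axis), which stay stable for near-vertical strokes; the angle
between two slopes is \(\arctan |m_1 - m_2| / |1 + m_1 m_2|\) with the
perpendicular (denominator zero) case mapped to 90° and two vertical lines
to 0°. The construction task checks 9 configured edge pairs with a 10°
tolerance and a 50% match requirement. A cube has more parallel edge pairs
than 9; the package designates three pairs per edge direction
(`cube_parallel_pairs()`), a documented configuration choice.

**Neighbor-matching graph similarity.** Node-pair similarity is refined
iteratively: the similarity of nodes \(i, j\) is the optimal assignment of
their neighbors' similarities divided by the larger degree (isolated-node
pairs count as 1), iterated until the largest entry moves less than `eps`
(default 1e-4). The whole-graph similarity is the mean optimal
node-assignment similarity, so it is exactly 1 for isomorphic graphs and
invariant to relabeling. The assignment step is an exact \(O(n^3)\)
Hungarian solve (no linear-assignment package ships in the environment),
verified against permutation enumeration. A property worth knowing: the
fixed point is strict — a single missing edge in an otherwise identical
figure can drive the similarity far below 1, because the discrepancy
propagates through every refinement round. The score therefore behaves
almost like a graded indicator of "figure reproduced correctly", which is
how the per-task scorers use it.

## Task scoring

**Inexact text matching.** All free-text answers are canonicalized (case
folded, punctuation stripped, whitespace collapsed) and compared with
Jaro–Winkler similarity: the Jaro match/transposition formula plus the
prefix boost \(jw = j + \ell p (1 - j)\) with \(p = 0.1\) and
\(\ell \le 4\). The boost applies whenever \(j > 0\); two empty strings
compare as 1. A similarity of at least **0.85** credits an answer as "knows
the word but misspelled it" — the threshold is a package default (the
methodology states none) and is an argument everywhere it is used. The raw
Jaro–Winkler values feed the three-feature Spelling group.

**Point rules.** Orientation (T6) gives one point per exactly matching
date component (max 3 — the literal accumulation rule, since the official
form's weighting is not restated in the source methodology). Picture naming
(T7) gives one point per picture, exact or above the JW threshold.
Similarities/calculation (T8) gives 2 points for an abstract answer, 1 for
a concrete one (an answer matching both lists scores abstract — the higher
interpretation wins), 1 point for the subtraction answer within **0.005**
(currency rounding) and 1 point for the exact division quotient. Verbal
fluency (T11) scores 2/1/0 for 12 / 10–11 / fewer distinct correct items,
with duplicates after canonicalization counted once and a 12-slot mean JW
auxiliary. Memory recall (T0) scores 2 for the exact phrase, 1 when
"finished" or "done" appears. The insights questionnaire (T5) is non-scored
and encoded as a deterministic 8-value block.

**Construction and executive replay.** The 3-D figure (T9), trail-making
(T12) and match-puzzle (T13) tasks replay an ordered action log against a
node layout. A stroke resolves to the nodes whose centers it passes within
the hit radius (default: the drawn node circle's radius), in first-touch
order. The error taxonomies are exactly the published ones: T9 counts wrong
connections, too-few-node strokes, too-many-node strokes and re-drawn
connections; T12 counts wrong connections, single-node touches and clicks
outside any node, and forms a path only when exactly two nodes resolve;
T13 executes insert/remove on sequential two-node touches, counts same-node
touches, out-of-zone touches and rule violations, and stops when the
operation budget reaches zero. All counters are non-negative and monotone
in the log prefix. Because the underlying point scales for these tasks are
not published, the package derives their SAGE-group points from the
similarity and error outcomes (2 for an essentially perfect figure, 1 for a
recognizable one, 0 otherwise); the thresholds are documented constants in
the scorers.

**Clock drawing (T10).** Only the automatic part is implemented: counting
stroke points outside the active contour (even-odd ray casting). The
clinical clock score is semi-automatic by design; a supplied supervisor
score is recorded unchanged, otherwise the points stay 0.

## Energy expenditure (T15)

Basal metabolic rate uses Mifflin–St Jeor with height in metres:
\(\mathrm{BMR} = 625H + 10W - 5A + 5\) for men, \(-161\) instead of \(+5\)
for women. TDEE multiplies by the physical-activity-level coefficient
(sedentary 1.2, light 1.375, moderate 1.55, heavy 1.725, athlete 1.9 — the
conventional multipliers, overridable, since the methodology names the
levels but not the numbers). Gained calories sum
\(m \cdot \mathrm{Cal}_{100} / 100\) over the food diary; burned calories
sum \(\mathrm{MET} \cdot W \cdot D / 60\); the balance is the exact
difference, with negative balances the clinically relevant signal. The
T15 feature group is fixed as {BMR, TDEE, gained, balance}. Product and
MET tables ship as editable CSVs.

## Speech features (T14)

Framing defaults to 30 ms Hamming windows with a 10 ms hop (not specified
by the methodology; these are the common speech-analysis values), and all
extractors operate at the clip's native rate. Silence is removed by
energy thresholding: frames more than 40 dB below the peak frame energy
are dropped, surviving segments shorter than 100 ms discarded.

Five pitch estimators cover the published inventory — normalized
correlation, harmonic-comb pitch estimation filter, cepstral peak,
log-harmonic summation and summation of residual harmonics (on the order-12
LPC residual spectrum) — over a 50–400 Hz search range with per-method
voicing confidence thresholds. MFCC and GTCC share one pipeline: magnitude
spectrum, filter bank (26 triangular mel filters, or 32 ERB-spaced
fourth-order gammatone magnitude responses from 50 Hz to Nyquist), log, and
an orthonormal DCT-II keeping coefficient 0. Ten spectral descriptors
follow their standard definitions (slope by linear regression, moments
about the magnitude-weighted centroid, decrease, flux, 0.85 rolloff,
flatness, normalized spectral entropy); all-zero frames yield `NA`.

The wavelet scattering transform uses analytic Morlet-style filter banks
with 8 and 1 wavelets per octave, a 0.5 s invariance scale, averaging into
exactly 8 scattering windows and a `log(x + 1e-10)` transform. Convolutions
are circular (FFT), which also gives the shift-stability the tests assert.
The E3-style per-frame sequence preset concatenates pitch (1), 13 MFCCs,
13 GTCCs and spectral skewness (1) — 28 z-scored columns; the exact
coefficient counts beyond the published method list are a documented
package choice.

## The 238-feature schema

The schema fixes 14 ordered groups with sizes 9, 10, 28, 22, 22, 30, 24,
2, 33, 25, 4, 3, 10, 16 (total 238): finger tapping (T1–T3), two spiral
trajectories, construction, clock, fluency, trails, problem solving,
energy, spelling, the SAGE scores and the 16 per-task durations. The
published schema fixes only these group *sizes*; the concrete within-group
feature lists (for example T1 = 3 layouts × {mean inter-tap interval, mean
touch offset, miss count}) are defined once in `feature_schema()` and every
extractor's output length is asserted against it. Two quirks are worth
recording: the group sizes total 238 *without* any speech group, so speech
features live on a separate analysis path (the sequence and scattering
classifiers), and the SAGE group is 10 wide for 9 scored tasks, which the
package resolves by splitting T8 into a similarities subscore and a
combined calculation subscore. Missing tasks produce `NA` groups that
`impute_features()` fills with per-column medians and flags with one
indicator column per affected group.

## Classification layer

Base learners sit behind one contract — `predict_proba()` returns
per-class probabilities summing to 1 — and delegate to the established
implementations where one exists (libsvm kernels, kernlab's SMO, random
forest, rpart stumps/trees, nnet MLP, MASS LDA). Learners without a
suitable installed implementation are authored here with calibrated
probability outputs: kNN vote fractions, distance-weighted LWL, Gaussian
naive Bayes (the "Bayes net" entry uses this simplest network structure),
Fisher's discriminant with 1-D Gaussian class conditionals, voted
perceptron, SGD logistic regression, and a logistic-model-tree (shallow
partition with per-leaf logistic fits).

**AdaBoost.M1** follows the textbook procedure: uniform weights, weighted
error \(\varepsilon\), stop at \(\varepsilon = 0\) (keep the single
perfect model) or \(\varepsilon \ge 0.5\), reweight correct instances by
\(\beta = \varepsilon / (1 - \varepsilon)\), vote weight
\(\log 1/\beta\). Learners that cannot take case weights are fitted on
weighted resamples. The one-round arithmetic is exposed as
`adaboost_weight_update()` so the update can be checked on paper.

**The hybrid ensemble** (`hybrid13_config()`) contains exactly 13 members —
seven AdaBoost.M1-wrapped learners (decision stump, random forest, MLP,
SMO, kNN, LWL, Bayes net), a sigmoid SVM + PCA, two linear SVMs + PCA,
FLDA, a recurrent neural learner, and a voted perceptron + PCA — fused by
the average of probabilities; majority voting is also implemented. Exact
probability ties go to class 0 (healthy), the conservative screening
default. The PCA preprocessor keeps the minimal leading components
reaching 95% explained variance by default.

**The recurrent sequence classifier** deserves its own note. The published
configuration ("two fully connected layers with 100 neurons each, followed
by softmax; RMSProp, max 10 epochs, batch 128, shuffling, piecewise
learning-rate drop 0.1") is ambiguous about where the recurrence sits, and
no deep-learning framework is available to this package. The
implementation encodes each sequence with a fixed bidirectional tanh
recurrent layer (orthogonal recurrent weights scaled to spectral radius
0.9, 100 units per direction, summarized by the final, time-averaged and
time-dispersion states of each direction — the dispersion pooling is what
carries jitter-like temporal-variability cues through the fixed encoder)
and trains exactly the quoted readout — two
fully connected layers and a softmax — by RMSProp with the quoted
schedule, plus early stopping with patience 3. This keeps the trainable
part faithful to the stated architecture while the recurrent encoding
stays deterministic per seed. It is a reservoir-style interpretation, not
a gated LSTM, and is documented as such.

**Metrics.** `evaluate()` reports confusion counts, accuracy, support-
weighted one-vs-rest TPR/TNR/precision/F1, Cohen's kappa (marginal-product
expected agreement), MCC from the 2×2 table, trapezoid ROC and
precision-recall AUCs, and the probability-error family (MAE/RMSE over
per-class probability residuals; RAE/RRSE in percent relative to the
class-prior constant predictor — the common toolkit semantics). The
support-weighted aggregation is the one that reproduces a published
confusion table's derived values exactly, which the acceptance tests
verify against the printed integrated-model row (77/2/47/3) and the speech
model counts (20/13/0/2).

**Validation protocols.** Stratified k-fold cross-validation pools
held-out predictions (deterministic per seed; folds are re-split if a
class goes missing). The leave-subjects-out split removes all records of
the held-out subjects from training and reports per-test-set error counts
and mean prediction confidence, so no subject straddles training and
testing. Feature selection offers correlation ranking, PCA by explained
variance, greedy best-first wrapper search, and a binary grey-wolf /
particle-swarm hybrid (sigmoid transfer, CV-accuracy fitness with a small
cardinality penalty) following its cited construction.

## The synthetic cohort

The study dataset (150 records, 15 subjects, 5 rounds) is not deposited,
so the generator emulates its shape: 89 healthy records from 8 subjects
and 61 impaired records from 7 subjects by default, rounds assigned
round-robin. Class-conditional effects are the package's modeling
choices, set once to values a movement-disorders reader would call
plausible and not revisited: tremor as a 4–8 Hz sinusoid in the stroke's
normal direction (amplitude 1 px healthy vs 6 px impaired) plus white
positional jitter; response latency +250 ms; per-character typo rate 0.02
vs 0.15; graph-task error rate 0.03 vs 0.25; voice jitter 0.5% vs 2.5%,
shimmer 3% vs 8%, HNR 25 vs 12 dB; and a −500 kcal daily calorie-balance
shift for the impaired class (the negative energy balance typical of
hypermetabolic CNS disease). `effect_scale` interpolates every effect
toward the healthy value; scale 0 produces two statistically identical
classes and is the null-calibration setting used to verify the pipeline
cannot separate label noise. Every generator is a pure function of
(parameters, seed).

What passing tests show — and what they do not: the synthetic cohort
establishes that the pipeline is wired correctly (large planted effects
are recovered; zero effects score at chance), not that the classifier
reaches any particular accuracy on real patients. Real tremor is not a
stationary sinusoid, real typos are not uniform character noise, real
session-to-session correlation within a subject is richer than a shared
parameter vector, and the synthetic voices are five-harmonic sources, not
dysarthric speech. Published dataset-specific accuracies are therefore
checked analytically (from their printed confusion counts), never
re-estimated from synthetic data.

## Numerical choices and degenerate inputs

Curves must be non-empty and finite; a single-point curve is legal for
matching but rejected for line fitting. Zero-length strokes produce zero
speeds rather than divisions by zero. The silence remover flags an
entirely silent clip, and downstream extractors reject empty clips with a
domain error. Probability outputs are floored/renormalized so rows sum to
1 within 1e-9; log-space computation prevents underflow in the
discriminant and naive Bayes learners. WAV output scales 16-bit samples by
32768 with clamping, keeping the round-trip error under \(2^{-15}\).
Seeds are explicit function arguments everywhere; internal per-purpose
seeds are derived deterministically and stay below \(2^{31}\).

Problem sizes used by the test-suite and acceptance runs are the package's
defaults: the full 150-record cohort for the separability and null runs,
10-fold cross-validation, 20 trials of planted-feature recovery on 80 × 55
data, and property checks on curves of at most 7 points where brute-force
enumeration is exact.

## Known limitations

The clock score remains semi-automatic; only its boundary-error counter is
computed. Speech features are speaker-sensitive (no speaker
normalization). The neighbor-matching similarity is strict, as discussed
above. The "Bayes net" and "LSTM" ensemble members are the documented
approximations described in this vignette. The BGWOPSO selector follows
its cited construction but is a search heuristic; its output depends on
the seed and the cardinality penalty.
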