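---
title: "Simulating federated learning across heterogeneous memory clinics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating federated learning across heterogeneous memory clinics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedcog)
```

## The problem

Speech-derived acoustic features (eGeMAPS-style pitch, jitter, shimmer,
loudness, spectral descriptors, extracted per task) carry signal about
cognitive impairment, but the labeled recordings live in individual memory
clinics and cannot be pooled. Federated learning (FL) sidesteps the data
sharing problem: each institution trains a classifier locally and only model
parameters are exchanged and aggregated. The open question `fedcog` is built
to study is *how institutional heterogeneity — unequal cohort sizes
(quantity skew) and unequal class mixes (label skew) — changes what FL buys
you* relative to each clinic training alone.

Because real multi-site speech cohorts are privacy-restricted, the package
simulates the entire design: a synthetic cohort generator with a known
Bayes-optimal AUC, a partitioner that splits one cohort into virtual
institutions, a class-weighted multilayer perceptron (MLP), two aggregation
operators (FedAvg, IDA), round-based orchestration, and a six-metric
evaluation panel. Every stage is seeded and reproducible.

## The classifier

The local model is a feed-forward MLP with an input unit per acoustic
feature (176 by default: two speech tasks times 88 descriptors), two ReLU
hidden layers of 20 units, and one sigmoid output unit giving the
probability that a participant is cognitively impaired (CI, the positive
class; cognitively unimpaired, CU, is the negative class).

Training is plain minibatch SGD: initial learning rate 0.01 decaying by a
factor 0.95 per epoch, batch size 32, 150 epochs, no dropout, batch
normalization or weight decay. The loss is binary cross-entropy with
per-class weights inversely proportional to class frequency and normalized
by 2,

$$ w_c = \frac{N}{2\,N_c}, $$

so a balanced sample gives unit weights and the (rare) CU class is
up-weighted at the ~10% prevalence the cohorts emulate. The weights are
computed once per node from its training labels and applied per sample in
every batch; recomputing them per batch is undefined for single-class
batches, which are common at batch size 32 and 10% prevalence.

Two interpretation choices the recipe leaves open:

* **Decay "per step" means per epoch.** Applied per batch, 0.95 per step
  collapses the learning rate to ~$10^{-16}$ within two epochs at $n
  \approx 800$; per epoch it leaves $0.01 \cdot 0.95^{149} \approx
  4.7\cdot10^{-6}$ at the end of training, a conventional exponential
  schedule. Both are available via `training_config()`.
* **Features are z-standardized** with training-set statistics fitted per
  node (raw acoustic descriptors differ by orders of magnitude across
  features, and SGD without standardization is hopeless). In federated mode
  each client uses its own training statistics; under covariate shift this
  means clients see differently calibrated inputs — a realistic artifact of
  institution-local preprocessing, and a known caveat when interpreting
  cross-site results.

Initialization (unspecified in the recipe) is Glorot-uniform weights,
$U(\pm\sqrt{6/(f_{in}+f_{out})})$, with zero biases. Backpropagation is
implemented explicitly over the parameter tree so that aggregation operates
on the same object training does; its gradients are tested against central
finite differences at relative error $10^{-4}$.

## Aggregation

Two operators, both entrywise over the flattened parameter tree (weights
and biases):

**FedAvg** weights each client by its training-sample count:
$$ w_{t+1} = \sum_{k=1}^{K} \frac{n_k}{n}\, w_k^{t+1}, \qquad n = \sum_k n_k .$$

**IDA** (inverse-distance aggregation) weights each client inversely to its
$\ell_1$ distance from the unweighted average model $\bar w_t$:
$$ \alpha_k = \frac{1}{Z}\,\bigl(\lVert \bar w_t - w_k^t \rVert_1 + \varepsilon\bigr)^{-1},
\qquad w_{t+1} = \sum_k \alpha_k w_k^{t+1}, $$
with $Z$ normalizing $\sum_k \alpha_k = 1$ and $\varepsilon$ (default
$10^{-8}$; only its sign matters short of exact ties) guarding the division.
Outlying updates are damped rather than amplified.

A consequence worth stating plainly: **with exactly two clients IDA always
reduces to the unweighted mean**, because both clients are equidistant from
their midpoint. In the two-institution design this makes IDA a
quantity-skew equalizer — the 10%-sized node gets weight 0.5 instead of the
0.1 FedAvg gives it — which is precisely why it is the default aggregator
for the heterogeneity experiments here. A plain-mean aggregator is included
as the baseline both operators degenerate to. The $\ell_1$ distance is
computed over all parameters, biases included.

## Round structure

The number of communication rounds is a free design parameter; `fedcog`
defaults to 150 rounds of 1 local epoch each, preserving the 150-epoch local
budget while aggregating as often as possible (the classical FedAvg
reading). The learning-rate schedule is *global*: it decays with the
cumulative epoch count across rounds, so the local and federated conditions
experience identical learning-rate trajectories and differ only in
aggregation. After the final round the single global model is evaluated on
every node's test set; the individual condition instead trains one model per
node and cross-evaluates each on both nodes' test sets.

## The synthetic cohort

`generate_cohort()` draws class-conditional Gaussians with identity
covariance: non-informative features are standard normal in both classes;
each of `n_informative` features is shifted by `effect_size` standard
deviations in the CI class. This form was chosen because it has a
closed-form Bayes-optimal AUC,
$$ \mathrm{AUC}^\ast = \Phi\!\left(\frac{d\sqrt{m}}{\sqrt{2}}\right), $$
for effect size $d$ on $m$ independent informative features — an analytic
ceiling every trained model can be tested against
(`bayes_auc()`, `effect_size_for_auc()`).

Defaults are the study conditions: 176 features, CU prevalence 0.099
(realized as the exact quota `round(n * 0.099)`, so a 2,239-participant
cohort has 222 CU cases), and 10 informative features at the effect size
giving Bayes AUC 0.90 ($d \approx 0.573$) — a class separation comparable
to a good acoustic biomarker panel, deliberately far from trivially
separable. Optional label noise flips labels only (keeping the Bayes oracle
valid at noise 0), and an optional site shift adds a constant offset to one
half of the cohort to emulate covariate shift.

What the generator does *not* emulate: correlation between acoustic
descriptors (real eGeMAPS blocks are strongly correlated), heavy tails,
age/sex confounding, or site-specific label definitions. Passing tests
therefore demonstrate that the machinery behaves as specified under a
controlled, favorable generative model — not that the classifier would
reach any particular performance on clinical recordings.

## Scenarios and the partition arithmetic

Three two-institution presets stress different axes of heterogeneity:

| preset | node shares | target CI shares | stress |
|---|---|---|---|
| `scenario1` | 50% / 50% | 90% / 90% | none (control) |
| `scenario2` | 10% / 90% | 90% / 90% | quantity skew |
| `scenario3` | ~62% / ~38% | 97% / ~79% | label skew |

Node sizes follow a floor convention (`floor(fraction * N)` for all nodes
but the last, which takes the remainder): at $N = 2{,}239$ this yields
(1,119, 1,120) and (223, 2,016) for scenarios 1 and 2. Each node is split
70/30 with `floor(0.7 n)` training rows, stratified by class via
largest-remainder allocation — giving (783, 336), (784, 336), (156, 67) and
(1,411, 605). Stratification matters in scenario 3, where the CI-heavy node
would otherwise risk losing all its CU test cases.

Class allocation is quota-based for every node but the last, which receives
the remainder of each class pool. The alternative — rounding every node's
class count independently — is infeasible: at 9.9% prevalence the quotas of
scenario 1 alone would demand 224 CU cases of the 222 that exist. The
remainder rule is the only allocation consistent with an exhaustive
partition, and it lands the realized compositions within a fraction of a
percent of the targets (scenario 3's second node realizes 78.7% CI against
the 78% target). Scenario 3's published-style counts are internally
inconsistent (its percentages sum to 104%); the preset takes the first
node's total (1,395 of 2,239) as canonical and gives the second node the
remaining 844. No quantitative claim in the package rests on scenario-3
counts.

## Evaluation

CI is the positive class throughout. The panel is balanced accuracy
(arithmetic mean of sensitivity and specificity), precision, sensitivity,
specificity, F1 and AUC, computed from a confusion matrix at a fixed 0.5
probability threshold (configurable; nothing in the training recipe
calibrates the threshold). AUC uses the rank-based Mann–Whitney form with
midranks, so ties contribute 1/2; it is checked in the tests against an
exhaustive pairwise oracle and against an independent ROC implementation.
Ratios with empty denominators (e.g. precision when nothing is predicted
positive) are reported as `NA` and flagged, never coerced to 0.

## Numerical and degenerate-input choices

* Probabilities are clamped to $[10^{-12}, 1 - 10^{-12}]$ inside the loss;
  gradients use the exact sigmoid-BCE cancellation so no clamping enters
  backpropagation.
* Zero-variance feature columns get scale 1 in the standardizer.
* Non-finite training losses or aggregated parameters abort with the epoch
  or round named.
* A node whose training set has one class fails alone (class weights are
  undefined there); other nodes proceed.
* A 70/30 split that strands a class entirely in train or test warns but
  proceeds — class weights make training possible either way.
* Seeds: every stage (generation, partition, per-epoch shuffles, weight
  initialization) is independently seeded; `run_experiment()` derives stage
  seeds from one master seed as `(master + 10007 * stage) mod (2^31 - 1)`.

## Problem sizes used by the test suite

The stochastic end-to-end properties are exercised at the full cohort size
(2,239 participants) but with reduced optimization budgets chosen as a
deliberate compromise: the quantity-skew rescue experiment uses 50 rounds
of 1 local epoch against a 150-epoch local baseline over 10 master seeds,
and the null-signal control uses 50 local epochs / 50 rounds over 5 seeds,
asserting the seed-averaged test AUC of every condition stays in
[0.40, 0.60]. The averaging is deliberate: a single 336-sample test set has
a null-AUC standard deviation of about 0.053, so per-draw bands this narrow
would fail by chance alone about once in four suites; the 5-seed mean has
standard deviation ~0.024.

## Known limitations

* Two-client IDA is indistinguishable from the plain mean, so with $K = 2$
  "IDA vs FedAvg" is really "uniform vs sample-size weighting".
* One simulated cohort partitioned in software is not multi-site data:
  device, protocol, language and annotation heterogeneity are all absent
  (site covariate shift can be injected, but only as a mean offset).
* The generator's independent-Gaussian features make the learning problem
  harder than correlated real features at matched Bayes AUC (no redundancy
  to exploit), so absolute metric values here should not be compared to
  clinical studies — only the *contrasts* between conditions are
  meaningful.
* Single-process simulation: no transport, stragglers, dropout or
  asynchrony, and no privacy mechanisms (secure aggregation, differential
  privacy) — parameters are exchanged in the clear inside one R session.
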