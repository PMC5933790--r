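---
title: "Routine and agitation analytics for in-home dementia monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Routine and agitation analytics for in-home dementia monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homewatch)
```

`homewatch` implements the analytics of an ambient in-home monitoring
deployment for people living with dementia: a small set of passive sensors
(PIR and motion detectors, pressure mats, a door contact, a mains energy
monitor) plus twice-daily self-recorded vitals. Two detectors run on that
stream at different temporal scales:

* the **macro track** models the *daily routine* as a Markov chain over
  discretised activity states and flags days whose entropy rate leaves
  deviation boundaries learned from a verification period;
* the **micro track** detects **AIA** (agitation, irritation, aggression)
  at the hourly scale by fusing three sensing groups — physiological
  threshold scores (G1), a participant-specific hidden Markov model over
  the chair/bed/bedroom-door sensors (G2) and a multi-occupancy HMM over
  the living-room/hallway/kitchen sensors (G3) — with reliability weights
  learned by cross-validation.

Real deployment data of this kind is not publicly deposited, so the package
ships a synthetic-data simulator with known ground truth; every claim the
package makes about its detectors is a claim about behaviour under that
simulator, a point this vignette returns to at the end.

# The macro model

## Pre-processing

Events are summed over 10-minute half-open slots, so a day is a
$24 \times 6 = 144$-slot window and each slot is an $n$-vector over the $n$
active sensors. Per-sensor activity is min-max scaled onto $[0, 10]$ with
the scaling learned on the training partition only and then frozen; test
values beyond the training range are clipped. Missing slots are zero
activity, not missing values — data loss is one of the anomaly sources the
detector is supposed to see, so it must not be imputed away.

Two K-means stages follow, both seeded, with 10 restarts, and both frozen
after training. The first clusters whole days ($144 \cdot n$ vectors) into
a low-active category D1 and a high-active category D2, ordered by total
activity; people behave differently on days spent mostly at home, so each
category gets its own chain. The second maps each slot vector to one of
`n_states` discrete states (default: the number of sensors), giving each
day a length-144 state sequence. New days are assigned by nearest centroid
with ties broken toward the lowest index.

## Entropy rate and deviation boundaries

For a fitted chain with occupancy $P_\alpha$ and transition matrix
$P_{\alpha\beta}$,

$$\epsilon = -\sum_{\alpha\beta} P_{\alpha\beta}\log P_{\alpha\beta},
\qquad
\xi = -\sum_{\alpha\beta} P_\alpha P_{\alpha\beta}\log P_{\alpha\beta},$$

in nats ($0\log 0 := 0$; the natural log only rescales all quantities
consistently). The entropy rate $\xi$ weights each row's transition entropy
by how often the state is occupied, so unlike $\epsilon$ it distinguishes
$\alpha\to\beta$ from $\beta\to\alpha$ traffic when the two states are
unequally occupied. Two useful bounds, both tested: $\xi \le \epsilon$ and
$\xi \le \log|S|$.

Transition probabilities are count ratios over within-day consecutive
pairs; chains never cross midnight, because the day is the unit of
analysis. The training chain of each category gives $\xi_T$; each
verification day $i$ gives $\xi_i$, and

$$\sigma = \sqrt{\tfrac{1}{v}\sum_i (\xi_i - \xi_T)^2}, \qquad
\Delta = \xi_T \pm \mu\sigma,$$

with confidence coefficient $\mu = 2$ by default (about 95% coverage under
normality; configurable). A test day is assigned a category, discretised
with the frozen codebook, scored, and flagged when its entropy rate leaves
$\Delta$. Flagging is two-sided by default: away days collapse the
sequence into near-constant states and push $\xi$ far *below* the band,
while visitors and agitation push it up; the literal one-sided rule
($\xi > \Delta$) is available as `mode = "upper"`.

## How a day is scored: two readings of "entropy rate for each day"

Scoring a single day admits two readings, and the package implements both
(`day_entropy_rate()`):

* **own** — the entropy rate of the day's own fitted chain. This measures
  *internal regularity only*: a visitor day full of unusual midday
  movement is internally quite regular, and in simulation this statistic
  detects essentially no visitor days.
* **cross** (default) — the day's empirical occupancy and transitions
  scored under the *trained* matrix,
  $-\sum \hat P_\alpha \hat P_{\alpha\beta} \log T_{\alpha\beta}$. This is
  a direct measure of deviation from the learned routine, which is what
  the detector is for. Transitions never seen in training would give an
  infinite penalty, so the trained matrix is mixed with a uniform
  component of weight 0.01 — large enough to keep a single novel
  transition among 143 from dominating a day's score, small enough that a
  day full of novel transitions stands far outside the band. When the day
  matches the model exactly the cross score reduces to the model's own
  entropy rate, so centring the band at $\xi_T$ remains coherent.

## Evaluation

Weekly sensitivity labels a week anomalous when at least 2 of its days are
flagged (the week-level rule is otherwise undefined; 2 tolerates a single
false-positive day) and reports the fraction of labelled weeks that
contain a true anomaly. Across participants, the correlation between
detected-anomaly counts and validated-notification counts is Pearson's $r$
after min-max normalising both series.

## What the macro detector can and cannot see

The simulation study (60 training, 14 verification, 60 test days, ten
anomalous test days, $\mu = 2$, 20 seeds — the problem sizes used
throughout the tests) gives a consistent picture:

* **Away days are detected essentially always.** They are structural
  anomalies: the state sequence collapses.
* **Visitor days are detected roughly half the time and agitation days
  less.** These are largely *magnitude* anomalies on sensors that are
  already active, and three mechanisms mask them: K-means quantisation
  maps an unusually intense slot to the same centroid as an ordinarily
  busy one, so the state sequence barely changes; nearest-centroid
  category routing assigns an anomalous day to the category it most
  resembles, comparing it against the most forgiving band; and a day
  contributes only 143 transitions, so normal-day entropy rates scatter
  with a standard deviation comparable to the anomaly shift, while
  $\sigma$ itself is estimated from only ~7 verification days per
  category.

This is a property of the method, not of a particular tuning: it persisted
across both per-day scoring methods, smoothing weights, state-space sizes
and event-rate regimes. It is also exactly the motivation for the micro
track, which sees magnitude anomalies directly through per-sensor hourly
thresholds. The day-level operating point at $\mu = 2$ is roughly 55%
sensitivity at a 10% false-positive rate under these conditions; at the
weekly scale — the scale the deployment actually reports at — labelled
weeks are validated at ~90%.

# The micro model

## Decision layer I

**G1.** Each vital with clinician-set thresholds $(T_L, T_H)$ contributes
one increment to the expert decision score $D_{CS}$ when the observation is
strictly outside (a value exactly on a threshold is in range; the same
strict-outside convention is used everywhere). The score is divided by the
number of vitals in the physiological group — blood pressure (systolic,
diastolic), heart rate, body temperature — to give a class probability.
Weight and hydration are monitored but are not agitation-scoring vitals.
Shipped default thresholds (90–160 / 60–100 mmHg, 50–110 bpm,
36.0–37.8 °C) are package defaults meant to be overridden per deployment.

**G2/G3.** Hourly per-sensor aggregates $P_x$ are labelled normal or
abnormal against per-sensor bounds learned from training data by the
adjusted box-plot: with quartiles $Q_1, Q_3$ and medcouple $MC$,

$$[\,Q_1 - 1.5\,e^{-4MC}\,\mathrm{IQR},\; Q_3 + 1.5\,e^{3MC}\,\mathrm{IQR}\,]
\quad (MC \ge 0),$$

and with $-3/ -4$ swapped in the exponents for $MC < 0$. The medcouple is
the median of the kernel $h(x_i, x_j) = ((x_j - m) - (m - x_i))/(x_j - x_i)$
over pairs straddling the median — a robust skewness measure that widens
the fence on the long-tail side, which matters because hourly activity
counts are strongly right-skewed. The $O(n^2)$ kernel evaluation is used
directly; training samples are a few thousand points at most. Quartiles use
linear interpolation (type 7), configurable.

Each sensor's label pair is globally unique, so the per-hour concatenation
of a group's labels (fixed sensor order) is a composite symbol that decodes
uniquely back to per-sensor labels. MAD-based flagging
($|x - \mathrm{med}| > k\,\mathrm{MAD}/0.6745$, $k = 3$) is provided to
seed candidate event flags from training data, mirroring how deployments
bootstrap annotation.

## Decision layer II

Each group's hourly symbol sequence feeds a 2-state (AIA/normal)
discrete-emission HMM $\lambda = \{T, B, \pi\}$. Forward, forward–backward
and Viterbi are implemented in log space (a linear-space forward exists as
an independent numerical route and the two are required to agree to 1e-9
on day-length sequences); all three are tested against exhaustive-path
enumeration on small instances. Viterbi ties break toward "normal", the
same bias against false alarms used everywhere.

Parameters are estimated by supervised additive-smoothed counting from
labelled sequences (the simulator's ground truth stands in for the
clinician-generated seed data such a deployment would use); a hook accepts
expert-specified matrices directly. Baum–Welch refinement is deliberately
not implemented: supervised seeding is the deployment's path, and
unsupervised refitting could drift the hidden states away from their
clinical meaning.

A window's group score is the **maximum** per-hour posterior P(AIA) over
the window (default window: one day). The maximum, not the mean: episodes
last a few hours, so a day-level mean is bounded by the episode-to-day
ratio (≈ 4/24) and can never cross the argmax threshold, which silently
breaks the downstream reliability learning — a failure mode we observed
directly. The mean remains available for windows matched to episode
length.

## Decision fusion

Group precisions per class, $p_i = TP_i/(TP_i + FP_i)$ with the group's
hard prediction being its argmax class, are estimated by stratified 10-fold
cross-validation (fold-averaged, deterministic given the seed) and
normalised *within each group over classes* into reliability scores
$Rs_{ij} = p_{ij}/\sum_i p_{ij}$. The fused score for class $i$ is
$\sum_j Rs_{ij} P_j(i)$, the label its argmax (ties toward normal); a
missing group — participants do skip vitals — is omitted with its weight
renormalised over the remaining groups.

One consequence of the within-group normalisation deserves a warning:
because each *group's* column sums to 1, a group that is informative for
neither class still carries full weight, landing entirely in the row of
the class it happens to predict. With a deliberately uninformative G3 the
normal row collects nearly all of G3's weight, and the fused *label*
skews toward normal even when the fused *score* ranks days almost
perfectly (the reported weighted precision/recall of the label reflect
this). Ranking metrics (AUC) are unaffected, and this is the behaviour of
the published weighting scheme rather than a defect we chose to repair.

Under the reference micro scenario (60 training days with 12 seeded
agitation days, 120 test days with 30 agitation and 15 visitor days,
physiological excursions on about half the episodes), fusion delivers what
it promises: mean AUCs over 20 seeds are ≈ 0.73 (G1, weakly informative),
≈ 0.91 (G2), ≈ 0.47 (G3, noise plus visitor confounds) and ≈ 0.96 fused —
the fused model beats the best single group in essentially every seed.

# The simulator

Event sensors are independent inhomogeneous Poisson processes with
piecewise-constant hourly rates encoding a plausible single-occupant
routine (hallway transit 08:00–11:00, living-room evening 20:00–22:00,
kitchen meal peaks, bed pressure at night). Rates are tens of events per
hour in occupied rooms — PIR and motion sensors re-trigger every one to
three minutes under occupancy — and near zero otherwise; the door contact
is genuinely rare. A Bernoulli high/low day mixture (p = 0.5, rate
multipliers 1.3/0.7) models day-to-day variability. The energy monitor
emits one continuous hourly reading (baseline + activity-proportional term
+ Gaussian noise) rather than events, and participates in the macro grid
like any other sensor (excludable via the sensor index).

Scheduled departures from routine, with ground-truth labels:

* **visitor days** — the multi-occupancy (G3) sensors are multiplied by 3
  within a visit window, 10:00–16:00 by default: visits are a daytime,
  hours-long phenomenon whose signature is concentrated midday movement,
  not a uniform 24-hour inflation;
* **away days** — all non-energy rates × 0.02 (the home is empty but
  appliances still draw power);
* **AIA episodes** — participant-proximal (G2) rates × 5 over the episode
  hours (13:00–17:00 by default), optionally with a physiological
  excursion that pushes systolic, diastolic and heart rate above their
  upper thresholds (sympathetic arousal elevates blood pressure and pulse
  together) on both of the day's readings;
* **dropout** — a named sensor emits exactly nothing over a day range.

Vitals are drawn truncated strictly inside their thresholds on ordinary
days, twice daily at 08:00 and 20:00. Identical profile, schedule, horizon
and seed give byte-identical output; every stochastic stage derives its
seed from one master seed.

**What the simulator does not emulate** — and hence what passing tests do
not demonstrate about real homes: sensor noise other than loss (no false
firings, no clock drift), correlated multi-sensor artefacts, seasonal and
weekday structure, behavioural drift from disease progression, visitor
patterns other than a rate change, and annotation noise in the ground
truth (labels are exact by construction). Results on real deployments
depend on exactly these, so the simulation numbers above should be read as
validation of the *implementation*, not as clinical performance claims.

# Numerical and design choices

* Natural logarithms throughout; $0 \log 0 := 0$; unobserved transition
  rows are all-zero and contribute nothing.
* K-means: seeded, `nstart = 10`, ties toward the lowest centroid index;
  degenerate inputs (all days identical) collapse to one category with a
  warning rather than an error.
* Min–max normalisation with clipping; a constant sensor maps to zero with
  a warning. A percentile-based robust variant is exposed (`probs`).
* The inclusion filter reads "reporting continuously for three months" as
  ≥ 90% of days with at least one event per sensor over the trailing
  90-day window, tolerating the brief outages real deployments show.
* Strict-outside threshold convention everywhere (clinical thresholds,
  box-plot bounds, MAD).
* MAD uses the 0.6745 normal-consistency constant and $k = 3$.
* HMM smoothing: additive pseudo-count 1.0 by default; zero-smoothing fits
  guard fully unobserved rows with a uniform fallback.
* Stratified folds are dealt round-robin within class after a seeded
  shuffle; when the smaller class cannot populate every fold, k is reduced
  with a warning.
* Seeds: one master seed per run; stage seeds derived through a fixed
  affine map kept below $2^{31}$.

# Known limitations

* Day-level macro sensitivity for magnitude-type anomalies is modest (see
  above); the weekly aggregate is the reliable unit.
* The fused label inherits the reliability-weighting pathology for
  strongly one-sided groups; use the fused score when a ranking suffices.
* Static clinical thresholds; per-home personalisation is supported only
  via override files.
* The macro track deliberately does not classify anomaly causes
  (technical vs visitor vs clinical) — that distinction requires the
  complementary information a monitoring team holds.
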