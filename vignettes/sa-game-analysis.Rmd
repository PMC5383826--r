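---
title: "Modelling and analysing a situation-awareness video game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and analysing a situation-awareness video game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sagame)
```

## The task being modelled

`sagame` analyses a SAGAT-style hazard-perception game for cyclists. A
player watches short first-person cycling videos; each video is suddenly
masked and two or three screen locations are highlighted. The player must
select exactly those locations that held a *hazard* at the moment of
masking — either an **overt** hazard (a visible road user on a potentially
intersecting path) or a **covert** one (an occluder, such as a bus stop or
building corner, from behind which someone could emerge). The remaining
locations are empty. Points reward hits (+5), punish misses (−5), mildly
reward correct rejections (+1), and ignore false alarms (0); the on-screen
total never drops below zero.

The package provides, as separately testable stages: a synthetic stimulus
bank, a generative observer model, the game's scoring rules, the
performance measures (signal-detection and working-memory scores), dynamic
area-of-interest gaze statistics, and the inferential toolkit, orchestrated
by `run_study()`.

Because the original participants and video footage are not modelled, every
claim the package can check is either *structural* (composition of the
stimulus bank, arithmetic of scoring) or *statistical* (parameter recovery,
directional group differences under generative profiles seeded from the
published group means). Passing tests show that the estimators recover the
generative model's parameters and reproduce the published orderings under
that model — not that the model captures every property of real players.

## The stimulus bank

The default bank mirrors the study conditions: 30 game clips probing 79
locations — 33 overt, 12 covert, 34 empty — plus 3 practice clips. Three
structural constraints are honoured by construction and re-checked by
`validate_bank()`:

* every clip probes 2 or 3 locations;
* every game clip holds one or two targets, and a three-location clip never
  holds three;
* among two-location game clips, clips with one target outnumber clips with
  two.

With 79 locations over 30 clips, exactly 19 clips probe three locations and
11 probe two; the generator samples the number of two-target two-location
clips uniformly from its feasible range (0–5) and derives the rest. Game
clip durations are drawn from a normal distribution truncated to
[4.81, 24.19] s and then recentred so their mean is *exactly* 11.47 s
(deviations are shrunk, never shifted past the bounds), so a full game
always shows 344.1 s ≈ 5 min 44 s of video. Probe circles live in
normalized screen coordinates (origin top-left), decoupling the analysis
from any physical display size.

The published composition is attributed to the game clips only; the three
practice clips get a fixed composition (overt+empty, covert+empty,
overt+covert). Practice clips are played and scored but excluded from all
analyses.

## The observer model

Responses follow equal-variance signal detection theory. For each probed
location the observer draws evidence from N(0, 1) if the location is empty
and N(d′, 1) if it holds a target (overt and covert targets are not
distinguished, matching how the analyses collapse them), and selects the
location when the evidence exceeds a criterion λ. Learning is phase-wise:
d′ and λ are constant within each third of the participant's own randomized
clip order (positions 1–10, 11–20, 21–30) and d′ never decreases across
phases. The default profiles take their per-phase d′ and criterion values
from the published per-phase group means (children 0.88/1.06/1.43, adults
1.74/1.82/2.04 for d′). Clip response times are lognormal with
phase-dependent means (4.82 s → 3.47 s, linearly interpolated in the middle
phase), consistent with the published start/end means; the lognormal shape
(0.4) is a modelling choice. A `lapse_rate` (default 0) can replace
selections with fair coin flips to stress-test estimator robustness.

Between-subject heterogeneity is Gaussian jitter on d′ (one shared offset
across phases, preserving monotone learning), on the criterion, and on the
probability of looking at a gaze target. The published between-subject
standard deviations (≈0.7 for d′, ≈0.5 for the criterion, 0.16–0.21 for
the looking proportion) include the estimation noise from the finite
location counts (about 0.45 sd for d′ estimated from 26-location windows,
0.15 for a 10-target looking proportion), so using them directly as
generative sds would double-count that noise. The defaults (0.5, 0.4, 0.1)
are chosen so that the *measured* spread approximates the published one.

The counting-span generator runs the published schedule — set sizes 2
through 8, three trials each, at most 105 tallies — and recalls each tally
correctly with probability 1 − noise up to `wm_capacity`, degrading by
`overload_penalty` (default 0.2) per item beyond capacity. The task stops
after three consecutive trials with *no* correct tally. With independent
per-tally errors, stopping on any-error trials would paradoxically raise
low-capacity observers' scores (they would stop before the hard trials
while scoring partial credit on easy ones), so the full-failure rule is
used as the generative convention. Defaults (capacity 2 for children, 6
for adults, noise 0.05) produce the right group ordering; the model is
deliberately coarse and is not calibrated to reproduce the published PCU
means exactly.

The gaze generator is likewise deliberately simple: no saccade kinematics,
no smooth pursuit. With probability `p_look` a trace makes a Poisson
(min 1) number of entries into the target's AOI, the first a lognormal
latency after the target becomes identifiable, each dwelling a lognormal
time; otherwise a centre-biased random walk stays outside the AOI. Its only
job is to exercise glance detection and support parameter recovery.
Per-glance dwell defaults are the published per-target total dwell divided
by the published glance frequency, so the recovered totals land near the
published values.

## Performance measures

Let *h* and *f* be the hit and false-alarm rates. The log-linear rule is
applied unconditionally before any quantile transform: 0.5 is added to the
hit and false-alarm counts and 1 to the signal and noise trial counts, so
corrected rates are always interior.

* **Sensitivity**: d′ = Φ⁻¹(h) − Φ⁻¹(f).
* **Observed criterion**: λ_obs = −Φ⁻¹(f), measured from the noise-
  distribution mean. The negation matters: a liberal group with a 41%
  false-alarm rate must sit at a small *positive* criterion (+0.23), which
  is how the published group tables read. This sign convention is used
  everywhere in the package.
* **Optimal criterion**: λ_opt = d′/2 − logit(s)/d′, where s is the
  prevalence of targets among probed locations. With the default bank
  s = 45/79 > 0.5, so the accuracy-maximizing criterion shifts liberal.
  Prevalence is computed from the *realized* locations in each
  participant's window: clip order is randomized per participant, so the
  phase composition (and hence λ_opt) genuinely varies across participants,
  which is consistent with the large between-subject spread the published
  per-phase criterion tables show. At exactly zero estimated d′ the optimal
  criterion is undefined; summaries report NA for λ_opt and bias in that
  case rather than failing.
* **Response bias** = λ_obs − λ_opt; negative values mean over-selecting.
* **Accuracy** is the uncorrected proportion correct; before regressions it
  is logit-transformed, with a log-linear-style shrink ((k+0.5)/(n+1))
  applied only when a participant is exactly at 0 or 1, consistent with the
  correction philosophy used for the rates.
* **PCU** (partial-credit unit) averages, over administered counting-span
  trials, the proportion of tallies recalled in the correct position.
  Trials never administered because of an early stop are excluded from the
  average, following the standard partial-credit definition.

## Gaze analysis

Ten target AOIs in distinct game clips, deliberately off-centre, are
analysed from the moment the target is first identifiable until the mask.
The published analysis never states an event criterion, so the package
fixes one: a **glance** is a maximal run of valid in-AOI samples lasting at
least 100 ms, after merging runs separated by gaps of at most 75 ms (both
configurable). Gap duration discounts one sample period, since the
interruption begins after the last in-AOI sample; invalid samples break
runs but count toward gaps. AOI circles are linearly interpolated between
keyframes. These conventions matter at the 10–30 Hz effective sampling
rates of a head-mounted tracker, where a single dropped sample can
otherwise split one glance in two.

Exclusions follow the published rules: participants with a mean nine-point
calibration error above 2° are dropped (a manual-inspection flag is also
honoured, as that exclusion is not algorithmic), and individual clips with
an effective sample rate below 5 Hz — computed as (n−1)/(t_last−t_first) —
are dropped. Exclusion is idempotent and fully logged.

The four summary statistics are the percentage of retained targets glanced
at least once and, over looked-at targets only, the mean glance count, the
mean first-glance latency from target appearance (glance *onset* is used),
and the mean total dwell.

## Inference

`welch_t()` wraps the Welch unequal-variances t-test and adds Cohen's d;
the pooled-sd variant is the default (the published effect sizes do not
identify the variant; an unpooled option is available). `mixed_anova()`
implements the split-plot decomposition for one between- and one
within-subject factor directly (balanced within, unequal group sizes
allowed), with partial η² = SS_effect/(SS_effect + SS_error) and the
Greenhouse–Geisser ε computed from the eigenvalues λᵢ of the
double-centred pooled within-group covariance, ε = (Σλᵢ)²/((k−1)Σλᵢ²),
clamped to [1/(k−1), 1]. Both uncorrected and GG-corrected within-effect
p-values are always reported; ε is exactly 1 for k = 2. The implementation
is cross-checked in the test suite against `stats::aov` (sums of squares,
F, p) and `car::Anova` (ε and corrected p).

Polynomial trend over the three phases uses the (−1, 0, +1) contrast
scored per participant and a one-sample t against zero (a per-contrast
error term); zero-variance contrast scores are flagged as degenerate
rather than tested. `ols_regression()` wraps `stats::lm`; `nested_f()`
computes the ΔR² F-test from the two fits' R² values (cross-checked
against `stats::anova`), and treats identical models as a zero-ΔR²
comparison. Two-sided tests at α = 0.05 throughout; no multiple-testing
correction is applied anywhere, matching the original analysis style.

## Seeding and determinism

Every public generator takes a seed; child streams (per participant, per
stage) are derived by a stable 32-bit FNV-1a hash of the root seed and a
purpose label, so adding a participant never reshuffles another's data.
RNG state is isolated with `withr::with_seed`, leaving the caller's stream
untouched. A `study_config()` plus seed reproduces a `run_study()` report
byte-for-byte.

## Problem sizes used in the test suite

The suite checks rate convergence on ~10,000 simulated locations,
parameter recovery on 300 simulated observers, directional reproduction of
the published group/phase orderings on 100 replicates of the full 36+22
cohort (requiring ≥95 successes), null calibration of the Welch t, nested
F and ANOVA group tests on 1,000 replicates each, and the formula chain
against a brute-force quantile-inversion oracle on 1,000 random confusion
matrices at 10⁻⁸. These sizes keep each property comfortably testable on a
single CPU while leaving Monte-Carlo margins well clear of the thresholds.

## Known limitations

* The generative model is stationary within phases; real players may adapt
  continuously, and criterion dynamics under feedback are not modelled.
* The gaze generator produces schematic traces; glance statistics recovered
  from it validate the detector, not human oculomotor behaviour.
* The counting-span recall model treats tallies as independent; serial
  position effects and rehearsal strategies are absent, so only orderings
  (not absolute PCU levels) should be compared with human data.
* Group-level published statistics (e.g. overall accuracies of 72% vs 83%)
  depend on the original raw data; the package reproduces their direction
  and approximate magnitude under the seeded generative model, not their
  exact values.
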