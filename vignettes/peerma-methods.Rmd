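---
title: "Methods: dyadic agreement statistics for EMA/PeerMA studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dyadic agreement statistics for EMA/PeerMA studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peerma)
```

## The problem

In a two-role experience-sampling protocol a participant answers brief
prompts about their momentary stress, fatigue, anxiety, and well-being
several times a day (EMA), while a designated peer — spouse, relative,
friend — answers the same questions *about the participant* (PeerMA),
adding a confidence rating to each report. The scientific question is the
degree of self–other agreement: does the peer track the participant's
states, their day-to-day changes, and their overall level? peerma
implements the full analysis path from the raw long-format response table
to the agreement statistics, plus a generative simulator that makes every
stage testable against known ground truth.

Two protocol presets are built in: a dense schedule (`study_a_config()`:
8 signal-contingent prompts/day, 9 AM–9 PM, adjacent prompts ≥ 45 min
apart, stress/fatigue/anxiety) and a sparse one (`study_b_config()`:
3 prompts/day, 8 AM–8 PM, ≥ 2 h apart, with a directly reported well-being
item in addition). Notification expiry is recorded in the configuration but
plays no computational role: an expired prompt is simply an unanswered one.

## Data conditioning

**Normalization.** People use response scales idiosyncratically, so values
are min–max rescaled *per person per state*:
$v' = (v - \min)/(\max - \min)$. Per-state grouping (rather than pooling a
person's states) was chosen because the states are distinct constructs
whose per-state summaries are reported separately; since the transform is
affine and order-preserving within each group, all rank-based statistics
downstream are unaffected by this choice. A person whose assessments of a
state are all identical carries no range information; the group maps to
0.5 with a warning — keeping it usable (and all-flat) for directional
analysis without fabricating extremes.

**Derived well-being.** $w = 1 - (s + f + a)/3$ on normalized values; high
stress, fatigue, or anxiety depresses well-being, making $w$ antitone in
each argument and confined to $[0, 1]$. It is evaluated per survey
instance — the set of states sharing one (person, timestamp) — and only
when all three states were answered; incomplete instances contribute
nothing, so the daily mean of computed well-being is a mean of
instance-level values, exactly like the raw states.

**Daily pairing.** Participants and peers answer different numbers of
prompts each day, so prompt-level pairing is impossible. Every dyad × state
is therefore reduced to a paired series of *daily means*; a day on which a
member gave no assessment carries a missing marker, never zero. All
correlation and equality tests operate on days where both members have a
value. This daily-mean pairing is the one genuinely open design decision in
the analysis — the alternative (pairing closest prompts in time) discards
data asymmetrically and was rejected.

**Imputation is cosmetic.** For plotting only, interior gaps of a daily
series can be filled by an order-4 (cubic) interpolating spline
(`spline_impute()`, delegating to `stats::splinefun(method = "fmm")`, whose
end conditions reproduce cubic polynomials exactly). Observed points are
reproduced exactly, imputed values are clipped to $[0, 1]$, and leading or
trailing gaps are never extrapolated. No statistic ever sees imputed
values.

**Confidence filtering.** Peers rate their confidence per assessment;
`filter_by_confidence()` can discard peer reports below a threshold (e.g.
the zero-labelled ones). The default threshold 0 keeps everything, because
dropping data is an analysis decision the user should make explicitly.

## Agreement statistics

**Mean directional accuracy.** A transition between consecutive days is
`up`, `down`, or `flat` (three-valued sign; changes below $\varepsilon =
10^{-9}$ count as flat, a pure float-noise guard — real daily means that
differ, differ by far more). A participant transition *matches* when the
peer's transition has the same sign; flat matches only flat. The
*same-or-next-day* window additionally credits a match when the peer's
following transition agrees — the behaviour of a peer who registers a
change one day late. MDA is matches over evaluable transitions, where
evaluable means the same-day comparison is defined (both members present on
both days); the evaluable set is deliberately identical for both windows,
which makes `mda(same_or_next_day) >= mda(same_day)` a theorem rather than
a tendency. Using evaluable transitions as denominator (not "days with
data") is the only computable reading of a per-transition statistic:
isolated days have no direction. Study-level summaries default to the mean
of per-dyad accuracies (each dyad one unit, matching how dyads are the
sampling unit); a pooled-transition mode is provided for comparison.

**Rank correlation.** `spearman_rank()` computes the tie-corrected
coefficient as the Pearson correlation of midranks, identical to
$1 - 6\sum d_i^2 / (n(n^2-1))$ when no ties exist (property-tested).
P-values are two-sided: for $n \le 9$ an exact permutation null over all
$n!$ pairings (valid under ties, and cross-checked against base R's exact
route on tie-free data); above that, the usual
$t = r\sqrt{(n-2)/(1-r^2)}$ approximation. Fewer than three complete pairs,
or a constant ranked vector, yield an explicitly undefined result rather
than a number.

**Strength bins.** Coefficients are rounded to two decimals — the
resolution at which such tables are reported — and classified into six
bins: highly/moderately/weakly positive and negative, with bounds
$[0.67, 1]$, $[0.34, 0.66]$, $[0, 0.33]$, $[-0.33, -0.01]$,
$[-0.66, -0.34]$, $[-1, -0.67]$. The bins partition $[-1, 1]$ on the
two-decimal grid; an exact zero is weakly positive, $-0.33$ is weakly
negative, and $-0.34$ moderately negative. Per-state percentages use the
state's count as denominator; the overall row uses all classified
coefficients. Percentages are rounded to integers.

**Statistical equality.** `wilcoxon_signed_rank()` tests the null that the
paired daily means share one distribution. Zero differences are dropped
(signed-rank convention); for $n \le 25$ without ties among $|d|$ the exact
null distribution is used, otherwise a normal approximation with tie
correction and continuity correction. Both branches are tested against an
exhaustive $2^n$ sign-flip oracle and against `stats::wilcox.test`. A dyad
is *statistically equal* for a state when the p-value, rounded to two
decimals, is at least $\alpha = .05$ — rounded-inclusive, so a reported
p = .05 counts as equal, which is the convention that makes published
two-decimal tables internally consistent. `equality_fraction()` turns
per-dyad verdicts into a per-state percentage; dyads absent from a table
(denominator larger than the p-value count) count as not equal. No
multiple-testing correction is applied anywhere: the analyses report raw
per-dyad p-values, and the equality fractions are descriptive.

**Residual metrics.** MAAPE, $\text{mean}(\arctan|{(a-f)/a}|)$, is the
preferred overall-difference measure because momentary-assessment daily
means can be exactly zero, where MAPE is undefined; the $a = 0$ term
contributes $\arctan(\infty) = \pi/2$ (or 0 when the prediction is also
exact). MAPE is provided for comparison only.

## The synthetic-study generator

The generator's job is to emulate the features of a two-role field study
that the pipeline must survive: signal-contingent schedules with a minimum
separation, per-role response rates, bounded autocorrelated states, a peer
who is a noisy, possibly biased, possibly lagged observer, and a
confidence rating tied to daily contact.

Per dyad and state, the participant's latent daily level follows a
mean-reverting AR(1) on the logit scale squashed through the logistic into
$(0, 1)$ — bounded, autocorrelated, and tunable, which is all the recovery
properties require; no claim is made that real affect dynamics are AR(1).
Prompt-level responses add small within-day noise. The peer's daily view is
$\rho\,L(d - \ell) + (1-\rho)\,L_{\perp}(d) + b$: a convex mixture of the
participant's (possibly lagged) latent state and an independent latent
series, plus bias, with observation noise at the prompt level. Prompt times
are drawn uniformly in the daily window and the whole day is redrawn until
the minimum separation holds, i.e. rejection sampling from the uniform
distribution conditioned on feasibility; infeasible configurations are
rejected at construction. Each prompt is answered independently with the
role's response rate (this is where notification expiry lives, implicitly).
Confidence is drawn from a high- or low-mean normal component according to
a daily contact Bernoulli, clipped to the scale.

Defaults are the dense-protocol study conditions: 20 dyads, 28 days,
8 prompts/day, response rates 0.65 (participants) and 0.44 (peers),
state means 0.4 on the unit scale, AR coefficient 0.5 with innovation SD
0.5 on the logit scale, coupling 0.7, no bias, no lag. Where the emulated
studies print no value (the AR parameters, noise SDs, confidence means)
the defaults were chosen once as values producing realistic-looking series
— day-to-day autocorrelation visible but far from unit-root, within-day
scatter small relative to between-day movement — and are not tuned
thereafter.

What the generator does *not* emulate: reactivity (self-reports changing
the state being reported), time-of-day effects within the daily window,
missingness correlated with state (a stressed peer skipping prompts), or
relationship-type heterogeneity. Passing recovery tests therefore shows the
*statistics* behave correctly on data with known structure — not that real
dyads satisfy the generative model.

## Numerical and testing choices

- Timestamps are timezone-naive local times at minute resolution; a "day"
  is the calendar date. Duplicate (person, state, timestamp) keys are
  rejected at read time.
- Exact-test regimes: permutation Spearman p for $n \le 9$ (the $n!$
  enumeration is instant there), exact signed-rank null for $n \le 25$
  tie-free. Both switch to standard approximations above, matching the
  sample sizes (≈ 2–5 weeks of daily means) these analyses meet.
- Reported statistics are rounded to two decimals and percentages to
  integers only at the summary layer; raw values are kept alongside.
- Recovery simulations in the test suite and acceptance script use 200
  dyads per condition (40 per point of the 9-point coupling sweep) on the
  sparse 3-prompt protocol over 28 days — sizes at which the Monte-Carlo
  error of mean MDA is below 0.01 while a full run stays in the minutes
  range. Chance-level behaviour of same-day MDA under zero coupling is
  asserted within 3 Monte-Carlo standard errors; lag detection
  (same-or-next-day > same-day under a one-day lag) uses noise SDs of 0.02
  and full response so the contrast isolates the lag mechanism.

## Known limitations

- The daily-mean pairing basis cannot be validated against prompt-level
  agreement, which is undefined when the two members answer different
  numbers of prompts.
- Profile correlations computed from two-decimal rounded medians can shift
  ranks relative to full-precision medians; recomputed coefficients may
  differ from full-precision ones by a few hundredths.
- Equality fractions treat a non-rejected Wilcoxon null as "statistically
  equal", which is evidence of absence only in the loose, descriptive sense
  such feasibility analyses use; the package reports the fraction, not an
  equivalence test.
- The simulator's independence assumptions (response and state, contact
  and state) are simplifications; agreement statistics under informative
  missingness are untested territory.
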