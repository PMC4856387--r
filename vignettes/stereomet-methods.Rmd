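---
title: "Methods: behavioural sequence, bias and stereotypy metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioural sequence, bias and stereotypy metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereomet)
```

`stereomet` computes the outcome measures of a mouse behavioural battery that
relates home-cage stereotypies to recurrent perseveration and cognitive
(judgement) bias. This vignette documents the models, the tunable parameters,
the numerical decisions, and what the synthetic-data generators do and do not
emulate.

## The adaptive guessing task

On each trial of the two-choice guessing task exactly one goal compartment is
baited. The probability of baiting the **right** compartment equals the
proportion of **left** responses in the subject's previous twenty trials; for
trials before the window fills, all previous trials are used, and the very
first trial (no history) baits either side with probability 0.5 — the only
symmetric choice. This negative feedback cancels any side bias: a subject
choosing right 90% of the time finds the right pot baited only ~10% of the
time. Reward is maximised, at 50% in expectation, by choosing both sides
equally often, whether randomly or by pattern; the *pattern* is what the
perseveration analysis detects.

Implementation decisions:

* The window is a sliding one: trials $t-20,\dots,t-1$ once $t > 20$, all
  previous trials otherwise (at $t = 20$ the two regimes coincide).
* The bait is drawn *before* the agent's choice, consuming exactly one
  uniform draw per trial, and is never visible to the agent — the same
  information structure as the live apparatus, where pots are baited
  pre-trial.
* Simulated sessions always run the configured `n_trials` (default 80);
  termination by session time or off-task behaviour is a husbandry event,
  not part of the computation.
* During shaping both pots are baited and a side chosen three times in
  succession is closed on the next trial (`shaping_block = TRUE` forces the
  agent to the open side); shaping sessions carry no baiting probabilities.

One consequence worth knowing: a strict alternator earns slightly *more*
than 50% during the first twenty trials, because on even trials the
all-previous-trials window of an alternating history is unbalanced by one
choice in the agent's favour (expected ≈ 41.1 rewards over 80 trials rather
than 40). From trial 21 on, the 20-trial window of an alternation is exactly
balanced and reward probability is exactly 1/2. Tests of the
"chance-reward" property therefore examine trials 21–80.

## The perseveration score

Recurrent perseveration — inappropriate repetition or patterning of
responses — is scored as sequential dependence of the choice sequence at
Markov order $k = 3$ (the default; `order` is exposed for sensitivity
analysis). For each three-choice context $c$ that occurs in the sequence,
let $n(c)$ be its occurrence count and $O(c, x)$ the count of choice
$x \in \{L, R\}$ following it. Expected counts under the null are

$$E(c, x) = n(c)\, \hat m(x),$$

where $\hat m(x)$ is the marginal proportion of choice $x$ over the whole
sequence. Using the marginal rather than 0.5 makes the null "sequential
independence *given* the animal's side bias": side bias and perseveration
are distinct outcome measures and must not contaminate one another. The sum
chi-square is

$$\chi^2 = \sum_{c,\,x:\,E(c,x)>0} \frac{(O(c,x) - E(c,x))^2}{E(c,x)},$$

with tail probability $p$ — the probability that the sequence is
sequentially independent. The score is $P = 1 - p$ and its logit,
$\mathrm{logit}[P] = \ln(P/(1-P))$, computed after clamping $P$ into
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-12}$ (a `clamped`
flag records when the clamp was active; $P \in \{0, 1\}$ occurs for
degenerate sequences).

**Degrees of freedom.** Cells with $E = 0$ are skipped and only contexts
that occur contribute. Each occurring context contributes one free cell
(the two next-choice counts sum to $n(c)$), and one further degree of
freedom is absorbed because $\hat m$ is estimated from the same sequence —
the classical correction when a fitted lower-order model supplies the
expectations. Hence

$$\mathrm{df} = \max(\#\{\text{occurring contexts}\} - 1,\ 1).$$

This choice is not cosmetic: with all eight contexts occurring the statistic
is compared to $\chi^2_7$, and in simulation (10,000 i.i.d. fair 80-trial
sequences) the empirical rejection rate at $\alpha = 0.05$ is ≈ 0.043 —
close to nominal, mildly conservative because the chi-square approximation
is imperfect at $n(c) \approx 10$. Without the correction ($\chi^2_8$) the
test rejects at only ≈ 0.024. A fully one-sided sequence has
$\chi^2 = 0$ and $p = 1$ by convention ($P = 0$: no evidence of sequential
dependence beyond its total side bias).

**Tetragrams.** The same choice string, with no burn-in discarded, is split
into overlapping four-choice windows (an $n$-trial sequence has $n-3$; 77
for $n = 80$, over $2^4 = 16$ configurations, uniform expectation
$77/16 = 4.8125$). Pure repetitions are `RRRR` + `LLLL`, pure alternations
`RLRL` + `LRLR`. These are reported as counts, side bias as the proportion
of right choices, and correct-choice proportion as the mean reward
indicator.

## Cognitive-bias arm scores

Radial-maze sessions (600 s by default) are summarised by time in arms per
role and by entries. With $T_r$ the summed visit time in arms of role $r$:

* positive arm score $= (T_{+} - T_{-}) / (T_{+} + T_{-})$,
* reference arm score $= (T_{\mathrm{ref}} - T_{\mathrm{amb}}) /
  (T_{\mathrm{ref}} + T_{\mathrm{amb}})$,
* ambiguous arm score $= (T_{\mathrm{near+}} - T_{\mathrm{near-}}) /
  (T_{\mathrm{near+}} + T_{\mathrm{near-}})$.

Denominators use arm time only; central-arena time is reported separately
(relative to session duration) and can never be negative. A score whose
denominator is zero is **undefined** and surfaces as `NA` with a warning —
never 0, which would assert indifference. Visits still open at session end
are truncated at the session boundary, since tracking ends with the session.
Training sessions reuse the same operations with a four-arm role map
(ambiguous arms `closed`); visiting a closed arm is an input error, and the
session id is carried through the long-format output so per-session trends
can be tabulated downstream.

## Ethogram scoring

Stereotypic bouts are classified from timed events before sampling:
bar-mouthing qualifies when performed continuously for ≥ 3 s; the
discrete-repetition forms (circling, cage-top twirling, back-flipping,
route-tracing) qualify when repeated at least three times in a row without
pauses *longer than* 3 s — a pause of exactly 3 s keeps the run (strict
inequality breaks it), since "without pauses longer than 3 s" admits 3 s.
Each event row of a discrete form is one repetition; qualifying runs merge
into one bout from first start to last end. Rows carrying `n_reps` (the
classifier's own output) re-enter as pre-merged runs, making classification
idempotent.

One-zero sampling uses half-open intervals $[t, t+15)$: a touch exactly at a
boundary belongs to the later interval. A form scores 1 in an interval iff a
qualifying bout overlaps it. An interval is `inactive` when the animal is
motionless throughout, allowing brief twitches: operationally, when
non-inactive events overlap the interval for at most 5 s in total and no
stereotypic bout touches it. `active` is the complement, so a flagged
interval is always active and levels are well-ordered:
$0 \le \mathrm{level}(f) \le \mathrm{level}(\mathrm{all}) \le 1$, where
`all` uses the union of forms (levels are deliberately non-additive across
co-occurring forms). The level of a form is its flagged-interval count
divided by the active-interval count — interval counts, not summed seconds,
matching the one-zero design. With no active intervals the level is
undefined (`NA`). The default scheme — 15-s intervals, four 15-min blocks
(start of the 2nd–5th hour of the dark phase) on two days — yields 480 data
points per subject. The square root of each level, the transform
conventionally applied before mixed-model fitting, is exported as a plain
column; no inference is performed here.

## Synthetic data: what it emulates, and what not

The generators exist so that every analysis stage has inputs with known
ground truth.

**Choice agents** (`make_agent`): i.i.d. biased, order-1 Markov repeat
(repeat probability $\rho$; $\rho = 0.5$ is a fair random responder),
deterministic alternator, and win-stay/lose-shift. Agents draw from the
ambient RNG stream, so a session seeded through `controller_config(seed =)`
is reproducible bit-for-bit. Run through the controller and the
perseveration metrics, agents with $\rho = 0.5, 0.7, 0.9$ give strictly
increasing mean logit[P] (≈ 0, ≈ 4.4, ≈ 19 over 500 sessions) and mean
pure-repetition counts — the qualitative direction expected of increasingly
perseverative responders.

**Maze sessions** (`simulate_visit_log`): the profile states occupancy
fractions per role, an entry count and a duration. Entries are apportioned
to roles by largest remainder, within-role exponential durations are
rescaled to the role's exact time budget, and centre gaps fill the
remainder, so the profile-implied scores are recovered *exactly* in every
session — randomness lives in visit order, arm identity and timing. This is
a deliberate sharpening: an expectation-matching generator would recover
scores only on average, and the exactness makes end-to-end tests sharp.
What it does not emulate: within-session dynamics (habituation, light/noise
contingencies reshaping behaviour mid-session) or any minimum-displacement
definition of an arm entry — logs are taken as ground truth.

**Ethogram streams** (`simulate_ethogram`): each sampling interval is active
with probability `activity` (default 0.7, a typical dark-phase value);
active intervals carry a 15-s active event and, independently per form with
probability equal to the form's `level`, one qualifying bout drawn from the
profile's duration/gap distributions (bar-mouthing 3–10 s; discrete forms
three-plus-Poisson repetitions of 0.5 s with 0.2–1 s gaps). The expected
measured level of a form is then *exactly* the profile's level parameter,
giving an unbiased recovery surface (a planted level of 0.15 — the
magnitude typical of stereotypic mice — is recovered to within Monte-Carlo
error across subjects). What it does not emulate: bouts spanning interval
boundaries (the sampler handles these, and unit tests exercise them with
hand-built events, e.g. a 30-s bout flagging two intervals) and
autocorrelated activity (real activity comes in runs; here intervals are
independent). Passing recovery tests therefore shows the scoring chain is
correct, not that real mouse data are this well behaved.

## Problem sizes and tolerances

Stochastic tests use fixed seeds and Monte-Carlo tolerances of three
standard errors of the simulated mean. The suite exercises: exhaustive
equality of the Markov chi-square against a brute-force contingency
enumeration for all sequences of length 4–12; null calibration on 10,000
fair 80-trial sequences (rejection at 0.05 required within [0.03, 0.08]);
parameter-recovery ordering over 1,000 sessions per agent; the controller
reward property over 500 sessions per agent; and generator-to-analysis
recovery over 20 maze and 50 ethogram subjects. `scripts/acceptance.R`
recomputes the same quantities from scratch under a caller-supplied seed.

## Known limitations

* The live task's original scoring program is not public; the
  marginal-expectation null and the df correction above are this package's
  documented choices, with `order` parameterised so alternatives can be
  compared.
* The chi-square approximation is mildly conservative at 80 trials; exact
  or permutation p-values are not implemented.
* Circling repetitions are taken as supplied (one event row per lap);
  the package does not decide what motion counts as a lap.
* No group-level inference (mixed models, post-hoc contrasts) is provided;
  outputs are long-format tables meant for any downstream stats
  environment.
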