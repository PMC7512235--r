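---
title: "Measuring strategies in iterated matching pennies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring strategies in iterated matching pennies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(penniesinfo)
```

## The game and its gate

Matching pennies is the simplest strictly competitive game: two players
simultaneously pick Left or Right; the matcher wins (utility 1) when the
picks agree, the mismatcher wins when they differ. The one-shot Nash
equilibrium is the uniform coin. `penniesinfo` fixes the bit encoding
L = 0, R = 1 once, package-wide, because the central identity of the
analysis is a logic gate and an undocumented encoding flip silently turns
an XNOR into an XOR:

$$u_n = \mathrm{XNOR}(a^m_n,\; a^c_n),$$

where $a^m_n$ and $a^c_n$ are the subject's and computer's choices and
$u_n$ the subject's reward on trial $n$. Two consequences drive everything
else. First, the state triple $S_n = (a^m_n, a^c_n, u_n)$ carries only two
free bits. Second, the win-stay/lose-switch rule (repeat after a reward,
switch after a loss) is itself the XNOR of $(u_n, a^m_n)$, and under the
reward gate it coincides, choice for choice, with Tit-for-Tat (copy the
opponent). Behavioural data alone cannot separate them; the package's
`strategy_signature()` makes that indistinguishability measurable rather
than anecdotal.

## The measures

All estimators are plug-in: empirical frequencies over a sliding window,
pushed through the defining sums in base-2 logarithms with $0\log 0 := 0$.
No bias correction is applied — the windowed empirical probability is the
modelling object itself, and corrections would move the traces off the
scale on which their surrogate baselines are computed. The bias that
plug-in estimation incurs is instead *measured*, by the surrogate
machinery below.

Per window the pipeline reports, against the next choice $a^m_{n+1}$:

* the total $I(S_n : a^m_{n+1})$, upper-bounded by 1 bit for a binary
  choice;
* the three pairwise channels $I(a^m_n : a^m_{n+1})$ (active memory),
  $I(u_n : a^m_{n+1})$ (reward following), $I(a^c_n : a^m_{n+1})$
  (opponent copying);
* $\delta I$ = total minus the three pairwise terms, reported *signed*:
  positive values bound higher-order synergy from below, and negative
  values are legitimate — they indicate redundancy among the channels,
  which the reward gate makes endemic in this game;
* the two-step memory $I(S_{n-1} : a^m_{n+1} \mid S_n)$, which is zero for
  any 1-step Markov strategy and picks up non-Markovian structure;
* transfer-entropy decompositions of the total. Because $u_n$ is a
  deterministic function of the two actions, the total decomposes
  *exactly* four ways (transfer entropy from the computer's choice or from
  the reward, plus memory; information from the computer's choice or from
  memory conditioned on the reward, plus the reward term).
  `decomposition_residuals()` verifies all four identities on every
  window; they hold to floating-point error on any session that satisfies
  the gate, so a nonzero residual is a data-integrity alarm, not a
  finding. The function therefore refuses sessions that fail
  `validate_session()`.

`synergy_pair()` isolates the XNOR signature: for deterministic
win-stay/lose-switch with uniform independent inputs, the joint
information $I((a^m_n, u_n) : a^m_{n+1})$ is exactly 1 bit while both
pairwise terms are exactly 0 — the textbook example of purely synergistic
(beyond-pairwise) dependence. Conversely a fully redundant construction
(subject repeats its choice while the computer always matches) drives
$\delta I$ to $-1$ bit; `delta_information()` accepts explicit
distributions so both poles are testable without a simulator in the loop.

## Window convention

`window_spec(width = 500, step = 1)` is the default throughout: windows
500 trials wide, sliding one trial at a time. Window $k$ covers the
`width` state/next-choice pairs $(S_n, a^m_{n+1})$ for
$n = k, \dots, k+\mathrm{width}-1$, so a one-step trace over an $N$-trial
session has $N - \mathrm{width}$ values and the two-step trace
$N - \mathrm{width} - 1$. The width trades temporal resolution against
estimation noise: at width 500 the plug-in bias of a binary mutual
information is $\approx 1/(2\cdot500\ln 2) \approx 0.0014$ bits, two
orders of magnitude below the 1-bit signals of interest, while strategy
changes smear over at most one window width (verified on switching
fixtures).

## Surrogate baselines

A windowed plug-in estimate is never exactly zero, so "no information"
needs a floor. `surrogate_baseline()` recomputes a measure with the
future-choice series led by `lag` trials instead of one (default
`lag = 3`, e.g. $I(a^m_n : a^m_{n+3})$ for the memory trace) and reports
the mean, SD, and mean + 2 SD over windows. Two caveats are inherent to
the method and documented rather than hidden. First, a series with genuine
structure at the surrogate lag (period-2 alternation with `lag = 2`)
makes the surrogate non-null; the lag is configurable for exactly this
reason. Second, the surrogate's finite-sample distribution matches the
real measure's null distribution only approximately: for the two-step
measure the conditional cell counts differ between the lag-1 and lag-3
embeddings (some joint cells have single-digit expected counts at width
500), so the real null measure exceeds the mean + 2 SD threshold slightly
more often than the Gaussian 2.3%. Overlapping windows also mean an
$N = 10^4$ session contains only about $N/\mathrm{width} \approx 20$
effectively independent windows, so below-threshold *fractions* are
reported pooled over many seeded replicate sessions (the test suite uses
50) rather than trusted from a single session.

## The simulator as a stand-in for behavioural data

No public dataset accompanies the primate matching-pennies experiments, so
the package generates sessions with the statistical structure the analysis
assumes. The generator emulates: binary simultaneous choices; reward as
the match gate; thousands to tens of thousands of trials per session
(sessions of 35,000+ trials, the scale of the real protocol, complete in
seconds); an opponent that records every subject choice and reward and
adapts. It deliberately does **not** emulate reaction times, motivation
drift, satiety, session boundaries, or any neural quantity — so passing
tests show the *pipeline* is correct and calibrated, not that real
subjects behave like the bundled agents.

Subject-side strategies (`agent_spec()`):

* `random` (Bernoulli `p_right`, default 0.5 — the Nash strategy);
* `tft`, `wsls`, and `stochastic_wsls` with `p_stay_win`/`p_switch_lose`
  (defaults 1, the deterministic rule; 0.8 is a realistic graded subject);
* `softmax_rl`: $P(R) = e^{\beta Q(R)}/(e^{\beta Q(R)} + e^{\beta Q(L)})$
  with a Rescorla–Wagner update $Q \leftarrow Q + \alpha(u - Q)$ applied
  to the chosen action only. The choice rule is standard; the update rule
  had to be chosen, and chosen-action-only Rescorla–Wagner is the minimal
  rule consistent with "reward following". $\beta$ (default 3) and
  $\alpha$ (default 0.2) are free parameters in conventional ranges; no
  additional forgetting is implemented.
* `markov_table`: arbitrary $l$-step policies ($l \le 4$, matching the
  deepest history the opponents test) over any subset of (own choice,
  opponent choice, reward) — `markov_policy()` enumerates the context
  table from a rule function;
* `switch`: follows one spec before trial `at` and another from `at`
  onward, for nonstationarity fixtures.

Strategies with memory choose uniformly at random until enough history
exists; the uniform start is the Nash strategy and adds no spurious
information. A single master seed is split into independent agent and
opponent streams, so sessions are bit-reproducible and changing one side's
strategy never perturbs the other side's draws.

The opponents (`opponent_spec()`) implement the adaptive computer: at
every trial, for each conditioning depth (0–4 over choice histories;
additionally 1–4 over joint reward-and-choice histories for Algorithm 2),
the realized context's conditional probability of choosing Right is tested
against 0.5 with a two-sided exact binomial test. If any realized context
is significant, the subject's next choice is predicted by sampling from
the most deviant significant context's estimated probability and the
computer plays the mismatching action; otherwise it plays the fair coin.
Defaults: `alpha = 0.05` (conventional, configurable — the test level was
a free design choice); `min_count = 10` observations before a context is
tested (near-empty contexts give degenerate p-values); statistics
accumulate over the whole session. Ties between equally deviant
significant contexts resolve to the lowest order, choice set before reward
set — an arbitrary but fixed rule required for reproducibility. A
`deterministic_counter` option plays the modal counter-action instead of
sampling. The two probabilistic choices in this design (sampled versus
modal prediction, and augmenting rather than replacing the choice-only
hypothesis set in Algorithm 2) follow the reading that most directly
minimizes the subject's reward rate.

`test_bias_hypotheses()` exposes the full hypothesis audit (every context
with `min_count` observations, not just realized ones) for offline
inspection; the in-loop opponent evaluates only realized contexts, since
only those predict the next trial.

## Numerical and degenerate-input choices

* Alphabets are declared, not inferred, so zero-count symbols survive in
  degenerate windows (e.g. a subject frozen on one choice).
* The exact binomial p-value under $p = 0.5$ is computed in closed form
  from the symmetric tail sum; it equals `binom.test()`'s value (asserted
  in tests) and is cheap enough for the per-trial loop.
* Log-normal fitting (`fit_lognormal()`) is closed-form ML on the logs;
  nonpositive values — exactly-zero information windows occur routinely —
  are dropped and counted, at least 10 positive values are required, and
  an all-equal sample is refused (degenerate scale).
* Windowed entropies are computed from count matrices via
  $\log_2 w - \sum c\log_2 c / w$, so the decomposition residuals are
  exact to ~1e-13 rather than accumulating renormalization error.

## Fixture choices worth knowing about

Two natural-sounding fixtures are degenerate in closed loop and were
replaced by non-degenerate equivalents. "Copy your own action from $k$
trials back" locks into a constant or period-2 sequence, after which every
windowed measure is zero; the two-step demonstration agent therefore
copies the *opponent's* action from two trials back, which against the
Nash opponent yields exactly 1 bit of two-step conditional information and
zero pairwise signal. Similarly, self-referential gate agents (e.g. AND of
the two previous actions) collapse their own choice marginal; the
redundancy pole of $\delta I$ is instead demonstrated on an explicitly
constructed distribution.

## Problem sizes

The test suite simulates sessions of $10^4$ trials (with windows of 500)
for trace-level checks, 20 mixed-agent sessions for the decomposition
identities, and 50 replicate sessions for the two-step null calibration;
the full suite runs in about two minutes on a laptop-class core. These
sizes put plug-in bias and its dispersion an order of magnitude below
every effect asserted, and match the per-condition scale of the
behavioural protocol the simulator emulates.

## Limitations

* Estimators are plug-in only (a Miller–Madow-style correction would
  change absolute levels but not the surrogate-relative conclusions, and
  is deliberately not applied).
* Continuous or large-alphabet variables are out of scope; everything is
  binary or small-discrete by construction.
* $\delta I$ bounds higher-order interaction information but is not a
  full partial information decomposition; it can be zero when synergy and
  redundancy cancel (the WSLS-versus-opponent-channel case is exactly
  such a cancellation).
* The opponents implement the *described* adaptive algorithms; no claim
  is made that they bit-match the historical laboratory implementations.
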