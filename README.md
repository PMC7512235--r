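# penniesinfo

Information dynamics of iterated matching-pennies play.

## The problem

In iterated two-choice competitive games — the canonical laboratory example
being rhesus monkeys playing thousands of rounds of *matching pennies*
against adaptive computer opponents — the scientific question is what the
player is *computing*: how much of its next choice is explained by the
previous state of the game, through which channel (its own previous choice,
the opponent's previous choice, or the reward), whether the dependence is
genuinely higher-order (synergistic or redundant across those variables),
and whether the strategy reaches further back than one trial. Parametric
strategy fits struggle here because the game's reward rule makes the
candidate explanations information-theoretically redundant; this package
takes the non-parametric route and measures the dependencies directly, in
bits.

`penniesinfo` is for researchers who want to run that analysis on session
logs (their own, or simulated): behavioural game theorists, decision
neuroscientists, and anyone studying strategy inference from discrete
choice sequences.

## What it computes

Each trial n records the state triple S_n = (a^m_n, a^c_n, u_n): the
subject's choice, the computer's choice, and the binary reward, with
u_n = XNOR(a^m_n, a^c_n) — the matcher is rewarded exactly when the choices
agree. Over a sliding window (500 trials wide by default, sliding one trial
at a time) the package computes plug-in (maximum-likelihood) estimates of:

- **Total one-step information** I(S_n : a^m_{n+1}) — the upper bound on
  what the next choice draws from the previous trial.
- **Pairwise traces** I(a^m_n : a^m_{n+1}) (active memory),
  I(u_n : a^m_{n+1}) (reward following), I(a^c_n : a^m_{n+1}) (opponent
  copying).
- **δI** = total − the three pairwise terms: a signed lower bound on
  higher-order interaction information (positive = synergy, negative =
  redundancy).
- **Exact decompositions** of the total into transfer-entropy + memory and
  reward-conditioned forms, whose residuals vanish identically because the
  reward is a deterministic gate of the two actions.
- **Two-step memory** I(S_{n−1} : a^m_{n+1} | S_n) — non-Markovian strategy
  content, judged against a time-shift surrogate baseline (mean + 2 SD of
  the same measure with the future-choice series led by 3 trials).
- **Log-normal fits** of trace-value distributions, and per-session
  **strategy signatures** (trace medians plus surrogate thresholds).

Because no public dataset accompanies the original experiments, the package
also contains a full closed-loop simulator: subject-side strategies
(Tit-for-Tat, win-stay/lose-switch and its stochastic version, a softmax
reinforcement learner P(R) = e^{βQ(R)} / (e^{βQ(R)} + e^{βQ(L)}), arbitrary
l-step Markov policy tables, mid-session switchers) against the three
computer opponents: Algorithm 0 (Nash random), Algorithm 1 (exact binomial
tests for choice-history biases at depths 0–4, countering the most deviant
significant bias), and Algorithm 2 (additionally tests reward×choice
histories at depths 1–4).

## Worked example

```r
library(penniesinfo)

s <- simulate_session(agent_spec("wsls"), opponent_spec(0), 10000, seed = 42)
s
#> mp_session: 10000 trials | agent wsls | Algorithm 0 | seed 42
#> subject reward rate: 0.4962

strategy_signature(s)
#>    measure median_bits surrogate_mu surrogate_threshold
#> 1    total    0.999434     0.003617            0.008797
#> 2   memory    0.000436     0.001527            0.005166
#> 3   reward    0.000498     0.001319            0.004682
#> 4 opponent    0.999434     0.000753            0.002694
#> 5    delta   -0.001397     0.000017            0.000396
#> 6  synergy    0.998002     0.000771            0.002832
#> 7 two_step    0.000000     0.005382            0.012571
```

A deterministic win-stay/lose-switch player against the Nash opponent earns
the equilibrium reward rate (~0.5) but is maximally predictable from the
previous trial: the total trace sits at the 1-bit ceiling, and *all* of it
appears in the opponent-copy channel — the behavioural fingerprint that
makes WSLS indistinguishable from Tit-for-Tat in this game. The pairwise
memory and reward channels are at the surrogate floor, yet the (own choice,
reward) pair jointly carries the full bit:

```r
unlist(synergy_pair(s))
#>   joint  memory  reward synergy
#>   1.000   0.000   0.000   1.000
```

The synergy is purely higher-order: WSLS *is* the XNOR gate on (reward, own
choice). Against the reward-aware opponent the same strategy is ruthlessly
exploited:

```r
mean(simulate_session(agent_spec("wsls"), opponent_spec(2), 10000, seed = 42)$reward)
#> [1] 0.0018
```

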