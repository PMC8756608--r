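---
title: "Range effects in mixed-gamble acceptance and the (un)reliability of lambda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Range effects in mixed-gamble acceptance and the (un)reliability of lambda}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In the accept--reject task, people see 50--50 mixed gambles -- a possible
monetary gain paired with a possible loss, each at probability one half --
and choose whether to play. Rejecting favourable gambles (say, win 20 or
lose 10) is conventionally read as loss aversion and quantified by prospect
theory's $\lambda$, the multiplicative weight on the loss branch of the
value function. This package implements, as simulation and estimation
machinery, two linked arguments about that practice:

1. **Acceptance is range-sensitive.** If an amount's subjective magnitude is
   its relative rank among comparison amounts (rank-based valuation, as in
   decision by sampling), then stretching the range of gains or losses on
   offer shifts acceptance of the *same* gambles, with no change in anyone's
   loss aversion.
2. **$\lambda$ is not reliably estimable from accept--reject choices.** When
   the data-generating process departs from the fitted model, the omitted
   mechanism biases $\hat\lambda$ in a way that depends on the composition of
   the choice set, so $\hat\lambda$ fails to generalize even across random
   halves of one balanced choice set; and $\lambda$ is confounded with a
   response-level accept/reject bias.

Everything here runs on synthetic agent populations; the package is the
laboratory for the argument, not a re-analysis of any participant data.

## Choice sets

A *condition* is a full factorial of `n_levels` equally spaced gain levels
(ending at `max_gain`) with the same number of loss levels (ending at
`max_loss`); losses are stored as positive magnitudes throughout, with the
sign applied only inside value functions. The canonical design
(`range_design()`) crosses maximum gain in {20, 40} with maximum loss in
{20, 40} at 20 levels per attribute, so the narrow and wide grids share
every second level and 100 gambles are common to all four conditions. The
exact stimulus grids of the original range experiments are not public; this
parameterization reproduces the structural property the argument needs -- a
substantial common gamble set -- without claiming fidelity to particular
stimuli. Cross-condition comparisons (proportions, $\lambda$ fits) are
always restricted to the common set, which keeps the measurement instrument
fixed across conditions.

## Rank-based choice (the misspecified generator)

An amount's subjective magnitude is its relative rank in a comparison pool:
the fraction of pool entries below it, counting ties at half weight, with
the amount's own instance excluded from its comparison set. The accept
probability of gamble $(g, l)$ is

$$P(\text{accept}) = (1 - 2t)\,\mathrm{logit}^{-1}\!\big(s\,[r(g) - r(l)]\big) + t,$$

with sensitivity $s$ (default 3) and tremble $t$ (default 0.05). The
comparison pools are task-endogenous: a condition's own gain and loss
levels, which is the cleanest reading of "the amounts experienced in the
task". A dense idealised pool over $(0, \max]$ is also provided
(`uniform_context()`); it uses midpoint spacing so that ranks of on-grid
amounts are exact fractions -- a 10-unit amount ranks 0.25 in a 0--40 pool
and 0.50 in a 0--20 pool.

The choice rule itself is a modelling commitment of this package: rank
theories make directional predictions but need a parametric link to
simulate trial-level data. Logistic-on-rank-difference is the minimal such
link; the tremble keeps simulated agents off the probability boundary the
way real lapses do. Two consequences matter for tests: in any condition
whose gain and loss levels coincide, a common set closed under swapping
gain with loss yields a mean accept probability of exactly one half (the
logistic is antisymmetric in the rank difference, and the tremble preserves
the symmetry); and the four-condition pattern LH > (LL = HH) > HL holds for
every positive sensitivity.

## The prospect-theory accept--reject model (the fitted model)

The fitted model is the reduced form standard for 50--50 mixed gambles: a
power value function with no probability weighting (any weight on the fixed
1/2 is absorbed into the sensitivity),

$$U(g, l) = \tfrac12 g^{\alpha} - \tfrac12 \lambda\, l^{\beta}, \qquad
P(\text{accept}) = \mathrm{logit}^{-1}(\mu\, U + b),$$

with curvature $\alpha = \beta$ by default (on mixed gambles, unequal
curvatures trade off against $\lambda$ so severely that freeing both is
rarely informative), sensitivity $\mu$, and intercept $b$ -- the bias toward
accepting or rejecting gambles irrespective of the amounts on offer. The
log-likelihood is Bernoulli, with probabilities clamped to
$[10^{-9}, 1 - 10^{-9}]$ so boundary parameter vectors stay finite.

Estimation (`fit_mle()`) is per-agent maximum likelihood under box
constraints ($\lambda \in [0.05, 20]$, $\mu \in [0, 50]$, $b \in [-10, 10]$,
$\alpha \in [0.2, 2]$), by L-BFGS-B with an analytic gradient, $\lambda$
optimized on the log scale, and 10 uniform random starts drawn from a seeded
stream -- the likelihood has ridges along the $\lambda$--$b$ and
$\alpha$--$\mu$ trade-offs, and single starts are unreliable. Estimates
within $10^{-6}$ of a bound are flagged; data with all-accept or all-reject
responses (routine in split halves) are fitted, flagged on `bias`, and
warned about rather than refused. Fits are deterministic given the records
and the `fit_spec`.

## Synthetic populations

`sample_population()` draws agent parameters:

* **cpt** (well-specified): $\lambda$ log-normal with median 2 and log-sd
  0.3, bias normal(0, 0.5), $\mu = 1$ and $\alpha = 0.9$ fixed. The fixed
  values sit where accept--reject fits of this form typically land and make
  the knife-edge example (win 20 / lose 10 at $\lambda = 2$, linear value)
  exact.
* **dbs** (misspecified): sensitivity normal(3, 0.5) truncated at zero,
  tremble 0.05.

`simulate_population()` resolves each agent's latent probabilities into
Bernoulli responses, one sub-seed per agent (master seed + agent index), so
any agent's data can be regenerated without the rest. What the generator
deliberately omits: sequential context (pools are static within a
condition, not running windows over experienced trials), learning and order
effects, and response times. Passing tests therefore show that the
*estimation logic* behaves as claimed under clean conditions; they do not
show that real participants satisfy the generators' assumptions.

## The split-half experiment

`rank_generalization()` repeats, per replicate: randomly halve every
agent's records; fit $\lambda$ on each half; rank agents by half-A
$\hat\lambda$; locate the agents at the 5th/25th/50th/75th/95th percentiles
(nearest rank, ties broken by agent id); and record those agents' half-B
ranks. Agents whose fit fails to converge or lands on a bound on either
half are dropped from that replicate's ranking -- a practical necessity,
since degenerate halves occur. The stochasticity-only null
(`stochasticity_null()`) asks how much ranks would move if the fitted model
were exactly right: it resimulates half-B choices from each agent's half-A
fitted probabilities, refits, and re-ranks. The headline contrast is the
misspecified population's rank scatter (and near-zero split-half rank
correlation) against both the well-specified control and the null.

## Problem sizes and numerical choices

The shipped analyses use: 50-agent populations (100 for the proportion
analysis), 20 split replicates, and the symmetric high-range condition for
the split-half experiment. Trial counts per agent are 400 (one pass of the
20x20 factorial) for the proportion analysis and the narrow-gain/wide-loss
$\lambda$-collapse fit, and 1600 (four passes) for the split-half
experiment. The larger budget is deliberate calibration, not convenience:
at small trial counts the $\alpha$--$\mu$--$\lambda$ ridge alone leaves the
well-specified population's generating-vs-estimated $\lambda$ rank
correlation well short of what a positive control requires, so a split-half
failure there could not be attributed to misspecification. At 1600 trials
the well-specified control recovers $\lambda$ ranks (rank correlation above
0.7) and generalizes across halves (split-half rank correlation above 0.5),
while the misspecified population still does not (below 0.2) -- which is
precisely the contrast the experiment exists to exhibit. More replicates smooth the rank
histograms but do not change any qualitative conclusion.

Other numerical choices: mid-rank ties with self-exclusion in
`relative_rank()` (so a grid median ranks near one half and a unique pool
maximum ranks exactly 1); L-BFGS-B with `factr = 1e4` so refitting from a
returned optimum cannot improve the log-likelihood by more than about
$10^{-6}$; empty common-gamble intersections warn and return an empty set
rather than erroring (the downstream operations then refuse the empty set
explicitly); and fewer than 10 usable agents in a ranking replicate is an
error, since percentile ranks over a handful of agents are meaningless.

## Known limitations

* The rank-based generator uses the limit-case rank (an effectively
  infinite comparison sample); binary-sampling dynamics with finite sample
  sizes would add variance the tests do not probe.
* The fitted model's curvature is tied ($\alpha = \beta$) by default;
  freeing both is supported but interacts badly with $\lambda$
  identification on mixed gambles, and no test asserts recovery in that
  configuration.
* Standard errors are not computed; the package's object of interest is
  ranks and their (non-)generalization, not confidence intervals.
* Conclusions about real participants require the model-free proportion
  analysis; the $\lambda$ machinery here demonstrates *why* fitted
  $\lambda$s should not carry that weight.
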