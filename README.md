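# lossrange

Simulation and estimation machinery for two linked claims about loss
aversion in the accept–reject task, where people accept or decline 50–50
gambles offering a monetary gain *g* or a loss *l*:

1. **Acceptance of the same gambles is range-sensitive.** If subjective
   magnitude is relative rank among experienced amounts (decision by
   sampling), then a 10-unit gain "feels" larger when gains span 0–20
   (rank 0.5) than when they span 0–40 (rank 0.25). Stretching only the
   loss range makes identical mixed gambles more attractive; stretching
   only the gain range makes them less so — with no change in anyone's
   loss aversion.
2. **Prospect theory's λ cannot be reliably estimated from accept–reject
   choices.** Fitting the standard model
   `P(accept) = logit⁻¹( μ·[g^α − λ·l^β]/2 + b )`
   to choices generated by the rank mechanism produces λ̂ values that track
   the range manipulation (dropping below 1 — apparent reversal of loss
   aversion — in narrow-gain/wide-loss conditions), are strongly confounded
   with the accept/reject bias *b*, and fail to generalize even across
   random halves of one balanced choice set.

The package is aimed at behavioural decision researchers who want to probe
these estimation pathologies on synthetic agent populations: it provides the
2×2 range-manipulation design with its common-gamble set, rank-based and
prospect-theory choice generators, per-agent multi-start maximum-likelihood
fitting, model-free accept proportions, and the split-half λ-rank
generalization experiment with its "stochasticity alone" null.

## Worked example

```r
library(lossrange)

design <- range_design(low = 20, high = 40, n_levels = 20)  # LL, LH, HL, HH
common <- common_gambles(design)                            # 100 shared gambles
predicted_proportion_table(design, common)
#>   condition mean_accept n_common_gambles
#> 1        LL   0.5000000              100
#> 2        LH   0.6531678              100
#> 3        HL   0.3468322              100
#> 4        HH   0.5000000              100
```

Symmetric conditions sit exactly at indifference; widening only the loss
range (LH: gains 0–20, losses 0–40) lifts acceptance of the *same* 100
gambles to 0.65, and the mirror condition depresses it to 0.35. Fitting the
prospect-theory model to rank-based choosers in the LH condition:

```r
lh   <- design$LH
pop  <- sample_population(population_spec(50, "dbs", seed = 1))
recs <- simulate_population(pop, lh, n_reps = 1, seed = 1001)  # 400 trials/agent
fits <- fit_population(recs, fit_spec(seed = 2001))
median(fits$lam)
#> [1] 0.4458
```

None of these agents weighs losses at all, yet the fitted λ says loss
aversion has *reversed* (λ̂ ≈ 0.45 < 1): the omitted rank mechanism is
absorbed into λ. The split-half experiment (`rank_generalization()`) shows
the deeper problem — for these misspecified populations the λ̂ ranking of
agents on one random half of their choices bears almost no relation to the
ranking on the other half, far beyond what Bernoulli response noise alone
(`stochasticity_null()`) produces, while a well-specified population's
ranking generalizes cleanly.

The `analysis/` scripts run the full pipeline in order
(`01_design.R` … `05_recovery.R`), printing what each stage finds and
writing tables under `results/`.

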