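# snakeid

Analysis of crowdsourced species-identification challenges, built for
online snake identification: who in a crowd can tell a harmless kingsnake
from a coralsnake, how sure can we be, and what makes a photo hard?

Snakebite treatment often depends on identifying the biting snake, and
online communities can identify snakes from photos in minutes. A
crowdsourced challenge yields one row per (participant, photo) with a
free-text identification. `snakeid` turns that table into inference:

* **Taxonomy-aware ordinal scoring.** Free-text answers (binomen, synonym,
  common name, bare genus or family) are resolved against a static taxonomy
  snapshot and scored 0 = incorrect/skip, 1 = family, 2 = genus,
  3 = species, plus a binary score for correctness about medically
  important venomous snake (MIVS) status.
* **A hierarchical Bayesian graded response model.** For score
  *Y* ∈ {0..3},

  *P*(*Y* ≤ *k*) = logit⁻¹(*α*·(*τ*ₖ₊₁ − *η*)),  
  *η* = *θ*(participant) + *x*ᵀ*β* + *b*(photo) + *b*(species),  
  *α* = exp(*δ*₀ + *d*(photo) + *d*(species)),

  with ordered thresholds *τ*, participant ability *θ* ~ N(0, 1) (fixing
  the latent scale), fixed effects *β* for snake family, photo region,
  home-region advantage and its region interactions, photo quality and the
  "taxa repeat" learning covariate, and correlated bivariate-normal
  difficulty/discrimination pairs per photo and per species on a log link.
  Posterior sampling is a gradient-based no-U-turn sampler with analytic
  gradients in compiled code.
* **Model comparison and evaluation.** Participant-stratified 80/20
  splitting, PSIS-LOO comparison of the six candidate fixed-effect
  structures, Bayesian R², and held-out mean absolute error in score units,
  each with and without group-level effects.
* **Descriptive tables.** Participant quintile accuracy, MIVS genus
  confusion, per-photo consensus and answer diversity, predicted accuracy
  grids, difficulty/discrimination rankings, diversity-vs-accuracy
  regression.
* **A forward simulator** with known ground truth (`simulate_challenge()`),
  whose defaults mirror the published challenge scale, for recovery testing
  and power analysis.

## A worked example

```r
library(snakeid)

# a challenge at reduced scale: 60 participants x 150 photos each
cfg <- sim_config(n_participants = 60, photos_per_participant = 150, seed = 42)
sim <- attach_answer_strings(simulate_challenge(cfg), seed = 43)
scored <- score_responses(sim$responses, sim$taxonomy)

score_response("Bitis gabonica", "Bitis arietans", example_taxonomy())
#> [1] 2      # congener of the puff adder: genus correct only

split <- split_train_test(scored, 0.8, seed = 44)
fit <- grm(split$train, sim$taxonomy, model = "home_x_region",
           chains = 2, iter = 300, warmup = 350, seed = 45)
print(fit)
#> Hierarchical graded response model (cumulative logit)
#> model: home_x_region | 7200 responses | 60 participants, 1000 photos, 100 species
#> draws: 2 chains x 300 post-warmup iterations; 0 divergent transitions
#> fixed-effect posterior medians:
#>   Colubridae ... home_region = T  taxa_repeat ...
#>        -1.94            2.90             0.06

psis_loo(fit)
#> PSIS-LOO: elpd_loo = -7618.4 (se 62.7); looic = 15236.7 | p_loo = 726.9
#> 7200 observations; 8 with Pareto k > 0.7
heldout_mae(fit, split$test, sim$taxonomy, re = FALSE)
#> [1] 1.031143   # score units, population-level prediction
heldout_mae(fit, split$test, sim$taxonomy, re = TRUE)
#> [1] 0.7967853  # knowing the participants and photos helps

round(quintile_table(scored)[, c("species_pct", "genus_pct", "family_pct")])
#>   species_pct genus_pct family_pct
#> 1          64        74         88
#> 2          45        58         78
#> 3          34        47         70
#> 4          23        33         58
#> 5          15        23         45
#> 6          36        47         68    # whole community
```

The fixed-effect medians land near the generating values (the simulator's
defaults are the published posterior medians: Colubridae −1.97, home-region
3.14, taxa-repeat 0.08), and the quintile accuracy profile of the simulated
community — 64% down to 15% species-level, 36% overall — mirrors the
published spread. `summary(fit)` adds 95% credible intervals,
rank-normalized split-chain Rhat and bulk/tail effective sample sizes;
`predict_accuracy_grid()` produces the family-by-region probability tables
behind the usual figures.

Numbers above are the printed output of this snippet; the same seeds
reproduce them exactly.

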