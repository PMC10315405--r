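# rpclust

Robust profile clustering (RPC) of categorical dietary consumption data:
a Bayesian joint global/local latent class model for finding dietary
patterns in populations made of unevenly sized subgroups — the setting where
an ordinary latent class model lets the largest subgroup (say, the biggest
race/ethnicity stratum in a national survey) dominate the fitted patterns
and wash out everyone else.

The package is for nutritional epidemiologists and biostatisticians working
with categorized food-group intake (e.g. 24-hour recalls summarized to food
pattern equivalents, coded none/low/medium/high), and for methodologists who
want a tested, reproducible reference implementation of the model with a
synthetic-data generator for validation studies.

## The model

For person $i$ with subgroup $s_i \in \{1,\dots,S\}$ and consumption levels
$y_{ij} \in \{1,\dots,d\}$ over $p$ food items:

* $z_i \sim \mathrm{Cat}(\pi)$ — global pattern, shared by the whole
  population ($\pi$ of length $K_0$);
* $c_i \sim \mathrm{Cat}(\lambda^{(s_i)})$ — local pattern, specific to the
  subgroup;
* $G_{ij} \sim \mathrm{Bernoulli}(\nu_{s_i j})$ — per-person-per-item switch:
  item $j$ follows the global process ($G_{ij}=1$) or the local one;
* $y_{ij} \sim \mathrm{Cat}(\theta_{0,j\cdot|z_i})$ if global,
  $\mathrm{Cat}(\theta_{1,j\cdot|c_i s_i})$ if local.

Estimation is by Gibbs sampling with Dirichlet–multinomial/Beta conjugacy
under noninformative priors, with deliberately overfitted mixtures (30
global and 30 local components by default, sparse $\mathrm{Dir}(1/30)$
weight priors) so that redundant components empty out and the count of
nonempty components estimates the number of patterns.  Post-processing
prunes empty components, resolves label switching, and reports each
pattern's *modal* consumption level per food plus a $p \times S$ heatmap of
global-allocation probabilities — low values mean an item's consumption
patterns are subgroup-specific.  See `vignette("rpc-methods")` for the full
account (conditionals, initialization, identifiability of the allocation
probabilities, preprocessing conventions).

## Worked example

Simulate a small dataset with known truth (150 persons, 6 items, 3
subgroups, 2 true global patterns, 1 local pattern per subgroup, items
globally allocated half the time), fit, and summarize:

```r
library(rpclust)

spec <- nhanes_like_spec("tiny", seed = 1)
sim  <- generate_dataset(spec)
cfg  <- mcmc_config(K0_max = 10, Ks_max = 10, n_iter = 1000,
                    burn_in = 500, thin = 2, seed = 2)
samples <- run_mcmc(sim$data, rpc_priors(), cfg)
summ <- summarize_rpc(samples, occupancy_threshold = 0.05)
print(summ)
#> rpc_pattern_summary (occupancy threshold 0.05)
#>   global patterns: 2 (occupancy: 0.59, 0.23)
#>   local patterns [subgroup1]: 1 (occupancy: 0.82)
#>   local patterns [subgroup2]: 1 (occupancy: 0.83)
#>   local patterns [subgroup3]: 1 (occupancy: 0.81)
#>   max global-allocation probability: 0.725
```

Of the 10 overfitted global components, exactly the 2 true ones survive the
5% occupancy threshold, and each subgroup keeps its single local pattern.
The modal consumption matrix of the recovered global patterns,

```r
summ$modal$global$levels
#>      item1 item2 item3 item4 item5 item6
#> [1,]     3     4     1     2     3     4
#> [2,]     4     1     2     3     4     1
```

matches the generative truth exactly (level 1 = no consumption, 4 = high
consumption); `summ$modal$global$prob` holds each mode's posterior
probability, and `summ$allocation$G` the item-by-subgroup global-allocation
heatmap.

## Analysis workflow

`analysis/` contains the numbered study workflow over the same functions —
simulate an NHANES-like all-local population, demonstrate the recall
averaging / eligibility / tertile-categorization / risk-flag chain, fit, and
summarize:

```sh
Rscript analysis/01_simulate.R     # 1,458 persons, 5 subgroups, 28 items
Rscript analysis/02_preprocess.R   # amounts -> 4-level coding, flags, weights
Rscript analysis/03_fit.R          # 6,000 Gibbs sweeps, overfitted 30+30
Rscript analysis/04_summarize.R    # patterns, heatmap, figures, truth scoring
```

Outputs land under `results/run/` (tables as CSV, figures as PNG).  In this
regime every item localizes (all heatmap entries below 0.30 against true
allocation probabilities ≤ 0.12) and each subgroup's modal local pattern is
recovered 28/28.

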