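---
title: "Robust profile clustering: model, estimation and design choices"
author: "rpclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust profile clustering: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpclust)
```

## The problem

Latent class models (LCMs) derive dietary patterns from categorical
consumption data by assuming one set of profiles for the whole population.
When the population mixes demographic subgroups of very different sizes, the
largest subgroup dominates the fitted profiles and smaller subgroups are
absorbed as noise.  Robust profile clustering (RPC) addresses this by letting
every food item of every person follow either a **global** process — latent
dietary profiles shared by the whole population — or a **local** process —
profiles specific to a predefined subgroup (here: race/ethnicity strata),
with a latent binary indicator deciding which.

## The model

Observed data: consumption levels $y_{ij} \in \{1,\dots,d\}$ for persons
$i = 1,\dots,n$ and food items $j = 1,\dots,p$ (level 1 = no consumption;
levels 2–4 = tertiles of positive consumption), and a known subgroup label
$s_i \in \{1,\dots,S\}$.

Latent structure, as generated by `generate_dataset()` and inferred by
`run_mcmc()`:

* a global class $z_i \sim \mathrm{Cat}(\pi_1,\dots,\pi_{K_0})$;
* a local class $c_i \sim \mathrm{Cat}(\lambda^{(s_i)}_1,\dots,\lambda^{(s_i)}_{K_s})$,
  one per person (see "One local class per person" below);
* allocation indicators $G_{ij} \sim \mathrm{Bernoulli}(\nu_{s_i j})$, with
  $G_{ij}=1$ meaning item $j$ of person $i$ follows the global process
  (this sign convention is used consistently in code and output; some
  presentations use the opposite coding);
* observations
  $y_{ij} \mid G_{ij}=1 \sim \mathrm{Cat}(\theta_{0,j\cdot|z_i})$ and
  $y_{ij} \mid G_{ij}=0 \sim \mathrm{Cat}(\theta_{1,j\cdot|c_i s_i})$,
  where each $\theta$ row is a $d$-simplex.

Conditional on the indicator row, one person's likelihood factorizes as

$$f(y_i \mid s_i, G_i) \;=\;
\Big[\sum_{h=1}^{K_0} \pi_h \prod_{j:\,G_{ij}=1} \theta_{0,j y_{ij}|h}\Big]
\times
\Big[\sum_{l=1}^{K_s} \lambda^{(s_i)}_l \prod_{j:\,G_{ij}=0} \theta_{1,j y_{ij}|l s_i}\Big],$$

implemented in log space by `rpc_log_likelihood()`.  For testing,
`rpc_marginal_log_likelihood()` integrates the $2^p$ indicator
configurations exactly (capped at $p \le 12$; the sampler never needs this).

### One local class per person

Some presentations of this likelihood write the local factor as
$\prod_j \sum_l \lambda_l \theta_{1,jy_{ij}|ls}$, i.e. with the mixture sum
inside the item product, which would make every item choose its local class
independently.  The RPC construction, and this package, use a single local
class $c_i$ per person: the local product sits inside one sum over $l$.  The
enumeration oracle in the test suite checks the implemented (single-class)
form.  The distinction matters: a per-person local class is what lets the
local side capture within-subgroup correlation across items.

### Priors

Noninformative throughout, so the data drive estimation: symmetric
Dirichlet on the weights with concentration $1/K_0^{\max}$ and
$1/K_s^{\max}$ (the sparse overfitted-mixture regime), symmetric
Dirichlet(1) on every consumption-profile row, and Beta(1, 1) on each
allocation probability.  All are exposed in `rpc_priors()`.

### Overfitted mixtures

The number of patterns is unknown a priori, so the model is deliberately
overfitted — 30 global and 30 local components by default
(`mcmc_config(K0_max = 30, Ks_max = 30)`).  Under the sparse weight prior,
redundant components empty out during sampling, and the number of
**nonempty** components estimates the number of patterns.  "Nonempty" is
operationalized in `prune_and_relabel()` as posterior-median occupancy at or
above 5% of the component's reference population (all $n$ persons for global
components, the subgroup for local ones).  The 5% default is a config value,
not a modeling constant.

## Gibbs sampler

`run_mcmc()` runs full conditional sweeps in a fixed order (all conjugate):

1. $z_i \propto \pi_h \prod_{j: G_{ij}=1}\theta_{0,jy_{ij}|h}$ (log-space
   normalization);
2. $c_i \propto \lambda^{(s_i)}_l \prod_{j: G_{ij}=0}\theta_{1,jy_{ij}|ls_i}$;
3. $G_{ij} \sim \mathrm{Bernoulli}\big(\nu\theta_0 / (\nu\theta_0 + (1-\nu)\theta_1)\big)$
   at the current classes;
4. $\pi \sim \mathrm{Dir}(1/K_0^{\max} + \text{counts})$;
5. $\lambda^{(s)} \sim \mathrm{Dir}(1/K_s^{\max} + \text{counts in } s)$;
6. each global row $\theta_{0,j\cdot|h} \sim \mathrm{Dir}(1 + \text{level
   counts among globally allocated items in class } h)$;
7. each local row analogously from locally allocated items;
8. $\nu \sim \mathrm{Beta}(1 + \#\text{global}, 1 + \#\text{local})$.

Empty components simply receive prior-only Dirichlet draws.  The sweep is
implemented once, in compiled code, using R's own RNG, so chains are
bit-reproducible from `set.seed()` / `config$seed`; `gibbs_step()` exposes a
single sweep of the same kernel.  Draw retention is
`floor((n_iter - burn_in)/thin)` with a subject-specific log-likelihood
trace per retained draw.

### Initialization: why not prior draws

The textbook start (everything drawn from the prior) reproducibly settles
this model into a metastable *blended-profile* mode whenever both sides of
the hierarchy have spare capacity: the subgroup-local classes discover the
global class structure first and duplicate it within every subgroup (or the
global side absorbs the subgroup structure), after which the indicators have
no gradient to crystallize — both processes hold the same blended rows, and
the conditional log-likelihood plateaus far below the factorized mode (on
the package's recovery benchmark, around −22,000 against −5,250; the gap
does not close within tens of thousands of sweeps because escaping requires
a coordinated change of thousands of latent variables).

The default `init = "factorized"` therefore starts from observed **item
marginals**: every global profile row at the pooled marginal of its item
(jittered), each subgroup's *first* local class at the subgroup marginal
with the remaining local classes at prior draws and initial local weights
concentrated on that first class, $\nu = 0.5$, indicators fair coin flips,
global labels uniform at random, local labels merged.  Starting the local
side *merged* means the only initial between-person structure available to
explain is cross-subgroup — exactly the global side's job — so the shared
patterns crystallize first and the indicators then route the
subgroup-specific residue to the local side.  `init = "random"` retains the
prior-draw start (it is fine whenever one side is fixed, e.g. the
`nu_fixed` reductions).

### Allocation indexing and identifiability

`mcmc_config(nu_index = )` offers two conventions for the allocation
probability: one $\nu_{sj}$ per (subgroup, item) — the default — or one
$\nu_j$ per item shared by all subgroups.  The per-subgroup version is the
more flexible, but in strongly localized data it is only weakly identified:
a global component can *clone* one subgroup's local profile and serve that
subgroup at zero likelihood cost, so the allocation posterior for weakly
differentiated items spreads over mid-range values.  With the item-shared
$\nu_j$, an item can only be globally allocated if a single global row
serves **every** subgroup at once, which makes strong localization
identifiable.  The all-local analyses in `analysis/` and the acceptance
script use `nu_index = "item"` for this reason; the degenerate reductions
and the half-and-half recovery benchmark use the default.

## Post-processing

`prune_and_relabel()` drops components with posterior-median occupancy below
the threshold, then resolves label switching per retained draw by greedy
total-variation matching of profile rows against the last retained draw, and
finally orders components by descending mean occupancy; posterior means are
computed after relabeling.  Greedy matching (rather than full
Hungarian/ECR machinery) is sufficient here because the matched objects are
full $p \times d$ profiles of well-separated nonempty components; a
constructed label-switched fixture in the tests guards this choice.
Pruning and relabeling never alter the retained log-likelihood trace.

`modal_patterns()` reports, per pattern and item, the consumption level with
the highest posterior-mean probability; exact ties break toward the lower
level and are flagged.  `allocation_heatmap()` reports both the
indicator-based estimate (posterior mean fraction of subgroup members with
$G_{ij}=1$) and the posterior mean of $\nu$; the two agree up to Monte-Carlo
error and both are emitted because published heatmaps do not always say
which was used.

`weighted_descriptives()` computes Horvitz–Thompson weighted
means/proportions by stratum with person-level bootstrap variability.
Design-based (stratum/PSU linearized) standard errors are deliberately out
of scope, and the output's `method` column says so; estimates are invariant
to rescaling all weights, and pooled-cycle weight rescaling is assumed done
upstream.

## Preprocessing conventions

* **Recall averaging**: the unweighted mean over available complete recall
  days (one or two); persons with no complete recall are excluded with a
  logged reason.
* **Tertiles**: cutpoints are type-1 (inverse ECDF) empirical quantiles at
  1/3 and 2/3 of the *strictly positive* amounts pooled over the whole
  analytic population, not within subgroup and unweighted by default.  The
  convention is frozen for reproducibility rather than as a claim about any
  particular statistical software's default.
* **Level assignment**: $0 \to$ 1 (none), $(0, t_1] \to$ 2, $(t_1, t_2] \to$
  3, $(t_2, \infty) \to$ 4; ties at a cutpoint go to the lower level.  A
  column with fewer than 3 distinct positive values is degenerate: positives
  map to a single "consumed" level.
* **Eligibility order**: sex → age (20–80, both inclusive; surveys top-code
  age at 80) → race/ethnicity known and allowed → poverty-income ratio
  ≤ 1.30 → pregnancy/lactation → diet completeness.  The exclusion tally is
  reported per criterion in this order, so any other ordering can be
  re-derived.
* **Risk flags**: high cholesterol (total > 200 mg/dL, or LDL > 150, or
  medication), obesity (BMI ≥ 30, inclusive), hypertension (SBP > 140 or
  DBP > 90 or medication), diabetes (fasting glucose > 126 or medication),
  current smoker.  Three-valued logic: a missing input leaves the flag
  missing unless a known TRUE disjunct decides it; flagged-missing persons
  stay in the analysis but drop out of that flag's summaries.

## The synthetic-data generator

`generate_dataset()` draws from exactly the generative process above, so
every downstream stage is testable without any external data, and returns
the latent truth ($z, c, G$) for recovery scoring.  `nhanes_like_spec()`
provides preset regimes:

* `study_scale` / `all_local` — five race/ethnicity subgroups with sizes in
  the proportions 526/386/999/805/201 (2,917 persons at full scale;
  `all_local` defaults to half scale, n = 1,458), 28 food items, 4 levels,
  3 weakly separated global patterns (modal mass 0.35, zero-inflated), one
  local pattern per subgroup, and all-local allocation
  ($\nu_{\text{true}} \in [0.04, 0.12]$).  Local profiles are designed to be
  pairwise distinct on every item — different modal level where possible
  (only 4 levels exist for 5 subgroups), otherwise clearly different modal
  mass (0.55–0.80) — because localization is only identifiable when no
  single global row can serve two subgroups; zero-inflation (level-1 mass
  0.15–0.30 on episodically consumed items) mimics foods many participants
  never report.
* `well_separated` — the recovery benchmark: 2 subgroups × 500 persons, 2
  global patterns, 1 local pattern per subgroup, $\nu = 0.5$ everywhere,
  modal mass 0.99.  The sharpness is a design calculation, not decoration:
  with $m \approx 250$ observations per profile cell and a Dirichlet(1) row
  prior, the posterior-mean sup-error over all cells behaves like a
  shrinkage bias of $\approx (4q-1)/(m+4)$ plus a noise envelope of
  $\approx 3.4\sqrt{q(1-q)/m}$; at modal mass $q = 0.99$ the expected
  sup-error is ≈ 0.03, so the benchmark's 0.05 recovery bound holds with
  margin, while at $q = 0.95$ it would sit at the bound and pass or fail by
  data realization.
* `all_global`, `local_lcm` — single-population degenerate regimes
  ($\nu \equiv 1$, $\nu \equiv 0$) for which RPC provably reduces to a plain
  latent class model; used to cross-check the sampler against an independent
  reference LCM implementation.
* `tiny` — a 150-person smoke-test fixture.

What the generator does **not** emulate: dietary measurement error (under-
and over-reporting), day-to-day intake variation before averaging, survey
design effects (clustering, unequal selection), item-level correlation
beyond what the class structure induces, and continuous-amount marginals
(the categorical process is generated directly at the food-group level;
`analysis/02_preprocess.R` exercises the amount-to-level chain separately).
Passing recovery tests therefore demonstrates correctness of the estimation
machinery under the model's own assumptions — not robustness of the model to
real recall data's violations of them.

## Numerical choices

Log-sum-exp for every categorical conditional; Dirichlet draws as normalized
gammas with a uniform fallback if all components underflow (relevant only
for concentrations like $1/30$); indicator odds with a 0.5 fallback when
both sides have zero mass; all randomness through R's RNG so a single seed
reproduces data, chain and summaries bit-for-bit.  Chain-length defaults in
the shipped experiments (3,000–6,000 sweeps, half burn-in, thinning 3–5)
were chosen as the sizes at which the benchmark posteriors stabilize at desk
scale; at the full survey scale the same machinery simply runs longer.

## Known limitations

* The blended-profile mode is a property of the posterior landscape, not
  only of the sampler; the factorized start avoids it in all shipped
  regimes, but pathological data could still trap a single chain.  Running
  a few seeds and comparing the retained log-likelihood traces is cheap
  insurance.
* With per-(subgroup, item) allocation probabilities, strongly localized
  data leave $\nu$ weakly identified (the cloning degeneracy above); prefer
  `nu_index = "item"` when the scientific question is "which items localize
  at all".
* Survey-design variance estimation is out of scope; the bootstrap SEs in
  `weighted_descriptives()` treat persons as independent.
* No missing-data machinery in the model itself: the consumption matrix
  must be complete (preprocessing handles exclusions upstream).
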