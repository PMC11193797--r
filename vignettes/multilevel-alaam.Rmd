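---
title: "Multilevel ALAAMs for household wealth dynamics: models, generator, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel ALAAMs for household wealth dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlalaam)
```

## The scientific problem

In many rural, kin-centred settings a household is a social group rather
than a street address: individuals can belong to several households at
once (so-called stretched households) or change membership over time, and
these shared memberships knit households into an inter-household support
network.  `mlalaam` studies how a binary household outcome — here, whether
a household's asset-wealth quintile changed between two survey waves — and
a binary regional outcome — whether a region's wealth inequality rose —
co-depend on this network and on each other.

The data structure is a two-level network: households (level A) linked by
shared-member ties, nested in regions (level B) via a geographic
affiliation, with a derived region-region meta-network (two regions are
meta-tied when at least one household tie crosses between them).

## The model

The core is a multilevel autologistic actor-attribute model (ALAAM).  With
household outcomes $y$ and regional outcomes $Y$, conditional on the
household network $A$, the region level $B$, the affiliation $X$ and nodal
covariates,

$$\Pr(y, Y) = \frac{1}{\kappa(\theta)} \exp \sum_I \theta_I\, z_I(y, Y, A, B, X, \ldots),$$

where each $z_I$ counts a network configuration and $\kappa$ normalises
over all $2^{N+R}$ joint outcome states.  The implemented configurations
are listed in `?alaam_effects`: outcome-weighted degree, triangle
membership, within-/cross-region degree, external (non-resident) ties with
a quadratic term, within- and cross-region contagion (concordant tied
pairs), a poorest-dyad contagion, region density, within-region and
cross-boundary tie counts, region-region contagion, a cross-level
interaction ($Y_v$ times the count of outcome-positive households in $v$),
and the micro-macro link ($Y_v$ times the count of within-region concordant
tied pairs).  Positive $\theta_I$ means configuration $I$ occurs more often
than expected given everything else; $\exp(\theta_I)$ is a conditional odds
multiplier per unit of the configuration's change statistic.

Because outcomes are interdependent, estimation cannot use ordinary
logistic regression.  `alaam()` solves the exponential-family moment
condition $E_\theta[z] = z_{\text{obs}}$ by three-phase Robbins–Monro
stochastic approximation over a Gibbs sampler whose full conditionals are
$\operatorname{logit} \Pr(\text{node } i = 1 \mid \text{rest}) = \theta
\cdot \Delta z_i$, with $\Delta z_i$ the vector of change statistics.  The
sampler is compiled code; change statistics are exact local computations
and are tested against global statistic differences and, on networks of up
to 20 nodes, against full enumeration (`alaam_exact_probs()`).

### Estimation settings and their defaults

All sampler units are full Gibbs sweeps (every free node updated once in a
re-shuffled order).  The defaults in `alaam_control()`:

* phase 1 (100 draws, 10 sweeps apart, after 50 burn-in sweeps) estimates
  the per-statistic variance used as a diagonal step-scaling matrix — the
  standard diagonal Robbins–Monro scheme; a full Newton matrix is
  deliberately out of scope.
* phase 2 runs 5 sub-phases with gain $a_k = 0.1/2^{k-1}$ and sub-phase
  lengths growing by 1.5×
  from 50 iterations, averaging $\theta$ over the second half of each
  sub-phase (Polyak averaging stabilises the noisy updates).  The
  sub-phase counts follow common stochastic-approximation practice for
  these models; they are conventions, not derived quantities, and are
  fully configurable.
* phase 3 (1000 draws, thinned every 5 sweeps) yields convergence
  t-ratios $(\bar z_I - z_{\text{obs},I})/\mathrm{sd}(z_I)$ — the fit is
  declared converged when all modelled $|t| < 0.1$ — standard errors from
  the inverse simulated covariance of the modelled statistics, and
  goodness-of-fit t-ratios for *all* implemented statistics, including
  those not in the model, with $|t| < 1.96$ read as adequate.  Up to two
  extra phase-2 passes are run when not converged; failure is reported in
  the object (`converged = FALSE`), never as an error.

Degenerate statistics (zero simulated variance) are flagged with infinite
standard errors rather than inverted.  All randomness flows from one root
seed through a counter-based splitter (`split_seed()`), so fits are
bit-reproducible.

### Missing outcomes

Households lacking an outcome (e.g. missing the second survey wave) can be
handled two ways: `"clamp"` fixes them at zero and never updates them;
`"latent"` (default) treats them as latent — their contribution to the
observed statistics is integrated out by conditional Gibbs imputation with
observed outcomes clamped, and they are re-sampled during model
simulation.  With no missing outcomes the two modes are exactly identical,
which the tests assert.

## Outcome construction

Asset wealth is a first principal component of the standardised household
asset items, pooled over both survey waves so the two waves share one
scale, sign-oriented to correlate positively with the raw item sum, and
cut into pooled quintiles (1 = poorest).  Quintile boundaries come from
the empirical quantiles of the pooled score; equal scores always receive
equal quintiles, so a household with identical responses in both waves
cannot spuriously "change".  (With continuous scores the five pooled
quintile groups are balanced to within one household-wave; exact ties can
unbalance them slightly — we prefer tie-consistency over exact balance.)

The household outcome is $1\{\Delta w_h \neq 0\}$, with `up`, `down` and
`stable` as sensitivity definitions selectable by one argument.  Regional
inequality is the Gini mean-difference index computed on quintile values,
$G = \sum_{ij} |x_i - x_j| / (2 n^2 \bar x)$.  We use quintile values
rather than raw PCA scores because scores can be negative (the Gini is
then undefined); a region with a perfectly uniform quintile distribution
scores $4/15 \approx 0.267$, consistent with an observed baseline average
of about 0.26 under population-wide quintile assignment.  The $n^2$
denominator (not $n(n-1)$) is chosen for that same consistency; the choice
is isolated in `quintile_gini()`.  The regional outcome flags a rise of at
least 2 percentage points of the score, the operational form of an
upper-75th-percentile selection; the $\mu + 0.675\sigma$ normal-theory cut
is reported as a diagnostic but never used for selection, because a fixed
cut is reproducible across datasets.

## The synthetic population generator

The restricted surveillance data cannot be redistributed, so
`simulate_population()` generates populations with the statistical
structure the analysis assumes.  Its defaults *are* the study conditions:
11,834 households in 23 regions, roughly 7.8 individuals per household
with 28% non-resident members, membership spells within 2000–2016, and a
tie network calibrated to mean degree 1.72 and global clustering 0.21 with
a long-tailed degree distribution.

Mechanism: households scatter around region centroids (regions of unequal
expected size; affiliation is nearest-centroid).  Each individual holds a
primary membership; with probability 0.1105 they acquire a second one.
With probability 0.59 the second household is chosen two steps away in the
running tie graph, closing a triangle (this produces the clustering);
otherwise a region is drawn by exponential distance decay (rate 8 on
centroid distances, making most ties co-located) and a household within it
by a lognormal "sociality" weight (log-sd 0.95, producing the heavy degree
tail).  One in ten secondary events is a sequential membership change —
the mover's primary spell is truncated, creating a tie with zero concurrent
years, mirroring ties inferred from membership changes.  The three wiring
parameters were calibrated once against the two descriptive targets (mean
degree within 0.05 of 1.72; clustering within 0.03 of 0.21, checked over
ten seeds in the tests) and then frozen.  Average path length is emulated
only qualitatively: jointly constraining degree, clustering *and* path
length at fixed size would over-constrain this simple mechanism, so path
length is reported, not asserted.

Asset items are binary logistic responses to a standard-normal latent
wealth score with loadings 0.8–1.8 and intercepts spanning −1.2 to 1.2
(items range from rare to common, all wealth-graded, as asset batteries
typically are).  Between waves a household keeps its latent score with
probability 0.2; otherwise the score is redrawn with autocorrelation 0.7
and, optionally, a shift proportional to the mean centred baseline
quintile of same-region network partners (`contagion_strength`).  These
defaults put the share of households changing quintile slightly above 50%
and the average regional inequality near 0.26 at baseline, matching the
study conditions.  Calendar granularity is whole years: tie definitions
need only year-level overlap, so sub-annual survey rounds are collapsed.
Attrition defaults to zero; the missing-outcome group is emulated only
when configured.

What the generator does **not** emulate: demography (births, deaths,
ageing, HIV), true kinship structure, economic covariate dependence
(covariates are independent draws), spatially autocorrelated wealth, or
migration as a process.  Consequently, passing tests demonstrate that the
*pipeline and estimator* behave correctly under the assumed statistical
structure — not that the substantive findings would replicate on real
surveillance data.

## Validation design

Three layers, mirrored in the test suite and the acceptance script:

1. **Oracle equivalence.**  Statistics match an independent loop-based
   recount; local change statistics match global differences; on networks
   of up to 20 nodes the Gibbs sampler's stationary distribution matches
   exact enumeration (total variation below 0.02 at $10^5$ draws) and
   `alaam()` matches grid-search exact maximum likelihood within 0.05.
2. **Parameter recovery at literature-scale effect sizes.**
   `recover_multiplier()` simulates outcomes on ~1,000-household,
   10-region synthetic networks with one focal parameter set to the log of
   a reported odds multiplier (1.27 for same-region contagion, 1.11 for
   the micro-macro link, 1.26 for the external-ties indicator), density
   terms pilot-calibrated to ~50% prevalence, and re-estimates; the median
   exponentiated estimate over ten replicates recovers the multiplier.
   The 1,000-household scale keeps a full recovery study inside minutes on
   one core while leaving enough information for stable estimates.
3. **Null calibration.**  Data simulated at $\theta = 0$ yield estimates
   within three standard errors of zero for at least 90% of effects across
   twenty seeds.

## Known limitations

* The closure statistic is outcome-weighted triangle membership, the
  simplest attribute-closure consistent with standard ALAAM menus; other
  closure variants exist and are not implemented.
* `shared_years` is capped at 16 to match the covariate's documented 0–16
  range, although 2000–2016 inclusive spans 17 calendar years.
* Mean tie duration is aggregated to the household level (mean of
  `shared_years` over incident ties, zero for isolates) before entering
  the model; an edge-level treatment would require edge covariates the
  model family does not use here.
* Path lengths on components larger than 3,000 nodes are estimated from
  seeded BFS source samples (at least 10,000 pairs), not exact all-pairs.
* The estimator uses a diagonal derivative approximation; strongly
  collinear effect sets converge slowly and may need larger phase-2
  settings.
* Regional baseline regressions with 23 observations will often be
  separated; the flagged ridge fallback (penalty $10^{-6}$) keeps them
  finite but their standard errors should be read with care.

## A worked example

```{r example, eval = FALSE}
cfg <- generator_config(n_households = 1000, n_regions = 10, seed = 3)
pop <- simulate_population(cfg)
idx <- wealth_index(pop$assets$wave1, pop$assets$wave2)
y <- household_outcome(idx)
ineq <- regional_inequality(idx, pop$affiliations)
Y <- regional_outcome(ineq)

eff <- alaam_effects(c("h_density", "r_density", "same_region_contagion",
                       "cross_region_contagion", "cross_level",
                       "micro_macro"))
fit <- alaam(y, pop$net, eff, Y = as.integer(Y), seed = 7)
summary(fit)
```

The pipeline wrapper `run_study()` chains all stages (simulation, network
construction, wealth and inequality scoring, baseline regressions, ALAAM
estimation, goodness of fit, report) and writes every artefact to disk;
`ladder_fit()` reproduces the ground-up specification ladder, refusing to
add the micro-macro link before the cross-level interaction is present.
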