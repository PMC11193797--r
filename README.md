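# mlalaam

Multilevel autologistic actor-attribute models (ALAAM) for household
wealth dynamics on inter-household social networks.

## What problem this solves, and for whom

In rural, kin-centred settings a "household" is a social group, not an
address: people hold concurrent memberships in several households or move
between them, and these shared memberships tie households into a support
network along which economic resources flow.  For demographers,
epidemiologists and network scientists working with household panel or
surveillance data, `mlalaam` provides the full analysis chain for asking
whether changes in household asset wealth — and rises in regional wealth
inequality — are associated with position in that network:

* build the two-level network (household ties from membership episodes,
  household-to-region affiliation, derived region-region meta-ties);
* score asset wealth by pooled-wave PCA, assign quintiles, and construct
  the binary household change outcome and the quintile-Gini regional
  inequality outcome;
* fit baseline logistic regressions with average marginal effects;
* fit the multilevel ALAAM itself, with geographically defined
  configurations (co-located vs cross-region ties and contagion, external
  ties, cross-level interaction, micro-macro link);
* validate everything against a calibrated synthetic population
  generator, because the real surveillance data are access-restricted.

## The model

For household outcomes $y$ (did the wealth quintile change?) and regional
outcomes $Y$ (did inequality rise by ≥ 2 points?), conditional on the
household network $A$, region level $B$, affiliation $X$ and covariates:

$$\Pr(y, Y) = \frac{1}{\kappa(\theta)}\exp\sum_I \theta_I\, z_I(y, Y, A, B, X, \ldots)$$

Each statistic $z_I$ counts a configuration (e.g. same-region contagion
$\sum_{(h,h') \in E,\ \text{same region}} y_h y_{h'}$, or the micro-macro
link $\sum_v Y_v \cdot \#\{\text{within-}v\text{ concordant tied pairs}\}$).
$\exp(\theta_I)$ is a conditional odds multiplier.  Estimation is
Robbins–Monro MCMC maximum likelihood over a compiled Gibbs sampler, with
convergence t-ratios (|t| < 0.1), simulation-based standard errors, and
goodness-of-fit t-ratios (|t| < 1.96) for all implemented statistics —
including ones left out of the model.  Networks with at most 20 nodes
admit exact likelihoods by enumeration, which anchor the test suite.

## Worked example

```r
library(mlalaam)
cfg <- generator_config(n_households = 1000, n_regions = 10, seed = 3)
pop <- simulate_population(cfg)
network_summary(pop$net)
#> Network: 1000 nodes, 813 edges
#>   mean degree 1.626 (sd 1.558), clustering 0.249
#>   mean path length 16.54 (sd 7.24) on largest component (510)

idx <- wealth_index(pop$assets$wave1, pop$assets$wave2)
y   <- household_outcome(idx)            # 1 = quintile changed; 48.5% here
ineq <- regional_inequality(idx, pop$affiliations)
Y   <- regional_outcome(ineq)            # 1 = inequality rose >= 2 points

eff <- alaam_effects(c("h_density", "r_density", "same_region_contagion",
                       "cross_region_contagion", "cross_level",
                       "micro_macro"))
fit <- alaam(y, pop$net, eff, Y = as.integer(Y), seed = 7)
summary(fit)
#> Effects (conditional log-odds):
#>                          theta odds_multiplier percent_change     se  conv_t
#> h_density              -0.0342          0.9663        -3.3650 0.0855 -0.0093
#> r_density              -1.0538          0.3486       -65.1392 2.5595 -0.0449
#> same_region_contagion  -0.0828          0.9205        -7.9507 0.0970  0.0271
#> cross_region_contagion  0.0834          1.0870         8.6995 0.1208  0.0415
#> cross_level            -0.0010          0.9990        -0.0996 0.0926 -0.0848
#> micro_macro            -0.1175          0.8892       -11.0843 0.3253 -0.0529
#>
#> Converged: TRUE (threshold 0.10 on |conv_t|)
#> GOF: 13/13 statistics adequate (|t| < 1.96)
```

Here the outcomes were generated by the asset module without network
contagion, and the fit correctly finds no significant network effects
(every interval covers zero) while converging and passing all
goodness-of-fit checks.  The `percent_change` column reads as "one more
unit of this configuration multiplies the odds of the outcome by
`odds_multiplier`", e.g. a coefficient of −0.14 on a configuration would
be a 13% reduction in the conditional odds.

`run_study()` chains every stage end-to-end and writes CSV/JSON artefacts
plus a markdown report; `ladder_fit()` fits the ground-up specification
ladder.

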