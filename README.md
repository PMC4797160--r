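# winterpit

Winter is a survival bottleneck for stream fish, and it is also the
season in which they are hardest to observe: surface ice and snow grow
over the channel and throttle the read range of the antennas used to
track PIT (passive integrated transponder) tagged individuals. A raw
*return rate* — the proportion of tagged fish found at a tracking
occasion — confounds two very different processes: **apparent survival**
φ (surviving *and* staying in the study reach) and **detection
probability** p (being found given present and alive). winterpit
separates the two for weekly winter tracking data on brown trout and
sculpin-like assemblages, and quantifies how detection is driven by ice
growth, tag size and habitat structure while survival follows individual
body condition.

The package provides, end to end:

* **Ice growth** — a snow-coupled Stefan model: thickness
  `h_i = sqrt(2 k_si S' / (rho L))` driven by freezing degree-days `S`,
  with the effective conductivity `k_si = (h_i + h_s) / (h_i/k_i + h_s/k_s)`
  of the layered ice–snow pack solved self-consistently, and snow
  resets after shoveling occasions. The weekly mean thickness becomes a
  detection covariate.
* **Encounter histories** — rule-based processing of tracking records:
  transient classification (never redetected, or no activity beyond
  downstream drift and no spring recapture), mortality truncation at
  the last discernible upstream move, biweekly pooling, per-fish
  covariates (Fulton condition `K = 100 W / L_cm^3`, habitat complexity,
  depth, distance to reach end, tag burden).
* **CJS estimation** — an individual-covariate Cormack–Jolly–Seber
  likelihood with design-matrix model strings such as
  `{phi(t x cond)p(g x ice + complex x t)}`, logit link, analytic
  gradients, multistart BFGS with a simulated-annealing fallback,
  delta-method SEs, and numerical-rank estimability (including the
  classical terminal φ·p confound).
* **Selection and fit** — QAICc ranking with Akaike weights, the
  simulation-based median-ĉ overdispersion estimate, and ĉ-inflated
  standard errors.
* **Association** — single-stratum continuity-corrected Mantel–Haenszel
  test and risk ratio for maturity state vs transience.
* **Synthetic data** — a generator with known ground truth (groups,
  winters, transients, tag loss) so the whole pipeline is testable
  without field data.

## Worked example

Simulate a study bundle (393 tagged fish in three groups, 26 weekly
occasions over a winter) and run the full analysis:

```r
library(winterpit)

d <- simulate_dataset(sim_config(seed = 1))
cfg <- pipeline_config(d$registry, d$tracking, d$winter, d$reach,
  models = c("phi(1)p(g)", "phi(1 + cond)p(g x ice)",
             "phi(1 + cond)p(g x ice + complex)"),
  gof = list(levels = c(1, 1.5, 2), n_rep = 10), seed = 1)
rep <- run_pipeline(cfg)

rep$fate_counts
#>                 fate
#> group            resident transient
#>   sculpin             142        40
#>   juvenile_trout       43         7
#>   adult_trout          97        64

rep$gof
#> Median c-hat: 1.230 (SE = 0.116); observed deviance c = 0.482 on 230 df

rep$ranking
#> Model selection table (QAICc)
#>                               model logLik K qaicc delta    weight
#> 1 phi(1 + cond)p(g x ice + complex)  -1215 9  1994   0.0  9.95e-01
#> 2           phi(1 + cond)p(g x ice)  -1223 8  2005  10.7  4.69e-03
#> 3                        phi(1)p(g)  -1598 4  2606 612.0 1.26e-133
```

The fate table says who stayed analysable: transients (fish that left
the reach, or shed/dead tags) are excluded before fitting. The ĉ of
1.23 reflects the individual heterogeneity in the generating model and
inflates all SEs by √1.23. The ranking recovers the generating
structure — survival driven by condition, detection by group-specific
ice slopes plus habitat complexity — with essentially all QAICc weight.

Real-parameter estimates from the top model show what the raw return
rates hide: biweekly apparent survival is uniformly high
(≈0.998 ± 0.001), while sculpin detection collapses from 0.94 to below
0.1 as the ice thickens and recovers only near breakup:

```r
head(subset(rep$top_p, group == "sculpin"), 4)
#>      group t estimate      se
#> 1  sculpin 2    0.937 0.00924
#> 4  sculpin 3    0.850 0.01479
#> 7  sculpin 4    0.772 0.01705
#> 10 sculpin 5    0.747 0.01744
```

`plot_detection(rep)` draws the per-group detection curves;
`rep$top_phi` holds the survival series; with `out_dir` set,
`run_pipeline()` writes every stage's output (including MARK-style
`.inp` histories for cross-checks with external CMR software) plus a
seed-stamped manifest.

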