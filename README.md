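# cbkit — clustering + burden association tests and mutational hotspot models for rare missense variants

Rare missense variants that cause Mendelian disease often concentrate in
discrete functional regions of a protein, while benign rare variation is
spread roughly uniformly. `cbkit` is an R toolkit for case–control
rare-missense-variant analysis in protein coordinates that exploits both
the *burden* signal (more carriers among cases) and the *clustering*
signal (case variants sit in different places than control variants):

* **BIN-test** — the protein `[1, L]` is cut into `k ≈ n^(2/5)`
  equal-length bins and the binned case/control position counts are
  compared with a Pearson χ² test on the `k × 2` table (empty bins are
  dropped with a df reduction; counts can be adjusted by the reciprocal
  of per-bin mean 10× sequencing coverage).
* **Burden test** — one-sided Fisher's exact test (hypergeometric upper
  tail) for carrier excess in cases.
* **ClusterBurden** — Fisher's-method combination,
  `X = −2(ln p_burden + ln p_cluster) ~ χ²₄`, with the closed-form tail
  `e^(−X/2)(1 + X/2)`, testing the joint hypothesis of excess burden and
  differential clustering.
* **hotspot models** — penalized-spline binomial GAMs
  `logit P(case) = β₀ + β₁·carrier + s(position, by = carrier)` (REML
  smoothing, coverage-weighted likelihood) that yield a per-residue
  odds-ratio map `OR(x) = exp(β₁ + s(x))` with 95% CIs and ACMG-style
  evidence strata (OR ≥ 5 / 10 / 20 / 100 → weak / supporting /
  moderate / strong).
* **hotspot+ models** — the hotspot GAM plus in-silico predictor scores
  as carrier-nested linear terms, selected by a strict two-stage
  Bonferroni procedure (0.05/24 marginal screen, then backwards
  elimination), evaluated by held-out AUC over ten stratified 80/20
  splits.
* **simulator & evaluation harness** — a generative case–control
  simulator (benign background + clustered pathogenic variants with
  incomplete penetrance and an ultra-rare AF spectrum), `(r+1)/(n+1)`
  power/type-I-error estimation, a Fisher-independence diagnostic, and
  post hoc sample-size-equivalence calculations via non-centrality
  scaling.

Inputs are tab-separated variant tables in protein residue coordinates
(columns `gene`, `protein_position`, `cohort`, `carrier_count`,
`popmax_af`, optional score columns), optional per-residue coverage
profiles, and optional score tables; everything can also be simulated.
Analyses target ultra-rare variants (popmax AF < 1e-4 by default;
missing AF is kept).

## Worked example

Simulate a 500-residue gene with a single pathogenic cluster at
residues 100–175 (500 cases, 5000 controls), then test it:

```r
library(cbkit)

sc  <- SimulationScenario("single_cluster", L = 500L,
                          nCases = 500L, nControls = 5000L)
sim <- simulateGene(sc, seed = 7)
clusterBurden(sim@dataset)
#> TestResult: sim_single_cluster (85 case / 203 control variant records)
#>   burden (one-sided)   p = 7.599e-58
#>   BIN-test             p = 1.379e-25  (X2 = 142.366, df = 10)
#>   ClusterBurden        p = 1.989e-80
```

The burden test sees the carrier excess, the BIN-test sees the
positional shift (χ² = 142.4 on 10 df), and ClusterBurden combines them
into a single, stronger association p-value.

Fit the hotspot model and read off per-residue odds ratios:

```r
m <- fitHotspot(assembleGamFrame(sim@dataset))
predictPositionOR(m, c(50L, 137L, 300L))
#>   position    log_or        se        or     ci_low   ci_high evidence
#> 2       50 0.4360224 0.4674323  1.546544  0.6186937  3.865882     none
#> 3      137 3.8166478 0.2106382 45.451589 30.0780893 68.682786 moderate
#> 4      300 0.4486774 0.4801366  1.566239  0.6111638  4.013827     none
```

Residue 137 lies inside the simulated cluster: a carrier there has 45
times the case odds of a non-carrier (95% CI 30–69), moderate evidence
on the hotspot scale; residues outside the cluster sit at OR ≈ 1.5 —
the gene-wide background burden.

How many more samples would the burden-alone test need to match a
combined result? For observed p-values 1e-4 (burden) and 1e-6
(combined):

```r
posthocMultiplier(1e-4, 1e-6)[c("multiplier", "percent_increase")]
#> $multiplier    1.658779
#> $percent_increase    65.87791
```

A command-line wrapper over the same functions lives at
`inst/scripts/cbkit.R` (subcommands `simulate`, `scan`, `power`,
`hotspot`).

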