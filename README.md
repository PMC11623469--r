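# ccdpanel

Coupling coordination analysis of regional environment–health panels in R.

`ccdpanel` measures how synergistically two composite regional indices — an
ecological environmental civilization (EEC) index and a resident public
health (RPH) index — develop together across a panel of units (e.g. 31
provinces observed over 13 years), and asks what drives that synergy. It is
aimed at researchers in environmental health, regional science, and
sustainability who work with yearbook-style indicator panels.

## The model

Each subsystem is scored by the **entropy weight method**. Indicators are
min–max normalized by attribute sign (pooled over all units and years),

- positive: x′ = (x − min x) / (max x − min x)
- negative: x′ = (max x − x) / (max x − min x),

then weighted by their information content: with proportions
p\_ijt = x′\_ijt / Σ\_{i,t} x′\_ijt and entropy
e\_j = −(1/ln N) Σ p ln p (N = units × years), the weight is
w\_j = (1 − e\_j) / Σ\_j (1 − e\_j) and the subsystem score is
U = Σ\_j w\_j x′\_ijt ∈ [0, 1].

The **modified coupling coordination degree** of the two scores
(U₂ = max(U₁, U₂)) is

    C = [1 − (U₂ − U₁)] · √(U₁/U₂)      (coupling degree)
    T = ½U₁ + ½U₂                        (coordination index)
    D = √(C·T)                           (coupling coordination degree)

classified into ten decile levels from extreme non-coordination to
excellent coordination. Unlike the traditional product form, this C spreads
over the whole [0, 1] interval and equals 1 exactly when the subsystems
match.

Around the CCD the package provides the full spatiotemporal toolkit:

- **Dagum Gini decomposition** — yearly inequality G split exactly into
  within-region, net between-region, and transvariation (overlap) parts;
- **kernel density estimation** — Gaussian KDE of the cross-sectional CCD
  distribution per year and region, with mode/peak/tail summaries;
- **Markov chains** — pooled-quartile states, the traditional transition
  matrix, spatially conditioned matrices by neighbour (spatial-lag) class,
  and global Moran's I with permutation inference (plus a panel-level
  pooled-years Moran test);
- **panel Tobit** — a random-effects two-limit Tobit of the CCD on five log
  socio-economic drivers (per-capita GDP, urbanization, openness, education,
  government health expenditure), fitted by adaptive Gauss–Hermite
  quadrature, nationally and per region;
- **a synthetic generator** — panels with rising latent levels, regional
  offsets, spatial spillover (SAR with strength ρ), and missing cells, so
  the whole pipeline runs with no external data.

## Worked example

```r
library(ccdpanel)

cfg    <- synthetic_config(seed = 42)      # 31 units x 2010-2022, rho = 0.6
sim    <- generate_panel(cfg)
panel  <- impute_linear(sim$panel)         # fill deleted cells
scored <- score_subsystems(panel)          # entropy weights + U scores
tbl    <- ccd_panel(scored$scores)         # C, T, D, level per unit-year

head(tbl, 3)
#> # A tibble: 3 x 8
#>   unit   year U_EEC U_RPH     C     T     D level
#> 1 P01    2010 0.507 0.624 0.796 0.565 0.671 Primary coordination
#> 2 P01    2011 0.505 0.729 0.646 0.617 0.632 Primary coordination
#> 3 P01    2012 0.462 0.644 0.693 0.553 0.619 Primary coordination
```

`U_EEC`/`U_RPH` are the two subsystem development levels; `D` combines their
match (C) and joint level (T). The national mean rises from near
coordination to intermediate coordination over the window:

```r
smry <- ccd_summary(tbl, sim$region_map)
smry[smry$scope == "National", ][c(1, 7, 13), ]
#>    year scope        D level
#> 1  2010 National 0.574 Near coordination
#> 2  2016 National 0.680 Primary coordination
#> 3  2022 National 0.786 Intermediate coordination

dagum_gini(tbl$D[tbl$year == 2022],
           sim$region_map$region[match(tbl$unit[tbl$year == 2022],
                                       sim$region_map$unit)])
#> Dagum Gini decomposition
#>   G = 0.0457 = within 0.0149 + between 0.0126 + transvariation 0.0181
#>   contribution rates: 32.63% / 27.64% / 39.73%
```

So in 2022 total cross-unit inequality in D is G = 0.046, of which about a
third lies within regions and 40% in the overlap (transvariation) between
them. Persistence and spatial structure:

```r
transition_matrix(discretize_ccd(tbl))
#> Markov transition probability matrix (traditional, 372 transitions)
#>                low lower-middle upper-middle  high
#> low          0.713        0.238        0.050 0.000
#> lower-middle 0.072        0.454        0.361 0.113
#> upper-middle 0.010        0.219        0.427 0.344
#> high         0.013        0.038        0.231 0.718
```

Diagonal dominance in the corner states is the "club convergence" pattern:
low and high units tend to stay where they are. The whole chain — including
the spatial Markov matrices, yearly Moran's I, KDE curves, and the Tobit
fits — runs in one call:

```r
res <- run_ccd_pipeline(out_dir = "ccd-output", synthetic = cfg)
```

which writes one tidy CSV per stage plus a JSON run manifest. A thin CLI
with per-stage subcommands lives at `inst/cli/ccd-pipeline.R`:

```sh
Rscript inst/cli/ccd-pipeline.R simulate --seed 42 --out sim
Rscript inst/cli/ccd-pipeline.R run-all  --seed 42 --out results
Rscript inst/cli/ccd-pipeline.R gini --panel sim/panel.csv \
    --regions sim/regions.csv --edges sim/edges.csv --out gini-only
```

## Documentation

The methods vignette (`vignettes/ccd-methods.Rmd`) documents the model
choices, default parameters, the structure the synthetic generator does and
does not emulate, and numerical details (entropy denominators, tie rules,
quadrature, degenerate inputs).
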