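# syntromix

Individual-based simulation of a two-species biofilm that trades **food for
detoxification**, with the analysis pipeline used to characterise such
communities: interaction classification, spatial segregation, productivity,
frequency dynamics, and demographic-feedback diagnostics.

## The science

A producer **A** grows on a shared nutrient **R** diffusing in from the
liquid bulk and excretes a by-product **E** that inhibits its own growth
(simple inhibition, `1/(1 + E/K_tox)`). A cross-feeder **B** consumes E —
feeding itself while detoxifying its partner's microenvironment. Growth is
Monod throughout; B's reliance on E versus R is a single obligacy weight
`omega`:

```
mu = (1 - omega) * mu_max_R * R/(K_R + R) * 1/(1 + E/K_tox)
   +      omega  * mu_max_E * E/(K_E + E)
```

Cells are discrete agents on an inert surface: they grow on local
concentrations, divide at a threshold radius, and shove overlapping
neighbours apart. Solutes are solved to quasi-steady state on a 2D grid
each timestep (sparse Newton–Picard reaction–diffusion solver, cyclic /
zero-flux / bulk-permeable boundaries). Sweeping by-product toxicity
against cross-feeder obligacy produces the full range of ecological
outcomes — competition, exploitation, mutualism — and the corresponding
spatial signatures, from segregated towers to intermixed branching
lineages held together by negative frequency-dependent selection.

The neighbourhood **segregation index** quantifies lineage mixing: for each
cell the fraction of neighbours within 10 µm of its own species, averaged
per species and normalised by global frequency, `s = (seg - p)/(1 - p)`;
1 = clonal patches, 0 = random mixing, negative = over-mixed.

## Worked example

```r
library(syntromix)

## strong interdependence: obligate cross-feeder, highly toxic by-product,
## fully mixed two-microcolony inoculum (60 + 60 cells)
scn <- build_scenario("segregation_sweep", toxicity = 5, obligacy = "B_obl",
                      initial_segregation = 0, dt = 0.1)
tr <- run_simulation(scn, seed = 1)
tr
#> <syn_trajectory> scenario: segregation_sweep  seed: 1
#>   times: 0 .. 96 h in 9 snapshots
#>   final counts: A:536  B_obl:911
producer_fraction(tr)[c(1, 5, 9), ]
#>   time_h producer_fraction
#> 1      0         0.5000000
#> 5     48         0.3751584
#> 9     96         0.3704216
```

Starting from half producers, the community relaxes toward roughly one
third producers — the stable coexistence frequency set by the by-product
budget (production `gamma_E * mu * X_A` balancing consumption
`mu * X_B / Y_E`). Rare lineages are favoured, so the same frequency is
reached from other starting proportions.

```r
cells <- tr$snapshots[[length(tr$snapshots)]]$cells
segregation_index(cells, radius = 10, width = 260, cyclic = TRUE)$s
#>         A     B_obl
#> 0.1759600 0.1839778
```

Low `s` for both species: strong metabolic interdependence keeps the
lineages intermixed. Re-running the toxicity ladder at fixed obligacy
(see `tests/testthat/test-acceptance.R`) shows mean `s_A` falling as the
by-product becomes more toxic — mixing tracks the need for detoxification.

There is also a small CLI:

```sh
Rscript -e 'syntromix::syn_main()' list-scenarios
Rscript -e 'syntromix::syn_main()' run --scenario grid_cell --seed 1 \
    --out out/ --override toxicity=5 --override obligacy=B_obl
Rscript -e 'syntromix::syn_main()' analyze --run out/ \
    --stats segregation,frequency --out stats.csv
```

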