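# mycoGraze

Survey analysis for macrofungal communities under forest grazing
(silvopasture). The package is aimed at field mycologists and community
ecologists who record sporocarp-forming fungi (and slime molds) in nested
quadrat designs — forest types × {grazed, ungrazed} plots, 400 m² quadrats
split into 100 m² subquadrats — and need the full before/after analysis:
validated data tables, distance-based sporocarp-to-individual coding,
alpha-diversity indices, rank-based treatment comparisons with effect
sizes, a dominance (importance-value) index over species and trait
partitions, ordination against litterfall/plant-remains covariates, and
spore morphometric notation. A seeded synthetic-survey generator makes the
whole pipeline testable without field data.

## The statistics at the core

For a sampling unit or stratum with species abundances `n_i`, total `N`
and species count `S`:

* **Simpson's diversity** `Div = 1 − Σ (n_i/N)² ∈ [0, 1]`
* **Pielou's evenness** `Eve = −Σ (n_i/N) ln(n_i/N) / ln S ∈ [0, 1]`
  (undefined when `S ≤ 1`)
* **Margalef's richness** `Ric = (S − 1)/ln N ≥ 0`

Grazed vs ungrazed contrasts use the two-sided **Mann–Whitney U** test
(α = 0.05) and **Cliff's delta** `δ = 2U/(n₁n₂) − 1`, with the smaller U
reported (so δ ≤ 0 and direction is carried by a separate arrow code) and
magnitude bands negligible/minor/moderate/large at |δ| cut points
0.147 / 0.33 / 0.474.

Group dominance on any classification axis (species, order, trophic,
attachment, sporocarp type, geographic component, edibility):

```
Dom_j = { (q_j/Q) / Σ_i(q_i/Q) + n_j/N } / 2  ∈ [0, 100%]
```

with `q_i` per-species unit occupancy and `Q` the stratum's unit count;
group occupancy is additive over member species, so every complete
partition sums to exactly 100%.

Spore measurements are summarised in the notation
`{a/b/c} (d) e–f (g) [h ± i, j]` with `[e, f]` covering ≥ 90 % of values.

## Worked example

```r
library(mycoGraze)

cfg <- simulationConfig(seed = 42)   # defaults = the standard study design
ds  <- generateDataset(cfg)
ds$survey
#> FungalSurvey: 185 observation(s) of 86 species over 72 sampling unit(s)
#> SurveyDesign: 3 forest type(s) x {ungrazed, grazed}; 3 quadrat(s) (400 m2)
#>   x 4 subquadrat(s) (100 m2); analysis level: subquadrat

b <- runFullAnalysis(ds$survey)
b$diversityComparison[b$diversityComparison$stratum == "General",
                      c("variable", "U", "p", "delta_text", "conclusion")]
#>         variable     U     p delta_text conclusion
#>  Diversity index 311.5 0.002     -0.442     ↑ * ++
#>   Evenness index 191.5 0.010     -0.420     ↑ * ++
#>  Richness index  326.0 0.003     -0.416     ↑ * ++
```

Each row compares the 36 ungrazed against the 36 grazed sampling units:
the reported (smaller) Mann–Whitney U, its two-sided p, Cliff's delta from
that U, and the conclusion code — here all three indices increase
significantly after grazing with moderate effects, matching the planted
simulation truth. The environment table reads the same way (litterfall
layers drop, plant remains rise):

```r
b$environmentComparison[b$environmentComparison$stratum == "General",
                        c("variable", "U", "p", "delta_text", "conclusion")]
#>               variable     U     p delta_text conclusion
#>     Undecomposed layer 314.0 0.000     -0.515    ↓ * +++
#>  Semi-decomposed layer 289.0 0.000     -0.554    ↓ * +++
#>       Decomposed layer 581.5 0.345     -0.103        ↓ -
#>  All litterfall layers 279.5 0.000     -0.569    ↓ * +++
#>    Large plant remains 204.0 0.000     -0.685    ↑ * +++
```

Species pools, dominance and ordination:

```r
b$venn[c("total", "shared", "uniqueGrazed", "uniqueUngrazed")]
#> 86 total = 17 shared + 53 grazed-only + 16 ungrazed-only

head(b$dominance[b$dominance$stratum == "General" &
                 b$dominance$axis == "trophic", ], 3)
#>  treatment rank           group dominance_display
#>   ungrazed    1   alga symbiont            59.05%
#>   ungrazed    2 wood saprotroph            25.84%
#>   ungrazed    3 soil saprotroph             6.48%

round(b$ordination$integrated_subquadrat$explained[1:3], 3)
#> 0.426 0.301 0.106   # variance fractions of the first three components
```

Morphometrics:

```r
v <- generateMeasurements(40, 6.2, 0.45, seed = 42)
formatNotation(summarizeMeasurements(v, nSporocarps = 3, nCollections = 2))
#> "{40/3/2} (5) 5.5–7 [6.18 ± 0.56, 6.00]"
```

A command-line wrapper is in `inst/scripts/mycograze.R`
(`simulate`, `report`, `diversity`, `compare`, `dominance`, `pca`,
`individuals`, `sporometrics`); see `?surveyCli`.

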