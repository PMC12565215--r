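---
title: "Methods: quantifying grazing impacts on macrofungal communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying grazing impacts on macrofungal communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycoGraze)
```

## The survey model

mycoGraze analyses nested quadrat surveys of macrofungal communities that
contrast grazed with ungrazed forest plots. The sampling design is
hierarchical: within each forest type, one grazed and one ungrazed plot; in
each plot, quadrats of 400 m² subdivided into four 100 m² subquadrats. The
subquadrat is the minimum recording unit; with the default three quadrats a
plot type holds 12 sampling units. Where the nominal quadrat count and the
reported unit count disagree in a survey's documentation, the package treats
the number of sampling units per plot type (12) as authoritative, because
every downstream sample size (n = 12 per plot type, n = 36 pooled) follows
from it; the analysis level (subquadrat versus quadrat) remains an explicit
parameter, defaulting to subquadrat.

Observations are long-format rows (unit, species, individual number): sparse
field data make a tidy long table a better primary format than a wide
species × unit matrix, so absent combinations are implicit zeros and
`wideToLong()` converts matrices on the way in. Unit keys are hierarchical
strings `forest/treatment/quadrat/subquadrat`; quadrat-level analysis pools
the four subquadrats by summing individual numbers and OR-ing presence.

### From sporocarps to individuals

Because fungal individuals are mostly unobservable mycelia, abundance is
coded from sporocarp spacing. Conspecific sporocarps within a unit chain
into one group whenever neighbours are ≤ 2 m apart (single linkage; the
split between groups is strict at > 2 m), and each group is coded by its
largest within-group nearest-neighbour gap *g*: a singleton is 1; *g* ≤ 0.5 m
is 2; *g* ≤ 1 m is 3; *g* ≤ 2 m is 4, all thresholds inclusive. "Adjacent
sporocarps inside the group" is read as the nearest-neighbour gap under
single linkage — the chain reading is the only computable one consistent
with groups being linkage components. A species' recorded individual number
in a unit is the **sum** of its group codes; how multiple groups combine is
a genuinely open convention, so `individualNumber(..., combine = "max")`
provides the alternative. Points are never clustered across subquadrats,
since the subquadrat is the recording unit.

## Statistics

### Diversity indices

Per sampling unit or stratum, with $n_i$ the individual number of species
$i$, $N = \sum_i n_i$ and $S$ the species count:

* Simpson's diversity $Div = 1 - \sum_i (n_i/N)^2 \in [0, 1]$;
* Pielou's evenness $Eve = -\sum_i (n_i/N)\ln(n_i/N) / \ln S \in [0, 1]$;
* Margalef's richness $Ric = (S-1)/\ln N \ge 0$.

Natural logarithms throughout. $Eve$ is reported as undefined (`NA`) when
$S \le 1$ — not 0 or 1 — because the $\ln S$ denominator vanishes; report
tables render it blank, and the ordination imputes it (below). $Ric$ at
$N = 1$ is defined as 0, the $S = 1$ limit. Indices are carried at full
precision and rounded (3 decimals) only in rendered tables.

### Comparison: Mann–Whitney U, Cliff's delta, conclusion codes

Grazed and ungrazed samples are compared with the two-sided Mann–Whitney U
test at α = 0.05 — the deliberate, assumption-light answer to the partial
non-independence of subquadrats nested in quadrats (no mixed model is
fitted; that is out of scope by design). Midranks handle ties; the p-value
is exact (full null distribution) when the pooled sample is tie-free with
$n_1 + n_2 \le 25$, otherwise a normal approximation with tie correction
and a 0.5 continuity correction.

Effect size is Cliff's delta, $\delta = 2U/(n_1 n_2) - 1$. The **reported**
U is $\min(U_1, U_2)$, which makes every reported delta ≤ 0; the direction
of change is carried separately by the conclusion code. This convention is
adopted because it is the only one consistent with all published instances
the package mirrors. Magnitude bands: negligible $|\delta| < 0.147$, minor
$0.147 \le |\delta| < 0.33$, moderate $0.33 \le |\delta| < 0.474$, large
$|\delta| \ge 0.474$.

The conclusion code renders direction (sign of the grazed-minus-ungrazed
median difference; on an exact median tie, the sign of the mean-rank
difference; `|` only when both vanish), a `*` for p < α, and the effect
symbol `-`/`+`/`++`/`+++`. Even-sized medians are midpoints of the central
order statistics. Deltas render at 3 decimals, keeping a 4th digit when the
3-decimal rounding is ambiguous (an exact `-0.6875` stays `-0.6875`);
rendering rounds half away from zero, so `-0.8125` prints `-0.813`.

### Dominance index

For a group $j$ of species on any classification axis (species identity,
taxonomic order, trophic type, substrate attachment, sporocarp type,
geographic component, edibility),

$$Dom_j = \frac{1}{2}\left[\frac{q_j/Q}{\sum_i q_i/Q} + \frac{n_j}{N}\right]
\in [0, 100\%],$$

with $q_i$ the number of units occupied by species $i$ and $Q$ the unit
count. Group occupancy $q_j$ is **additive** over member species
($q_j = \sum_{i \in j} q_i$), not "units where any member occurs": only the
additive reading makes every complete partition sum to exactly 100%, which
published binary-axis tables satisfy row by row; the literal reading is
available via `occupancy = "literal"`. Ranking uses unrounded values, ties
share a rank (and can extend a top-k table), and percentages round to 2
decimals at display time only.

### Ordination

The feature matrix joins per-unit indices (Div, Eve, Ric) with the
environment covariates: the three litterfall-layer thicknesses (cm), their
total, and the ordinal 1–4 abundance of large plant remains treated as
numeric. PCA is run on **standardised** columns (correlation PCA): the
variables mix centimeters, ordinal levels and unitless indices, so
covariance PCA would be dominated by measurement units. Zero-variance
columns (for example a decomposed layer that is 0 in every plantation unit)
are removed first and reported. Undefined evenness is imputed as 0 with a
warning — units holding a single species carry minimal evenness information
— with row-dropping available via `naAction = "drop"`. Component signs are
fixed (largest-magnitude loading positive) so results are reproducible
bit-for-bit. The layer total is kept alongside its three summands, as the
standard stratifications list all four; the induced collinearity simply
concentrates variance in fewer components. No significance testing of
loadings is attempted; `correlationSummary()` gives the pairwise Pearson
correlations with direction/strength labels instead.

### Spore morphometrics

Descriptions use the notation `{a/b/c} (d) e–f (g) [h ± i, j]`: *a* spores
from *b* sporocarps in *c* collections; [e, f] covering ≥ 90 % of values;
extremes d and g shown only when outside [e, f]; mean h, sample (n−1) SD i,
mode j. No published quantile rule pins down e–f, so the package uses the
symmetric trimmed range snapped outward to the 0.5 µm recording grid and
then shrunk grid-step-wise while coverage holds, making each bound
grid-minimal; mode ties resolve to the smallest value. The length/width
shape ratio is computed per spore before summarising, with snapping
disabled (2-decimal reporting). `parseNotation()` inverts
`formatNotation()` exactly at the stored precision.

## The synthetic-survey generator

`generateDataset()` emits a complete, validated survey whose defaults *are*
the study conditions the analysis targets: three forest types × two
treatments × 12 units; species pools partitioned 17 shared / 53 grazed-only
/ 16 ungrazed-only; geometric-series abundances with concentration θ = 0.8
ungrazed (monopolistic dominance) versus θ = 0.3 grazed (balanced) — one
parameter sweeps the dominance axis, which is why a geometric series was
chosen over a log-series; per-unit presence probability
$1 - (1-\pi)^{\lambda_i}$ with base rate π = 0.15 and $\lambda_i$ the
species' expected per-unit abundance (mean 12 individuals per unit);
individual-number codes drawn from 1–4 with abundance-weighted
probabilities; trait frequencies that favour alga symbionts and ascomycetes
ungrazed and wood saprotrophs, agarics and polypores grazed, with the
ungrazed pool's geographic components restricted to
cosmopolitan/pantropical; litterfall layers gamma-distributed on a 0.25 cm
grid around per-forest means (2.5/1.25/0.5 cm in the secondary forest,
1.0/0.5/0 cm in plantations — the zero decomposed layer deliberately
produces the zero-variance column the ordination must drop), halved under
grazing; and a +1 ordinal shift of the remains level under grazing. Every
pool species is forced to occur at least once in its treatment so the
configured species-set partition is realised exactly.

What the generator does **not** emulate: spatial autocorrelation between
neighbouring subquadrats, temporal turnover, phylogenetic correlation of
traits, and observation error in species identification. Passing recovery
tests therefore demonstrates that the pipeline detects effects of the
planted kind at the survey's sample sizes — not that real communities meet
the generator's independence assumptions.

Two calibration facts are worth stating plainly. First, with the default
effect sizes the pipeline flags the planted richness increase, litterfall
decrease and remains increase essentially always at n = 36 per side.
Second, under a no-effect configuration the pooled comparison is
*conservative* (observed false-positive rates well below α): the pooled
samples are balanced across forest types (a stratified, not iid, layout)
and exact pool realisation couples units within a treatment, both of which
shrink between-group rank differences relative to the iid null. The test's
level is still respected — rejection rates stay below nominal — which is
the property the pipeline needs.

## Problem sizes and numerical choices

The validation suite runs everything at the survey's own scale (72 units,
86 species) or smaller; Monte Carlo checks use 100 seeds for effect
recovery, 500 for null calibration, 1,000 random cases for the oracle
equivalences (rank statistics, dominance partitions, notation round-trips)
and 200 planted point sets for the clustering — sizes chosen so each
property is measured at tight binomial resolution while the whole suite
stays interactive. Exact rational arithmetic is used wherever the formulas
allow (delta from U, dominance shares); tolerances of 1e−9 to 1e−12 guard
the algebraic identities; linkage thresholds are inclusive; all rendering
happens at the edge, never inside the pipeline.

## Known limitations

* The Mann–Whitney p-value convention (exact versus corrected normal) is a
  package choice; published p-values from other software may differ in the
  third decimal, which is why only U-derived quantities are treated as
  reproducible.
* The dominance index has no attached inferential test, deliberately.
* Evenness imputation at 0 biases pooled PCA loadings for extremely sparse
  units; prefer `naAction = "drop"` when many units hold single species.
* The individual-number coding is a survey convention, not a claim about
  genets; its sum-of-codes convention is one of two defensible readings.
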