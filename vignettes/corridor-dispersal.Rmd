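---
title: "Corridor dispersal along linear landscape elements: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corridor dispersal along linear landscape elements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(corrscape)
```

## The question and the inference logic

In intensively farmed landscapes most plant species cannot live in, or move
through, the field matrix. Linear landscape elements (LLE) — field margins,
road verges, ditches — are both the remaining habitat and the candidate
corridors. Direct observation of plant dispersal is impractical, so the
pipeline uses an indirect contrast: the floristic similarity of plot pairs
is modelled once against plain Euclidean distance and once against the
effective resistance of the element network between the plots. Euclidean
distance-decay is the null expectation of any spatial community process
(environmental gradients, shared history, dispersal through any medium).
Resistance distance additionally encodes the number, width and continuity of
connecting elements. If similarity decays *more steeply* in resistance than
in Euclidean distance, the surplus decay is attributed to dispersal along
the elements.

The assumptions this logic rests on, and which the synthetic generator makes
explicit, are: (i) communities started from low, quasi-random initial
similarity (the element networks are only a few decades old) and similarity
has since accumulated through dispersal; (ii) no unmeasured environmental
gradient is correlated with network connectivity but not with distance;
(iii) pairwise similarity is informative about pairwise exchange even though
each plot takes part in several pairs — which is why the models carry random
intercepts for both plots of a pair.

## Resistance surface

Element polygons (centreline plus width) are rasterised at 1-m resolution by
a centre-point test: a cell is habitat iff its centre lies within
`width / 2` of the centreline. Habitat cells get resistance 0.01 per cell
(conductivity 100, an arbitrary but fixed unit), the matrix is infinite.
Every matrix cell whose centre lies within 5 m of a habitat cell centre
becomes a buffer cell at the doubled resistance 0.02. Growing from both
sides, the buffer closes any inter-polygon gap narrower than 10 m — small
gaps are assumed crossable, but at a cost — while wider gaps stay
impassable. Buffering is idempotent (buffer cells do not seed further
buffering) and never overwrites habitat cells. Each study area's raster
covers the area square plus a configurable frame (500 m by default) so that
currents are not artificially confined at the map edge.

Numerical conventions, chosen where no single standard exists and fixed
here: ESRI ASCII grid serialisation with `NODATA` for infinite resistance;
row 1 is the northernmost row; internal indexing is (row, column); buffer
distance is measured centre-to-centre, which makes the operation exactly
testable on grids.

## Effective resistance

The finite cells form a conductance graph: one node per cell, edges between
neighbouring cells with conductance equal to the mean of the two cell
conductances, divided by √2 for diagonal edges. The 8-cell neighbourhood
with this averaging rule is the default because it is the convention of the
widely used circuit-analysis raster tools; the tool chain the approach
descends from does not document its convention, so this is an explicit
assumption, and the 4-neighbour variant is available for tests. The
effective resistance between nodes a and b is obtained by grounding b,
injecting a unit current at a, and solving the reduced Laplacian system with
a sparse Cholesky factorisation (`Matrix::Cholesky`); the potential at a is
the resistance. For all pairs among the plots of one study area the
factorisation is computed once per connected component and reused:
`R(i, j) = v_i[i] + v_j[j] − 2 v_i[j]` with `v_k` the grounded solve for
injection at k.

Plots are snapped to the nearest finite cell within 5 m (ties broken by
(row, column) order, deterministically); a plot further than that from the
network is an error, not a silent repair. Pairs in different components are
flagged disconnected and *excluded* from the models — infinite resistance is
not on the modelled scale and a large stand-in constant would fabricate
leverage. So that the resistance and Euclidean slopes of one species set are
estimated on identical observations, both models use only the connected
pairs.

The solver is verified in the test suite against closed-form series and
parallel laws, against an independent dense Moore–Penrose pseudo-inverse
oracle (`R_ab = L⁺_aa + L⁺_bb − 2 L⁺_ab`) on random graphs, and for
Rayleigh monotonicity (adding a path never increases any resistance) and
scale equivariance.

## Similarity, coding, and the pair table

For every unordered within-area plot pair, `J = c / S` is computed for each
species set: all species, each phytosociological group, each
dispersal-distance class, and the aquatic-dispersal overlap class. A pair
with an empty union for a set keeps its row with `J = NA` and is dropped
per model, not globally, so one sparse group does not shrink the sample of
the others. Similarity enters the models as binomial proportion data —
`c` successes of `S` trials. The trial count is the union size `S`: it is
the only weighting under which `J` is literally a binomial proportion, and
this choice matters because no weighting convention is self-evident for a
similarity index. Sets in which more than half of the defined pairs share no
species are coded binary instead (`J > 0` yes/no); the threshold is
configurable, the automatic rule reproduces the intended "many zeros"
behaviour, and binary sets never receive an observation-level effect.

Isolation measures are z-transformed (sample standard deviation, n − 1) over
the rows entering each model, and the transform parameters are stored with
the fit so predictions can be asked for on the data scale. Computing the
transform per model keeps the coefficients of a model internally comparable
even after per-model row exclusions.

## The mixed models

Each species set × isolation measure is fitted as a binomial-logit GLMM with
fixed effects `isolation_z * lle_combo` (baseline margin–margin; six
parameters when all three combinations occur) and crossed random intercepts
for study area, plot A and plot B, via `lme4::glmer` (Laplace
approximation). Overdispersion of proportion models is assessed by the
Pearson ratio (summed squared Pearson residuals over residual df, counting
fixed and variance parameters) with a χ² test at α = 0.05; a significant
ratio adds an observation-level random intercept, the standard absorber of
extra-binomial variation.

**Simple slopes.** The margin–margin slope is the isolation main effect; the
other combinations add the interaction, with standard error
`sqrt(se_main² + 2·cov(main, int) + se_int²)`. The covariance is taken from
the fitted model's fixed-effect covariance matrix — the only place such a
covariance exists. Each slope is t-tested twice, under
`df_max = N − p − g − 1` (N pairs) and `df_min = n − p − g − 1` (n plots);
`df_min` is the conservative, headline p-value. `n` is always the number of
plots actually entering the model rather than a fixed constant, which also
resolves the ambiguity of a survey that samples 50 plots but uses 49.

**Slope differences.** Resistance vs Euclidean slopes are compared with
`Z = (b₁ − b₂)/sqrt(se₁² + se₂²)` against the standard normal; the statistic
is antisymmetric under swapping the measures and invariant to common
rescaling.

**Parametric bootstrap of the main effect.** The null model removes the
isolation main effect *and* its interaction — a main effect cannot be
removed while its interaction stays. Responses are simulated B times from
the fitted null with the random effects redrawn (unconditional bootstrap),
both models are refitted to each draw, and
`p = (1 + #{LRT* ≥ LRT_obs}) / (B + 1)`, the standard Monte-Carlo estimator
that cannot return zero. For desk-scale runtimes all likelihood-ratio
statistics in this test — observed and simulated — are computed on the
PIRLS-profiled (`nAGQ = 0`) deviance scale with the variance parameters
re-optimised per replicate; observed and bootstrap statistics are therefore
exactly comparable, and the calibration of the procedure is itself verified
by a type-I-error simulation in the acceptance tests.

**Linearity.** A goodness-of-link check orders the Pearson residuals of a
fixed-effect GLM variant (study area as a factor, since cumulative-residual
software does not accept mixed models) by the isolation predictor and takes
the supremum of the absolute cumulative process, normalised by √n. The null
distribution uses a wild bootstrap with Rademacher weights — a deliberate
simplification of the classical score-resampling construction with the same
calibration target, checked by simulation (near-nominal size under a linear
logit, high rejection under a quadratic one).

**Predictions.** `predict_jaccard()` evaluates the fixed-effect predictor at
a data-scale isolation value with random effects at zero (population-level
conditioning, the standard `glmer` convention; marginalising over the
random effects would shrink every prediction toward 0.5 and is not what the
coefficient tables describe). The prediction table takes each measure from
its observed maximum to its observed minimum over the margin–margin rows of
the model — the combination where corridor effects are expected and
reported — and converts the difference in predicted gains to species counts
by `Δc = round(ΔJ × S̄)`, with `S̄` the mean union size of the same rows; a
switch widens both to all rows.

## The synthetic generator

The generator exists so that every stage has data with known ground truth.
Per study area it draws Poisson-spaced vertical and horizontal boundary
lines (a rectangular field mosaic; mean spacing `width̄ / density`, which
offers about twice the boundary length needed), grows a *connected* random
subset of boundary segments until a target LLE areal density drawn from
2.5–10 % is reached, assigns widths (2–5 m) and types (ditch with
probability 0.4), deletes gap intervals at a configurable rate (default 1
per km, lengths 4–15 m so that some gaps are closable by the 5-m buffer and
some are not), and places 5–8 plots on ≥ 2-m-wide elements with a minimum
spacing (100 m at full scale). Plot placement retries an unlucky mosaic a
bounded, deterministic number of times; a genuinely infeasible configuration
fails naming the area and the achieved count. All randomness derives from
one run seed through fixed integer arithmetic, so equal seeds give
byte-identical landscapes and relevés.

Communities start as independent Bernoulli(0.15) occupancies over a fixed
pool of 106 pseudo-species spread over the field's phytosociological groups
and three dispersal-distance classes. Each generation, species colonise
unoccupied plots of their area from every occupied plot independently with
probability `exp(−d/λ)`, where `d` is the metre-equivalent resistance
distance for corridor-channel species (short- and medium-distance classes),
the Euclidean distance for matrix-channel species (long-distance class), or
the more permissive of the two for `both`. Resistance is converted to metres
at 8 000 m per ohm — roughly the length of a typical corridor cross-section
(≈3.5 m of element at conductivity 100 plus 10 m of flanking buffer at 50)
times the path multiplicity of a connected network — which puts the two
kernels on commensurate scales. The decay scales self-calibrate to one
fifth of the median pairwise isolation of the landscape unless set
explicitly, so the kernel spans the isolation range at any problem size.
Eight generations at roughly five or six years per plant generation
correspond to the ~50 years since the land-consolidation era in which such element networks
were formed. Under these settings the simulated worlds match the broad
survey conditions: per-plot richness in the twenties, mean pair union
richness of a few dozen species, mean Jaccard similarity around 0.3, and a
moderate resistance–Euclidean correlation.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: no environmental gradients or habitat quality
differences between margins and ditches, no extinction, seed banks or
abundance dynamics, no directed water flow in ditches, no observation error
in the relevés, and rectangular mosaics only. The end-to-end tests
demonstrate that the estimator chain recovers a corridor signal that is
present by construction; they cannot validate the ecological assumptions
linking similarity to dispersal in the field.

## Problem sizes and numerical settings used by the tests

The test and acceptance suites run the full design at reduced spatial size:
eight areas of 500 m with 50-m plot spacing and a 150-m frame, which keeps a
complete pipeline run in the tens of seconds while preserving the sampling
structure (the package defaults remain the full-scale 1-km/500-m-frame
conditions). The corridor-contrast reproduction uses 20 seeded worlds; the
Wald-coverage study uses 50 replicates of ~2 000 pairs; the bootstrap
type-I study uses 100 null replicates at B = 199. Solver tolerances: sparse
Cholesky solves are exact to factorisation accuracy and verified to 1e−8
against the dense oracle; the zero-variance degenerate fit agrees with an
IRLS GLM to 1e−6; bootstrap theta re-optimisation stops at a bobyqa rhoend
of 2e−3 on the deviance scale, far below the resolution of a rank-based
p-value at B ≤ 999.

## Known limitations

Resistance distance conflates connectivity with habitat amount along the
way; the analysis inherits that property. The bootstrap engine's profiled
deviance is an approximation to the Laplace deviance (identical ranking in
the simulations used here, but not guaranteed in pathological fits).
Disconnected pairs carry no information in either model by design. The
package fits no families beyond binomial-logit, no random slopes, and
applies no multiple-testing correction across species sets — the tables are
meant to be read as coordinated descriptive inference, matching the
reporting style of the field.
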