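---
title: "Methods: ensemble niche models and transboundary accounting on virtual worlds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble niche models and transboundary accounting on virtual worlds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(borderniche)
```

`borderniche` implements a complete macroecological analysis chain —
climatic-niche modelling of many species under current and future climates,
national aggregation of the projected richness changes, and border-by-border
accounting of transboundary range shifts — together with a synthetic-world
generator that provides ground truth for every stage. This vignette records
the modelling choices, their defaults, and the reasoning behind decisions the
method descriptions leave open.

## The modelling problem

A species distribution model (SDM) associates species occurrence with
climate and projects occupancy under changed climate. The pipeline follows
the classic ensemble design:

1. **Occurrence preparation.** Ranges are rasterised to an equal-area grid
   (a cell is presence when at least 10% of it is covered; the boundary is
   inclusive). Species present in fewer than 10 cells are excluded: for such
   range-restricted species climate is unlikely to be the limiting factor,
   and models fitted to a handful of cells are unstable. For each retained
   species 1,000 pseudoabsence cells are drawn uniformly, without
   replacement, from the zoogeographic realm(s) in which the species occurs,
   excluding its presence cells. Drawing from occupied realms keeps
   pseudoabsences out of regions that are climatically suitable but
   unreachable (oceans, mountain barriers); excluding presence cells avoids
   contaminated absences, which would bias every downstream AUC and
   threshold. When fewer eligible cells exist the full eligible set is used
   and the shortfall is logged.

2. **Predictor selection.** Eight candidate bioclimatic variables (four
   temperature-class, four precipitation-class: means, seasonality,
   extremes) are screened systematically: all subsets of size 3–8 are
   enumerated (219), subsets lacking either climate class are discarded
   (10), and subsets containing a variable pair with absolute Pearson
   correlation above 0.7 are dropped (a pair at exactly 0.7 is kept — the
   rule is a strict inequality). The survivors are ranked by fitting one
   penalised additive model per subset per test species and tallying how
   often each subset lands in the best AIC quartile (the best `ceiling(n/4)`
   subsets; AIC ties break towards fewer members). The winning subset is the
   one with the highest tally, ties towards smaller subsets then
   lexicographic order. Correlations are computed over all land cells of the
   current climate; absolute correlation is used because strongly negative
   collinearity destabilises coefficients just as much as positive.

3. **Spatial blocking.** Noncontiguous pieces of ecoregions (4-connected
   components; "fragments") are the sampling units. Fragments are grouped
   into 10 blocks so that total area and area-weighted mean climate are
   approximately equal across blocks. The grouping is a greedy heuristic:
   fragments sorted by area descending (seeded random tie-breaks), each
   assigned to the block minimising an explicit imbalance score — the
   between-block SD of total area (scaled by mean fragment area) plus the
   mean across predictors of the between-block SD of area-weighted climate
   means (each scaled by the between-fragment SD). Exact multi-way balanced
   partitioning is NP-hard; the greedy score is written down precisely so it
   can be tested (the suite checks it beats the best of 1,000 random
   assignments and keeps the block-area max/min ratio below 1.5 on worlds
   with 100+ fragments). "Full range of bioclimates per block" is enforced
   softly: each block's climate envelope is compared with the global
   envelope and coverage below 80% per variable is reported, not fatal.
   Blocks are global — shared by all species — and a species' folds are the
   intersections of its rows with each block.

4. **The four-family ensemble.** Each species is fitted with four model
   families under leave-one-block-out cross-validation (10 blocks × 4
   families = 40 fits):
   * *Polynomial logistic regression* — every assignment of maximum degree
     1–3 to each of the five predictors (3^5 = 243 formulations, orthogonal
     polynomial expansion) is scored by mean held-out AUC over the 10 folds;
     the best formulation's per-fold fits are kept. The screening fits use a
     fixed-iteration IRLS in compiled code (15 iterations, relative-deviance
     stop at 1e-6): under quasi-separation — the normal state on noise-free
     virtual species — the likelihood is flat and extra iterations only
     rescale the linear predictor, leaving the held-out ranking (an AUC)
     unchanged. The winner is refit with `stats::glm.fit` at full precision.
   * *Penalised thin-plate splines* — an additive logistic model with one
     thin-plate regression spline per predictor, smoothing chosen by fast
     REML (`mgcv::bam(discrete = TRUE)`; on these data sizes its fitted
     probabilities agree with `mgcv::gam` to correlation > 0.999 at a
     fraction of the cost).
   * *Random forests* — probability forests over `mtry` 1–3; the tree count
     starts at 1,000 and grows in steps of 500 until the step's relative
     gain in mean held-out AUC drops below 1%, the final count being the
     last tested one. Because a forest's prediction is the mean over
     exchangeable trees, tree counts are evaluated by truncating the
     per-tree predictions of one capped forest — bit-identical to refitting
     smaller forests with the same seed, at a third of the cost.
   * *Boosted regression trees* — shrinkage 0.001, 5,000 trees, interaction
     depth 1–4 chosen to minimise the summed held-out binomial deviance
     across blocks (xgboost, histogram grower with 64 bins; the climate
     fields are smooth, so 64 quantile bins lose essentially nothing).
   Each fitted model converts its held-out scores into a binary map using
   the threshold maximising sensitivity + specificity (ties resolved towards
   the lower threshold, favouring sensitivity). Thresholds and AUCs are
   computed on the held-out block — the only data the model never saw.

5. **AUC-weighted projection.** Each model scores every cell of the
   species' projection domain (its occupied realms plus adjacent realms),
   binarised at its own threshold; the ensemble occupancy fraction is the
   AUC-weighted mean of the binary values, and the ensemble binary map is
   `fraction >= 0.5` (the natural majority rule; the cutoff is exposed
   nowhere because weighted fractions are symmetric around it). A current
   projection pools 40 model maps; a future scenario pools 40 × 3 pseudo-GCM
   climates = 120. Models with failed folds drop out and the weights are
   renormalised; below 20 surviving projections the species is flagged
   unreliable.

6. **National aggregation.** Per-cell richness is the count of species
   whose binary map occupies the cell; percentage change is
   `100 (future - current)/current`, undefined where current richness is
   zero (those cells are excluded from national means — a ratio with a zero
   denominator carries no information, and imputing it would leak an
   arbitrary constant into the country averages). National change is the
   unweighted mean over a country's defined cells, regressed (Gaussian GLM)
   on the governance score (mean of six indicators, each in [-2.5, 2.5]),
   log GDP per capita and log CO2 per capita — logs because both are
   heavily right-skewed.

7. **Border accounting.** The border graph links countries sharing at least
   one 4-adjacent cell pair. A border bisects a species' current range when
   the species has presence cells on both sides (set semantics — one cell
   suffices). A species shifts across a border when it currently occupies
   exactly one side and its projected future niche includes at least one
   cell of the other country; directions are folded and a species counts at
   most once per border. Future gains in countries not border-adjacent to
   any currently occupied country are long-distance jumps, reported
   separately and attributed to no border. "Currently occupied" always
   means the observed range, not the modelled current niche — the question
   is whether the species is *known* from the country. Barrier analysis
   restricts to nonflying mammals and barrier-flagged edges: a species is
   blocked when its shift condition holds on at least one fortified border.
   Normalised statistics divide by the number of distinct species present
   in either of the two countries.

## The virtual world generator

The generator is first-class, tested code: every assumption the analysis
makes is built in with known parameters so each stage can be validated by
recovery instead of by eyeballing.

* **Grid.** An abstract equal-area grid; all areas are cell counts times
  `cell_area`. A nominal latitude runs from 65° (row 0) to 0°.
* **Climate.** Eight layers = deterministic base pattern + Gaussian-filtered
  white noise (filter radius `autocorr_range`, default 3 cells; amplitude
  `noise_sd`, default 1, in units of a tenth of the layer's dynamic range).
  The temperature profile is deliberately *flat near the equator and steep
  poleward* (quadratic in latitude), as on the real Earth: a uniform warming
  then creates novel climates in the tropics rather than merely translating
  isotherms. Futures add per-scenario shifts (default mean warming +1.0,
  +1.8, +2.5, +3.7 °C for the four scenario analogues — roughly the 2070
  anomaly ladder) spread across three pseudo-GCMs by multipliers
  0.85/1.0/1.15 plus a small GCM-specific spatial noise. A zero delta spec
  reproduces the current climate exactly.
* **Regions.** Realms are contiguous longitudinal bands; ecoregions
  partition each realm by jittered nearest-seed assignment (the jitter
  yields occasional disjunct ecoregions, so fragment handling is genuinely
  exercised); countries partition the grid by randomised multi-source flood
  fill (contiguous, non-empty). Both fragment contiguity and country
  adjacency use 4-connectivity — unambiguous and oracle-checkable. A
  configurable fraction of borders (default 15%) carries a barrier flag.
  Countries are land-contiguous only; maritime adjacency does not exist on
  the grid.
* **Species.** Gaussian suitability over mean annual temperature plus one or
  two further predictors, with the optimum drawn from an actual cell's
  climate and breadth in global-SD units (default 0.5–1.5). Presences are
  exactly the cells at or above the (1 - prevalence) suitability quantile:
  no label noise, so the occupied/unoccupied suitability partition is sharp
  and testable. Niche breadth narrows towards the equator
  (`tropical_narrowing = 0.6`): combined with the flat tropical temperature
  profile this reproduces the empirical pattern that low-latitude
  assemblages are the most exposed to warming — the pattern the national
  covariate analysis is designed to detect.
* **Covariates.** Six governance indicators (clamped to [-2.5, 2.5]), GDP
  and CO2 per capita, all tied to country mean latitude with strength
  `gradient_strength` (0 disables the link entirely, giving the null world
  for calibration checks).

**What the generator does not emulate:** real geographic geometry, dispersal
limits, biotic interactions, land use, observation error in range maps, and
label noise in presences. Passing recovery tests therefore demonstrates that
the pipeline's statistics are implemented correctly and that the ensemble
can recover niches *when the SDM assumptions hold exactly*; they say nothing
about how well those assumptions fit real occurrence data.

## Numerical choices and degenerate inputs

* AUC is the rank-based (Mann–Whitney) form with ties counted half;
  single-class inputs raise rather than return a default.
* Threshold candidates are the observed scores; with all scores identical
  the single candidate attains sensitivity + specificity = 1.
* Polynomial bases for the GLM search are computed once on the full species
  table. The basis is an unsupervised reparameterisation of the same model
  space, so per-fold fitted probabilities — and hence held-out AUCs — are
  identical to recomputing the basis per fold.
* Single-class training folds skip the affected model (NA metrics); the
  ensemble renormalises. Constant predictor columns are treated as
  collinearity violations, with a warning.
* Cells whose polygon overlap is within 1e-12 of the 10% rasterisation
  threshold count as covered (floating-point guard on an inclusive rule).
* Per-stage seeds derive deterministically from the global seed, so stages
  can be re-run independently and the full pipeline is bit-reproducible.

## Problem sizes used by the test suite

The suite validates the pipeline at sizes chosen to exercise every rule on
one CPU: the niche-recovery study runs 10 virtual species on a 40 × 40 grid
(each with 500+ presence cells and 1,000 pseudoabsences, 241 ecoregion
fragments, 10 blocks, all four families, three pseudo-GCMs), and the
covariate-recovery study runs 100 simulations of 30 species on an 18 × 18
grid with 14 countries. The acceptance script repeats the same computations
at slightly smaller sizes (an 8-species ensemble pipeline, a 50-species
border-accounting world, 30 covariate simulations). The package itself has
no size limits beyond memory.

## Known limitations

* The greedy blocking is near-optimal, not optimal; its guarantees are
  empirical (tested against random assignments), not analytic.
* The quartile-tally ranking refits one additive model per subset per
  species; on the full 209-subset pool this is the slowest stage and is best
  run with a moderate number of test species (the default configuration uses
  8).
* Range rasterisation assumes retained sub-polygons do not overlap (their
  per-cell areas are summed); overlapping polygons would over-count
  coverage.
* Boosted trees use a histogram grower (64 bins) rather than exact splits;
  on smooth climate fields the difference is negligible but it is an
  approximation.
* The ensemble stores model objects only transiently; pipeline outputs are
  projections and audit tables, so a single species' models cannot be
  re-examined after a full run without refitting.
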