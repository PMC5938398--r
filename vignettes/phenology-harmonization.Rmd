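---
title: "Harmonizing status-based and event-based plant phenology observations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing status-based and event-based plant phenology observations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenokit)
```

## The problem

Large phenology monitoring networks encode the same biological fact — "this
maple's leaves came out in mid April" — in incompatible ways. Status-based
networks (USA-NPN, NEON) revisit marked plants on a cadence and record, per
phenophase, whether it is currently occurring, sometimes with an intensity
range ("10–20 unfolded leaves"). Event-based networks (PEP725) record a
single day of year per plant and year on which a BBCH-coded developmental
event occurred. phenokit harmonizes both into one flat, queryable table by
(1) translating source codes into a shared catalog of phenological traits,
(2) expressing every record as a count or percentage *range*, and
(3) mechanically inferring qualitative present/absent classes — and all of
their more general consequences — from those ranges.

## The trait catalog and its derived hierarchies

A catalog declares plant structures (leaf buds, true leaves, flowers, ...),
subclass links between them ("dormant leaf bud" is a kind of "leaf bud"),
parthood links ("breaking leaf bud" has a visible "unfolding true leaf"),
and traits, each measured by the count or percentage of exactly one
structure. Traits carry a *modality*: `attached` traits count structures on
the plant; `abscised` traits count structures the plant has shed.

For every trait, `derive_presence_classes()` creates two qualitative
classes, *present* and *absent*, and derives their hierarchies from the
structure graph. The key property is the **inversion** of the absent
hierarchy. If a plant has dormant leaf buds it certainly has leaf buds, so
present(dormant leaf bud) ⊑ present(leaf bud). But lacking dormant leaf buds
says nothing about leaf buds in general — whereas lacking leaf buds
altogether rules out dormant ones, so absent(leaf bud) ⊑ absent(dormant leaf
bud). Mechanically: the absent edge set is always the present edge set with
every edge reversed and polarity flipped, and `validate_catalog()` asserts
that mirror on any catalog.

Parthood licenses the analogous inference through an existential
requirement: if a breaking leaf bud must show an unfolding true leaf, then
present(breaking leaf bud) ⊑ present(unfolding true leaf), and
contrapositively absent(unfolding true leaf) ⊑ absent(breaking leaf bud).
Two deliberate choices here:

* **Modality guard.** Presence propagation — for subclass *and* parthood
  edges — only pairs traits of the same modality. "Abscised leaf presence"
  counts shed leaves; letting it imply (or be implied by) attached-leaf
  classes would manufacture false facts such as "leaves on the plant"
  entailed by leaves on the ground.
* **Parthood as a toggle.** The subclass rule is forced by the structure
  hierarchy itself; the parthood rule depends on how strictly "has visible
  part" is read. It defaults on, and `derive_presence_classes(use_parthood
  = FALSE)` turns it off for users whose catalogs use looser parthood.

Closures (`presence_superclasses()`) are reflexive-transitive and returned
in a deterministic order: breadth-first from the query class, lexicographic
within a level. Determinism matters because the harmonized table stores
closures as serialized lists and we promise byte-identical output for
identical input.

## Measurement ranges and inference

A measurement datum is a range `[lower, upper]` of counts (whole numbers;
`Inf` upper expresses "at least lower") or percentages (within [0, 100]).
Classification is three-valued:

* present — `lower >= 1` for counts, `lower > 0` for percentages
  (mirroring "one or more");
* absent — `upper == 0`;
* indeterminate — `lower == 0 < upper`: the range straddles zero and
  licenses **no** assertion. We deliberately emit nothing rather than a
  disjunction; downstream queries then simply never see the observation
  for that trait.

`materialize()` applies this per measurement and stores the *full* closure
per observation (eager materialization), so the exported table is
self-contained: selecting "true leaves present" needs no catalog at query
time. Contradictions (one observation asserting a trait both present and
absent) are detected by `check_consistency()`, excluded from the export,
and reported — data problems are data, not exceptions.

Percentages carry the same rules for individual plants (fraction of a
structure class in a state) and for populations (fraction of member plants
bearing the trait); the inference machinery is identical by design.

## The four-stage pipeline

`run_pipeline()` chains: dialect parsing (malformed rows are rejected with
line numbers, never aborting), code mapping (unmapped and agricultural codes
become skip notices; `status = "no"` becomes the exact zero range;
`status = "yes"` without intensity becomes lower 1 with unbounded upper),
materialization, and flat export. Three contracts are load-bearing:

* **Conservation** — rows read = harmonized + rejected + skipped, exactly,
  on every run (conflict-excluded observations are counted among skips).
* **Dialect symmetry** — a status record and an event record encoding the
  same onset day produce identical inferred present-classes.
* **Determinism** — output row order is source order then record id, so
  identical inputs give byte-identical CSVs.

Agricultural records (e.g. harvest dates in BBCH-coded sources) are mapped
to an explicit `excluded_agricultural` rule rather than silently dropped:
they are out of the model's scope but must stay visible in the accounting.

## Onset analysis

The analysis surface reproduces a standard onset-estimation recipe:

1. `select_observations()` — keep rows bearing a required class and not an
   excluded one (e.g. 'true leaves present' without 'senescing true leaves
   present', so late-season foliage does not masquerade as leaf-out).
2. `grid_cell()` — round coordinates to a 0.1° grid, half-away-from-zero.
   The tie-break is not dictated by the recipe itself; half-away-from-zero
   is sign-symmetric and matches everyday decimal rounding.
3. `earliest_per_cell_year()` — one estimate per occupied (cell, year): the
   minimum day of year, ties resolved by observation id.
4. `filter_decades()` — calendar decades (`floor(year/10)*10`); decades
   with fewer records than a threshold are discarded. The two conventional
   thresholds are 1,000 (most analyses) and 400 (sparser genera).
5. `decade_summary()` — per-decade count, median (mean of the central pair
   for even counts), and a Gaussian KDE of the onset distribution.

The KDE bandwidth is the interquartile-range rule of thumb

$$ h = 0.9\,\min\!\left(s,\ \frac{\mathrm{IQR}}{1.34}\right) n^{-1/5}, $$

with linear-interpolation quantiles (type 7) — the default convention in
mainstream statistical environments. If the IQR is zero under heavy ties,
the standard deviation alone is used; fewer than two values, or zero
spread, raise typed errors rather than producing a meaningless curve. The
evaluation grid spans the data range ± 4h, so the trapezoidal integral of
every emitted density is 1 within 10⁻³. Day of year is computed from the
real calendar (leap years have 366 days) with no further adjustment.

## What the simulator emulates — and what it does not

`simulate_dataset()` generates both dialects from one ground truth so every
claim above is testable without network downloads. Per plant-year, onset is
drawn from Normal(a + b·latitude, σ²), truncated to [1, 366 − season
length] by inverse-CDF sampling; the structure stays visible for
`season_length` days. The status network visits on days 1, 1+c, 1+2c, ...
and reports yes/no with an intensity window (k, k+10), k growing through
the season; the event network reports the true onset day, with a seeded
fraction of records replaced by an agricultural code. The ledger records
every true onset and the expected emitted-row counts, making conservation
and recovery checks exact.

Defaults are chosen once as a plausible mid-latitude leaf-out scenario:
latitudes 40–60°N and longitudes −10–30°E (roughly Europe's observational
extent), intercept 20 DOY with slope 2.5 days per degree latitude (onset
near DOY 120 at 45°N), σ = 5 days, season length 150 days, weekly visits,
5% agricultural contamination, 200 plants over 2000–2009.

Real data differ in ways the simulator deliberately ignores: no between-year
autocorrelation, no climate driver, no observer error beyond visit cadence,
no spatial clustering of stations, no missing-visit gaps, and uniform rather
than road-biased locations. Passing the recovery tests therefore shows the
*pipeline arithmetic* is right — that medians shift only by the sampling lag
the design implies — not that the model describes any real network's biases.

Two quantified recovery properties follow from the design and are enforced
in tests: the event dialect is lossless, so per-decade medians of
earliest-per-cell-year estimates track the ledger median within 2 days
(cell collisions, which bias minima early, are rare at the default plant
density); and the status dialect first sees an onset at the next visit, so
its median bias lies in [0, cadence] days.

## Numerical and degenerate-input choices

* Count bounds must be whole numbers (tolerance 10⁻⁹); fractional counts
  fail loudly instead of being coerced.
* An unbounded upper count is `Inf` in memory and an empty field on disk;
  the observation CSV round-trips field-for-field.
* Cycle detection is an explicit iterative DFS; self-loops are cycles.
* Catalogs are normalized (rows sorted, edges deduplicated) at load, so any
  permutation of the input file yields an identical catalog.
* Missing coordinates are a validation *warning*: such records flow through
  the pipeline but are skipped (and counted) by the spatial analysis.
* Truncation windows that leave essentially no probability mass raise a
  parameter error instead of looping or returning clamped garbage.

## Problem sizes used by the test suite

The suite exercises: random-catalog equivalence against an independent
igraph reachability oracle (200 catalogs up to 50 structures, plus 100
measurement cases), pipeline conservation at ~51,000 simulated rows, onset
recovery at 1,000 plant-years per dialect, KDE accuracy at n = 5,000
against the closed-form normal density, and a twice-run end-to-end demo
compared by file checksum. These sizes were chosen to make the statistical
assertions stable at tight tolerances while keeping a full run comfortable
on a laptop.

## Known limitations

* The shipped catalog is a compact working subset (24 traits over 22
  structures), not a complete ontology release; the shipped mapping covers
  only the simulator's vocabularies and is illustrative for real BBCH/NPN
  codes, whose published mappings are not reproduced here.
* Description-logic features beyond subclass/parthood presence propagation
  (role chains, nominals, disjointness) are out of scope.
* No trend inference: the analysis stops at medians and densities by
  design; regression or significance testing on harmonized data needs the
  fitness-for-use scrutiny the per-source report is meant to support.
* Taxonomic name reconciliation is not attempted; genus filters are exact
  string matches.
* "Unknown" status records are skipped rather than modeled as a weaker
  assertion — there is no established convention for them, and an explicit
  skip count keeps them auditable.
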