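# phenokit

Tools for integrating plant phenology observations that were collected under
incompatible monitoring protocols, and for running standard onset analyses on
the result.

Status-based networks (USA-NPN, NEON) revisit marked plants and record, per
visit and phenophase, whether it is occurring — optionally with an intensity
range such as "10–20 unfolded leaves". Event-based networks (PEP725) record
one day of year per plant and year on which a BBCH-coded event first
occurred. phenokit harmonizes both dialects into a single flat table by
mapping source codes onto a catalog of phenological traits, expressing every
record as a count/percentage range `[lower, upper]`, and inferring
qualitative presence/absence classes from those ranges:

- `lower ≥ 1` (counts) or `lower > 0` (percentages) entails the trait's
  *present* class plus every more general present class — e.g. a 10–20
  count on 'unfolded true leaf presence' entails both 'unfolded true leaves
  present' and 'true leaves present';
- `upper = 0` entails the *absent* class, whose hierarchy is the exact
  mirror: absent(leaf bud) ⊑ absent(dormant leaf bud), the reverse of
  present(dormant leaf bud) ⊑ present(leaf bud);
- a range straddling zero entails nothing.

The hierarchies are never authored — they are derived mechanically from
subclass and parthood links among plant structures, and the package asserts
the present/absent mirror property on every catalog.

On the harmonized table, the analysis functions implement the usual onset
recipe: select rows bearing one class but not another (leaf-out = 'true
leaves present' without 'senescing true leaves present'), round coordinates
to a 0.1° grid, keep the earliest observation per grid cell and year, drop
decades with too few records (the conventional thresholds are 1,000 and
400), and summarize each decade with its median day of year and a Gaussian
kernel density estimate using the IQR rule-of-thumb bandwidth
`h = 0.9 · min(s, IQR/1.34) · n^(−1/5)`.

A seeded simulator generates both dialects from a known ground truth (onset
~ Normal(a + b·latitude, σ²) per plant-year, truncated to the feasible
window) together with a ledger of true onsets and expected row counts, so
the whole chain is testable offline.

## Worked example

```r
library(phenokit)

catalog <- default_catalog()
catalog
#> <trait_catalog>
#>   structures:       22
#>   subclass links:   16
#>   parthood links:   1
#>   traits:           24
#>   presence classes: 48 ( 34 derived edges )

# a researcher counts 10-20 unfolded true leaves on a sunflower
infer_types("unfolded_true_leaf_presence", "count", 10, 20, catalog)
#> [1] "unfolded_true_leaf_present" "true_leaf_present"

# simulate both networks, ingest, and analyze leaf-out onsets
cfg <- load_run_config(system.file("extdata", "demo_config.yaml",
                                   package = "phenokit"))
report <- run_end_to_end(cfg, "demo_out")
str(report$stages)
#> List of 3
#>  $ simulate:List of 1
#>   ..$ plant_years: int 600
#>  $ ingest  :List of 5
#>   ..$ rows_read : num 32400
#>   ..$ rejected  : num 0
#>   ..$ skipped   : num 30
#>   ..$ conflicts : int 0
#>   ..$ harmonized: int 32370
#>  $ analyze :List of 3
#>   ..$ selected_rows   : int 13449
#>   ..$ onset_estimates : int 600
#>   ..$ decades_retained: int 1

readr::read_csv("demo_out/decade_summary.csv")
#> # A tibble: 1 × 3
#>   decade     n median_doy
#>    <dbl> <dbl>      <dbl>
#> 1   2000   600        150
```

Reading the numbers: 60 plants × 10 years gives 600 plant-years; weekly
status visits plus one event record per plant-year make 32,400 source rows.
The 30 skips are the simulated agricultural event records (5% of 600),
which the mapping deliberately excludes, and every remaining row lands in
the harmonized table — the accounting identity `read = harmonized +
rejected + skipped` holds exactly. Of the harmonized rows, 13,449 carry
'true leaves present' without 'senescing true leaves present'; collapsing
them to the earliest observation per 0.1° cell and year leaves 600 onset
estimates in one retained decade with median leaf-out at day 150 —
consistent with the simulated onset model (intercept 20 + 2.5 days/°lat at
latitudes 40–60°N) plus the visit-cadence lag.

A thin command-line wrapper with `simulate`, `ingest`, `analyze`, and `run`
subcommands is installed at `inst/cli/phenokit`.

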