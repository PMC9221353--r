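# nkscreen

Analysis toolkit for high-throughput **luciferase-release NK-cell
cytotoxicity screens**: plate-based drug screens that look for small
molecules enhancing the killing of nano-luciferase-labelled tumour target
cells by natural killer (NK) effectors. It is aimed at screening groups who
have plate-reader luminescence exports and want a reproducible, tested path
from raw RLU to a ranked candidate list and dose-response validation.

## What it computes

**Percent specific lysis** normalises an experimental luminescence reading
between the spontaneous release of targets alone and the maximal release of
digitonin-lysed targets:

```
% specific lysis = (experimental − spontaneous) / (maximal − spontaneous) × 100
```

**Plate QC** uses the Z′-factor per assay plate, from the eight positive-
and eight negative-control wells (sample SDs, n − 1):

```
Z′ = 1 − (3·SD⁺ + 3·SD⁻) / |m⁺ − m⁻|
```

with bands: good (0.5 ≤ Z′ ≤ 1), fair (0 ≤ Z′ < 0.5), poor (Z′ < 0).

**Hit calling** computes each compound well's fold-change over the mean of
its own plate's column-1 DMSO wells, separately per condition and
screening day, then calls:

* `excluded_toxic` — target-alone fold-change ≥ threshold in any replicate
  (the compound lyses targets directly; its co-culture signal is
  uninterpretable); this dominates every other status;
* `hit` — co-culture fold-change ≥ threshold (default 1.3, inclusive) on
  **every** screening day, with ≥ 2 days;
* `single_replicate_hit` — one day available, threshold met;
* `non_hit` — otherwise.

**Dose-response validation** turns titration reads (doses including 0,
two E:T ratios, replicate wells) into lysis tables and calls a **minimum
effective dose**: the smallest dose whose lysis exceeds vehicle by an
exact one-sided rank-sum test (full enumeration, mid-ranks under ties) at
α = 0.05 *and* by a relevance margin (default 5 lysis percentage points).

**The synthetic screen generator** simulates the whole screen — paired
target-alone/co-culture plates, saturating E:T kill curve, planted
enhancers and toxic compounds, lognormal well noise, plate gain, and
seeding-order potency drift — with known ground truth, so the entire
pipeline is testable end to end without any external data.

## Worked example

```r
library(nkscreen)
library(dplyr)

cfg <- sim_config(n_compounds = 160, seed = 7)   # 2 plates x 2 conditions x 2 days
sim <- simulate_screen(cfg)

screen_qc_report(sim$reads, sim$layout)$condition_summary
#>   condition    mean_z n_plates n_undefined
#> 1 coculture     0.391        4           0
#> 2 target_alone  0.642        4           0

fc   <- fold_change_screen(sim$reads, sim$layout)
hits <- call_hits(filter(fc, condition == "coculture"),
                  filter(fc, condition == "target_alone"))
table(hits$status)
#> excluded_toxic            hit        non_hit
#>              5             15            140

head(screen_hits(hits)[, c("compound_id", "mean_fc", "status")])
#>   compound_id  mean_fc status
#> 1       C0031 2.182953    hit
#> 2       C0061 2.117262    hit
#> 3       C0150 2.031240    hit
```

The co-culture plates land in the *fair* Z′ band and the target-alone
plates in the *good* band — the usual split for this assay, where the 9:1
positive control drifts toward the DMSO control as effector potency decays
over a seeding day. All 15 planted enhancers are recovered as hits and all
5 planted toxic compounds are excluded by the counter-screen.

Dose-response validation of an enhancer whose effect switches on at 5 µM:

```r
eff <- setNames(c(1, 1, 3, 3, 3), c(0, 1, 5, 10, 20))   # dose -> multiplier
dr  <- dose_response_lysis(
  simulate_dose_response(eff, config = sim_config(n_compounds = 80,
                                                  noise_cv = 0.05, seed = 7)))
minimum_effective_dose(dr)
#>   drug_id et_ratio minimum_effective_dose alpha    tail min_effect
#> 1    drug        1                      5  0.05 greater          5
#> 2    drug        3                      5  0.05 greater          5
```

The drug is called effective starting from 5 µM at both E:T ratios.

A transcribed published hit list ships as a fixture for regression tests:

```r
rec  <- fixture_fold_change_records(table1_fixture())
hits <- call_hits(rec$coculture, rec$target_alone)      # 14 passing compounds
nrow(select_candidates(hits,
  tibble::tibble(compound_id = table1_fixture()$compound_id,
                 deprioritize = !table1_fixture()$candidate)))  # 8 candidates
```

## Command line

A thin subcommand CLI wraps the same functions
(`inst/cli/nkscreen`, or call `nkscreen_cli()` directly):

```sh
nkscreen simulate  --seed 7 --out run/
nkscreen qc        --reads run/reads.csv --layout run/layout.json --out run/qc
nkscreen call-hits --reads run/reads.csv --layout run/layout.json --out run/hits
```

Long CSV (`plate_id,replicate_id,condition,well,rlu`) is the canonical
interchange format; 8×12 grid CSVs with a `key=value` metadata header are
accepted for import. All stage outputs embed their analysis parameters as
header comments or JSON fields.

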