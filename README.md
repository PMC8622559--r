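# fcmscreen

Untargeted GC-EI-HRMS screening and TTC risk assessment of plastic
food-contact-material (FCM) extracts.

`fcmscreen` is for analysts screening plastic FCM — in particular recycled
polymers — for unknown migrating substances: intentionally added substances
(IAS, on the EU 10/2011 Union list, possibly with a specific migration
limit, SML) and non-intentionally added substances (NIAS). Starting from
deconvoluted GC features (retention time, area, centroided EI spectrum), it
provides:

* **Spectral library matching** against NIST-style MSP libraries with a
  composite score: the Stein–Scott search-index similarity
  (weighted dot product, weights `I^0.6 · mz^3`, plus a paired-peak
  intensity-ratio term) combined with a **high-resolution filtering (HRF)**
  score — the fraction of spectral intensity explainable by exact-mass
  subformulas of the candidate formula, with radical-cation (electron-mass
  corrected) theoretical m/z.
* **Retention-index calibration** (linear van den Dool–Kratz form) against
  n-alkane ladders, with `RI(C_n) = 100·n`.
* A restrictive **identification gate**: total score > 90, mass accuracy
  < 2 ppm for ≥ 3 annotated fragments (or 2 plus the molecular ion), and
  |ΔRI| < 50 when a library RI exists — all strict comparisons.
* **Semi-quantification** from the average internal-standard response
  factor, converted to migration via
  `conc × V_extract / A_film × 6 dm²/kg`, plus OLS calibration for
  compounds confirmed with standards and system-suitability statistics.
* A **TTC risk screen**: substances migrating above 0.00015 mg/kg are
  assessed — NIAS by comparing the estimated daily intake
  (EDI = migration × 1 kg/day) against the Cramer-class tolerable daily
  intake (Class I 1.80, II 0.54, III 0.09 mg person⁻¹ day⁻¹), IAS against
  their SML; NIAS at or above the 0.01 mg/kg functional-barrier ceiling are
  flagged.
* A **synthetic-data generator** (exact-mass fragment libraries, triplicate
  runs, decoys, internal standards, alkane ladders) for hermetic
  end-to-end validation, and a **bundled reference dataset** from a screen
  of post-consumer recycled LDPE film (83 identified substances, 12 IAS,
  45 above the consideration threshold).

See `vignettes/fcmscreen-methods.Rmd` for the methods account.

## Worked example

Risk-screen the bundled recycled-LDPE case study:

```r
library(fcmscreen)
screened <- screen_risk(ldpe_screen_input())
rep <- risk_report(screened)
str(rep$summary)
#> List of 4
#>  $ n_input                   : int 83
#>  $ n_considered              : int 45
#>  $ n_above_functional_barrier: int 9
#>  $ n_exceedances             : int 0
head(rep$table[, c("compound", "migration_mg_kg", "ias", "sml_mg_kg",
                   "cramer_class", "tdi", "edi", "verdict")], 4)
#>                          compound migration_mg_kg   ias sml_mg_kg cramer_class  tdi   edi verdict
#> 1                     Irgafos 168           2.000  TRUE        NA         <NA>   NA    NA    pass
#> 2                Methyl palmitate           0.058 FALSE        NA            I 1.80 0.058    pass
#> 3                 Methyl stearate           0.058 FALSE        NA            I 1.80 0.058    pass
#> 4             1,2-Diphenoxyethane           0.033 FALSE        NA          III 0.09 0.033    pass
```

Of the 83 identified substances, 45 migrate above the 0.00015 mg/kg
consideration threshold, 9 sit at or above the 0.01 mg/kg
functional-barrier level at the table's printed precision, and none exceeds
its TDI (NIAS) or SML (IAS) — the screened material raises no TTC-level
concern. Irgafos 168 passes as an authorized substance without a listed
SML; methyl palmitate's EDI of 0.058 mg person⁻¹ day⁻¹ is far below the
Class I TDI of 1.80.

A fully synthetic end-to-end run:

```r
cfg <- sim_config(seed = 1, n_planted = 20, n_decoys = 20)
lib <- make_library(default_formulas(20), cfg)
sim <- simulate_runs(lib, cfg)
res <- run_screen(sim$features, lib$records, sim$ladder, sim$standards,
                  default_cramer_class = "III")
str(res$counters)
#> List of 6
#>  $ n_features                : int 120
#>  $ n_identified              : int 20
#>  $ n_ias                     : int 0
#>  $ n_considered              : int 20
#>  $ n_above_functional_barrier: int 0
#>  $ n_exceedances             : int 0
```

All 20 planted compounds (and no shuffled decoys) pass the gate in all
three replicates; their semi-quantified migrations land in the sub-0.01
mg/kg range implied by the simulated concentrations, and under the
conservative Class III default none approaches the 0.09 mg person⁻¹ day⁻¹
TDI.

## Command line

A thin subcommand wrapper over the same functions ships in
`inst/scripts/fcmscreen.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/fcmscreen.R", package="fcmscreen"))')" \
    run-all --config config.yaml --seed 1 --output out/
```

Subcommands: `simulate`, `match`, `identify`, `quantify`, `risk`,
`suitability`, `run-all`. Each stage writes CSV artifacts plus a JSON run
manifest; reruns with the same config and seed are byte-identical.

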