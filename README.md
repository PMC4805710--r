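# alidose

Aerosol dosimetry and tiered dose–response statistics for air–liquid
interface (ALI) nanotoxicology.

## The problem

When airway cell cultures are exposed directly to an aerosol of
nanostructured metal particles, the biological response must be related to
the dose actually *delivered* to the cells — the particle number, mass,
and surface area deposited per cm² of the cell layer — not merely to the
airborne concentration.  For fractal metal aggregates this takes a chain
of measurements: SMPS number size distributions, the DMA-APM mass-mobility
relation (aggregates do not follow the spherical `m ∝ d³` law), TEM
primary-particle statistics for the specific surface area, and SEM wafer
counting for the exposure chamber's deposition efficiency.  `alidose`
implements that chain, and the three-tier statistics relating the doses to
viability and cytokine responses, for aerosol scientists and inhalation
toxicologists running ALI exposure studies.

## The core quantities

With `c_N`, `c_m`, `c_SA` the number, mass and surface-area concentrations
entering the chamber, `v` the aerosol volume passed over one insert,
`E_SEM` the deposition efficiency, and `SA_insert` the membrane area:

    N_dose  = c_N  · v · E_SEM / SA_insert        (#/cm²)
    m_dose  = c_m  · v · E_SEM / SA_insert        (µg/cm²)
    SA_dose = c_SA · v · E_SEM / SA_insert        (cm²/cm²)

Aggregate mass uses the mass-mobility power law `m(d_me) = k · d_me^D_mm`
(OLS in ln–ln space; `D_mm ≈ 2.0–2.2` for diffusion-limited cluster
aggregates), surface area uses the TEM-derived specific surface area
`SSA = 6 / (ρ · d_va)` with `d_va = Σd³/Σd²` the Sauter diameter, and
sintered near-spheres use the bulk density directly.  Tier 1 tests the
pooled exposed/control ratio against 1, tier 2 does so per material, and
tier 3 fits linear dose–response models per dose metric, with an ANCOVA
for material-specific slopes.

## Worked example

Build an exposure from its measured characteristics (a lognormal aerosol
with `c_N = 1.05e6` #/cm³, CMD 58.8 nm, GSTD 1.68, TEOM mass concentration
0.39 mg/m³) and compute its doses under the default chamber configuration
(`v = 1500` cm³, `SA_insert = 0.33` cm², `E_SEM = 0.36`):

```r
library(alidose)

d   <- make_lognormal(1.05e6, CMD = 58.8, GSTD = 1.68,
                      grid = log_grid(5, 1000, 96), label = "Ag_2")
rec <- exposure_record("Ag_2", d, "aggregate", "Ag", c_m_teom_mg_m3 = 0.39)
compute_dose(rec, exposure_config())
#> Dose for Ag_2 (pathway: teom)
#>   c_N = 1.05e+06 #/cm^3, CMD = 58.8 nm, GSTD = 1.68
#>   c_m = 0.39 mg/m^3
#>   N_dose = 1.72e+09 #/cm^2, m_dose = 0.64 ug/cm^2, SA_dose = -
```

`N_dose = 1.72e9` #/cm² is the deposited particle number per cm² of a
confluent cell layer; `m_dose = 0.64` µg/cm² comes from the online TEOM
mass pathway; the surface-area dose is reported absent because silver
aggregates carry neither a primary-particle SSA nor sphere geometry.

Aggregating wafer-area deposition efficiencies and computing a specific
surface area:

```r
aggregate_deposition(c(55, 27, 43, 48, 11, 17, 52))
#> Deposition efficiency E_SEM = 36 +/- 18 % (n = 7 areas)

specific_surface_area(5.00, 8.96)   # Sauter diameter nm, density g/cm^3
#> [1] 133.9286                      # m^2/g
```

See `vignettes/alidose-methods.Rmd` for the models, assumptions, and
design choices, and `inst/cli/alidose.R` for a command-line front end
(`simulate`, `fit-massmob`, `sauter`, `deposition`, `compute-dose`,
`tox-tiers`).

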