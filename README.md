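# resrisk

Residue-to-risk analysis for supervised pesticide field trials: from
analytical method validation through dissipation kinetics to deterministic
and probabilistic dietary-risk assessment, with a synthetic-data generator
so the whole chain runs and is tested without access to raw trial or survey
data. The worked setting is a grape trial of the fungicides pyraclostrobin
and cyazofamid (with its monitored metabolite CCIM), but every stage is
parameterized.

## What it computes

**Method validation** — linear calibration fits; matrix effect
`ME% = (K1/K2 − 1) × 100` from the matrix/solvent slope pair (|ME| ≥ 20%
significant); spike recovery `100·mean(m)/s` with sample-SD RSD; LOQ
screening at the 70–120% / RSD ≤ 20% band.

**Dissipation kinetics** — first-order decay `Ct = C0·e⁻ᵏᵗ` fitted
log-linearly, half-life `T½ = ln2/k`, dissipation percentage
`DT% = 100·(C0 − Ct)/C0`, with selectable handling of <LOQ points
(LOQ/2 substitution, drop, or LOQ).

**Deterministic risk** — acute: `NESTI = LP·HR·v/bw` and
`%ARfD = 100·NESTI/ARfD`; chronic: `EDI = Σ STMRᵢ·Fᵢ/bw` and
`%ADI = 100·EDI/ADI`; parent+metabolite aggregation via `total_residue()`
(plain sum by default). Risk above 100% of the reference dose is flagged.

**Probabilistic risk** — lognormal fits to consumption and residue data,
Monte-Carlo exposure `yᵢ = Σ xᵢₖ·cᵢₖ/bwᵢ`, and percentile reports
(P50…P99.9) as percent of ADI/ARfD, stratified by consumer subgroup.

## Worked example

```r
library(resrisk)

# acute risk of cyazofamid total residue for children
hr  <- total_residue(parent = 0.31, metabolite = 0.47)   # 0.78 mg/kg
chd <- population_subgroup("children", bw = 16.14, lp = 0.366)
percent_arfd(nesti(chd, hr), arfd = 0.2)$percent
#> [1] 26.5316

# half-life from a noiseless synthetic decay series
s <- generate_decay_series(trial_config(0.65, log(2) / 17.8,
                                        c(0, 3, 7, 14, 21, 28)))
fit_first_order(s)
#> First-order dissipation fit: compound @ site-1
#>   C0 = 0.65 mg/kg, k = 0.03894 /day, T1/2 = 17.8 days
#>   r^2 = 1.0000 (log-linear), n = 6, censoring = half_loq
```

The 26.5% means the children's short-term intake of cyazofamid residues at
the highest observed residue is about a quarter of the acute reference
dose — acceptable; the same calculation for pyraclostrobin (HR 1.88 mg/kg,
ARfD 0.05 mg/kg bw) exceeds 250%, which is flagged.

## Analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic inputs
and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R            # generate inputs with known truth
Rscript analysis/02_method_validation.R   # calibration, ME, recovery, LOQ
Rscript analysis/03_dissipation.R         # half-lives vs ground truth
Rscript analysis/04_deterministic_risk.R  # %ARfD and %ADI per subgroup
Rscript analysis/05_probabilistic_risk.R  # Monte-Carlo percentile reports
```

`run_pipeline(load_run_config("…/run_config.yaml"))` runs the same four
stages programmatically on any config; a packaged fixture config ships in
`inst/extdata/`. Outputs carry provenance headers (version, seed, config
hash) and fixed-seed runs are byte-identical.

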