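#!/usr/bin/env Rscript
# Regenerates the synthetic fixture tables under inst/extdata/ from the
# package's own generators at fixed seeds. Run from the repository root:
#   Rscript tools/make_fixtures.R
# All fixtures are synthetic; reference parameter tables (subgroups,
# toxicology, residue summaries) carry the standard Chinese-population and
# JMPR reference values used throughout the package documentation.

library(resrisk)

out_dir <- "inst/extdata"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
plain <- function(df, name)
  write.csv(df, file.path(out_dir, name), row.names = FALSE, quote = FALSE)

## Calibration series reconstructed from the reference regression lines
## (response = slope * level + intercept, exact), 5 levels per curve.
curves <- data.frame(
  compound = rep(c("pyraclostrobin", "cyazofamid", "CCIM"), each = 2),
  medium = rep(c("solvent", "matrix"), 3),
  slope = c(75.023, 79.557, 46.077, 44.765, 83.679, 79.642),
  intercept = c(-0.1507, 0.8196, -0.5829, 0.4464, -1.0367, 0.9445))
levels <- c(0.05, 0.1, 0.5, 1, 5)
cal <- do.call(rbind, lapply(seq_len(nrow(curves)), function(i)
  data.frame(compound = curves$compound[i], medium = curves$medium[i],
             level_mg_per_L = levels,
             response = curves$slope[i] * levels + curves$intercept[i])))
plain(cal, "calibration_synthetic.csv")

## Spike-recovery replicates, three fortification levels per compound.
rec_spec <- expand.grid(level = c(0.05, 0.5, 2.0),
                        compound = c("pyraclostrobin", "cyazofamid", "CCIM"),
                        stringsAsFactors = FALSE)
rec_spec$recovery <- c(0.84, 0.94, 0.89, 0.92, 0.98, 0.95, 0.99, 1.04, 1.01)
rec_spec$rsd <- c(9, 6, 7, 5, 3, 4, 3, 2, 2)
rec <- do.call(rbind, lapply(seq_len(nrow(rec_spec)), function(i)
  generate_recovery_table(rec_spec$level[i], rec_spec$recovery[i],
                          rec_spec$rsd[i], n_reps = 5,
                          compound = rec_spec$compound[i], seed = 400 + i)))
plain(rec, "recovery_synthetic.csv")

## Dissipation series: two sites per compound, reference half-life regimes.
decay_spec <- data.frame(
  compound = rep(c("pyraclostrobin", "cyazofamid", "CCIM"), each = 2),
  site = rep(c("site-A", "site-B"), 3),
  c0 = c(0.65, 0.45, 0.46, 0.30, 0.32, 0.25),
  t_half = c(17.8, 28.9, 4.3, 7.8, 16.9, 16.9))
decay <- do.call(rbind, lapply(seq_len(nrow(decay_spec)), function(i) {
  s <- generate_decay_series(trial_config(
    decay_spec$c0[i], log(2) / decay_spec$t_half[i],
    sample_days = c(0, 3, 7, 14, 21, 28), noise_cv = 0.08, loq = 0.05,
    compound = decay_spec$compound[i], site = decay_spec$site[i],
    seed = 500 + i))
  data.frame(compound = s$compound, site = s$site, day = s$days,
             residue_mg_per_kg = s$residues,
             censored = as.integer(s$censored))
}))
plain(decay, "decay_synthetic.csv")

## Final-residue observations (harvest samples), lognormal around the
## reference medians, censored at LOQ 0.05.
set.seed(42)
res_spec <- data.frame(compound = c("pyraclostrobin", "cyazofamid"),
                       median = c(0.13, 0.11), sdlog = c(1.2, 1.0))
residue <- do.call(rbind, lapply(seq_len(nrow(res_spec)), function(i) {
  v <- rlnorm(24, log(res_spec$median[i]), res_spec$sdlog[i])
  data.frame(compound = res_spec$compound[i],
             residue_mg_per_kg = round(v, 4),
             censored = as.integer(v < 0.05))
}))
plain(residue, "residue_synthetic.csv")

## Subgroup consumption samples; intake lognormal with mean matching the
## subgroup mean daily intake in subgroups_reference.csv.
sg_spec <- data.frame(
  name = c("general", "children", "women_childbearing"),
  bw = c(53.23, 16.14, 52.6), lp = c(0.570, 0.366, 0.297),
  fi = c(0.045, 0.055, 0.043), sigma = c(0.9, 0.9, 0.85))
cons <- do.call(rbind, lapply(seq_len(nrow(sg_spec)), function(i)
  generate_consumption_sample(population_config(
    sg_spec$name[i], bw_mean = sg_spec$bw[i],
    intake_mu = log(sg_spec$fi[i]) - sg_spec$sigma[i]^2 / 2,
    intake_sigma = sg_spec$sigma[i], n_individuals = 150,
    seed = 600 + i))))
cons$intake_kg_per_day <- round(cons$intake_kg_per_day, 6)
plain(cons, "consumption_synthetic.csv")

plain(data.frame(name = sg_spec$name, bw_kg = sg_spec$bw,
                 lp_kg_per_day = sg_spec$lp, fi_kg_per_day = sg_spec$fi,
                 v = 3),
      "subgroups_reference.csv")
plain(data.frame(compound = c("pyraclostrobin", "cyazofamid"),
                 adi = c(0.03, 0.2), arfd = c(0.05, 0.2)),
      "toxicology_reference.csv")
plain(data.frame(compound = c("pyraclostrobin", "cyazofamid"),
                 hr_mg_per_kg = c(1.88, 0.78),
                 stmr_mg_per_kg = c(0.13, 0.11)),
      "residue_summary_reference.csv")

writeLines(c(
  "calibration: calibration_synthetic.csv",
  "recovery: recovery_synthetic.csv",
  "decay: decay_synthetic.csv",
  "residue: residue_synthetic.csv",
  "residue_summary: residue_summary_reference.csv",
  "consumption: consumption_synthetic.csv",
  "subgroups: subgroups_reference.csv",
  "toxicology: toxicology_reference.csv",
  "censor_policy: half_loq",
  "variability_factor: 3",
  "n_iter: 1000",
  "seed: 20240314",
  "loq: 0.05",
  "output_dir: resrisk_run"),
  file.path(out_dir, "run_config.yaml"))

cat("fixtures written to", out_dir, "\n")
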