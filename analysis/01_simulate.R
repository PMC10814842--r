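#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs with known ground truth.
#
# Emulates a two-site supervised grape trial of pyraclostrobin and
# cyazofamid (plus the cyazofamid metabolite CCIM): first-order decay series
# in the reference half-life regimes, spike-recovery tables, final-residue
# samples around the reference medians, and lognormal consumption samples
# for three consumer subgroups. Writes everything under
# results/synthetic_inputs/ together with a pipeline config.

library(resrisk)

seed <- 20240314
out <- "results/synthetic_inputs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
put <- function(df, name) {
  write.csv(df, file.path(out, name), row.names = FALSE, quote = FALSE)
  cat("  wrote", file.path(out, name), "-", nrow(df), "rows\n")
}

cat("== simulating decay series ==\n")
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
    seed = seed + i))
  data.frame(compound = s$compound, site = s$site, day = s$days,
             residue_mg_per_kg = s$residues,
             censored = as.integer(s$censored))
}))
put(decay, "decay.csv")
cat(sprintf("  true half-lives: %s\n",
            paste(decay_spec$t_half, collapse = ", ")))

cat("== simulating spike-recovery tables ==\n")
rec_spec <- expand.grid(level = c(0.05, 0.5, 2.0),
                        compound = c("pyraclostrobin", "cyazofamid", "CCIM"),
                        stringsAsFactors = FALSE)
rec_spec$recovery <- c(0.84, 0.94, 0.89, 0.92, 0.98, 0.95, 0.99, 1.04, 1.01)
rec_spec$rsd <- c(9, 6, 7, 5, 3, 4, 3, 2, 2)
rec <- do.call(rbind, lapply(seq_len(nrow(rec_spec)), function(i)
  generate_recovery_table(rec_spec$level[i], rec_spec$recovery[i],
                          rec_spec$rsd[i], n_reps = 5,
                          compound = rec_spec$compound[i], seed = seed + 100 + i)))
put(rec, "recovery.csv")

cat("== reconstructing calibration tables from the reference lines ==\n")
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
put(cal, "calibration.csv")

cat("== simulating final-residue and consumption samples ==\n")
set.seed(seed)
res_spec <- data.frame(compound = c("pyraclostrobin", "cyazofamid"),
                       median = c(0.13, 0.11), sdlog = c(1.2, 1.0))
residue <- do.call(rbind, lapply(seq_len(nrow(res_spec)), function(i) {
  v <- rlnorm(24, log(res_spec$median[i]), res_spec$sdlog[i])
  data.frame(compound = res_spec$compound[i],
             residue_mg_per_kg = round(v, 4),
             censored = as.integer(v < 0.05))
}))
put(residue, "residue.csv")

sg_spec <- data.frame(
  name = c("general", "children", "women_childbearing"),
  bw = c(53.23, 16.14, 52.6), lp = c(0.570, 0.366, 0.297),
  fi = c(0.045, 0.055, 0.043), sigma = c(0.9, 0.9, 0.85))
cons <- do.call(rbind, lapply(seq_len(nrow(sg_spec)), function(i)
  generate_consumption_sample(population_config(
    sg_spec$name[i], bw_mean = sg_spec$bw[i],
    intake_mu = log(sg_spec$fi[i]) - sg_spec$sigma[i]^2 / 2,
    intake_sigma = sg_spec$sigma[i], n_individuals = 150,
    seed = seed + 200 + i))))
put(cons, "consumption.csv")

put(data.frame(name = sg_spec$name, bw_kg = sg_spec$bw,
               lp_kg_per_day = sg_spec$lp, fi_kg_per_day = sg_spec$fi, v = 3),
    "subgroups.csv")
put(data.frame(compound = c("pyraclostrobin", "cyazofamid"),
               adi = c(0.03, 0.2), arfd = c(0.05, 0.2)),
    "toxicology.csv")
put(data.frame(compound = c("pyraclostrobin", "cyazofamid"),
               hr_mg_per_kg = c(1.88, 0.78),
               stmr_mg_per_kg = c(0.13, 0.11)),
    "residue_summary.csv")

writeLines(c(
  "calibration: calibration.csv",
  "recovery: recovery.csv",
  "decay: decay.csv",
  "residue: residue.csv",
  "residue_summary: residue_summary.csv",
  "consumption: consumption.csv",
  "subgroups: subgroups.csv",
  "toxicology: toxicology.csv",
  "censor_policy: half_loq",
  "variability_factor: 3",
  "n_iter: 1000",
  sprintf("seed: %d", seed),
  "loq: 0.05",
  "output_dir: ../pipeline"),
  file.path(out, "run_config.yaml"))
cat("  wrote", file.path(out, "run_config.yaml"), "\n")
cat("done; downstream stages read from", out, "\n")
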