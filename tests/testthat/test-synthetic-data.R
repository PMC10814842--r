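test_that("noiseless decay series lie exactly on the first-order curve", {
  cases <- list(list(c0 = 1, k = log(2) / 10, days = c(0, 10),
                     expect = c(1, 0.5)),
                list(c0 = 0.65, k = log(2) / 17.8, days = c(0, 17.8),
                     expect = c(0.65, 0.325)))
  for (cs in cases) {
    s <- generate_decay_series(trial_config(cs$c0, cs$k, cs$days))
    expect_equal(s$residues, cs$expect, tolerance = 1e-12)
  }
  # dense grid, exact curve membership
  cfg <- trial_config(0.46, log(2) / 4.3, c(0, 1, 2, 5, 9, 14, 21, 28))
  s <- generate_decay_series(cfg)
  expect_equal(s$residues, 0.46 * exp(-log(2) / 4.3 * s$days),
               tolerance = 1e-12)
})

test_that("decay generator is reproducible under a fixed seed and noisy draws stay positive", {
  cfg <- trial_config(1, 0.1, c(0, 3, 7, 14, 21, 28), noise_cv = 0.1,
                      seed = 11)
  a <- generate_decay_series(cfg)
  b <- generate_decay_series(cfg)
  expect_identical(a$residues, b$residues)
  cfg2 <- trial_config(1, 0.1, c(0, 3, 7, 14, 21, 28), noise_cv = 0.1,
                       seed = 12)
  expect_false(identical(a$residues, generate_decay_series(cfg2)$residues))
  expect_true(all(a$residues > 0))
})

test_that("noise has median one and the requested coefficient of variation", {
  cfg <- trial_config(1, 1e-9, c(0, seq_len(4999)), noise_cv = 0.25,
                      seed = 7)
  eps <- generate_decay_series(cfg)$residues  # mean curve ~ 1 throughout
  expect_equal(median(eps), 1, tolerance = 0.03)
  expect_equal(sd(eps) / mean(eps), 0.25, tolerance = 0.03)
})

test_that("sub-LOQ values are flagged censored with the latent value retained", {
  cfg <- trial_config(1, log(2) / 5, c(0, 5, 10, 15, 20, 25), loq = 0.1)
  s <- generate_decay_series(cfg)
  expect_identical(s$censored, s$residues < 0.1)
  expect_true(any(s$censored))
  expect_true(all(s$residues[s$censored] > 0))  # latent value kept
})

test_that("trial_config rejects invalid fields by name", {
  expect_error(trial_config(-1, 0.1, c(0, 1)), "c0_true")
  expect_error(trial_config(1, 0, c(0, 1)), "k_true")
  expect_error(trial_config(1, 0.1, c(1, 2)), "sample_days")
  expect_error(trial_config(1, 0.1, c(0, 5, 3)), "sample_days")
  expect_error(trial_config(1, 0.1, c(0, 1), noise_cv = -0.1), "noise_cv")
  expect_error(trial_config(1, 0.1, c(0, 1), loq = -1), "loq")
})

test_that("consumption sample matches its generating distribution", {
  # degenerate: sigma = 0 collapses to a point mass at exp(mu)
  cfg0 <- population_config("g", bw_mean = 60, intake_mu = log(0.05),
                            intake_sigma = 0, n_individuals = 10)
  s0 <- generate_consumption_sample(cfg0)
  expect_equal(s0$intake_kg_per_day, rep(0.05, 10), tolerance = 1e-12)
  expect_equal(s0$bw_kg, rep(60, 10))

  # mean log-intake within 3 standard errors of mu
  cfg <- population_config("g", bw_mean = 60, intake_mu = -3,
                           intake_sigma = 0.8, n_individuals = 1000,
                           seed = 21)
  s <- generate_consumption_sample(cfg)
  se <- 0.8 / sqrt(1000)
  expect_lt(abs(mean(log(s$intake_kg_per_day)) - (-3)), 3 * se)
  expect_true(all(s$intake_kg_per_day > 0))

  # reproducibility and seed sensitivity
  expect_identical(generate_consumption_sample(cfg), s)
  cfg2 <- population_config("g", 60, -3, 0.8, 1000, seed = 22)
  expect_false(identical(generate_consumption_sample(cfg2)$intake_kg_per_day,
                         s$intake_kg_per_day))

  # bodyweight variability: truncated-normal draws are positive with the
  # requested mean
  cfgbw <- population_config("g", bw_mean = 16, bw_cv = 0.2, intake_mu = -3,
                             intake_sigma = 0.5, n_individuals = 2000,
                             seed = 23)
  sbw <- generate_consumption_sample(cfgbw)
  expect_true(all(sbw$bw_kg > 0))
  expect_equal(mean(sbw$bw_kg), 16, tolerance = 0.05)

  expect_error(population_config("g", 60, -3, 0.5, 0), "n_individuals")
})

test_that("recovery table generator hits its target recovery and spread", {
  # rsd = 0: all replicates identical at level x recovery
  t0 <- generate_recovery_table(0.05, 1.0, rsd = 0, n_reps = 4)
  expect_equal(t0$measured_mg_per_kg, rep(0.05, 4))

  # re-estimating recovery from a generated sample lands near the target
  tab <- generate_recovery_table(0.5, 0.92, rsd = 5, n_reps = 5, seed = 31)
  r <- compute_recovery(tab$measured_mg_per_kg, 0.5)
  expect_lt(abs(r$mean_recovery - 92), 3 * 5 / sqrt(5))

  expect_error(generate_recovery_table(0.5, 0.92, rsd = -1, n_reps = 5),
               "rsd")
  expect_error(generate_recovery_table(0.5, 0.92, rsd = 5, n_reps = 1),
               "n_reps")
})
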