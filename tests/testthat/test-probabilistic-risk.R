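test_that("lognormal fitting recovers parameters on log-transformed data", {
  # constant sample: point mass
  f0 <- fit_lognormal(rep(0.25, 5))
  expect_equal(f0$mu, log(0.25))
  expect_equal(f0$sigma, 0)

  # parameter recovery within 3 standard errors at n = 2000
  set.seed(51)
  x <- rlnorm(2000, 0, 0.5)
  f <- fit_lognormal(x)
  expect_lt(abs(f$mu - 0), 3 * 0.5 / sqrt(2000))
  expect_equal(f$sigma, 0.5, tolerance = 0.05)
  expect_equal(f$n_fit, 2000L)

  # independent cross-check against fitdistrplus MLE on the same sample
  ref <- fitdistrplus::fitdist(x, "lnorm", method = "mle")
  expect_equal(f$mu, unname(ref$estimate["meanlog"]), tolerance = 1e-4)
  expect_equal(f$sigma, unname(ref$estimate["sdlog"]), tolerance = 1e-4)
})

test_that("lognormal fitting applies censoring policies before the transform", {
  obs <- c(0.2, 0.3, 0.01, 0.4)
  cen <- c(FALSE, FALSE, TRUE, FALSE)
  f_drop <- fit_lognormal(obs, cen, "drop", loq = 0.05)
  expect_equal(f_drop$n_fit, 3L)
  expect_equal(f_drop$mu, mean(log(c(0.2, 0.3, 0.4))))
  f_half <- fit_lognormal(obs, cen, "half_loq", loq = 0.05)
  expect_equal(f_half$mu, mean(log(c(0.2, 0.3, 0.025, 0.4))))
  f_loq <- fit_lognormal(obs, cen, "loq", loq = 0.05)
  expect_gt(f_loq$mu, f_half$mu)
  # a zero observation is only usable if dropped
  expect_error(fit_lognormal(c(0, 0.2, 0.3)), "positive")
  expect_equal(fit_lognormal(c(0, 0.2, 0.3), c(TRUE, FALSE, FALSE), "drop",
                             loq = 0.05)$n_fit, 2L)
  expect_error(fit_lognormal(0.2), "2 usable")
})

test_that("degenerate simulation collapses to the deterministic model", {
  sg <- ref_subgroups()$general
  sim <- exposure_simulation(sg,
                             lognormal_params(log(0.045), 0),
                             lognormal_params(log(0.13), 0),
                             n_iter = 500, seed = 61)
  sim <- simulate_exposure(sim)
  expected <- 0.045 * 0.13 / 53.23
  expect_equal(sim$samples, rep(expected, 500))
  rep_ <- percentile_report(sim, reference = 0.03, compound = "x")
  expect_true(all(rep_$percent_of_reference ==
                    rep_$percent_of_reference[1]))
  # chronic P50 equals the deterministic risk quotient exactly
  det <- risk_quotient(edi(0.13, 0.045, 53.23), 0.03)$percent
  expect_equal(rep_$percent_of_reference[rep_$percentile == "P50"], det)
})

test_that("simulation is reproducible under its seed", {
  sg <- ref_subgroups()$children
  mk <- function(seed) simulate_exposure(exposure_simulation(
    sg, lognormal_params(-3.3, 0.9), lognormal_params(log(0.13), 1.2),
    n_iter = 1000, seed = seed))
  expect_identical(mk(71)$samples, mk(71)$samples)
  expect_false(identical(mk(71)$samples, mk(72)$samples))
  expect_true(all(mk(71)$samples >= 0))
  expect_length(mk(71)$samples, 1000)
})

test_that("single-food quantiles match the closed-form lognormal product", {
  sg <- population_subgroup("g", bw = 53.23)
  mu_x <- -3.3; s_x <- 0.9
  mu_c <- log(0.13); s_c <- 1.2
  sim <- simulate_exposure(exposure_simulation(
    sg, lognormal_params(mu_x, s_x), lognormal_params(mu_c, s_c),
    n_iter = 20000, seed = 81))
  mu_y <- mu_x + mu_c - log(53.23)
  s_y <- sqrt(s_x^2 + s_c^2)
  for (p in c(0.5, 0.9, 0.95)) {
    expect_equal(unname(quantile(sim$samples, p, type = 7)),
                 qlnorm(p, mu_y, s_y), tolerance = 0.05)
  }
})

test_that("percentile reports are monotone and correctly referenced", {
  expect_equal(unique(percentile_report(rep(2, 50), 1)$percent_of_reference),
               200)
  r <- percentile_report(rep(0.03, 10), 0.03)
  expect_true(all(r$percent_of_reference == 100))
  # monotonicity across random samples
  set.seed(91)
  for (i in 1:20) {
    s <- rlnorm(500, runif(1, -5, 0), runif(1, 0.1, 1.5))
    r <- percentile_report(s, 0.03)
    expect_true(all(diff(r$percent_of_reference) >= 0))
  }
  expect_error(percentile_report(numeric(0), 1), "samples")
  expect_error(percentile_report(rep(1, 5), 0), "reference")
  expect_error(percentile_report(rep(1, 5), 1, levels = c(0, 50)), "levels")
})

test_that("P95 is stable when the iteration count doubles", {
  sg <- ref_subgroups()$general
  mk <- function(n, seed) simulate_exposure(exposure_simulation(
    sg, lognormal_params(-3.3, 0.9), lognormal_params(log(0.13), 1.2),
    n_iter = n, seed = seed))
  s1k <- mk(1000, 101)$samples
  s2k <- mk(2000, 102)$samples
  p95_1 <- quantile(s1k, 0.95, names = FALSE)
  p95_2 <- quantile(s2k, 0.95, names = FALSE)
  set.seed(103)
  boot <- replicate(200, quantile(sample(s1k, replace = TRUE), 0.95,
                                  names = FALSE))
  expect_lt(abs(p95_2 - p95_1), 3 * sd(boot))
})

test_that("stratified runs cover subgroups, record failures, and rank intake", {
  sgs <- ref_subgroups()
  tox <- data.frame(compound = "pyraclostrobin", adi = 0.03, arfd = 0.05)
  set.seed(111)
  residue <- data.frame(compound = "pyraclostrobin",
                        residue_mg_per_kg = rlnorm(30, log(0.13), 1.2),
                        censored = 0)
  cons <- rbind(
    generate_consumption_sample(population_config(
      "general", 53.23, log(0.045) - 0.405, 0.9, 200, seed = 112)),
    generate_consumption_sample(population_config(
      "children", 16.14, log(0.055) - 0.405, 0.9, 200, seed = 113)))

  run <- stratified_run(sgs, residue, cons, tox, "chronic",
                        n_iter = 2000, seed = 114)
  # women subgroup has no consumption data: recorded, run continued
  expect_length(run$reports, 2L)
  expect_length(run$errors, 1L)
  expect_match(run$errors[[1]], "women_childbearing")

  # children consume more per kg bodyweight: dominance at every level
  gen <- run$reports[["general x pyraclostrobin"]]
  chi <- run$reports[["children x pyraclostrobin"]]
  expect_true(all(chi$percent_of_reference > gen$percent_of_reference))

  # acute mode rescales by ARfD instead of ADI
  run_ac <- stratified_run(sgs["general"], residue, cons, tox, "acute",
                           n_iter = 2000, seed = 114)
  ga <- run_ac$reports[["general x pyraclostrobin"]]
  expect_equal(ga$percent_of_reference,
               gen$percent_of_reference * 0.03 / 0.05)
})
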