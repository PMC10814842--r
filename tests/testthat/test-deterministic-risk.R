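test_that("total residue sums parent and converted metabolite", {
  expect_identical(total_residue(0.31, 0.47), 0.78)
  expect_equal(total_residue(0.31, 0), 0.31)
  expect_equal(total_residue(0.31, 0.47, conversion_factor = 0.5),
               0.31 + 0.235)
  # both below LOQ 0.05 under half-LOQ substitution
  expect_equal(total_residue(0.025, 0.025), 0.05)
  expect_error(total_residue(-0.1, 0.2), "parent")
  expect_error(total_residue(0.1, 0.2, conversion_factor = 0), "conversion")
})

test_that("NESTI is LP x HR x v / bw", {
  sg <- ref_subgroups()
  expect_equal(nesti(sg$children, 1.88), 0.366 * 1.88 * 3 / 16.14)
  expect_equal(nesti(sg$children, 1.88), 0.12790, tolerance = 1e-4)
  expect_equal(nesti(sg$children, 0), 0)
  unit <- population_subgroup("u", bw = 2, lp = 2, variability_factor = 1)
  expect_equal(nesti(unit, 1), 1)
  expect_error(nesti(list(bw = 1), 1), "subgroup")
  expect_error(population_subgroup("b", bw = 0, lp = 1), "bw")
})

test_that("acute %ARfD reproduces the reference subgroup values within 1%", {
  sg <- ref_subgroups()
  tox <- ref_toxicology()
  # pyraclostrobin, HR 1.88, ARfD 0.05
  pyr <- vapply(sg, function(s)
    percent_arfd(nesti(s, 1.88), tox$pyraclostrobin$arfd)$percent, numeric(1))
  expect_equal(unname(pyr), c(120.86, 256.36, 63.73), tolerance = 0.01)
  # cyazofamid total residue, HR 0.78, ARfD 0.2
  cya <- vapply(sg, function(s)
    percent_arfd(nesti(s, 0.78), tox$cyazofamid$arfd)$percent, numeric(1))
  expect_equal(unname(cya), c(12.54, 26.59, 6.61), tolerance = 0.01)
  # acceptability: strictly above 100% is flagged
  expect_false(percent_arfd(pyr[["general"]] / 100 * 0.05, 0.05)$acceptable)
  expect_true(all(vapply(cya, function(p) p < 100, logical(1))))
  expect_equal(percent_arfd(0.05, 0.05)$percent, 100)
  expect_true(percent_arfd(0.05, 0.05)$acceptable)
  expect_error(percent_arfd(0.1, 0), "arfd")
})

test_that("EDI sums residue x intake over foods per kg bodyweight", {
  expect_equal(edi(0, 0.1, 60), 0)
  expect_equal(edi(0.13, 0.1, 65), 0.0002)
  # linearity across foods
  expect_equal(edi(c(0.13, 0.2), c(0.1, 0.05), 65),
               edi(0.13, 0.1, 65) + edi(0.2, 0.05, 65))
  expect_error(edi(0.1, 0.1, 0), "bw")
  expect_error(edi(c(0.1, 0.2), 0.1, 60), "stmr/fi")
})

test_that("chronic risk quotient is 100 x EDI/ADI with a >100% flag", {
  expect_equal(risk_quotient(0.03, 0.03)$percent, 100)
  expect_true(risk_quotient(0.03, 0.03)$acceptable)
  expect_false(risk_quotient(0.031, 0.03)$acceptable)
  expect_equal(risk_quotient(0, 0.03)$percent, 0)
  expect_error(risk_quotient(0.1, 0), "adi")
})

test_that("risk measures are homogeneous in residues and scale-free in dose ratios", {
  sg <- ref_subgroups()$children
  for (hr in c(0.1, 0.78, 1.88))
    expect_equal(nesti(sg, 2 * hr), 2 * nesti(sg, hr))
  expect_equal(edi(2 * 0.13, 0.1, 65), 2 * edi(0.13, 0.1, 65))
  for (c in c(0.5, 3)) {
    expect_equal(percent_arfd(c * 0.06, c * 0.05)$percent,
                 percent_arfd(0.06, 0.05)$percent)
    expect_equal(risk_quotient(c * 0.001, c * 0.03)$percent,
                 risk_quotient(0.001, 0.03)$percent)
  }
})

test_that("deterministic risk table matches the scalar operations", {
  sg <- ref_subgroups()
  residues <- data.frame(compound = c("pyraclostrobin", "cyazofamid"),
                         hr_mg_per_kg = c(1.88, 0.78),
                         stmr_mg_per_kg = c(0.13, 0.11))
  tox <- data.frame(compound = c("pyraclostrobin", "cyazofamid"),
                    adi = c(0.03, 0.2), arfd = c(0.05, 0.2))
  tab <- deterministic_risk_table(sg, residues, tox)
  expect_equal(nrow(tab), 6L)
  row <- tab[tab$compound == "pyraclostrobin" & tab$subgroup == "children", ]
  expect_equal(row$nesti, nesti(sg$children, 1.88))
  expect_equal(row$percent_arfd,
               percent_arfd(nesti(sg$children, 1.88), 0.05)$percent)
  expect_equal(row$edi, edi(0.13, sg$children$fi, sg$children$bw))
  expect_equal(row$acceptable, 0L)  # acute > 100%
  cy <- tab[tab$compound == "cyazofamid", ]
  expect_true(all(cy$acceptable == 1L))
  expect_error(deterministic_risk_table(
    sg, data.frame(compound = "unknown", hr_mg_per_kg = 1,
                   stmr_mg_per_kg = 0.5), tox), "toxicology")
})
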