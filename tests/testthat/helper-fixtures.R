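# Shared reference objects: the three Chinese-population subgroups and the
# JMPR reference doses used throughout the package examples.

ref_subgroups <- function() {
  list(
    general  = population_subgroup("general", bw = 53.23, lp = 0.570,
                                   fi = 0.045),
    children = population_subgroup("children", bw = 16.14, lp = 0.366,
                                   fi = 0.055),
    women    = population_subgroup("women_childbearing", bw = 52.6,
                                   lp = 0.297, fi = 0.043)
  )
}

ref_toxicology <- function() {
  list(
    pyraclostrobin = toxicology_reference("pyraclostrobin", adi = 0.03,
                                          arfd = 0.05),
    cyazofamid = toxicology_reference("cyazofamid", adi = 0.2, arfd = 0.2)
  )
}

# Noiseless decay series on an exact first-order curve.
exact_series <- function(c0, t_half, days = c(0, 3, 7, 14, 21, 28)) {
  generate_decay_series(trial_config(c0, log(2) / t_half, days))
}

fixture_path <- function(...) system.file("extdata", ..., package = "resrisk")
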