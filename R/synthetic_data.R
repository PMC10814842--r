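#' Configuration for a synthetic dissipation trial
#'
#' Holds the ground-truth parameters of a first-order decay experiment,
#' \eqn{C_t = C_0 e^{-kt}}, plus the observation noise and censoring limit
#' used when the trial is simulated.
#'
#' @param c0_true True initial deposit, mg/kg. Must be > 0.
#' @param k_true True first-order rate constant, per day. Must be > 0.
#' @param sample_days Sampling days, non-negative, sorted ascending, starting
#'   at day 0 (deposit samples are taken at application).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise (median 1). `0` gives noiseless observations.
#' @param loq Limit of quantification, mg/kg; observations below it are
#'   flagged censored. `0` disables censoring.
#' @param compound,site Identifiers carried into the generated series.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#'
#' @return An object of class `"trial_config"`.
#' @seealso [generate_decay_series()]
#' @export
trial_config <- function(c0_true, k_true, sample_days,
                         noise_cv = 0, loq = 0,
                         compound = "compound", site = "site-1",
                         seed = NULL) {
  check_scalar_num(c0_true, "c0_true", positive = TRUE)
  check_scalar_num(k_true, "k_true", positive = TRUE)
  check_scalar_num(noise_cv, "noise_cv", nonneg = TRUE)
  check_scalar_num(loq, "loq", nonneg = TRUE)
  if (!is.numeric(sample_days) || length(sample_days) < 1L ||
      any(!is.finite(sample_days)) || any(sample_days < 0))
    stop_field("sample_days", "must be finite non-negative days")
  if (is.unsorted(sample_days))
    stop_field("sample_days", "must be sorted ascending")
  if (sample_days[1] != 0)
    stop_field("sample_days", "must start at day 0")
  if (!is.null(seed)) check_count(seed, "seed", min = -.Machine$integer.max)
  structure(
    list(c0_true = c0_true, k_true = k_true,
         sample_days = as.numeric(sample_days),
         noise_cv = noise_cv, loq = loq,
         compound = as.character(compound), site = as.character(site),
         seed = seed),
    class = "trial_config"
  )
}

#' Configuration for a synthetic consumption survey subgroup
#'
#' Parameters of the generative model behind a consumer subgroup: lognormal
#' daily commodity intake and (optionally variable) bodyweight. Bodyweight
#' defaults to a point mass (`bw_cv = 0`) because reference assessments use a
#' fixed subgroup weight; setting `bw_cv > 0` draws from a normal truncated
#' at zero.
#'
#' @param subgroup_name Label for the subgroup.
#' @param bw_mean Mean bodyweight, kg. Must be > 0.
#' @param bw_cv Coefficient of variation of bodyweight (unitless, >= 0).
#' @param intake_mu Log-scale location of daily intake (log kg/day).
#' @param intake_sigma Log-scale scale of daily intake (>= 0).
#' @param n_individuals Number of individuals to draw (>= 1).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#'
#' @return An object of class `"population_config"`.
#' @seealso [generate_consumption_sample()]
#' @export
population_config <- function(subgroup_name, bw_mean, intake_mu, intake_sigma,
                              n_individuals, bw_cv = 0, seed = NULL) {
  check_scalar_num(bw_mean, "bw_mean", positive = TRUE)
  check_scalar_num(bw_cv, "bw_cv", nonneg = TRUE)
  check_scalar_num(intake_mu, "intake_mu")
  check_scalar_num(intake_sigma, "intake_sigma", nonneg = TRUE)
  n_individuals <- check_count(n_individuals, "n_individuals", min = 1L)
  if (!is.null(seed)) check_count(seed, "seed", min = -.Machine$integer.max)
  structure(
    list(subgroup_name = as.character(subgroup_name),
         bw_mean = bw_mean, bw_cv = bw_cv,
         intake_mu = intake_mu, intake_sigma = intake_sigma,
         n_individuals = n_individuals, seed = seed),
    class = "population_config"
  )
}

#' Simulate a residue dissipation time series
#'
#' Draws observations \eqn{y(t) = C_0 e^{-kt} \varepsilon} with
#' \eqn{\varepsilon} lognormal with median 1 and coefficient of variation
#' `noise_cv`. Values below the LOQ are flagged censored; the latent numeric
#' value is retained so downstream censoring policies can be compared against
#' the truth.
#'
#' @param config A [trial_config()].
#' @return A [dissipation_series()] with one observation per sampling day.
#' @examples
#' cfg <- trial_config(c0_true = 1, k_true = log(2) / 10,
#'                     sample_days = c(0, 10), noise_cv = 0)
#' generate_decay_series(cfg)$residues  # exactly c(1, 0.5)
#' @export
generate_decay_series <- function(config) {
  if (!inherits(config, "trial_config"))
    stop_field("config", "must be a `trial_config`")
  mean_curve <- config$c0_true * exp(-config$k_true * config$sample_days)
  eps <- if (config$noise_cv > 0) {
    sigma <- lognormal_sigma_from_cv(config$noise_cv)
    with_seed(config$seed,
              stats::rlnorm(length(mean_curve), meanlog = 0, sdlog = sigma))
  } else rep(1, length(mean_curve))
  values <- mean_curve * eps
  dissipation_series(
    compound = config$compound, site = config$site,
    days = config$sample_days, residues = values,
    censored = values < config$loq, loq = config$loq
  )
}

#' Simulate a subgroup consumption sample
#'
#' Intake is drawn lognormal(`intake_mu`, `intake_sigma`); bodyweight is
#' drawn from a normal with mean `bw_mean` and CV `bw_cv`, truncated at zero
#' by rejection (a point mass when `bw_cv = 0`).
#'
#' @param config A [population_config()].
#' @return A data frame with columns `subgroup`, `intake_kg_per_day`, `bw_kg`.
#' @export
generate_consumption_sample <- function(config) {
  if (!inherits(config, "population_config"))
    stop_field("config", "must be a `population_config`")
  n <- config$n_individuals
  with_seed(config$seed, {
    intake <- if (config$intake_sigma > 0)
      stats::rlnorm(n, config$intake_mu, config$intake_sigma)
    else rep(exp(config$intake_mu), n)
    bw <- if (config$bw_cv > 0) {
      sd <- config$bw_mean * config$bw_cv
      out <- stats::rnorm(n, config$bw_mean, sd)
      while (any(bad <- out <= 0))
        out[bad] <- stats::rnorm(sum(bad), config$bw_mean, sd)
      out
    } else rep(config$bw_mean, n)
    data.frame(subgroup = config$subgroup_name,
               intake_kg_per_day = intake, bw_kg = bw)
  })
}

#' Simulate a spike-recovery table
#'
#' Generates replicate measured concentrations for a fortification experiment
#' with target mean `true_level * recovery_mean` and relative standard
#' deviation approximately `rsd` percent (normal measurement error).
#'
#' @param true_level Spiked concentration, mg/kg (> 0).
#' @param recovery_mean Expected recovered fraction (e.g. 0.92 for 92%).
#' @param rsd Target relative standard deviation, percent (>= 0).
#' @param n_reps Number of replicates (>= 2).
#' @param compound Identifier carried into the table.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A data frame with columns `compound`, `spike_mg_per_kg`,
#'   `replicate`, `measured_mg_per_kg`.
#' @export
generate_recovery_table <- function(true_level, recovery_mean, rsd, n_reps,
                                    compound = "compound", seed = NULL) {
  check_scalar_num(true_level, "true_level", positive = TRUE)
  check_scalar_num(recovery_mean, "recovery_mean", positive = TRUE)
  check_scalar_num(rsd, "rsd", nonneg = TRUE)
  n_reps <- check_count(n_reps, "n_reps", min = 2L)
  target <- true_level * recovery_mean
  measured <- if (rsd > 0)
    with_seed(seed, stats::rnorm(n_reps, target, target * rsd / 100))
  else rep(target, n_reps)
  data.frame(compound = as.character(compound),
             spike_mg_per_kg = true_level,
             replicate = seq_len(n_reps),
             measured_mg_per_kg = measured)
}
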